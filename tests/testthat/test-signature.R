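# Signature construction: RF redundancy filter, univariate Cox trimming,
# PCA model, scoring, cutpoint, orientation.

test_that("RF filter keeps informative genes and removes most noise", {
  kept_info <- integer(0)
  noise_removed <- numeric(0)
  for (s in 1:10) {
    set.seed(s)
    n <- 200
    truth <- rep(c("A", "B"), each = n / 2)
    x <- matrix(rnorm(100 * n), 100, n,
                dimnames = list(c(sprintf("info%02d", 1:5),
                                  sprintf("noise%02d", 1:95)),
                                sprintf("s%03d", 1:n)))
    x[1:5, truth == "B"] <- x[1:5, truth == "B"] + 3
    kept <- rf_redundancy_filter(x, truth, n_trees = 300, seed = s)
    kept_info <- c(kept_info, sum(grepl("^info", kept)))
    noise_removed <- c(noise_removed, mean(!sprintf("noise%02d", 1:95) %in% kept))
  }
  expect_equal(median(kept_info), 5)
  expect_gte(median(noise_removed), 0.8)
})

test_that("RF filter under shuffled labels keeps roughly half at random", {
  set.seed(21)
  n <- 120
  x <- matrix(rnorm(60 * n), 60, n,
              dimnames = list(sprintf("g%02d", 1:60), sprintf("s%03d", 1:n)))
  labels <- sample(rep(c("A", "B"), each = n / 2))
  kept <- rf_redundancy_filter(x, labels, n_trees = 300, seed = 4)
  expect_gt(length(kept) / 60, 0.3)
  expect_lt(length(kept) / 60, 0.7)
})

test_that("RF filter is seed-deterministic and skips below 10 genes", {
  d <- make_de_matrix(n_genes = 40, n_per_group = 30, n_true = 10,
                      shift = 2, seed = 5)
  a <- rf_redundancy_filter(d$x, d$labels, n_trees = 200, seed = 9)
  b <- rf_redundancy_filter(d$x, d$labels, n_trees = 200, seed = 9)
  expect_identical(a, b)
  expect_warning(all_pass <- rf_redundancy_filter(d$x[1:5, ], d$labels,
                                                  seed = 1),
                 "skipped")
  expect_identical(all_pass, rownames(d$x)[1:5])
})

test_that("univariate Cox coefficient matches grid maximization of the partial likelihood", {
  # 6 subjects, no ties, all events; Efron = Breslow here
  time <- c(1, 2, 3, 4, 5, 6)
  event <- rep(1, 6)
  x <- matrix(c(1.2, -0.5, 0.3, -1.1, 0.8, -0.7), 1, 6,
              dimnames = list("g1", sprintf("s%d", 1:6)))
  z <- as.numeric(scale(x[1, ]))
  log_pl <- function(beta) {
    ord <- order(time)
    lp <- 0
    for (i in seq_along(ord)) {
      risk <- ord[i:length(ord)]
      lp <- lp + beta * z[ord[i]] - log(sum(exp(beta * z[risk])))
    }
    lp
  }
  beta_grid <- optimize(log_pl, c(-5, 5), maximum = TRUE, tol = 1e-9)$maximum
  fit <- cox_fit(time, event, data.frame(expr = z))
  expect_lt(abs(fit$coefficients$coef[1] - beta_grid), 1e-4)
})

test_that("Cox filter retains null genes at the nominal rate and strong genes always", {
  set.seed(31)
  n <- 150
  sv <- make_survival(n = n, hr = 1, seed = 31)
  x <- matrix(rnorm(500 * n), 500, n,
              dimnames = list(sprintf("g%03d", 1:500), sprintf("s%03d", 1:n)))
  kept <- suppressWarnings(
    cox_univariate_filter(x, sv$time, sv$event, alpha = 0.05))
  expect_gt(length(kept) / 500, 0.02)
  expect_lt(length(kept) / 500, 0.09)

  hits <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    n <- 300
    z <- rnorm(n)
    t_ev <- rexp(n, 0.1 * 2^z)          # HR 2 per SD
    cens <- rexp(n, 0.04)
    time <- pmin(t_ev, cens); event <- as.integer(t_ev <= cens)
    g <- matrix(z, 1, n, dimnames = list("g1", sprintf("s%03d", 1:n)))
    length(cox_univariate_filter(g, time, event)) == 1L
  }, logical(1))
  expect_equal(mean(hits), 1)
})

test_that("PCA model matches a dense eigendecomposition oracle", {
  set.seed(5)
  E <- matrix(rnorm(12), 3, 4,
              dimnames = list(c("g1", "g2", "g3"), sprintf("s%d", 1:4)))
  mod <- fit_signature(E, rownames(E))
  z <- t(scale(t(E)))
  ev <- eigen(tcrossprod(z) / (ncol(E) - 1))
  for (j in 1:2) {
    L <- ev$vectors[, j]
    if (L[which.max(abs(L))] < 0) L <- -L
    expect_lt(max(abs(mod$loadings[, j] - L)), 1e-9)
  }
  expect_lt(abs(sum(mod$loadings[, 1] * mod$loadings[, 2])), 1e-9)
  expect_equal(unname(colSums(mod$loadings^2)), c(1, 1), tolerance = 1e-12)
  expect_identical(mod, fit_signature(E, rownames(E)))   # deterministic
})

test_that("two perfectly correlated genes put all variance on PC1", {
  E <- rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 4, 6, 8) + 5)
  colnames(E) <- sprintf("s%d", 1:4)
  mod <- fit_signature(E, c("g1", "g2"))
  expect_equal(mod$explained[1], 1, tolerance = 1e-12)
  expect_lt(mod$explained[2], 1e-12)
})

test_that("scores are centered projections and additive in the two PCs", {
  d <- make_de_matrix(n_genes = 10, n_per_group = 10, n_true = 4,
                      shift = 2, seed = 7)
  mod <- fit_signature(d$x, rownames(d$x))
  sc <- score_samples(d$x, mod)
  z <- (d$x - rowMeans(d$x)) / apply(d$x, 1, sd)
  proj1 <- as.numeric(t(z) %*% mod$loadings[, 1])
  proj2 <- as.numeric(t(z) %*% mod$loadings[, 2])
  expect_equal(sc$score, proj1 + proj2, tolerance = 1e-12)

  # a sample sitting exactly at the gene means scores 0
  x2 <- cbind(d$x, mean_sample = rowMeans(d$x))
  mod2 <- fit_signature(x2, rownames(x2))
  sc3 <- score_samples(x2, mod2, standardize = "training")
  expect_lt(abs(sc3$score[ncol(x2)]), 1e-9)
})

test_that("a hand-built 2-gene model reproduces the arithmetic oracle", {
  mod <- structure(list(
    genes = c("g1", "g2"),
    center = c(g1 = 5, g2 = 7),
    scale = c(g1 = 2, g2 = 2),
    loadings = matrix(rep(1 / sqrt(2), 4), 2,
                      dimnames = list(c("g1", "g2"), c("PC1", "PC2"))),
    explained = c(0.5, 0.5), oriented = FALSE), class = "signature_model")
  # standardized sample (1, 1): each projection = 2/sqrt(2) = sqrt(2)
  E <- matrix(c(7, 9), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  sc <- score_samples(E, mod, standardize = "training")
  expect_equal(sc$score, 2 * sqrt(2), tolerance = 1e-12)
})

test_that("score is invariant to gene order and to extra genes", {
  d <- make_de_matrix(n_genes = 12, n_per_group = 8, n_true = 4, seed = 8)
  genes <- rownames(d$x)[1:8]
  mod <- fit_signature(d$x, genes)
  base <- score_samples(d$x, mod)
  shuffled <- d$x[rev(rownames(d$x)), ]
  expect_equal(score_samples(shuffled, mod)$score, base$score,
               tolerance = 1e-12)
  extra <- rbind(d$x, extra1 = rnorm(ncol(d$x)))
  expect_equal(score_samples(extra, mod)$score, base$score,
               tolerance = 1e-12)
})

test_that("missing signature genes renormalize; below 80% present is an error", {
  d <- make_de_matrix(n_genes = 10, n_per_group = 10, n_true = 4, seed = 9)
  mod <- fit_signature(d$x, rownames(d$x))
  drop1 <- d$x[-1, ]
  sc <- score_samples(drop1, mod)         # 9/10 = 90% present: allowed
  present <- rownames(drop1)
  z <- (drop1 - rowMeans(drop1)) / apply(drop1, 1, sd)
  L <- mod$loadings[present, ]
  L <- sweep(L, 2, sqrt(colSums(L^2)), "/")
  expect_equal(sc$score, as.numeric(t(z) %*% (L[, 1] + L[, 2])),
               tolerance = 1e-12)
  expect_error(score_samples(d$x[-(1:3), ], mod), "g0001")
})

test_that("cutpoint: perfect separation, brute-force oracle, degenerate input", {
  sc <- c(1, 2, 3, 10, 11, 12)
  time <- c(1, 1.5, 2, 10, 10, 10)
  event <- c(1, 1, 1, 0, 0, 0)
  cut <- optimal_cutoff(sc, time, event, minprop = 0.1)
  expect_gt(as.numeric(cut), 3)
  expect_lt(as.numeric(cut), 10)

  expect_error(optimal_cutoff(rep(2, 6), time, event), "all scores are equal")
  expect_error(optimal_cutoff(sc, time, c(0, 0, 0, 0, 0, 1)), ">= 2 events")

  # independent slow oracle on a 20-sample toy: recompute the standardized
  # log-rank score statistic for every admissible split with plain loops
  set.seed(41)
  n <- 20
  score <- rnorm(n)
  sv <- make_survival(n = n, hr = 1.5, seed = 41)
  got <- optimal_cutoff(score, sv$time, sv$event, minprop = 0.1)
  # Nelson-Aalen scores by loop
  a <- numeric(n)
  for (i in 1:n) {
    H <- 0
    for (t in sort(unique(sv$time[sv$event == 1]))) {
      if (t <= sv$time[i]) H <- H + sum(sv$time == t & sv$event == 1) / sum(sv$time >= t)
    }
    a[i] <- sv$event[i] - H
  }
  u <- sort(unique(score))
  cands <- (u[-length(u)] + u[-1]) / 2
  best <- -Inf; best_c <- NA
  for (cc in cands) {
    m <- sum(score <= cc)
    if (m < 2 || n - m < 2) next
    s_low <- sum(a[score <= cc])
    v <- m * (n - m) / (n * (n - 1)) * sum((a - mean(a))^2)
    stat <- abs(s_low - m * mean(a)) / sqrt(v)
    if (stat > best) { best <- stat; best_c <- cc }
  }
  expect_equal(as.numeric(got), best_c)
  expect_equal(attr(got, "statistic"), best, tolerance = 1e-12)
})

test_that("orientation flips exactly when high scores mark worse survival", {
  # high scorers die early -> must flip so that LOW = worse
  n <- 60
  set.seed(51)
  score <- rnorm(n)
  time <- rexp(n, 0.1 * 2^(score))        # higher score = higher hazard
  event <- rep(1L, n)
  scores <- data.frame(sample = sprintf("s%02d", 1:n), score = score)
  mod <- structure(list(genes = "g", center = c(g = 0), scale = c(g = 1),
                        loadings = matrix(c(1, 0), 1, 2,
                                          dimnames = list("g", c("PC1", "PC2"))),
                        explained = c(1, 0), oriented = FALSE),
                   class = "signature_model")
  cut <- median(score)
  ori <- orient_score(scores, mod, time, event, cut)
  expect_true(ori$flipped)
  expect_equal(ori$scores$score, -score)
  expect_equal(ori$cutoff, -cut)
  expect_true(ori$model$oriented)

  # idempotent: already-oriented scores are untouched
  ori2 <- orient_score(ori$scores, ori$model, time, event, ori$cutoff)
  expect_false(ori2$flipped)
  expect_equal(ori2$scores$score, ori$scores$score)
})
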