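# Survival machinery against closed forms and hand/enumeration oracles.

test_that("KM on (1,2,3) all events gives the closed-form curve", {
  fit <- km_fit(c(1, 2, 3), c(1, 1, 1))
  expect_equal(fit$surv, c(2 / 3, 1 / 3, 0), tolerance = 1e-12)
  expect_equal(fit$median, 2)
  expect_equal(fit$n_risk, c(3, 2, 1))
})

test_that("KM with everything censored stays at 1 with no median", {
  fit <- km_fit(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(fit$surv == 1))
  expect_true(is.na(fit$median))
})

test_that("KM matches a hand-computed product-limit table with censoring", {
  time <- c(1, 2, 2, 3, 4, 5, 5, 6, 8, 9)
  event <- c(1, 1, 0, 1, 0, 1, 1, 0, 1, 0)
  fit <- km_fit(time, event)
  # hand product-limit over event times
  s <- 1
  hand <- c()
  for (t in sort(unique(time[event == 1]))) {
    d <- sum(time == t & event == 1)
    n <- sum(time >= t)
    s <- s * (1 - d / n)
    hand <- c(hand, s)
  }
  expect_equal(fit$surv[fit$n_event > 0], hand, tolerance = 1e-12)
  # no censoring: KM equals the empirical survival function
  fit2 <- km_fit(1:8, rep(1, 8))
  expect_equal(fit2$surv, 1 - (1:8) / 8, tolerance = 1e-12)
})

test_that("log-rank: mirrored groups give statistic 0, oracle on an 8-sample toy", {
  time <- c(1, 2, 3, 4, 1, 2, 3, 4)
  event <- c(1, 1, 0, 1, 1, 1, 0, 1)
  lr <- logrank_test(time, event, rep(c("x", "y"), each = 4))
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)

  # hand hypergeometric accumulation on a non-trivial 8-sample toy
  time <- c(1, 3, 5, 7, 2, 4, 6, 8)
  event <- c(1, 1, 1, 0, 1, 0, 1, 1)
  group <- rep(c(0, 1), each = 4)
  oe <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    d <- sum(time == t & event == 1)
    n <- sum(time >= t)
    n1 <- sum(time >= t & group == 1)
    d1 <- sum(time == t & event == 1 & group == 1)
    oe <- oe + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  lr2 <- logrank_test(time, event, group)
  expect_equal(lr2$statistic, oe^2 / v, tolerance = 1e-10)
  # invariant under group relabeling
  lr3 <- logrank_test(time, event, 1 - group)
  expect_equal(lr2$statistic, lr3$statistic, tolerance = 1e-12)
  expect_error(logrank_test(time, rep(0, 8), group), "event")
})

test_that("log-rank rejects at the nominal rate under the null", {
  reject <- vapply(1:500, function(s) {
    sv <- make_survival(n = 50, hr = 1, seed = 2000 + s)
    logrank_test(sv$time, sv$event, sv$group)$p < 0.05
  }, logical(1))
  expect_gt(mean(reject), 0.03)
  expect_lt(mean(reject), 0.07)
})

test_that("Cox coefficient equals the bisection root of the score equation", {
  time <- c(2, 4, 6, 8, 10, 12)
  event <- rep(1, 6)
  x <- c(0, 1, 0, 1, 0, 1)
  score_eq <- function(beta) {
    u <- 0
    ord <- order(time)
    for (i in seq_along(ord)) {
      if (event[ord[i]] == 0) next
      risk <- ord[i:length(ord)]
      w <- exp(beta * x[risk])
      u <- u + x[ord[i]] - sum(x[risk] * w) / sum(w)
    }
    u
  }
  root <- uniroot(score_eq, c(-5, 5), tol = 1e-12)$root
  fit <- cox_fit(time, event, data.frame(x = x))
  expect_lt(abs(fit$coefficients$coef[1] - root), 1e-6)
  expect_equal(fit$coefficients$hr[1], exp(fit$coefficients$coef[1]))
  expect_true(fit$coefficients$lower[1] <= fit$coefficients$hr[1] &&
                fit$coefficients$hr[1] <= fit$coefficients$upper[1])
})

test_that("Cox is calibrated under the null", {
  out <- vapply(1:500, function(s) {
    sv <- make_survival(n = 60, hr = 1, seed = 4000 + s)
    fit <- cox_fit(sv$time, sv$event, data.frame(g = sv$group))
    c(fit$coefficients$coef[1], fit$coefficients$p[1] < 0.05)
  }, numeric(2))
  expect_lt(abs(mean(out[1, ])), 0.05)
  expect_gt(mean(out[2, ]), 0.03)
  expect_lt(mean(out[2, ]), 0.08)
})

test_that("time-dependent AUC: perfect and null markers behave as expected", {
  set.seed(61)
  n <- 100
  time <- rexp(n, 0.2)
  event <- rep(1L, n)
  tr <- time_roc(time, event, -time, horizons = quantile(time, c(0.3, 0.6)))
  expect_equal(tr$auc$auc, c(1, 1))

  set.seed(62)
  n <- 500
  sv <- make_survival(n = n, hr = 1, seed = 62)
  marker <- rnorm(n)
  tr0 <- time_roc(sv$time, sv$event, marker, horizons = median(sv$time))
  expect_lt(abs(tr0$auc$auc - 0.5), 0.05)
  expect_error(time_roc(sv$time, sv$event, marker, horizons = max(sv$time) + 1),
               "beyond")
})

test_that("time-dependent AUC matches exhaustive pair enumeration on a censored toy", {
  set.seed(63)
  n <- 12
  time <- rexp(n, 0.2)
  event <- rbinom(n, 1, 0.7)
  marker <- -time + rnorm(n, 0, 2)
  h <- unname(quantile(time, 0.5))
  got <- time_roc(time, event, marker, horizons = h)$auc$auc

  # oracle: censoring KM by loop, then weighted double loop over pairs
  cens_t <- sort(unique(time[event == 0]))
  G <- function(t, left = FALSE) {
    s <- 1
    for (ct in cens_t) {
      keep <- if (left) ct < t else ct <= t
      if (keep) s <- s * (1 - sum(time == ct & event == 0) / sum(time >= ct))
    }
    s
  }
  num <- 0; den <- 0
  for (i in 1:n) {
    for (j in 1:n) {
      if (event[i] == 1 && time[i] <= h && time[j] > h) {
        w <- (1 / G(time[i], left = TRUE)) * (1 / G(h))
        num <- num + w * ((marker[i] > marker[j]) + 0.5 * (marker[i] == marker[j]))
        den <- den + w
      }
    }
  }
  expect_equal(got, num / den, tolerance = 1e-12)
})

test_that("with no censoring, time_roc equals binary_roc on event-by-horizon", {
  set.seed(64)
  n <- 80
  time <- rexp(n, 0.15)
  marker <- -log(time) + rnorm(n)
  h <- unname(quantile(time, 0.6))
  tr <- time_roc(time, rep(1L, n), marker, horizons = h)
  br <- binary_roc(as.integer(time <= h), marker)
  expect_equal(tr$auc$auc, br$auc, tolerance = 1e-12)
})

test_that("binary AUC equals Mann-Whitney U / (n1 n0), with closed-form limits", {
  y <- c(0, 0, 0, 0, 0, 1, 1, 1, 1, 1)
  set.seed(65)
  m <- rnorm(10) + y
  got <- binary_roc(y, m)$auc
  u <- unname(wilcox.test(m[y == 1], m[y == 0], exact = TRUE)$statistic)
  expect_equal(got, u / 25)
  expect_equal(binary_roc(y, y * 10)$auc, 1)
  expect_equal(binary_roc(y, rep(3, 10))$auc, 0.5)
  expect_error(binary_roc(rep(1, 5), rnorm(5)), "both classes")
})

test_that("rank-sum: exact enumeration oracle at n1 = n2 = 4 and tied limit", {
  set.seed(66)
  x <- rnorm(4); y <- rnorm(4) + 0.5
  got <- wilcoxon_ranksum(x, y)
  pooled <- c(x, y)
  r <- rank(pooled)
  obs <- sum(r[1:4])
  splits <- combn(8, 4)
  ws <- apply(splits, 2, function(i) sum(r[i]))
  p_lo <- mean(ws <= obs); p_hi <- mean(ws >= obs)
  oracle <- min(1, 2 * min(p_lo, p_hi))
  expect_equal(got, oracle, tolerance = 1e-12)

  expect_gte(wilcoxon_ranksum(c(1, 2), c(1, 2)), 0.99)
})

test_that("Spearman: monotone pairs give rho 1; zero variance is flagged", {
  x <- c(1, 3, 5, 9, 11)
  res <- spearman_cor(x, exp(x))
  expect_equal(res$rho, 1)
  expect_warning(flat <- spearman_cor(rep(2, 5), rnorm(5)), "zero variance")
  expect_true(is.na(flat$rho))
})
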