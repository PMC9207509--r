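# Building and applying the m6A scoring model: random-forest redundancy
# removal, univariate Cox trimming, PCA over the surviving genes, scoring
# as the sum of the first two principal-component sample scores, a
# maximally selected log-rank cutpoint, and the survival-based sign
# convention (low score = poor prognosis).

#' Random-forest redundancy filter for DEGs
#'
#' Fits a random-forest classifier (bootstrap trees, sqrt(p) candidate
#' features per split) predicting the cluster labels from the DEG-restricted
#' expression matrix, ranks genes by permutation importance (mean decrease
#' in accuracy), and retains genes whose importance lies strictly above
#' the larger of the median and the mean importance. Under informative
#' labels the heavy right tail of the importance distribution pulls the
#' mean above the bulk of uninformative genes, so most noise genes are
#' discarded; under null labels the two coincide near zero and about half
#' the genes pass, as expected of a rank-based cut. With fewer than 10
#' candidate genes the filter is skipped with a warning and all genes
#' pass.
#'
#' @param expr DEG-restricted gene-by-sample matrix.
#' @param labels two-class labels, one per sample.
#' @param n_trees number of trees (default 500).
#' @param seed integer seed for bit-reproducible selection.
#' @return character vector of retained gene symbols.
#' @export
rf_redundancy_filter <- function(expr, labels, n_trees = 500, seed = NULL) {
  assert_expression_matrix(expr)
  n_trees <- assert_count(n_trees, "n_trees", min = 1)
  y <- factor(labels)
  if (length(y) != ncol(expr) || nlevels(y) != 2L) {
    stop("`labels` must be a two-class vector, one label per sample",
         call. = FALSE)
  }
  genes <- rownames(expr)
  if (length(genes) < 10L) {
    warning("fewer than 10 genes: redundancy filter skipped, all genes pass")
    return(genes)
  }
  rf <- with_seed(seed, randomForest::randomForest(
    x = t(expr), y = y, ntree = n_trees, importance = TRUE
  ))
  imp <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1L]
  genes[imp > max(stats::median(imp), mean(imp))]
}

#' Univariate Cox filter on standardized expression
#'
#' Per gene, fits a univariate Cox proportional-hazards model (Efron tie
#' handling) on the z-scored expression and keeps genes whose Wald p-value
#' is below `alpha`. Genes whose fit fails to converge are dropped with a
#' warning.
#'
#' @param expr gene-by-sample matrix.
#' @param time,event survival data aligned with the samples.
#' @param genes genes to test (default: all rows).
#' @param alpha Wald significance threshold (default 0.05).
#' @return character vector of prognostic genes.
#' @export
cox_univariate_filter <- function(expr, time, event, genes = rownames(expr),
                                  alpha = 0.05) {
  assert_expression_matrix(expr)
  assert_survival(time, event)
  assert_scalar_number(alpha, "alpha", lower = 0, upper = 1)
  if (length(time) != ncol(expr)) {
    stop("survival vectors must align with the samples", call. = FALSE)
  }
  missing <- setdiff(genes, rownames(expr))
  if (length(missing) > 0L) {
    stop("gene(s) absent from expression matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  keep <- logical(length(genes))
  dropped <- character(0)
  for (i in seq_along(genes)) {
    z <- as.numeric(scale(expr[genes[i], ]))
    if (any(!is.finite(z))) { dropped <- c(dropped, genes[i]); next }
    fit <- cox_fit(time, event, data.frame(expr = z))
    if (!fit$converged || !is.finite(fit$coefficients$p[1L])) {
      dropped <- c(dropped, genes[i])
      next
    }
    keep[i] <- fit$coefficients$p[1L] < alpha
  }
  if (length(dropped) > 0L) {
    warning(sprintf("%d gene(s) dropped (non-convergent or degenerate): %s",
                    length(dropped),
                    paste(utils::head(dropped, 5), collapse = ", ")))
  }
  genes[keep]
}

#' Fit the PCA scoring model over the signature genes
#'
#' Z-scores each signature gene on the training cohort, runs PCA on the
#' samples x genes matrix and stores the first two loading vectors
#' (unit-norm, orthogonal). Each component's sign is fixed so that its
#' largest-magnitude loading is positive, which makes the fit
#' deterministic.
#'
#' @param expr gene-by-sample matrix containing the signature genes.
#' @param genes >= 2 signature gene symbols.
#' @return Object of class `signature_model`: list with `genes`, `center`
#'   and `scale` (per-gene training constants), `loadings` (genes x 2),
#'   `explained` (variance fractions of PC1/PC2), `oriented` (logical,
#'   set by [orient_score()]).
#' @export
fit_signature <- function(expr, genes) {
  assert_expression_matrix(expr)
  if (length(genes) < 2L) stop("need >= 2 signature genes", call. = FALSE)
  if (ncol(expr) < 3L) stop("need >= 3 samples", call. = FALSE)
  missing <- setdiff(genes, rownames(expr))
  if (length(missing) > 0L) {
    stop("signature gene(s) absent: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- expr[genes, , drop = FALSE]
  mu <- rowMeans(x)
  s <- row_sds(x)
  if (any(s <= 0)) {
    stop("constant signature gene(s): ",
         paste(genes[s <= 0], collapse = ", "), call. = FALSE)
  }
  z <- (x - mu) / s
  pc <- stats::prcomp(t(z), center = FALSE, scale. = FALSE)
  k <- min(2L, ncol(pc$rotation))
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  if (k < 2L) {                       # degenerate: duplicate PC1 direction
    load <- cbind(load, 0 * load[, 1L])
  }
  for (j in 1:2) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(
    list(genes = genes,
         center = stats::setNames(mu, genes),
         scale = stats::setNames(s, genes),
         loadings = structure(load, dimnames = list(genes, c("PC1", "PC2"))),
         explained = ev[1:2],
         oriented = FALSE),
    class = "signature_model"
  )
}

#' Score samples with a fitted signature model
#'
#' Per sample, the m6A score is the sum of its PC1 and PC2 sample scores:
#' the standardized signature-gene vector projected onto the two stored
#' loading vectors and added. By default the signature genes are z-scored
#' within the cohort being scored (making the score portable across
#' platforms); `standardize = "training"` reuses the frozen training
#' means/SDs instead. At least 80% of the signature genes must be present;
#' absent genes contribute zero and each loading vector is renormalized to
#' unit norm over the present genes.
#'
#' @param expr gene-by-sample matrix to score.
#' @param model a `signature_model`.
#' @param standardize `"cohort"` (default) or `"training"`.
#' @param refit if `TRUE`, re-fit the PCA on this cohort's signature genes
#'   instead of projecting on the frozen loadings (provided for
#'   comparison; the frozen projection is the default behaviour).
#' @param cutoff optional score cutoff; when given, a `group` column
#'   (`"high"` if score > cutoff else `"low"`) is added.
#' @return data.frame: sample, score (and group/cutoff when `cutoff`
#'   given).
#' @export
score_samples <- function(expr, model, standardize = c("cohort", "training"),
                          refit = FALSE, cutoff = NULL) {
  assert_expression_matrix(expr)
  stopifnot(inherits(model, "signature_model"))
  standardize <- match.arg(standardize)
  present <- intersect(model$genes, rownames(expr))
  frac <- length(present) / length(model$genes)
  if (frac < 0.8) {
    stop("only ", round(100 * frac), "% of signature genes present; missing: ",
         paste(setdiff(model$genes, rownames(expr)), collapse = ", "),
         call. = FALSE)
  }
  if (refit) {
    model <- fit_signature(expr, present)
  }
  x <- expr[present, , drop = FALSE]
  if (standardize == "cohort" && !refit) {
    mu <- rowMeans(x)
    s <- row_sds(x)
    if (any(s <= 0)) {
      stop("constant signature gene(s) in scoring cohort: ",
           paste(present[s <= 0], collapse = ", "), call. = FALSE)
    }
  } else {
    mu <- model$center[present]
    s <- model$scale[present]
  }
  z <- (x - mu) / s
  load <- model$loadings[present, , drop = FALSE]
  norms <- sqrt(colSums(load^2))
  norms[norms == 0] <- 1
  load <- sweep(load, 2, norms, "/")
  score <- as.numeric(t(z) %*% (load[, 1L] + load[, 2L]))
  out <- data.frame(sample = colnames(expr), score = score,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(cutoff)) {
    assert_scalar_number(cutoff, "cutoff")
    out$group <- ifelse(out$score > cutoff, "high", "low")
    out$cutoff <- cutoff
  }
  out
}

#' Log-rank scores for maximally selected cutpoints
#'
#' Per-subject log-rank (Peto) scores `a_i = event_i - H(time_i)` where H
#' is the Nelson-Aalen cumulative hazard estimate; the linear statistic of
#' any two-group split is the within-group sum of these scores.
#'
#' @param time,event survival data.
#' @return numeric vector of scores (sums to ~0).
#' @noRd
logrank_scores <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  dN <- vapply(ut, function(t) sum(time == t & event == 1), numeric(1))
  Y <- vapply(ut, function(t) sum(time >= t), numeric(1))
  hstep <- cumsum(dN / Y)
  H <- vapply(time, function(t) {
    i <- sum(ut <= t)
    if (i == 0L) 0 else hstep[i]
  }, numeric(1))
  event - H
}

#' Maximally selected log-rank cutpoint
#'
#' Scans every candidate cutpoint (midpoints between consecutive distinct
#' score values) that leaves at least `minprop` of the samples on each
#' side and evaluates the standardized log-rank statistic of the split:
#' the low-group sum of the per-subject log-rank scores, standardized by
#' its permutation mean and variance. Returns the cutpoint with the
#' largest absolute standardized statistic (the first one on exact ties).
#'
#' @param score per-sample scores.
#' @param time,event survival data (>= 2 events required).
#' @param minprop minimum fraction of samples on each side (default 0.1).
#' @return the optimal cutoff (numeric scalar) with attributes
#'   `"statistic"` (standardized log-rank statistic at the optimum) and
#'   `"candidates"` (data.frame cutoff, statistic).
#' @references Lausen B, Schumacher M (1992). Maximally selected rank
#'   statistics. Biometrics 48:73-85.
#' @export
optimal_cutoff <- function(score, time, event, minprop = 0.1) {
  assert_survival(time, event)
  assert_scalar_number(minprop, "minprop", lower = 0, upper = 0.5)
  if (length(score) != length(time) || any(!is.finite(score))) {
    stop("`score` must be finite and aligned with `time`", call. = FALSE)
  }
  if (sum(event) < 2) stop("need >= 2 events", call. = FALSE)
  n <- length(score)
  u <- sort(unique(score))
  if (length(u) < 2L) {
    stop("no candidate cutpoint: all scores are equal", call. = FALSE)
  }
  cand <- (u[-length(u)] + u[-1L]) / 2
  n_low <- vapply(cand, function(c) sum(score <= c), numeric(1))
  ok <- n_low >= minprop * n & (n - n_low) >= minprop * n
  cand <- cand[ok]
  if (length(cand) == 0L) {
    stop("no candidate cutpoint satisfies minprop = ", minprop, call. = FALSE)
  }
  a <- logrank_scores(time, event)
  a_bar <- mean(a)
  ss <- sum((a - a_bar)^2)
  ord <- order(score)
  a_cum <- cumsum(a[ord])
  s_sorted <- score[ord]
  stat <- vapply(cand, function(c) {
    m <- sum(s_sorted <= c)
    s_low <- a_cum[m]
    v <- m * (n - m) / (n * (n - 1)) * ss
    if (v <= 0) return(0)
    abs(s_low - m * a_bar) / sqrt(v)
  }, numeric(1))
  best <- which.max(stat)
  structure(cand[best], statistic = stat[best],
            candidates = data.frame(cutoff = cand, statistic = stat))
}

#' Orient the score so that low score means poor prognosis
#'
#' Compares the survival of the high-score and low-score groups on the
#' training data (KM median; restricted mean when a median is undefined).
#' If the high-score group fares worse, the sign of the scores, the
#' loadings and the cutoff are all flipped so that, by convention, a LOW
#' m6A score marks the poor-prognosis patients. Idempotent: an already
#' oriented score is returned unchanged.
#'
#' @param scores data.frame from [score_samples()] (column `score`).
#' @param model the `signature_model` that produced the scores.
#' @param time,event survival data aligned with `scores`.
#' @param cutoff the cutpoint separating high from low (e.g. from
#'   [optimal_cutoff()]).
#' @return list with `scores` (data.frame sample, score, group, cutoff),
#'   `model` (sign-adjusted, `oriented = TRUE`), `cutoff`, and `flipped`
#'   (logical).
#' @export
orient_score <- function(scores, model, time, event, cutoff) {
  stopifnot(inherits(model, "signature_model"))
  assert_survival(time, event)
  assert_scalar_number(cutoff, "cutoff")
  s <- scores$score
  if (length(s) != length(time)) {
    stop("`scores` must align with the survival vectors", call. = FALSE)
  }
  high <- s > cutoff
  if (!any(high) || all(high)) {
    stop("cutoff must split the samples into two non-empty groups",
         call. = FALSE)
  }
  surv_of <- function(i) {
    fit <- survival::survfit(survival::Surv(time[i], event[i]) ~ 1)
    tab <- summary(fit, rmean = max(time))$table
    med <- unname(tab["median"])
    if (is.na(med)) unname(tab[grep("rmean$", names(tab))][1L]) else med
  }
  flipped <- surv_of(high) < surv_of(!high)   # high group worse -> flip
  if (flipped) {
    s <- -s
    cutoff <- -cutoff
    model$loadings <- -model$loadings
  }
  model$oriented <- TRUE
  out <- data.frame(sample = scores$sample, score = s,
                    group = ifelse(s > cutoff, "high", "low"),
                    cutoff = cutoff, row.names = NULL,
                    stringsAsFactors = FALSE)
  list(scores = out, model = model, cutoff = cutoff, flipped = flipped)
}
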