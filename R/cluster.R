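# Consensus clustering of samples by resampled k-means, PAC-based
# selection of k, and survival-based naming of the two m6A clusters.

#' Consensus clustering by resampled k-means
#'
#' For each replicate, a fraction `subsample` of the samples is drawn
#' without replacement and partitioned by k-means (Euclidean distance,
#' `nstart` random restarts, best within-cluster SS kept). For every k the
#' consensus matrix is the ratio of co-clustering counts to co-sampling
#' counts (0/0 mapped to 0, diagonal fixed at 1). Final labels are the
#' average-linkage hierarchical clustering of `1 - M_k` cut at k. Features
#' (rows) are z-scored by default and never subsampled.
#'
#' Stability summaries per k: PAC (fraction of off-diagonal consensus
#' entries strictly inside `(0.1, 0.9)`), the area under the consensus CDF
#' and its relative increase (delta-area).
#'
#' @param expr feature-by-sample matrix (e.g. the 16-regulator panel).
#' @param k_max largest k; consensus is computed for k = 2..k_max.
#' @param reps number of resampling replicates (>= 1; with `reps = 1` and
#'   `subsample = 1` the consensus matrix is exactly the 0/1 co-membership
#'   matrix of a single k-means run).
#' @param subsample fraction of samples drawn per replicate, in (0, 1].
#' @param seed integer seed; fixes the whole procedure bit-reproducibly.
#' @param nstart k-means random restarts per replicate.
#' @param scale_features z-score each feature first (recommended when
#'   using Euclidean distance).
#' @return Object of class `consensus_result`: list with `k_values`,
#'   `consensus` (list of n x n matrices), `labels` (n x length(k_values)
#'   integer matrix), `pac`, `cdf_area`, `delta_area`, `n`, and the call
#'   parameters.
#' @export
consensus_cluster <- function(expr, k_max = 10, reps = 1000, subsample = 0.8,
                              seed = NULL, nstart = 20, scale_features = TRUE) {
  assert_expression_matrix(expr)
  k_max <- assert_count(k_max, "k_max", min = 2)
  reps <- assert_count(reps, "reps", min = 1)
  assert_scalar_number(subsample, "subsample")
  if (subsample <= 0 || subsample > 1) {
    stop("`subsample` must be in (0, 1]", call. = FALSE)
  }
  n <- ncol(expr)
  if (n <= k_max) {
    stop(sprintf("need more samples (%d) than k_max (%d)", n, k_max),
         call. = FALSE)
  }
  x <- if (scale_features) scale_rows(expr) else expr
  xt <- t(x)
  m <- ceiling(subsample * n)
  ks <- 2:k_max

  with_seed(seed, {
    co_sample <- matrix(0, n, n)
    conn <- lapply(ks, function(k) matrix(0, n, n))
    names(conn) <- as.character(ks)
    for (r in seq_len(reps)) {
      idx <- sort(sample.int(n, m))
      co_sample[idx, idx] <- co_sample[idx, idx] + 1
      sub <- xt[idx, , drop = FALSE]
      for (j in seq_along(ks)) {
        cl <- stats::kmeans(sub, centers = ks[j], nstart = nstart,
                            iter.max = 50)$cluster
        conn[[j]][idx, idx] <- conn[[j]][idx, idx] + outer(cl, cl, "==")
      }
    }
    consensus <- lapply(conn, function(cm) {
      M <- ifelse(co_sample > 0, cm / pmax(co_sample, 1), 0)
      M <- (M + t(M)) / 2
      diag(M) <- 1
      dimnames(M) <- list(colnames(expr), colnames(expr))
      M
    })
    labels <- vapply(seq_along(ks), function(j) {
      hc <- stats::hclust(stats::as.dist(1 - consensus[[j]]), method = "average")
      stats::cutree(hc, k = ks[j])
    }, integer(n))
    dimnames(labels) <- list(colnames(expr), as.character(ks))

    low <- lower.tri(consensus[[1L]])
    pac <- vapply(consensus, function(M) mean(M[low] > 0.1 & M[low] < 0.9),
                  numeric(1))
    cdf_area <- vapply(consensus, function(M) consensus_cdf_area(M[low]),
                       numeric(1))
    delta_area <- c(cdf_area[1L],
                    if (length(ks) > 1L) diff(cdf_area) / cdf_area[-length(ks)])
    names(delta_area) <- names(cdf_area)

    structure(
      list(k_values = ks, consensus = consensus, labels = labels,
           pac = pac, cdf_area = cdf_area, delta_area = delta_area,
           n = n, reps = reps, subsample = subsample, seed = seed,
           nstart = nstart),
      class = "consensus_result"
    )
  })
}

# Area under the empirical CDF of consensus values over [0, 1].
consensus_cdf_area <- function(v) {
  v <- sort(v)
  cdf <- stats::ecdf(v)
  grid <- sort(unique(c(0, v, 1)))
  sum(diff(grid) * cdf(grid[-length(grid)]))
}

#' Select the number of clusters by minimum PAC
#'
#' Returns the k with the smallest proportion of ambiguous clustering;
#' ties are broken in favour of the smaller k.
#'
#' @param result a `consensus_result`.
#' @return integer k.
#' @export
select_k <- function(result) {
  stopifnot(inherits(result, "consensus_result"))
  result$k_values[which.min(result$pac)]
}

#' Name two clusters "A" (poor prognosis) and "B" by survival
#'
#' The cluster whose Kaplan-Meier median survival is shorter is named
#' `"A"`, the other `"B"`, matching the convention that cluster A carries
#' the poorer outcome. If a median is undefined (survival never drops to
#' 0.5), the restricted mean survival time is compared instead. On exact
#' ties the smaller-index cluster becomes "A".
#'
#' @param labels integer/character cluster labels (exactly two distinct
#'   values), one per sample.
#' @param time,event survival times (> 0) and 0/1 event indicators
#'   aligned with `labels`.
#' @return list with `mapping` (named character: old label -> "A"/"B") and
#'   `labels` (the renamed per-sample vector).
#' @export
label_m6a_clusters <- function(labels, time, event) {
  assert_survival(time, event)
  labels <- as.character(labels)
  if (length(labels) != length(time)) {
    stop("`labels` must align with the survival vectors", call. = FALSE)
  }
  lv <- sort(unique(labels))
  if (length(lv) != 2L) {
    stop("exactly two clusters are required, got ", length(lv), call. = FALSE)
  }
  stat <- vapply(lv, function(l) {
    i <- labels == l
    fit <- survival::survfit(survival::Surv(time[i], event[i]) ~ 1)
    tab <- summary(fit, rmean = max(time))$table
    med <- unname(tab["median"])
    if (is.na(med)) unname(tab[grep("rmean$", names(tab))][1L]) else med
  }, numeric(1))
  # smaller survival -> "A"; ties resolved toward the smaller index
  a <- if (stat[1L] <= stat[2L]) lv[1L] else lv[2L]
  mapping <- stats::setNames(ifelse(lv == a, "A", "B"), lv)
  list(mapping = mapping, labels = unname(mapping[labels]))
}
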