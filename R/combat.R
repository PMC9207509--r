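#' Empirical-Bayes batch correction (parametric ComBat)
#'
#' Removes additive and multiplicative batch effects from a merged
#' gene-by-sample matrix using the parametric empirical-Bayes
#' location-scale model of Johnson, Li & Rabinovic (2007): genes are
#' standardized against the grand mean and pooled variance, per-batch
#' per-gene location (`gamma`) and scale (`delta^2`) effects are estimated,
#' shrunk toward moment-matched normal / inverse-gamma priors by iterating
#' the conditional posterior means to convergence, and the data are
#' adjusted and back-transformed. Dimensions are unchanged.
#'
#' With a single batch the matrix is returned unchanged with a warning;
#' a batch with fewer than 2 samples is an error (its scale effect is
#' inestimable).
#'
#' @param expr numeric gene-by-sample matrix (log scale).
#' @param batch per-sample batch labels (coerced to factor).
#' @param conv relative convergence tolerance of the EB iteration.
#' @param max_iter iteration cap.
#' @return list with `corrected` (adjusted matrix) and `model` (class
#'   `batch_model`: per-batch shrunken `gamma_star` location and
#'   `delta_star` scale matrices, `grand_mean`, `var_pooled`, batch
#'   levels and sizes). `delta_star` entries are strictly positive.
#' @references Johnson WE, Li C, Rabinovic A (2007). Adjusting batch
#'   effects in microarray expression data using empirical Bayes methods.
#'   Biostatistics 8(1):118-127.
#' @export
combat_adjust <- function(expr, batch, conv = 1e-10, max_iter = 500) {
  assert_expression_matrix(expr)
  batch <- droplevels(as.factor(batch))
  if (length(batch) != ncol(expr)) {
    stop("`batch` must have one label per sample", call. = FALSE)
  }
  sizes <- table(batch)
  if (nlevels(batch) == 1L) {
    warning("single batch: returning the matrix unchanged")
    return(list(corrected = expr, model = NULL))
  }
  if (any(sizes < 2L)) {
    stop("every batch needs >= 2 samples; offending batch(es): ",
         paste(names(sizes)[sizes < 2L], collapse = ", "), call. = FALSE)
  }

  n_array <- ncol(expr)
  levels_b <- levels(batch)
  idx_b <- lapply(levels_b, function(b) which(batch == b))

  # per-batch, per-gene means; grand mean weighted by batch size
  batch_means <- vapply(idx_b, function(i) rowMeans(expr[, i, drop = FALSE]),
                        numeric(nrow(expr)))                      # genes x batches
  w <- as.numeric(sizes) / n_array
  grand_mean <- as.numeric(batch_means %*% w)
  resid <- expr - batch_means[, as.integer(batch)]
  var_pooled <- rowSums(resid^2) / n_array
  if (any(var_pooled <= 0)) {
    stop("gene(s) with zero pooled variance cannot be standardized: ",
         paste(utils::head(rownames(expr)[var_pooled <= 0], 5), collapse = ", "),
         call. = FALSE)
  }

  z <- (expr - grand_mean) / sqrt(var_pooled)

  gamma_hat <- vapply(idx_b, function(i) rowMeans(z[, i, drop = FALSE]),
                      numeric(nrow(expr)))
  delta_hat <- vapply(idx_b, function(i) {
    apply(z[, i, drop = FALSE], 1, stats::var)
  }, numeric(nrow(expr)))

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  for (b in seq_along(levels_b)) {
    nb <- as.numeric(sizes[b])
    g_hat <- gamma_hat[, b]
    d_hat <- delta_hat[, b]
    g_bar <- mean(g_hat)
    t2 <- stats::var(g_hat)
    m <- mean(d_hat)
    s2 <- stats::var(d_hat)
    # inverse-gamma hyperparameters by moment matching; in the homogeneous
    # limit s2 -> 0 the posterior scale tends to the common value m
    if (s2 < 1e-12) {
      a_prior <- Inf
      b_prior <- Inf
    } else {
      a_prior <- (2 * s2 + m^2) / s2
      b_prior <- (m * s2 + m^3) / s2
    }
    zb <- z[, idx_b[[b]], drop = FALSE]
    g_new <- g_hat
    d_new <- d_hat
    for (it in seq_len(max_iter)) {
      g_old <- g_new
      d_old <- d_new
      g_new <- (t2 * nb * g_hat + d_old * g_bar) / (t2 * nb + d_old)
      sum2 <- rowSums((zb - g_new)^2)
      d_new <- if (is.finite(a_prior)) {
        (0.5 * sum2 + b_prior) / (nb / 2 + a_prior - 1)
      } else {
        rep(m, length(d_hat))
      }
      change <- max(abs(g_new - g_old) / pmax(abs(g_old), 1e-12),
                    abs(d_new - d_old) / pmax(abs(d_old), 1e-12))
      if (change < conv) break
    }
    gamma_star[, b] <- g_new
    delta_star[, b] <- d_new
  }
  if (any(delta_star <= 0)) {
    stop("internal error: non-positive posterior scale estimate", call. = FALSE)
  }

  bi <- as.integer(batch)
  z_adj <- (z - gamma_star[, bi]) / sqrt(delta_star[, bi])
  corrected <- z_adj * sqrt(var_pooled) + grand_mean
  dimnames(corrected) <- dimnames(expr)

  colnames(gamma_star) <- colnames(delta_star) <- levels_b
  model <- structure(
    list(gamma_star = gamma_star, delta_star = delta_star,
         gamma_hat = gamma_hat, delta_hat = delta_hat,
         grand_mean = grand_mean, var_pooled = var_pooled,
         batch_levels = levels_b, batch_sizes = as.integer(sizes)),
    class = "batch_model"
  )
  list(corrected = corrected, model = model)
}
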