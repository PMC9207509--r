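# Gene-set scoring: per-sample ssGSEA, two-phenotype GSEA with
# permutation NES, the 18-gene tumor-inflammation-signature mean, and
# marker-set immune scoring.

# Weighted KS running-sum enrichment score for one set.
# `stat` is the per-gene ranking statistic (any scale), `in_set` a logical
# vector aligned with it; genes are walked in decreasing order of `stat`
# and the maximal deviation between the weighted in-set ECDF
# (weight |stat|^exponent) and the uniform out-of-set ECDF is returned.
es_stat <- function(stat, in_set, exponent = 1) {
  ord <- order(stat, decreasing = TRUE)
  hit <- in_set[ord]
  w <- abs(stat[ord])^exponent
  w_hit <- w * hit
  denom_hit <- sum(w_hit)
  if (denom_hit == 0) return(0)
  p_hit <- cumsum(w_hit) / denom_hit
  p_miss <- cumsum(!hit) / sum(!hit)
  dev <- p_hit - p_miss
  unname(dev[which.max(abs(dev))])
}

# ssGSEA-style integrated (summed, not maximal) running-sum score for one
# sample: genes ordered by decreasing within-sample rank, in-set steps
# weighted by rank^alpha.
ssgsea_sample_score <- function(ranks, in_set, alpha = 0.25) {
  ord <- order(ranks, decreasing = TRUE)
  hit <- in_set[ord]
  w <- ranks[ord]^alpha
  w_hit <- w * hit
  denom <- sum(w_hit)
  if (denom == 0) return(NA_real_)
  sum(cumsum(w_hit) / denom - cumsum(!hit) / sum(!hit))
}

#' Single-sample gene-set enrichment (ssGSEA)
#'
#' Per sample, genes are ranked by expression (average ranks for ties),
#' and each set's score is the integrated difference between the
#' rank-weighted in-set ECDF (weight `rank^0.25`) and the out-of-set ECDF,
#' walking genes from highest to lowest expression. Being rank-based, the
#' score is invariant to monotone per-sample transformations. Scores are
#' finally divided by the overall range across the whole matrix. A sample
#' with constant expression carries no ranking information and scores 0; a
#' set with no member present scores `NA` with a warning.
#'
#' @param expr gene-by-sample matrix.
#' @param sets named list of character vectors (e.g. from [read_gmt()]).
#' @param alpha rank-weight exponent (default 0.25).
#' @param normalize divide by the overall score range (default TRUE).
#' @return sets x samples numeric matrix.
#' @references Barbie DA et al. (2009). Systematic RNA interference
#'   reveals that oncogenic KRAS-driven cancers require TBK1. Nature 462.
#' @export
ssgsea_score <- function(expr, sets, alpha = 0.25, normalize = TRUE) {
  assert_expression_matrix(expr)
  if (length(sets) == 0L || is.null(names(sets))) {
    stop("`sets` must be a non-empty named list", call. = FALSE)
  }
  genes <- rownames(expr)
  memb <- lapply(sets, function(s) genes %in% s)
  absent <- vapply(memb, function(m) !any(m), logical(1))
  if (any(absent)) {
    warning("set(s) with no member present score NA: ",
            paste(names(sets)[absent], collapse = ", "))
  }
  scores <- matrix(NA_real_, length(sets), ncol(expr),
                   dimnames = list(names(sets), colnames(expr)))
  for (j in seq_len(ncol(expr))) {
    v <- expr[, j]
    if (stats::sd(v) == 0) {          # no ranking information
      scores[!absent, j] <- 0
      next
    }
    r <- rank(v)
    for (i in seq_along(sets)) {
      if (absent[i]) next
      scores[i, j] <- ssgsea_sample_score(r, memb[[i]], alpha = alpha)
    }
  }
  if (normalize && any(is.finite(scores))) {
    rng <- range(scores, na.rm = TRUE)
    if (diff(rng) > 0) scores <- scores / diff(rng)
  }
  scores
}

#' Two-phenotype GSEA with permutation-based NES
#'
#' Genes are ranked by the signal-to-noise ratio between the two groups,
#' each set's enrichment score is the weighted KS running-sum statistic
#' (weight exponent 1), and significance comes from phenotype permutation:
#' the NES divides the observed ES by the mean magnitude of same-sign
#' permutation ES values, and the nominal p-value is the same-sign
#' permutation tail fraction (with the +1 floor correction). Groups
#' smaller than 3 make phenotype permutation meaningless; the routine
#' then falls back to gene-set permutation with a warning.
#'
#' A set is flagged significant when `|NES| > nes_min` and `p < alpha`
#' (defaults 1 and 0.05).
#'
#' @param expr gene-by-sample matrix.
#' @param labels two-level phenotype, one per sample.
#' @param sets named list of gene sets.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @param nes_min,alpha significance thresholds.
#' @return data.frame: set, size (members present), es, nes, p,
#'   significant.
#' @export
gsea_two_group <- function(expr, labels, sets, n_perm = 1000, seed = NULL,
                           nes_min = 1, alpha = 0.05) {
  assert_expression_matrix(expr)
  n_perm <- assert_count(n_perm, "n_perm", min = 100)
  g <- factor(labels)
  if (nlevels(g) != 2L || length(g) != ncol(expr)) {
    stop("`labels` must give exactly two groups, one per sample",
         call. = FALSE)
  }
  genes <- rownames(expr)
  memb <- lapply(sets, function(s) genes %in% s)
  sizes <- vapply(memb, sum, numeric(1))
  if (any(sizes == 0)) {
    stop("set(s) with no member present: ",
         paste(names(sets)[sizes == 0], collapse = ", "), call. = FALSE)
  }

  s2n <- function(grp) {
    i1 <- grp == levels(g)[1L]
    m1 <- rowMeans(expr[, i1, drop = FALSE])
    m2 <- rowMeans(expr[, !i1, drop = FALSE])
    s1 <- row_sds(expr[, i1, drop = FALSE])
    s2 <- row_sds(expr[, !i1, drop = FALSE])
    (m1 - m2) / pmax(s1 + s2, 1e-8)
  }
  obs_stat <- s2n(g)
  es_obs <- vapply(memb, function(m) es_stat(obs_stat, m), numeric(1))

  phenotype_perm <- min(table(g)) >= 3L
  if (!phenotype_perm) {
    warning("a group has < 3 samples: falling back to gene-set permutation")
  }

  es_perm <- with_seed(seed, {
    if (phenotype_perm) {
      vapply(seq_len(n_perm), function(b) {
        gp <- sample(g)
        st <- s2n(gp)
        vapply(memb, function(m) es_stat(st, m), numeric(1))
      }, numeric(length(sets)))
    } else {
      vapply(seq_len(n_perm), function(b) {
        vapply(sizes, function(sz) {
          m <- logical(length(genes))
          m[sample.int(length(genes), sz)] <- TRUE
          es_stat(obs_stat, m)
        }, numeric(1))
      }, numeric(length(sets)))
    }
  })
  es_perm <- matrix(es_perm, nrow = length(sets))

  nes <- numeric(length(sets))
  pval <- numeric(length(sets))
  for (i in seq_along(sets)) {
    same <- es_perm[i, ] * sign(es_obs[i]) > 0
    ref <- abs(es_perm[i, same])
    if (length(ref) == 0L) {           # degenerate: no same-sign nulls
      ref <- abs(es_perm[i, ])
    }
    nes[i] <- if (mean(ref) > 0) es_obs[i] / mean(ref) else 0
    pval[i] <- (1 + sum(ref >= abs(es_obs[i]))) / (1 + length(ref))
  }
  data.frame(set = names(sets), size = sizes, es = es_obs, nes = nes,
             p = pval, significant = abs(nes) > nes_min & pval < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Tumor inflammation signature (TIS) score
#'
#' Per sample, the mean of `log10(expression + pseudocount)` over the
#' 18 configured signature genes; expression must be on a linear scale.
#' The gene list is a required input (it is a configuration choice, not a
#' constant of this package). Missing genes are an error listing them.
#'
#' @param expr_linear gene-by-sample matrix on linear scale (non-negative).
#' @param tis_genes character vector of the 18 signature genes.
#' @param pseudocount added before the log (default 0; use a positive
#'   value when zeros can occur).
#' @return named numeric vector, one score per sample.
#' @export
tis_score <- function(expr_linear, tis_genes, pseudocount = 0) {
  assert_expression_matrix(expr_linear)
  assert_scalar_number(pseudocount, "pseudocount", lower = 0)
  missing <- setdiff(tis_genes, rownames(expr_linear))
  if (length(missing) > 0L) {
    stop("TIS gene(s) absent from expression matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x <- expr_linear[tis_genes, , drop = FALSE] + pseudocount
  if (any(x <= 0)) {
    stop("non-positive expression under log10; supply a pseudocount",
         call. = FALSE)
  }
  colMeans(log10(x))
}

#' Marker-set immune-infiltration scores
#'
#' Scores user-supplied immune-cell marker sets per sample via
#' [ssgsea_score()] and, when an m6A score (and optionally a high/low
#' group) is supplied, reports the Spearman correlation and the Wilcoxon
#' group difference of each cell type against the score.
#'
#' @param expr gene-by-sample matrix.
#' @param marker_sets named list of marker gene sets (e.g. a marker GMT).
#' @param score optional per-sample m6A score aligned with the samples.
#' @param group optional per-sample `"high"`/`"low"` assignment.
#' @return list with `scores` (cell types x samples matrix) and
#'   `association` (data.frame: cell_type, rho, rho_p, wilcoxon_p; only
#'   the columns whose inputs were supplied).
#' @export
immune_marker_scores <- function(expr, marker_sets, score = NULL,
                                 group = NULL) {
  sc <- ssgsea_score(expr, marker_sets)
  assoc <- NULL
  if (!is.null(score) || !is.null(group)) {
    assoc <- data.frame(cell_type = rownames(sc),
                        stringsAsFactors = FALSE)
    if (!is.null(score)) {
      stopifnot(length(score) == ncol(sc))
      cors <- lapply(seq_len(nrow(sc)), function(i) {
        if (anyNA(sc[i, ])) return(list(rho = NA_real_, p = NA_real_))
        spearman_cor(score, sc[i, ])
      })
      assoc$rho <- vapply(cors, `[[`, numeric(1), "rho")
      assoc$rho_p <- vapply(cors, `[[`, numeric(1), "p")
    }
    if (!is.null(group)) {
      stopifnot(length(group) == ncol(sc))
      assoc$wilcoxon_p <- vapply(seq_len(nrow(sc)), function(i) {
        if (anyNA(sc[i, ])) return(NA_real_)
        wilcoxon_ranksum(sc[i, group == "high"], sc[i, group == "low"])
      }, numeric(1))
    }
  }
  list(scores = sc, association = assoc)
}
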