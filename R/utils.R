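# Internal helpers shared across modules.

#' Evaluate code under a temporary, fully specified RNG state
#'
#' Sets the Mersenne-Twister / Inversion / Rejection RNG with the given seed,
#' evaluates `code`, and restores the caller's RNG state afterwards so that
#' seeded package functions never perturb the user's random stream.
#' A `NULL` seed evaluates `code` under the current stream.
#'
#' @param seed integer scalar or `NULL`.
#' @param code expression to evaluate.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  assert_scalar_number(seed, "seed")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(code)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("`%s` must be in [%s, %s], got %s", name,
                 format(lower), format(upper), format(x)), call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1) {
  assert_scalar_number(x, name, lower = min)
  if (x != round(x)) {
    stop(sprintf("`%s` must be an integer, got %s", name, format(x)),
         call. = FALSE)
  }
  invisible(as.integer(x))
}

assert_expression_matrix <- function(x, name = "expr") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric matrix (genes x samples)", name),
         call. = FALSE)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop(sprintf("`%s` must have gene rownames and sample colnames", name),
         call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) {
    stop(sprintf("`%s` has duplicated gene symbols", name), call. = FALSE)
  }
  if (anyDuplicated(colnames(x))) {
    stop(sprintf("`%s` has duplicated sample IDs", name), call. = FALSE)
  }
  if (any(!is.finite(x))) {
    stop(sprintf("`%s` contains non-finite values", name), call. = FALSE)
  }
  invisible(x)
}

assert_survival <- function(time, event) {
  if (!is.numeric(time) || length(time) == 0L) {
    stop("`time` must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop("survival times must be finite and > 0", call. = FALSE)
  }
  if (length(event) != length(time) || !all(event %in% c(0, 1))) {
    stop("`event` must be a 0/1 vector matching `time`", call. = FALSE)
  }
  invisible(NULL)
}

row_sds <- function(x) {
  n <- ncol(x)
  sqrt(rowSums((x - rowMeans(x))^2) / (n - 1))
}

# Row-wise z-score; constant rows are mapped to all-zero with a warning
# (they carry no clustering/scoring information either way).
scale_rows <- function(x) {
  s <- row_sds(x)
  zero <- s <= 0 | !is.finite(s)
  if (any(zero)) {
    warning(sprintf("%d constant feature(s) set to zero after standardization: %s",
                    sum(zero), paste(utils::head(rownames(x)[zero], 5), collapse = ", ")))
    s[zero] <- 1
  }
  z <- (x - rowMeans(x)) / s
  z[zero, ] <- 0
  z
}
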