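#' The 16-gene m6A-regulator panel
#'
#' The default clustering panel: the eight m6A "writer" methyltransferase
#' complex genes, seven "reader" effector genes and one "eraser" demethylase
#' commonly profiled together on expression arrays.
#'
#' @return A data.frame with columns `symbol` and `role`
#'   (`writer`/`reader`/`eraser`), 16 rows.
#' @examples
#' m6a_regulator_panel()
#' @export
m6a_regulator_panel <- function() {
  data.frame(
    symbol = c("WTAP", "RBM15", "RBM15B", "ZC3H13", "METTL3", "METTL14",
               "KIAA1429", "CBLL1",
               "HNRNPC", "HNRNPA2B1", "YTHDC1", "YTHDF2", "IGF2BP1",
               "ELAVL1", "LRPPRC",
               "ALKBH5"),
    role = c(rep("writer", 8L), rep("reader", 7L), "eraser"),
    stringsAsFactors = FALSE
  )
}

#' Subset an expression matrix to a feature panel
#'
#' @param expr numeric gene-by-sample matrix with gene rownames.
#' @param symbols character vector of gene symbols to keep (in this order).
#' @return The sub-matrix `expr[symbols, ]`.
#' @export
subset_features <- function(expr, symbols) {
  assert_expression_matrix(expr)
  missing <- setdiff(symbols, rownames(expr))
  if (length(missing) > 0L) {
    stop("feature row(s) absent from expression matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  expr[symbols, , drop = FALSE]
}
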