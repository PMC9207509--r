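# Reading/writing the plain-text interchange formats: expression TSV
# (genes as rows, first column the gene symbol, header = sample IDs),
# clinical TSV keyed by sample, and Broad-dialect GMT gene sets.

#' Read a gene-by-sample expression TSV
#'
#' Expects a tab-separated file whose first column holds gene symbols and
#' whose remaining columns are samples (header row = sample IDs). Values
#' must all be finite numbers; any unparseable or missing cell aborts with
#' the offending gene/sample named. Duplicate gene symbols are collapsed to
#' the row with the highest mean expression (the usual
#' probe-to-gene convention for microarray matrices).
#'
#' @param path file path.
#' @param batch_label optional cohort label stored as the `"batch"`
#'   attribute of the returned matrix.
#' @return Numeric matrix, genes x samples.
#' @export
read_expression <- function(path, batch_label = NULL) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    stop("empty or column-less expression file: ", path, call. = FALSE)
  }
  genes <- raw[[1L]]
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals),
                                 dimnames = list(genes, colnames(vals))))
  bad <- which(!is.finite(num), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric or missing expression value at gene '%s', sample '%s'",
                 genes[bad[1L, 1L]], colnames(num)[bad[1L, 2L]]),
         call. = FALSE)
  }
  if (anyDuplicated(genes)) {
    means <- rowMeans(num)
    keep <- unlist(lapply(split(seq_along(genes), genes),
                          function(i) i[which.max(means[i])]),
                   use.names = FALSE)
    num <- num[sort(keep), , drop = FALSE]
  }
  if (!is.null(batch_label)) attr(num, "batch") <- batch_label
  num
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()]; values are written at full double
#' precision so that a write/read round trip is exact to ~1e-15.
#'
#' @param expr numeric gene-by-sample matrix.
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  assert_expression_matrix(expr)
  df <- data.frame(gene = rownames(expr),
                   format(expr, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-sample clinical table
#'
#' TSV with at least `sample`, `os_time` (years, > 0) and `os_event`
#' (0/1); extra covariate columns pass through untouched.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_clinical <- function(path) {
  clin <- utils::read.delim(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  needed <- c("sample", "os_time", "os_event")
  missing <- setdiff(needed, names(clin))
  if (length(missing) > 0L) {
    stop("clinical table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  has_surv <- !is.na(clin$os_time)
  if (any(clin$os_time[has_surv] <= 0)) {
    stop("clinical os_time values must be > 0", call. = FALSE)
  }
  if (!all(clin$os_event[has_surv] %in% c(0, 1))) {
    stop("clinical os_event must be 0/1", call. = FALSE)
  }
  clin
}

#' Merge expression cohorts on their common genes
#'
#' @param cohorts named list of gene-by-sample matrices; names become the
#'   batch labels.
#' @return list with `expression` (merged matrix over the gene
#'   intersection) and `batch` (per-sample factor).
#' @export
merge_cohorts <- function(cohorts) {
  if (is.null(names(cohorts)) || any(names(cohorts) == "")) {
    stop("`cohorts` must be a named list (names = batch labels)", call. = FALSE)
  }
  common <- Reduce(intersect, lapply(cohorts, rownames))
  if (length(common) == 0L) stop("cohorts share no genes", call. = FALSE)
  mats <- lapply(cohorts, function(m) m[common, , drop = FALSE])
  expr <- do.call(cbind, unname(mats))
  batch <- factor(rep(names(cohorts), vapply(mats, ncol, 1L)))
  list(expression = expr, batch = batch)
}

#' Read gene sets from a GMT file
#'
#' Broad dialect: one set per line, tab-separated `name`, `description`,
#' then >= 1 member symbols. Duplicate members within a set are dropped.
#'
#' @param path file path.
#' @return Named list of character vectors (one per set).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path, call. = FALSE)
  sets <- vector("list", length(lines))
  nm <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    f <- f[nzchar(f)]
    if (length(f) < 3L) {
      stop(sprintf("malformed GMT line %d: need name, description and >= 1 member", i),
           call. = FALSE)
    }
    nm[i] <- f[1L]
    sets[[i]] <- unique(f[-(1:2)])
  }
  stats::setNames(sets, nm)
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description description field (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
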