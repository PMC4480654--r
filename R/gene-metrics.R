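# Expression-derived per-gene covariates.

#' Tissue specificity index (tau)
#'
#' `tau = sum_i (1 - x_i / x_max) / (n - 1)`: 0 for uniformly expressed
#' (housekeeping) genes, 1 for single-tissue expression. Invariant to positive
#' rescaling of the abundance vector.
#'
#' @param expr non-negative per-tissue abundances (>= 2 tissues)
#' @return tau in `[0, 1]`, or `NA` for an all-zero vector
#' @export
#' @examples
#' tau(c(8, 4, 0)) # 0.75
tau <- function(expr) {
  if (length(expr) < 2L) stop("tau needs >= 2 tissues", call. = FALSE)
  if (any(expr < 0)) stop("abundances must be non-negative", call. = FALSE)
  m <- max(expr)
  if (m == 0) return(NA_real_)
  sum(1 - expr / m) / (length(expr) - 1L)
}

#' Expression breadth
#'
#' Number of tissues with abundance above a presence threshold.
#' @param expr per-tissue abundances
#' @param threshold presence cutoff (default 0: any positive abundance)
#' @return integer tissue count
#' @export
breadth <- function(expr, threshold = 0) {
  sum(expr > threshold)
}

#' Z-score transform across genes
#'
#' `(x - mean) / sd` with the sample standard deviation, allowing direct
#' comparison of expression summaries from different platforms.
#' @param values per-gene summary values (>= 2 distinct)
#' @return standardized values (mean 0, sd 1)
#' @export
zscore <- function(values) {
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0)
    stop("zscore undefined for (near-)constant input", call. = FALSE)
  (values - mean(values)) / s
}

#' Per-gene covariate table from an expression matrix
#'
#' @param expr_matrix data.frame with a `gene_id` column and one column per
#'   tissue (non-negative abundances)
#' @param summary per-gene expression summary: across-tissue `mean` (default)
#'   or `max`
#' @param breadth_threshold presence cutoff for [breadth()]
#' @return data.frame: `gene_id, expression_level, expression_z, breadth, tau`
#' @export
gene_covariates <- function(expr_matrix, summary = c("mean", "max"),
                            breadth_threshold = 0) {
  summary <- match.arg(summary)
  stopifnot("gene_id" %in% names(expr_matrix))
  tissues <- setdiff(names(expr_matrix), "gene_id")
  if (anyDuplicated(tissues)) stop("tissue labels must be unique",
                                   call. = FALSE)
  m <- as.matrix(expr_matrix[, tissues, drop = FALSE])
  if (any(m < 0)) stop("expression matrix has negative entries", call. = FALSE)
  lvl <- if (summary == "mean") rowMeans(m) else apply(m, 1, max)
  data.frame(
    gene_id = expr_matrix$gene_id,
    expression_level = lvl,
    expression_z = zscore(lvl),
    breadth = apply(m, 1, breadth, threshold = breadth_threshold),
    tau = apply(m, 1, tau),
    stringsAsFactors = FALSE)
}
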