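# The statistical battery: Spearman, partial Spearman controlling for
# expression, comparison of dependent (overlapping) correlations via Fisher z,
# a 2x2 chi-square on the proportion of genes with dN/dS > 1, and a
# Kruskal-Wallis distribution comparison.

#' Spearman rank correlation
#'
#' Rho on average ranks (ties allowed), with the two-sided p-value from the t
#' approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` df.
#' Incomplete pairs are dropped (pairwise-complete deletion).
#'
#' @param x,y paired per-gene values
#' @return list `rho, n, p`
#' @export
spearman <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need >= 3 complete pairs", call. = FALSE)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("constant vector: Spearman's rho undefined", call. = FALSE)
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(t_stat), df = n - 2)
  }
  list(rho = rho, n = n, p = p)
}

#' Partial Spearman correlation
#'
#' Rank-transforms all three variables and computes
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`, removing
#' the (monotone) effect of the control variable. p from the t approximation
#' on `n - 3` df.
#'
#' @param x,y variables of interest
#' @param z control variable
#' @return list `rho, n, p`
#' @export
partial_spearman <- function(x, y, z) {
  ok <- stats::complete.cases(x, y, z)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  n <- length(x)
  if (n < 4L) stop("need >= 4 complete triples", call. = FALSE)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L ||
      length(unique(z)) < 2L)
    stop("constant vector: partial Spearman undefined", call. = FALSE)
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  r_xy <- stats::cor(rx, ry)
  r_xz <- stats::cor(rx, rz)
  r_yz <- stats::cor(ry, rz)
  if (abs(r_xz) >= 1 - 1e-12 || abs(r_yz) >= 1 - 1e-12)
    stop("degenerate control: |correlation with z| = 1", call. = FALSE)
  rho <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  p <- if (abs(rho) >= 1) 0 else {
    t_stat <- rho * sqrt((n - 3) / (1 - rho^2))
    2 * stats::pt(-abs(t_stat), df = n - 3)
  }
  list(rho = rho, n = n, p = p)
}

#' Compare two dependent correlations sharing one variable
#'
#' Tests `rho_a = cor(x, a)` against `rho_b = cor(x, b)` given
#' `rho_ab = cor(a, b)`, via Fisher z transforms (`atanh`) and Steiger's
#' (1980) modification of the Hotelling-Williams test, reported as a t
#' statistic on `n - 3` df (the form used here is named in the output).
#'
#' @param rho_a,rho_b the two correlations sharing a variable, in (-1, 1)
#' @param rho_ab correlation between the two non-shared variables
#' @param n sample size (>= 4)
#' @return list `t_stat, df, p, method`
#' @export
compare_dependent_correlations <- function(rho_a, rho_b, rho_ab, n) {
  rs <- c(rho_a, rho_b, rho_ab)
  if (any(abs(rs) >= 1)) stop("correlations must lie in (-1, 1)",
                              call. = FALSE)
  if (n < 4L) stop("need n >= 4", call. = FALSE)
  za <- atanh(rho_a)
  zb <- atanh(rho_b)
  rbar <- (rho_a + rho_b) / 2
  # covariance of the two Fisher z's under dependence (Steiger 1980)
  psi <- rho_ab * (1 - 2 * rbar^2) -
    0.5 * rbar^2 * (1 - 2 * rbar^2 - rho_ab^2)
  cz <- psi / (1 - rbar^2)^2
  t_stat <- (za - zb) * sqrt((n - 3) / (2 - 2 * cz))
  df <- n - 3
  list(t_stat = t_stat, df = df, p = 2 * stats::pt(-abs(t_stat), df),
       method = "steiger-fisher-z")
}

#' Chi-square test on a shift in the proportion of genes with dN/dS > 1
#'
#' 2x2 chi-square without continuity correction on
#' `[[a, n - a], [b, n - b]]`, where `a` and `b` count genes above 1 before
#' and after edge removal. Returns an NA flag when a margin is zero.
#'
#' @param a,b counts above 1 before / after
#' @param n genes in each condition
#' @return list `chisq, df, p, applicable`
#' @export
proportion_shift_test <- function(a, b, n) {
  stopifnot(a <= n, b <= n, a >= 0, b >= 0)
  if ((a + b) == 0 || (2 * n - a - b) == 0)
    return(list(chisq = NA_real_, df = 1L, p = NA_real_, applicable = FALSE))
  num <- 2 * n * (a * (n - b) - (n - a) * b)^2
  den <- (a + b) * (2 * n - a - b) * n * n
  chisq <- num / den
  list(chisq = chisq, df = 1L,
       p = stats::pchisq(chisq, 1, lower.tail = FALSE), applicable = TRUE)
}

#' Kruskal-Wallis comparison of two or more distributions
#'
#' Standard rank-based H with tie correction, via [stats::kruskal.test()].
#' @param groups list of >= 2 numeric vectors (each with >= 2 values)
#' @return list `H, df, p, degenerate`
#' @export
distribution_shift_test <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("each group needs >= 2 values", call. = FALSE)
  all_vals <- unlist(groups)
  if (length(unique(all_vals)) == 1L)
    return(list(H = 0, df = length(groups) - 1L, p = 1, degenerate = TRUE))
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value, degenerate = FALSE)
}

#' Correlation matrix of covariates against one or more statistics
#'
#' A Table-1-style summary: Spearman's rho, n and p for every covariate x
#' statistic pair, with pairwise-complete deletion.
#'
#' @param covariates data.frame of per-gene covariates (plus `gene_id`)
#' @param stats_df data.frame of per-gene statistics (plus `gene_id`)
#' @param control optional covariate name; when given, partial Spearman
#'   coefficients controlling for it are computed instead (Table-2 style)
#' @return data.frame `variable, statistic, rho, n, p`
#' @export
correlation_table <- function(covariates, stats_df, control = NULL) {
  merged <- merge(covariates, stats_df, by = "gene_id")
  vars <- setdiff(names(covariates), "gene_id")
  if (!is.null(control)) vars <- setdiff(vars, control)
  stats_cols <- setdiff(names(stats_df), "gene_id")
  rows <- list()
  for (v in vars) {
    for (st in stats_cols) {
      res <- tryCatch({
        if (is.null(control)) spearman(merged[[v]], merged[[st]])
        else partial_spearman(merged[[v]], merged[[st]], merged[[control]])
      }, error = function(e) NULL)
      if (is.null(res)) next
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, statistic = st, rho = res$rho, n = res$n, p = res$p,
        controlled_for = if (is.null(control)) NA_character_ else control,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
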