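# Correlation battery.

test_that("spearman matches hand-ranked computation, including ties", {
  expect_equal(spearman(1:3, 3:1)$rho, -1)
  expect_equal(spearman(1:10, 1:10)$rho, 1)
  expect_equal(spearman(1:3, 3:1)$p, 0)
  set.seed(101)
  x <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3) # ties present
  y <- c(2, 7, 1, 8, 2, 8, 1, 8, 2, 8)
  got <- spearman(x, y)
  rho_oracle <- stats::cor(rank(x), rank(y)) # average ranks
  expect_equal(got$rho, rho_oracle)
  t_stat <- rho_oracle * sqrt((10 - 2) / (1 - rho_oracle^2))
  expect_equal(got$p, 2 * stats::pt(-abs(t_stat), 8))
  # missing pairs are dropped
  x2 <- c(x, NA); y2 <- c(y, 1)
  expect_equal(spearman(x2, y2)$n, 10)
  expect_error(spearman(rep(1, 5), 1:5), "constant")
})

test_that("partial spearman removes monotone control effects", {
  set.seed(102)
  z <- stats::rnorm(100)
  x <- stats::rnorm(100)
  expect_equal(partial_spearman(x, x, z)$rho, 1)
  # exactly monotone functions of the control share its ranks: degenerate
  expect_error(partial_spearman(exp(z), z^3, z), "degenerate")
  # x and y associated only through z: partial correlation ~ 0 even though
  # the raw Spearman correlation is strongly negative
  set.seed(110)
  n0 <- 3000
  z0 <- stats::rnorm(n0)
  x0 <- exp(z0 + 0.3 * stats::rnorm(n0))
  y0 <- -z0^3 + 0.3 * stats::rnorm(n0)
  expect_lt(spearman(x0, y0)$rho, -0.5)
  expect_equal(partial_spearman(x0, y0, z0)$rho, 0, tolerance = 0.06)
  # formula oracle on ranks
  r <- function(v) rank(v)
  rxy <- stats::cor(r(x0), r(y0)); rxz <- stats::cor(r(x0), r(z0))
  ryz <- stats::cor(r(y0), r(z0))
  expect_equal(partial_spearman(x0, y0, z0)$rho,
               (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2)))
  # independent control: close to the plain Spearman (n = 2000 simulation)
  set.seed(103)
  n <- 2000
  a <- stats::rnorm(n)
  b <- 0.5 * a + stats::rnorm(n)
  c0 <- stats::rnorm(n)
  expect_equal(partial_spearman(a, b, c0)$rho, spearman(a, b)$rho,
               tolerance = 0.05)
  expect_error(partial_spearman(1:10, stats::rnorm(10), 1:10), "degenerate")
})

test_that("dependent-correlation comparison is null at equal rho and calibrated", {
  eq <- compare_dependent_correlations(0.4, 0.4, 0.3, 50)
  expect_equal(eq$t_stat, 0)
  expect_equal(eq$p, 1)
  expect_equal(eq$df, 47)
  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-4)
  expect_error(compare_dependent_correlations(1, 0.5, 0.2, 10), "\\(-1, 1\\)")

  # calibration: two noisy copies of one statistic vs a covariate
  set.seed(104)
  reps <- 500
  n <- 60
  rej <- 0
  for (r in seq_len(reps)) {
    base <- stats::rnorm(n)
    cov <- 0.5 * base + stats::rnorm(n)
    a <- base + 0.8 * stats::rnorm(n)
    b <- base + 0.8 * stats::rnorm(n)
    ra <- spearman(cov, a)$rho
    rb <- spearman(cov, b)$rho
    rab <- spearman(a, b)$rho
    res <- compare_dependent_correlations(ra, rb, rab, n)
    if (res$p <= 0.05) rej <- rej + 1
  }
  ci <- stats::binom.test(rej, reps, 0.05)$conf.int
  expect_true(0.05 >= ci[1] && 0.05 <= ci[2])
})

test_that("proportion-shift chi-square matches the closed form and chisq.test", {
  expect_equal(proportion_shift_test(10, 10, 100)$chisq, 0)
  got <- proportion_shift_test(10, 30, 100)
  expect_equal(got$chisq, 12.5)
  ct <- stats::chisq.test(rbind(c(10, 90), c(30, 70)), correct = FALSE)
  expect_equal(got$chisq, unname(ct$statistic))
  expect_equal(got$p, ct$p.value)
  na_case <- proportion_shift_test(0, 0, 50)
  expect_false(na_case$applicable)
  expect_true(is.na(na_case$chisq))
})

test_that("distribution shift test reproduces rank-sum arithmetic", {
  same <- distribution_shift_test(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$p, stats::kruskal.test(list(c(1, 2, 3),
                                                c(1, 2, 3)))$p.value)
  ident <- distribution_shift_test(list(c(2, 2), c(2, 2)))
  expect_true(ident$degenerate)
  expect_equal(ident$H, 0)
  disjoint <- distribution_shift_test(list(1:20, 101:120))
  expect_lt(disjoint$p, 0.001)
  # three-group toy against brute-force H (no ties)
  g1 <- c(1, 5, 9); g2 <- c(2, 6, 10); g3 <- c(3, 7, 30)
  all_v <- c(g1, g2, g3)
  rk <- rank(all_v)
  n <- length(all_v)
  Rbar <- tapply(rk, rep(1:3, each = 3), sum)
  H <- 12 / (n * (n + 1)) * sum(Rbar^2 / 3) - 3 * (n + 1)
  got <- distribution_shift_test(list(g1, g2, g3))
  expect_equal(got$H, H, tolerance = 1e-10)
})

test_that("correlation invariance under strictly monotone transforms", {
  set.seed(105)
  x <- stats::rlnorm(40)
  y <- stats::rnorm(40)
  z <- stats::rgamma(40, 2)
  expect_equal(spearman(x, y)$rho, spearman(log(x), y)$rho)
  expect_equal(partial_spearman(x, y, z)$rho,
               partial_spearman(exp(x / 10), y, sqrt(z))$rho,
               tolerance = 1e-12)
})

test_that("correlation_table produces Table-1/2 style summaries", {
  ds <- shared_dataset()
  pw <- pairwise_dnds_table(ds$genes, c("ingroup1", "ingroup2"))
  cov <- gene_covariates(ds$expression)
  stats_df <- data.frame(gene_id = pw$gene_id, omega = pw$omega)
  tbl <- correlation_table(cov, stats_df)
  expect_true(all(c("variable", "statistic", "rho", "n", "p") %in%
                    names(tbl)))
  expect_true(all(abs(tbl$rho) <= 1))
  ptbl <- correlation_table(cov, stats_df, control = "expression_level")
  expect_false("expression_level" %in% ptbl$variable)
  expect_true(all(ptbl$controlled_for == "expression_level"))
})
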