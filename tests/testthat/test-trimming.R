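# Edge trimming, matched random removal, and the randomization test.

make_clean_gene <- function(exon_codons = c(100), seed = 61, n_subs = 15) {
  set.seed(seed)
  codons <- exonedge:::all_codons()[exonedge:::sense_codon_idx()]
  n <- sum(exon_codons)
  a <- sample(codons, n, replace = TRUE)
  b <- a
  mut <- sample(n, n_subs)
  for (i in mut) b[i] <- sample(setdiff(codons, a[i]), 1)
  ends <- cumsum(exon_codons)
  starts <- c(0, ends[-length(ends)])
  gene_alignment("clean", c(sp1 = paste0(a, collapse = ""),
                            sp2 = paste0(b, collapse = "")),
                 data.frame(exon_index = seq_along(exon_codons) - 1,
                            codon_start = starts, codon_end = ends))
}

test_that("eligibility requires fully aligned, in-frame, multiple-of-three", {
  g <- make_two_species_gene(gap = TRUE)
  el <- eligible_exons(g, trim_spec(5))
  expect_equal(el$exon_index, 0) # gapped second exon excluded

  # upstream override columns are honoured
  g2 <- make_two_species_gene()
  g2$exon_blocks$multiple_of_three[2] <- FALSE
  expect_equal(eligible_exons(g2, trim_spec(5))$exon_index, 0)

  # all blocks gapped -> empty list
  g3 <- gene_alignment("x", c(a = "ATGAAA", b = "AT--AA"),
                       data.frame(exon_index = 0, codon_start = 0,
                                  codon_end = 2))
  expect_equal(nrow(eligible_exons(g3, trim_spec(1))), 0)
})

test_that("trim arithmetic matches the edge rules", {
  g <- make_clean_gene(100)
  tr <- trim_edges(g, trim_spec(10))
  expect_equal(tr$n_codons, 80)
  expect_true(attr(tr, "post_trim_ok"))

  g2 <- make_clean_gene(c(60, 60))
  tr2 <- trim_edges(g2, trim_spec(30))
  expect_s3_class(tr2, "trimmed_empty") # max(0, 60 - 60) twice
  expect_equal(tr2$n_codons, 0)
  expect_false(attr(tr2, "post_trim_ok"))

  g3 <- make_clean_gene(c(110, 110))
  tr3 <- trim_edges(g3, trim_spec(30))
  expect_equal(tr3$n_codons, 100)
  expect_true(attr(tr3, "post_trim_ok"))

  # internal_edges_only exempts the gene's terminal edges
  g4 <- make_clean_gene(c(50, 50))
  tr4 <- trim_edges(g4, trim_spec(10, "internal_edges_only"))
  expect_equal(tr4$n_codons, 80) # 10 off the 3' of exon1, 5' of exon2
})

test_that("trimmed codons are a subset of the original (multiset)", {
  g <- make_clean_gene(c(40, 60), seed = 62)
  tr <- trim_edges(g, trim_spec(5))
  orig <- exonedge:::codon_matrix(g)[, "sp1"]
  kept <- exonedge:::codon_matrix(tr)[, "sp1"]
  expect_true(all(table(kept) <= table(orig)[names(table(kept))]))
})

test_that("random_trim is paired, uniform, and seed-deterministic", {
  g <- make_clean_gene(100)
  plan <- exonedge:::trim_plan(g, trim_spec(10))
  expect_equal(length(plan$removed), 20)
  set.seed(1); r1 <- random_trim(g, 20)
  set.seed(1); r2 <- random_trim(g, 20)
  expect_identical(r1$sequences, r2$sequences)
  expect_equal(r1$n_codons, 80) # same number removed as sequential
  set.seed(2)
  expect_identical(random_trim(g, 0)$sequences, g$sequences)
  expect_error(random_trim(g, 101), "exceeds")
})

test_that("randomization p follows (s - q + 1) / (s + 1) within its bounds", {
  g <- make_clean_gene(c(80, 80), seed = 63, n_subs = 30)
  set.seed(5)
  rt <- randomization_test(g, trim_spec(10), c("dN", "dS", "omega"),
                           c("sp1", "sp2"), s = 50)
  expect_equal(rt$p, (rt$s - rt$q + 1) / (rt$s + 1))
  expect_true(all(rt$p >= 1 / (rt$s + 1) & rt$p <= 1))
  expect_true(all(!rt$unreliable))
  # shared removal sets: null matrices row-align across statistics
  nulls <- attr(rt, "null_values")
  expect_equal(dim(nulls), c(50, 3))
})

test_that("rho_randomization recovers a perfect correlation and attenuation", {
  ds <- shared_dataset()
  spec <- trim_spec(10)
  pair <- c("ingroup1", "ingroup2")
  # covariate == sequentially trimmed statistic -> observed rho = 1
  seq_stat <- vapply(ds$genes, function(g) {
    plan <- exonedge:::trim_plan(g, spec)
    if (!length(plan$kept)) return(NA_real_)
    ctx <- exonedge:::trim_stat_context(g, pair)
    exonedge:::trim_stat_value(ctx, plan$kept, "omega")
  }, numeric(1))
  set.seed(6)
  rr <- rho_randomization(ds$genes, seq_stat, spec, "omega", s = 10)
  expect_equal(rr$observed, 1)
  expect_equal(rr$p, (rr$s - rr$q + 1) / (rr$s + 1))
  expect_error(rho_randomization(ds$genes, rep(1, length(ds$genes)), spec,
                                 "omega", s = 5),
               "degenerate")
})

test_that("attenuation p-values are calibrated under no edge effect", {
  # scaled-down null calibration: gene sets simulated without edge
  # constraint, attenuation test at alpha = 0.05
  set.seed(71)
  n_sets <- 60
  rej <- 0
  for (r in seq_len(n_sets)) {
    cfg <- sim_config(n_genes = 40, phi_edge = 1, psi_edge = 1,
                      edge_expression_link = FALSE, expression_rho = -0.4)
    ds <- simulate_dataset(cfg, seed = 5000 + r)
    cov <- gene_covariates(ds$expression)
    rr <- rho_randomization(ds$genes, cov$expression_level, trim_spec(10),
                            "omega", s = 79, min_genes = 20)
    if (rr$p <= 0.05) rej <- rej + 1
  }
  ci <- stats::binom.test(rej, n_sets, 0.05)$conf.int
  expect_true(0.05 >= ci[1] && 0.05 <= ci[2])
})

test_that("sequential trimming under edge constraint raises dS medians", {
  cfg <- sim_config(n_genes = 120, phi_edge = 0.3, psi_edge = 0.3,
                    edge_expression_link = FALSE)
  ds <- simulate_dataset(cfg, seed = 81)
  spec <- trim_spec(10)
  pair <- c("ingroup1", "ingroup2")
  ds_untrimmed <- ds_trimmed <- c()
  for (g in ds$genes) {
    plan <- exonedge:::trim_plan(g, spec)
    if (!length(plan$kept) || 3 * length(plan$kept) < 150) next
    ctx <- exonedge:::trim_stat_context(g, pair)
    u <- exonedge:::trim_stat_value(ctx, plan$base, "dS")
    t <- exonedge:::trim_stat_value(ctx, plan$kept, "dS")
    if (!is.na(u) && !is.na(t)) {
      ds_untrimmed <- c(ds_untrimmed, u)
      ds_trimmed <- c(ds_trimmed, t)
    }
  }
  expect_gt(stats::median(ds_trimmed), stats::median(ds_untrimmed))
})
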