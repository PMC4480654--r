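# Synthetic-data generator: degenerate regimes, truth consistency, copula
# targets, edge localisation, file round trips.

test_that("zero branch rates give three identical sequences", {
  cfg <- sim_config(n_genes = 3, rate_ingroup1 = 0, rate_ingroup2 = 0,
                    rate_outgroup = 0, theta_s = 0, theta_n = 0)
  ds <- simulate_dataset(cfg, seed = 121)
  for (g in ds$genes) {
    expect_identical(g$sequences[["ingroup1"]], g$sequences[["ingroup2"]])
    expect_identical(g$sequences[["ingroup1"]], g$sequences[["outgroup"]])
  }
  expect_equal(nrow(ds$snps), 0)
})

test_that("omega_g = 0 yields zero non-synonymous differences on all branches", {
  cfg <- sim_config(n_genes = 5, omega_fixed = 0, phi_edge = 1, psi_edge = 1,
                    edge_expression_link = FALSE)
  # omega_fixed = 0 must silence every non-synonymous acceptance. (The
  # pathway-averaged recount Nd can be fractional even for an all-synonymous
  # history, e.g. two synonymous Leu steps whose reverse path ordering
  # crosses Phe, so the accepted-attempt bookkeeping is the right check.)
  ds <- simulate_dataset(cfg, seed = 122)
  expect_true(all(ds$truth$accepted_nonsyn_ingroup1 == 0))
  expect_true(all(ds$truth$accepted_nonsyn_ingroup2 == 0))
  expect_true(all(ds$truth$accepted_nonsyn_outgroup == 0))
  expect_true(any(ds$truth$Sd_ingroup1 > 0)) # synonymous changes still flow
})

test_that("truth records match a direct recount of tip-vs-root differences", {
  ds <- shared_dataset()
  tabs <- exonedge:::codon_diff_tables()
  codons <- exonedge:::all_codons()
  for (i in 1:10) {
    g <- ds$genes[[i]]
    td <- ds$truth_detail[[i]]
    root_idx <- match(td$root_codons, codons)
    for (b in exonedge:::BRANCHES) {
      tip <- exonedge:::codon_matrix(g)[, b]
      ij <- cbind(root_idx, match(tip, codons))
      expect_equal(unname(td$branch_Sd[[b]]), sum(tabs$SD[ij]),
                   tolerance = 1e-10)
      expect_equal(unname(td$branch_Nd[[b]]), sum(tabs$ND[ij]),
                   tolerance = 1e-10)
    }
  }
})

test_that("emitted files parse through the package readers unchanged", {
  ds <- simulate_dataset(sim_config(n_genes = 4, gap_fraction = 0.3),
                         seed = 123)
  dir <- tempfile("simdata")
  write_dataset(ds, dir)
  emap <- file.path(dir, "exon_map.tsv")
  for (g in ds$genes) {
    fa <- file.path(dir, "alignments", paste0(g$gene_id, ".fasta"))
    g2 <- read_gene_alignment(fa, emap, gene_id = g$gene_id)
    expect_identical(g2$sequences, g$sequences)
    expect_equal(g2$exon_blocks, g$exon_blocks)
    expect_s3_class(g2, "trio_alignment")
  }
  snps <- utils::read.delim(file.path(dir, "snps.tsv"))
  if (nrow(snps)) {
    g1 <- ds$genes[[match(snps$gene_id[1], vapply(ds$genes, `[[`,
                                                  character(1), "gene_id"))]]
    expect_no_error(classify_snp_table(g1, snps))
  }
  expect_true(file.exists(file.path(dir, "manifest.json")))
})

test_that("gap injection corrupts blocks and clears eligibility flags", {
  ds <- simulate_dataset(sim_config(n_genes = 12, gap_fraction = 0.5),
                         seed = 124)
  flags <- unlist(lapply(ds$genes, function(g) g$exon_blocks$fully_aligned))
  expect_true(any(!flags))
  expect_true(any(flags))
})

test_that("the expression copula hits its Spearman target", {
  cfg0 <- sim_config(n_genes = 500, expression_rho = 0, edge_depth = 0,
                     edge_expression_link = FALSE)
  ds0 <- simulate_dataset(cfg0, seed = 125)
  cov0 <- gene_covariates(ds0$expression)
  expect_lt(abs(spearman(cov0$expression_level, ds0$truth$omega_g)$rho), 0.1)

  cfg4 <- sim_config(n_genes = 500, expression_rho = -0.4)
  ds4 <- simulate_dataset(cfg4, seed = 126)
  cov4 <- gene_covariates(ds4$expression)
  expect_lt(abs(spearman(cov4$expression_level,
                         ds4$truth$omega_g)$rho - (-0.4)), 0.07)
  expect_error(sim_config(expression_rho = -0.99), "unreachable")
})

test_that("edge constraint localises substitutions away from exon edges", {
  cfg <- sim_config(n_genes = 300, phi_edge = 0.3, psi_edge = 0.3,
                    edge_depth = 10, edge_expression_link = FALSE)
  ds <- simulate_dataset(cfg, seed = 127)
  edge_subs <- edge_sites <- int_subs <- int_sites <- 0
  tabs <- exonedge:::codon_diff_tables()
  codons <- exonedge:::all_codons()
  for (i in seq_along(ds$genes)) {
    g <- ds$genes[[i]]
    td <- ds$truth_detail[[i]]
    cm <- exonedge:::codon_matrix(g)
    diffs <- tabs$HAM[cbind(match(cm[, "ingroup1"], codons),
                            match(cm[, "ingroup2"], codons))]
    edge_subs <- edge_subs + sum(diffs[td$edge_sites])
    int_subs <- int_subs + sum(diffs[!td$edge_sites])
    edge_sites <- edge_sites + sum(td$edge_sites)
    int_sites <- int_sites + sum(!td$edge_sites)
  }
  # one-sided binomial: edge density below interior density
  pt <- stats::prop.test(c(edge_subs, int_subs), c(edge_sites, int_sites),
                         alternative = "less")
  expect_lt(pt$p.value, 0.01)
})

test_that("per-gene streams make genes reproducible independently of order", {
  cfg <- sim_config(n_genes = 6)
  ds1 <- simulate_dataset(cfg, seed = 128)
  ds2 <- simulate_dataset(cfg, seed = 128)
  for (i in 1:6)
    expect_identical(ds1$genes[[i]]$sequences, ds2$genes[[i]]$sequences)
  expect_identical(ds1$snps, ds2$snps)
  expect_identical(ds1$expression, ds2$expression)
})
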