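# Lineage-specific estimator: parsimony ancestors, branch counts, filters.

test_that("ancestral inference matches exhaustive 61-codon enumeration", {
  t1 <- make_trio_from_codons("TTC", "TTT", "TTT")
  anc <- infer_ancestral_codons(t1)
  expect_equal(anc$ancestors[[1]], "TTT")
  expect_equal(anc$cost, 1)

  t0 <- make_trio_from_codons("TTT", "TTT", "TTT")
  anc0 <- infer_ancestral_codons(t0)
  expect_equal(anc0$ancestors[[1]], "TTT")
  expect_equal(anc0$cost, 0)

  t3 <- make_trio_from_codons("TTT", "TTC", "TTA")
  anc3 <- infer_ancestral_codons(t3)
  expect_setequal(anc3$ancestors[[1]], c("TTT", "TTC", "TTA"))
  expect_equal(anc3$cost, 2)

  # random columns against an independent exhaustive scan
  set.seed(21)
  sense <- exonedge:::all_codons()[exonedge:::sense_codon_idx()]
  for (r in 1:25) {
    tips <- sample(sense, 3, replace = TRUE)
    tr <- make_trio_from_codons(tips[1], tips[2], tips[3])
    got <- infer_ancestral_codons(tr)
    ham <- function(x, y) sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
    costs <- vapply(sense, function(anc) sum(vapply(tips, ham, numeric(1),
                                                    x = anc)), numeric(1))
    expect_equal(got$cost, min(costs))
    expect_setequal(got$ancestors[[1]], sense[costs == min(costs)])
  }
})

test_that("branch counts average over tied ancestors with uniform weights", {
  bc <- branch_counts(make_trio_from_codons("TTC", "TTT", "TTT"))
  expect_equal(unname(bc$branches$ingroup1["Sd"]), 1)
  expect_equal(unname(bc$branches$ingroup1["Nd"]), 0)
  expect_equal(unname(bc$branches$ingroup2["Sd"] +
                        bc$branches$ingroup2["Nd"]), 0)
  expect_equal(unname(bc$branches$outgroup["Sd"] +
                        bc$branches$outgroup["Nd"]), 0)

  # three-way tie: ancestors TTT, TTC, TTA each contribute toward tip TTT
  bc3 <- branch_counts(make_trio_from_codons("TTT", "TTC", "TTA"))
  expect_equal(unname(bc3$branches$ingroup1["Sd"]), 1 / 3)
  expect_equal(unname(bc3$branches$ingroup1["Nd"]), 1 / 3)

  all_same <- make_trio_from_codons(rep("ATG", 5), rep("ATG", 5),
                                    rep("ATG", 5))
  bca <- branch_counts(all_same)
  for (b in exonedge:::BRANCHES)
    expect_equal(unname(bca$branches[[b]]["Sd"] + bca$branches[[b]]["Nd"]), 0)
})

test_that("per-column branch differences sum to the mean parsimony cost", {
  set.seed(22)
  sense <- exonedge:::all_codons()[exonedge:::sense_codon_idx()]
  for (r in 1:20) {
    tips <- sample(sense, 3, replace = TRUE)
    tr <- make_trio_from_codons(tips[1], tips[2], tips[3])
    bc <- branch_counts(tr)
    anc <- infer_ancestral_codons(tr)
    total <- sum(vapply(exonedge:::BRANCHES, function(b)
      unname(bc$branches[[b]]["Sd"] + bc$branches[[b]]["Nd"]), numeric(1)))
    expect_equal(total, anc$cost, tolerance = 1e-10)
  }
})

test_that("label-swap of the ingroups exchanges their estimates exactly", {
  ds <- shared_dataset()
  g <- ds$genes[[3]]
  swapped <- trio_alignment(g$gene_id,
                            c(ingroup1 = g$sequences[["ingroup2"]],
                              ingroup2 = g$sequences[["ingroup1"]],
                              outgroup = g$sequences[["outgroup"]]),
                            g$exon_blocks[, 1:3])
  e1 <- estimate_lineage(g)
  e2 <- estimate_lineage(swapped)
  cols <- c("Sd", "Nd", "S", "N", "dS", "dN", "omega")
  expect_equal(e1[e1$branch == "ingroup1", cols],
               e2[e2$branch == "ingroup2", cols], ignore_attr = TRUE)
  expect_equal(e1[e1$branch == "ingroup2", cols],
               e2[e2$branch == "ingroup1", cols], ignore_attr = TRUE)
  expect_equal(e1[e1$branch == "outgroup", cols],
               e2[e2$branch == "outgroup", cols], ignore_attr = TRUE)
})

test_that("branch filters flag dS/dN thresholds with the right reasons", {
  # construct trios whose ingroup1 branch sits in each regime by simulation
  # at controlled rates, then check flags against the recomputed values
  set.seed(23)
  cfg_low <- sim_config(n_genes = 1, rate_ingroup1 = 0,
                        rate_ingroup2 = 0.1, rate_outgroup = 0.1,
                        phi_edge = 1, psi_edge = 1,
                        edge_expression_link = FALSE)
  ds <- simulate_dataset(cfg_low, seed = 77)
  e <- estimate_lineage(ds$genes[[1]])
  i1 <- e[e$branch == "ingroup1", ]
  expect_false(i1$valid)
  expect_equal(i1$reason, "dS_low")

  # columns with gaps are skipped and the <150 bp rule applies
  short <- make_trio_from_codons(rep("ATG", 20), rep("ATG", 20),
                                 rep("ATG", 20))
  es <- estimate_lineage(short)
  expect_true(all(!es$valid))
  expect_true(all(es$reason == "too_short"))
})

test_that("under a symmetric process ingroup omega differences centre at 0", {
  cfg <- sim_config(n_genes = 300, phi_edge = 1, psi_edge = 1,
                    edge_expression_link = FALSE)
  ds <- simulate_dataset(cfg, seed = 31)
  lin <- lineage_dnds_table(ds$genes)
  w1 <- lin[lin$branch == "ingroup1", c("gene_id", "omega", "valid")]
  w2 <- lin[lin$branch == "ingroup2", c("gene_id", "omega", "valid")]
  m <- merge(w1, w2, by = "gene_id")
  m <- m[m$valid.x & m$valid.y & m$omega.x != m$omega.y, ]
  bt <- stats::binom.test(sum(m$omega.x > m$omega.y), nrow(m))
  expect_gt(bt$p.value, 0.01)
})
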