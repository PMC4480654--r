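# Ground-truth generator: orthologue trios with exonic structure, optional
# elevated constraint at exon edges, gene-level constraint correlated with a
# simulated expression level, within-ingroup polymorphism, and EST chains.
#
# The per-site process is attempt-and-accept: substitution attempts arrive as
# a Poisson stream over sites, each proposing a uniform alternative base;
# attempts creating a stop codon are rejected, synonymous attempts are
# accepted with probability phi(site), non-synonymous attempts with
# probability omega_g * psi(site), where phi/psi drop below 1 within
# `edge_depth` codons of an exon edge. No indels are simulated: all exons are
# fully aligned by construction (a gap-injection switch corrupts a stated
# fraction of blocks to exercise eligibility flags).

#' Simulation configuration
#'
#' Defaults define the edge-constrained study condition: three-taxon trios
#' ((ingroup1, ingroup2), outgroup), geometric exon counts (mean 5),
#' log-normal exon lengths (median 53 codons), purifying gene-level
#' constraint (log-normal omega_g, median 0.2), stronger constraint on
#' non-synonymous than synonymous edge sites (psi_edge < phi_edge), edge
#' constraint strength tied to expression rank, and a generating Spearman
#' correlation of -0.4 between expression level and omega_g.
#'
#' @param n_genes genes to simulate
#' @param n_tissues tissues in the expression matrix
#' @param exon_count_mean mean of the (shifted) geometric exon-count
#'   distribution
#' @param exon_len_meanlog,exon_len_sdlog log-normal exon length (codons)
#' @param exon_len_min,exon_len_max truncation bounds (codons)
#' @param rate_ingroup1,rate_ingroup2,rate_outgroup expected substitution
#'   attempts per site per branch
#' @param omega_meanlog,omega_sdlog,omega_max gene-level non-synonymous
#'   acceptance distribution (log-normal, truncated)
#' @param omega_fixed when non-NULL, every gene uses this omega_g (calibration
#'   regimes)
#' @param branch_omega_scale named numeric of length 3: per-branch multipliers
#'   on the non-synonymous acceptance (lineage-specific selection regimes;
#'   default all 1)
#' @param edge_depth constraint depth at exon edges, in codons
#' @param phi_edge,psi_edge synonymous / non-synonymous acceptance multipliers
#'   at edge sites, in (0, 1]
#' @param edge_expression_link when TRUE, the per-gene edge constraint
#'   strength scales with the gene's expression rank (multiplier^u with u the
#'   expression percentile); when FALSE all genes get the full multiplier
#' @param expression_rho target Spearman correlation between expression level
#'   and omega_g (Gaussian copula; |rho| <= 0.95)
#' @param theta_s,theta_n polymorphism attempt rates per site for attempts
#'   resolving to synonymous / non-synonymous edits
#' @param est_mean_count mean mapped ESTs per gene (Poisson)
#' @param est_two_isoform_prob probability a gene has two incompatible
#'   isoforms (50/50 mixture)
#' @param gap_fraction fraction of exon blocks corrupted by a gap in one
#'   non-reference species (exercises trimming eligibility; default 0)
#' @return a `sim_config` list
#' @export
sim_config <- function(n_genes = 300, n_tissues = 8,
                       exon_count_mean = 5,
                       exon_len_meanlog = log(53), exon_len_sdlog = 0.45,
                       exon_len_min = 5, exon_len_max = 250,
                       rate_ingroup1 = 0.12, rate_ingroup2 = 0.12,
                       rate_outgroup = 0.35,
                       omega_meanlog = log(0.2), omega_sdlog = 0.5,
                       omega_max = 1.5, omega_fixed = NULL,
                       branch_omega_scale = c(ingroup1 = 1, ingroup2 = 1,
                                              outgroup = 1),
                       edge_depth = 10, phi_edge = 0.5, psi_edge = 0.15,
                       edge_expression_link = TRUE,
                       expression_rho = -0.4,
                       theta_s = 0.02, theta_n = 0.02,
                       est_mean_count = 15, est_two_isoform_prob = 0.5,
                       gap_fraction = 0) {
  stopifnot(n_genes >= 1, n_tissues >= 1,
            rate_ingroup1 >= 0, rate_ingroup2 >= 0, rate_outgroup >= 0,
            phi_edge > 0, phi_edge <= 1, psi_edge > 0, psi_edge <= 1,
            theta_s >= 0, theta_n >= 0, edge_depth >= 0,
            gap_fraction >= 0, gap_fraction <= 1,
            length(branch_omega_scale) == 3, all(branch_omega_scale >= 0),
            setequal(names(branch_omega_scale), BRANCHES))
  if (abs(expression_rho) > 0.95)
    stop("unreachable correlation target: |rho| > 0.95", call. = FALSE)
  structure(as.list(environment()), class = "sim_config")
}

#' Neutral calibration configuration
#'
#' omega_g fixed at 1, no edge constraint, expression independent of
#' constraint — the regime in which the pipeline's mean omega should be ~1 and
#' the median neutrality index ~0.
#' @param n_genes genes to simulate
#' @param ... overrides passed to [sim_config()]
#' @export
sim_config_neutral <- function(n_genes = 300, ...) {
  sim_config(n_genes = n_genes, omega_fixed = 1, phi_edge = 1, psi_edge = 1,
             edge_expression_link = FALSE, expression_rho = 0, ...)
}

# per-gene reproducible stream: derive a sub-seed below 2^31 from the master
# seed and gene index
.gene_seed <- function(seed, i) {
  (as.numeric(seed) * 48271 + i * 16807) %% 2147483647
}

# exon structure: counts, lengths, edge flags
.sim_structure <- function(cfg) {
  n_exons <- 1L + stats::rgeom(1, 1 / cfg$exon_count_mean)
  lens <- round(stats::rlnorm(n_exons, cfg$exon_len_meanlog,
                              cfg$exon_len_sdlog))
  lens <- pmin(pmax(lens, cfg$exon_len_min), cfg$exon_len_max)
  ends <- cumsum(lens)
  starts <- c(0L, ends[-n_exons])
  blocks <- data.frame(exon_index = seq_len(n_exons) - 1L,
                       codon_start = as.integer(starts),
                       codon_end = as.integer(ends))
  n_codons <- sum(lens)
  edge <- logical(n_codons)
  if (cfg$edge_depth > 0) {
    for (b in seq_len(n_exons)) {
      s <- starts[b] + 1L; e <- ends[b]
      d <- min(cfg$edge_depth, lens[b])
      edge[s:(s + d - 1L)] <- TRUE
      edge[(e - d + 1L):e] <- TRUE
    }
  }
  list(blocks = blocks, n_codons = n_codons, edge = edge)
}

# evolve a codon index vector along one branch; returns tip codon indices
# plus accepted-attempt bookkeeping. Pure integer-table operations.
.evolve_branch <- function(codon_idx, rate, omega_g, phi_site, psi_site) {
  mt <- codon_mutation_tables()
  L3 <- 3L * length(codon_idx)
  n_att <- stats::rpois(1, rate * L3)
  acc_syn <- 0L; acc_nonsyn <- 0L
  if (n_att > 0) {
    pos <- sample.int(L3, n_att, replace = TRUE)
    alt_pick <- sample.int(3L, n_att, replace = TRUE)
    u <- stats::runif(n_att)
    ci_all <- (pos - 1L) %/% 3L + 1L
    slot_all <- ((pos - 1L) %% 3L) * 3L + alt_pick
    for (a in seq_len(n_att)) {
      ci <- ci_all[a]
      j <- mt$NEIGH[codon_idx[ci], slot_all[a]]
      if (mt$IS_STOP[j]) next
      syn <- mt$SAME_AA[codon_idx[ci], j]
      p_acc <- if (syn) phi_site[ci] else omega_g * psi_site[ci]
      if (u[a] < p_acc) {
        codon_idx[ci] <- j
        if (syn) acc_syn <- acc_syn + 1L else acc_nonsyn <- acc_nonsyn + 1L
      }
    }
  }
  list(codon_idx = codon_idx, accepted_syn = acc_syn,
       accepted_nonsyn = acc_nonsyn)
}

# pathway-averaged recount of differences between two codon index vectors
.recount_branch <- function(anc_idx, tip_idx) {
  tabs <- codon_diff_tables()
  ij <- cbind(anc_idx, tip_idx)
  list(Sd = sum(tabs$SD[ij]), Nd = sum(tabs$ND[ij]))
}

#' Simulate one orthologue trio with known ground truth
#'
#' @param cfg a [sim_config()]
#' @param gene_id identifier for the gene
#' @param omega_g gene-level non-synonymous acceptance
#' @param edge_strength u in `[0, 1]`: effective edge multipliers are
#'   `phi_edge^u`, `psi_edge^u`
#' @return list `alignment` (a [trio_alignment()]) and `truth` (omega_g,
#'   per-branch realized counts by direct recount, per-site edge flags, ...)
#' @export
simulate_gene <- function(cfg, gene_id, omega_g, edge_strength = 1) {
  st <- .sim_structure(cfg)
  if (st$n_codons == 0L) stop("zero-length gene", call. = FALSE)
  phi_site <- ifelse(st$edge, cfg$phi_edge^edge_strength, 1)
  psi_site <- ifelse(st$edge, cfg$psi_edge^edge_strength, 1)
  codons <- all_codons()
  root <- sample(sense_codon_idx(), st$n_codons, replace = TRUE)
  bos <- cfg$branch_omega_scale
  tips <- list(
    ingroup1 = .evolve_branch(root, cfg$rate_ingroup1,
                              omega_g * bos[["ingroup1"]], phi_site, psi_site),
    ingroup2 = .evolve_branch(root, cfg$rate_ingroup2,
                              omega_g * bos[["ingroup2"]], phi_site, psi_site),
    outgroup = .evolve_branch(root, cfg$rate_outgroup,
                              omega_g * bos[["outgroup"]], phi_site, psi_site))
  seqs <- vapply(tips, function(t) paste0(codons[t$codon_idx], collapse = ""),
                 character(1))

  if (cfg$gap_fraction > 0 && nrow(st$blocks) > 0) {
    for (b in seq_len(nrow(st$blocks))) {
      if (stats::runif(1) < cfg$gap_fraction) {
        sp <- sample(c("ingroup2", "outgroup"), 1)
        ci <- sample(seq(st$blocks$codon_start[b] + 1L,
                         st$blocks$codon_end[b]), 1)
        substr(seqs[[sp]], 3L * (ci - 1L) + 1L, 3L * ci) <- "---"
      }
    }
  }

  aln <- trio_alignment(gene_id, seqs, st$blocks)
  realized <- lapply(tips, function(t) .recount_branch(root, t$codon_idx))
  truth <- list(
    gene_id = gene_id, omega_g = omega_g, edge_strength = edge_strength,
    n_codons = st$n_codons, n_exons = nrow(st$blocks),
    edge_sites = st$edge, root_codons = codons[root],
    branch_Sd = vapply(realized, `[[`, numeric(1), "Sd"),
    branch_Nd = vapply(realized, `[[`, numeric(1), "Nd"),
    accepted_syn = vapply(tips, `[[`, integer(1), "accepted_syn"),
    accepted_nonsyn = vapply(tips, `[[`, integer(1), "accepted_nonsyn"))
  list(alignment = aln, truth = truth)
}

#' Simulate within-ingroup SNPs for one simulated gene
#'
#' The same attempt-and-accept process as divergence, applied to the focal
#' (ingroup1) tip: attempts arrive at rate `max(theta_s, theta_n)` per site,
#' each proposing a uniform alternative base; stop-creating edits are
#' rejected; synonymous edits are accepted with probability
#' `(theta_s/theta_max) * phi(site)`, non-synonymous with
#' `(theta_n/theta_max) * omega_g * psi(site)`. Duplicate (position, alt)
#' records are collapsed.
#'
#' @param cfg a [sim_config()]
#' @param sim result of [simulate_gene()]
#' @return data.frame `gene_id, cds_position, ref_base, alt_base, class`
#' @export
simulate_polymorphism <- function(cfg, sim) {
  g <- sim$alignment
  truth <- sim$truth
  ref <- gsub(GAP_CHAR, "", g$sequences[["ingroup1"]], fixed = TRUE)
  ref_codons <- substring(ref, seq(1, nchar(ref), 3), seq(3, nchar(ref), 3))
  ref_idx <- match(ref_codons, all_codons())
  mt <- codon_mutation_tables()
  L3 <- nchar(ref)
  theta_max <- max(cfg$theta_s, cfg$theta_n)
  empty <- data.frame(gene_id = character(0), cds_position = integer(0),
                      ref_base = character(0), alt_base = character(0),
                      class = character(0), stringsAsFactors = FALSE)
  if (theta_max == 0) return(empty)
  u_str <- truth$edge_strength
  phi_site <- ifelse(truth$edge_sites, cfg$phi_edge^u_str, 1)
  psi_site <- ifelse(truth$edge_sites, cfg$psi_edge^u_str, 1)
  n_att <- stats::rpois(1, theta_max * L3)
  if (n_att == 0) return(empty)
  pos <- sample.int(L3, n_att, replace = TRUE)
  alt_pick <- sample.int(3L, n_att, replace = TRUE)
  u <- stats::runif(n_att)
  ci <- (pos - 1L) %/% 3L + 1L
  off <- (pos - 1L) %% 3L + 1L
  cur_idx <- ref_idx[ci]
  mut_idx <- mt$NEIGH[cbind(cur_idx, (off - 1L) * 3L + alt_pick)]
  ok <- !mt$IS_STOP[mut_idx] & !mt$IS_STOP[cur_idx]
  syn <- mt$SAME_AA[cbind(cur_idx, mut_idx)]
  p_acc <- ifelse(syn, (cfg$theta_s / theta_max) * phi_site[ci],
                  (cfg$theta_n / theta_max) * truth$omega_g * psi_site[ci])
  acc <- ok & u < p_acc
  if (!any(acc)) return(empty)
  cur_base <- substr(ref_codons[ci[acc]], off[acc], off[acc])
  alt_base <- vapply(which(acc), function(a) {
    DNA_BASES[DNA_BASES != substr(ref_codons[ci[a]], off[a], off[a])][
      alt_pick[a]]
  }, character(1))
  out <- data.frame(
    gene_id = truth$gene_id, cds_position = pos[acc] - 1L,
    ref_base = cur_base, alt_base = alt_base,
    class = ifelse(syn[acc], "synonymous", "non-synonymous"),
    stringsAsFactors = FALSE)
  out[!duplicated(out[, c("cds_position", "alt_base")]), , drop = FALSE]
}

#' Simulate EST chains for one gene
#'
#' Gene-local coordinates: each simulated exon is laid out with fixed 100-bp
#' introns between exons. With probability `est_two_isoform_prob` the gene has
#' a second isoform whose first intron acceptor is shifted by 9 bp (an
#' incompatible boundary); ESTs are drawn 50/50 from the two isoforms with
#' full-extent mapping. Single-exon genes have intronless chains.
#'
#' @param cfg a [sim_config()]
#' @param sim result of [simulate_gene()]
#' @return data.frame in the tidy EST-chain layout (possibly 0 rows)
#' @export
simulate_est_chains <- function(cfg, sim) {
  truth <- sim$truth
  blocks <- sim$alignment$exon_blocks
  n_ests <- stats::rpois(1, cfg$est_mean_count)
  empty <- data.frame(gene_id = character(0), est_id = character(0),
                      intron_start = numeric(0), intron_end = numeric(0),
                      est_extent_start = numeric(0),
                      est_extent_end = numeric(0), stringsAsFactors = FALSE)
  if (n_ests == 0L) return(empty)
  # gene-local nt layout: exon lengths 3*codons, introns of 100 nt
  exon_len <- 3L * (blocks$codon_end - blocks$codon_start)
  n_ex <- length(exon_len)
  starts <- cumsum(c(0L, exon_len[-n_ex] + 100L))
  ends <- starts + exon_len
  extent <- c(0, ends[n_ex])
  introns_a <- if (n_ex > 1)
    cbind(ends[-n_ex], starts[-1L]) else matrix(numeric(0), 0, 2)
  two_forms <- n_ex > 1 && stats::runif(1) < cfg$est_two_isoform_prob
  introns_b <- introns_a
  if (two_forms) introns_b[1, 2] <- introns_b[1, 2] + 9
  rows <- list()
  for (e in seq_len(n_ests)) {
    m <- if (two_forms && e > n_ests / 2) introns_b else introns_a
    eid <- sprintf("%s_est%03d", truth$gene_id, e)
    if (nrow(m) == 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = truth$gene_id, est_id = eid, intron_start = NA_real_,
        intron_end = NA_real_, est_extent_start = extent[1],
        est_extent_end = extent[2], stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = truth$gene_id, est_id = eid, intron_start = m[, 1],
        intron_end = m[, 2], est_extent_start = extent[1],
        est_extent_end = extent[2], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Simulate a full dataset: trios, SNPs, expression, ESTs, truth
#'
#' Gene-level omega_g and latent log-expression are drawn jointly from a
#' Gaussian copula hitting the configured Spearman correlation
#' (`r = 2 sin(pi rho_s / 6)` on the normal scale); tissue abundances are the
#' latent level times a per-gene tissue profile normalised to mean 1, so the
#' across-tissue mean preserves the generating ranks exactly. All randomness
#' flows from one master seed via per-gene derived streams, so per-gene
#' outputs are reproducible independently of iteration order.
#'
#' @param cfg a [sim_config()]
#' @param seed master seed (integer below 2^31)
#' @return list `genes` (list of [trio_alignment()]s), `truth` (data.frame),
#'   `truth_detail` (per-gene list), `snps`, `expression`, `est_chains`,
#'   `config`, `seed`
#' @export
simulate_dataset <- function(cfg, seed) {
  set.seed(seed %% 2147483647)
  n <- cfg$n_genes
  rho_target <- if (is.null(cfg$omega_fixed)) cfg$expression_rho else 0
  r <- 2 * sin(pi * rho_target / 6)
  z1 <- stats::rnorm(n)
  z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n) # expression latent
  omega_g <- if (is.null(cfg$omega_fixed))
    pmin(stats::qlnorm(stats::pnorm(z1), cfg$omega_meanlog, cfg$omega_sdlog),
         cfg$omega_max)
  else rep(cfg$omega_fixed, n)
  edge_strength <- if (cfg$edge_expression_link) stats::pnorm(z2) else
    rep(1, n)

  gene_ids <- sprintf("g%04d", seq_len(n))
  genes <- vector("list", n)
  truth_detail <- vector("list", n)
  snps <- vector("list", n)
  ests <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(.gene_seed(seed, i))
    sim <- simulate_gene(cfg, gene_ids[i], omega_g[i], edge_strength[i])
    genes[[i]] <- sim$alignment
    snps[[i]] <- simulate_polymorphism(cfg, sim)
    ests[[i]] <- simulate_est_chains(cfg, sim)
    sim$truth$expression_latent <- z2[i]
    sim$truth$Ps <- sum(snps[[i]]$class == "synonymous")
    sim$truth$Pn <- sum(snps[[i]]$class == "non-synonymous")
    truth_detail[[i]] <- sim$truth
  }

  # expression matrix: exp(latent) times a per-gene tissue profile with
  # gene-specific specificity, normalised to mean 1 across tissues
  set.seed((seed + 104729) %% 2147483647)
  Tt <- cfg$n_tissues
  expr <- matrix(0, n, Tt, dimnames = list(gene_ids,
                                           paste0("tissue", seq_len(Tt))))
  for (i in seq_len(n)) {
    shape <- exp(stats::runif(1, log(0.4), log(6)))
    w <- stats::rgamma(Tt, shape = shape)
    if (sum(w) == 0) w <- rep(1, Tt)
    w <- w / mean(w)
    w[w < 0.05] <- 0 # silent tissues, so breadth varies across genes
    w <- w / mean(w)
    expr[i, ] <- exp(z2[i]) * w
  }
  expression <- data.frame(gene_id = gene_ids, expr, stringsAsFactors = FALSE)

  truth <- data.frame(
    gene_id = gene_ids, omega_g = omega_g, edge_strength = edge_strength,
    expression_latent = z2,
    n_codons = vapply(truth_detail, `[[`, numeric(1), "n_codons"),
    n_exons = vapply(truth_detail, `[[`, numeric(1), "n_exons"),
    Sd_ingroup1 = vapply(truth_detail, function(t) t$branch_Sd[["ingroup1"]],
                         numeric(1)),
    Nd_ingroup1 = vapply(truth_detail, function(t) t$branch_Nd[["ingroup1"]],
                         numeric(1)),
    Sd_ingroup2 = vapply(truth_detail, function(t) t$branch_Sd[["ingroup2"]],
                         numeric(1)),
    Nd_ingroup2 = vapply(truth_detail, function(t) t$branch_Nd[["ingroup2"]],
                         numeric(1)),
    Sd_outgroup = vapply(truth_detail, function(t) t$branch_Sd[["outgroup"]],
                         numeric(1)),
    Nd_outgroup = vapply(truth_detail, function(t) t$branch_Nd[["outgroup"]],
                         numeric(1)),
    accepted_syn_ingroup1 = vapply(truth_detail, function(t)
      t$accepted_syn[["ingroup1"]], integer(1)),
    accepted_nonsyn_ingroup1 = vapply(truth_detail, function(t)
      t$accepted_nonsyn[["ingroup1"]], integer(1)),
    accepted_nonsyn_ingroup2 = vapply(truth_detail, function(t)
      t$accepted_nonsyn[["ingroup2"]], integer(1)),
    accepted_nonsyn_outgroup = vapply(truth_detail, function(t)
      t$accepted_nonsyn[["outgroup"]], integer(1)),
    Ps = vapply(truth_detail, `[[`, numeric(1), "Ps"),
    Pn = vapply(truth_detail, `[[`, numeric(1), "Pn"),
    stringsAsFactors = FALSE)

  list(genes = genes, truth = truth, truth_detail = truth_detail,
       snps = do.call(rbind, snps), expression = expression,
       est_chains = do.call(rbind, ests), config = cfg, seed = seed)
}

#' Read a dataset written by [write_dataset()]
#'
#' Loads every per-gene FASTA through [read_gene_alignment()] together with
#' the SNP, expression, EST-chain and truth tables.
#' @param dir directory previously populated by [write_dataset()]
#' @return list with the same shape as [simulate_dataset()] output (minus
#'   `truth_detail`)
#' @export
read_dataset <- function(dir) {
  emap_path <- file.path(dir, "exon_map.tsv")
  emap <- utils::read.delim(emap_path, stringsAsFactors = FALSE)
  fastas <- list.files(file.path(dir, "alignments"), pattern = "\\.fasta$",
                       full.names = TRUE)
  genes <- lapply(fastas, function(fa) {
    read_gene_alignment(fa, emap_path,
                        gene_id = sub("\\.fasta$", "", basename(fa)))
  })
  read_tsv <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) utils::read.delim(p, stringsAsFactors = FALSE)
    else NULL
  }
  list(genes = genes, snps = read_tsv("snps.tsv"),
       expression = read_tsv("expression.tsv"),
       est_chains = read_tsv("est_chains.tsv"), truth = read_tsv("truth.tsv"))
}

#' Write a simulated dataset to plain-text files
#'
#' Emits one gapped FASTA per gene plus a combined exon map, SNP, expression,
#' EST-chain and truth TSVs, and a JSON manifest recording the seed and
#' configuration. Every file re-reads through the package's own readers.
#'
#' @param ds result of [simulate_dataset()]
#' @param dir output directory (created if needed)
#' @return invisibly, the manifest path
#' @export
write_dataset <- function(ds, dir) {
  dir.create(file.path(dir, "alignments"), recursive = TRUE,
             showWarnings = FALSE)
  exon_rows <- list()
  for (g in ds$genes) {
    fa <- file.path(dir, "alignments", paste0(g$gene_id, ".fasta"))
    Biostrings::writeXStringSet(Biostrings::BStringSet(g$sequences), fa)
    exon_rows[[length(exon_rows) + 1L]] <-
      cbind(gene_id = g$gene_id,
            g$exon_blocks[, c("exon_index", "codon_start", "codon_end",
                              "in_frame", "multiple_of_three")])
  }
  utils::write.table(do.call(rbind, exon_rows),
                     file.path(dir, "exon_map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ds$snps[, c("gene_id", "cds_position", "ref_base",
                                 "alt_base")],
                     file.path(dir, "snps.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ds$expression, file.path(dir, "expression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ds$est_chains, file.path(dir, "est_chains.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ds$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- file.path(dir, "manifest.json")
  cfg <- ds$config
  cfg$omega_fixed <- if (is.null(cfg$omega_fixed)) NA else cfg$omega_fixed
  jsonlite::write_json(list(seed = ds$seed, n_genes = length(ds$genes),
                            config = unclass(cfg)),
                       manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
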