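# End-to-end orchestration: estimates, neutrality, trimming randomizations,
# correlation summaries, splicing indices, attrition bookkeeping and a
# machine-readable run manifest.

#' Pipeline configuration
#'
#' Thresholds default to the standard filters: 150 aligned bases, branch
#' filters dS < 0.02, dS > 2, dN > 2, trim depths k in {10, 20, 30}.
#'
#' @param min_aligned_bases minimum aligned bases (150)
#' @param ds_min,ds_max,dn_max lineage branch filters
#' @param trim_ks trim depths (codons per edge)
#' @param trim_mode see [trim_spec()]
#' @param randomizations replicates per gene for the randomization test
#' @param log_base logarithm base for the neutrality index
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(min_aligned_bases = 150, ds_min = 0.02,
                            ds_max = 2, dn_max = 2,
                            trim_ks = c(10, 20, 30),
                            trim_mode = "both_edges",
                            randomizations = 1000, log_base = exp(1)) {
  stopifnot(min_aligned_bases > 0, ds_min > 0, ds_max > 0, dn_max > 0,
            all(trim_ks >= 1), randomizations >= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

.write_stage <- function(df, path, run_id, seed) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# run_id=%s seed=%d", run_id, seed), con)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), "NA", sprintf("%.6g", x))
  })
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full analysis on a simulated (or loaded) dataset
#'
#' Stages: pairwise dN/dS (ingroup pair), lineage-specific dN/dS, neutrality
#' index, edge-trim randomization tables for each trim depth, Table-1/2-style
#' correlation summaries, the dN/dS > 1 proportion-shift test per depth, the
#' splicing index, per-stage gene attrition counts, and a JSON manifest
#' (seed, thresholds, versions, file checksums). Tables are written with a
#' fixed 6-significant-digit format, so reruns with the same seed are
#' byte-identical. A missing SNP table skips the neutrality stage with a
#' warning; other stages complete.
#'
#' @param ds dataset as returned by [simulate_dataset()] (fields `genes`,
#'   `snps`, `expression`, `est_chains`)
#' @param out_dir output directory
#' @param cfg a [pipeline_config()]
#' @param seed seed for the randomization stages
#' @return invisibly, a list of the result tables plus the manifest
#' @export
run_all <- function(ds, out_dir, cfg = pipeline_config(), seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genes <- ds$genes
  pair <- c("ingroup1", "ingroup2")

  # manifest first: its checksum stamps every table
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- list(
    package = "exonedge",
    version = as.character(utils::packageVersion("exonedge")),
    seed = seed, n_genes = length(genes),
    thresholds = list(min_aligned_bases = cfg$min_aligned_bases,
                      ds_min = cfg$ds_min, ds_max = cfg$ds_max,
                      dn_max = cfg$dn_max),
    trim = list(ks = cfg$trim_ks, mode = cfg$trim_mode,
                randomizations = cfg$randomizations))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  run_id <- unname(tools::md5sum(manifest_path))

  counts <- list(input = length(genes))
  set.seed(seed)

  pairwise <- pairwise_dnds_table(genes, pair, cfg$min_aligned_bases)
  counts$pairwise_valid <- sum(pairwise$valid)
  .write_stage(pairwise, file.path(out_dir, "pairwise_dnds.tsv"), run_id,
               seed)

  lineage <- lineage_dnds_table(genes, cfg$ds_min, cfg$ds_max, cfg$dn_max,
                                cfg$min_aligned_bases)
  counts$lineage_valid_ingroup1 <-
    sum(lineage$valid[lineage$branch == "ingroup1"])
  .write_stage(lineage, file.path(out_dir, "lineage_dnds.tsv"), run_id, seed)

  ni <- NULL
  if (!is.null(ds$snps) && nrow(ds$snps) > 0) {
    ni <- neutrality_table(genes, ds$snps, pair, cfg$min_aligned_bases,
                           cfg$log_base)
    counts$neutrality_valid <- sum(ni$valid)
    .write_stage(ni, file.path(out_dir, "neutrality.tsv"), run_id, seed)
  } else {
    warning("no SNP table: neutrality stage skipped", call. = FALSE)
  }

  # trimming randomization per depth; shared removal sets across statistics
  trim_rows <- list()
  prop_rows <- list()
  for (k in cfg$trim_ks) {
    spec <- trim_spec(k, cfg$trim_mode)
    stats_used <- if (is.null(ni)) c("dN", "dS", "omega") else
      c("dN", "dS", "omega", "NI")
    for (g in genes) {
      plan <- trim_plan(g, spec)
      if (length(plan$kept) == 0L) next
      if (3 * length(plan$kept) < cfg$min_aligned_bases) next
      rt <- randomization_test(g, spec, stats_used, pair, ds$snps,
                               s = cfg$randomizations,
                               min_aligned = cfg$min_aligned_bases,
                               log_base = cfg$log_base)
      trim_rows[[length(trim_rows) + 1L]] <- rt
    }
    # proportion of genes with omega > 1 before vs after sequential trimming
    before <- after <- 0L
    n_both <- 0L
    for (g in genes) {
      spec_k <- trim_spec(k, cfg$trim_mode)
      plan <- trim_plan(g, spec_k)
      if (length(plan$base) == 0L || length(plan$kept) == 0L) next
      ctx <- trim_stat_context(g, pair, NULL, cfg$min_aligned_bases)
      o0 <- trim_stat_value(ctx, plan$base, "omega")
      o1 <- trim_stat_value(ctx, plan$kept, "omega")
      if (is.na(o0) || is.na(o1)) next
      n_both <- n_both + 1L
      before <- before + (o0 > 1)
      after <- after + (o1 > 1)
    }
    pt <- proportion_shift_test(before, after, max(n_both, 1L))
    prop_rows[[length(prop_rows) + 1L]] <- data.frame(
      k = k, n = n_both, above1_before = before, above1_after = after,
      chisq = pt$chisq, p = pt$p, applicable = pt$applicable)
  }
  trim_tbl <- do.call(rbind, trim_rows)
  if (!is.null(trim_tbl))
    .write_stage(trim_tbl, file.path(out_dir, "trim_randomization.tsv"),
                 run_id, seed)
  prop_tbl <- do.call(rbind, prop_rows)
  .write_stage(prop_tbl, file.path(out_dir, "proportion_shift.tsv"), run_id,
               seed)

  # correlations of covariates with the pairwise estimates (Table-1 style)
  cors <- partials <- NULL
  if (!is.null(ds$expression)) {
    cov <- gene_covariates(ds$expression)
    stats_df <- data.frame(gene_id = pairwise$gene_id,
                           omega = pairwise$omega)
    if (!is.null(ni)) stats_df$NI <- ni$NI[match(stats_df$gene_id,
                                                 ni$gene_id)]
    cors <- correlation_table(cov[, c("gene_id", "expression_level",
                                      "expression_z", "breadth", "tau")],
                              stats_df)
    .write_stage(cors, file.path(out_dir, "correlations.tsv"), run_id, seed)
    partials <- correlation_table(cov[, c("gene_id", "expression_level",
                                          "breadth", "tau")],
                                  stats_df, control = "expression_level")
    .write_stage(partials, file.path(out_dir, "partial_correlations.tsv"),
                 run_id, seed)
  }

  spl <- NULL
  if (!is.null(ds$est_chains) && nrow(ds$est_chains) > 0) {
    spl <- splicing_index_table(ds$est_chains)
    counts$splicing_included <- sum(!spl$excluded)
    .write_stage(spl, file.path(out_dir, "splicing_index.tsv"), run_id, seed)
  }

  attrition <- data.frame(stage = names(counts),
                          n = unlist(counts, use.names = FALSE))
  .write_stage(attrition, file.path(out_dir, "attrition.tsv"), run_id, seed)

  manifest$tables <- as.list(tools::md5sum(list.files(
    out_dir, pattern = "\\.tsv$", full.names = TRUE)))
  names(manifest$tables) <- basename(names(manifest$tables))
  manifest$run_id <- run_id
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(pairwise = pairwise, lineage = lineage, neutrality = ni,
                 trim = trim_tbl, proportion_shift = prop_tbl,
                 correlations = cors, partial_correlations = partials,
                 splicing = spl, attrition = attrition, run_id = run_id,
                 manifest = manifest))
}
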