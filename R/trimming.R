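# Sequential exon-edge codon removal, matched random removal, and the
# randomization test. All trimming operates on the concatenation of a gene's
# ELIGIBLE exons (fully aligned, in frame, a multiple of three in length), so
# that "trimmed" and "untrimmed" conditions use the same exon set per gene.

#' Trimming specification
#'
#' @param k codons removed per trimmed edge (1..30)
#' @param mode `both_edges` removes `k` codons from each edge of every
#'   eligible exon; `internal_edges_only` exempts the gene's first exon 5'
#'   edge and last exon 3' edge (splice enhancers flank intron junctions)
#' @param min_post_trim_bases post-trim aligned-base floor (150)
#' @return a `trim_spec` list
#' @export
trim_spec <- function(k, mode = c("both_edges", "internal_edges_only"),
                      min_post_trim_bases = 150) {
  mode <- match.arg(mode)
  stopifnot(k >= 1)
  structure(list(k = as.integer(k), mode = mode,
                 min_post_trim_bases = min_post_trim_bases),
            class = "trim_spec")
}

#' Exons eligible for edge trimming
#'
#' Blocks that are fully aligned, in frame, and a multiple of three in length.
#' @param g a [gene_alignment()]
#' @param spec a [trim_spec()] (unused beyond interface symmetry)
#' @return data.frame subset of `g$exon_blocks`
#' @export
eligible_exons <- function(g, spec = trim_spec(1)) {
  eb <- g$exon_blocks
  eb[eb$fully_aligned & eb$in_frame & eb$multiple_of_three, , drop = FALSE]
}

# 1-based codon indices of the eligible-exon concatenation, and the removal
# plan: which of those indices the sequential treatment removes.
trim_plan <- function(g, spec) {
  el <- eligible_exons(g, spec)
  if (nrow(el) == 0L)
    return(list(base = integer(0), kept = integer(0), removed = integer(0)))
  eb <- g$exon_blocks
  first_exon <- eb$exon_index[which.min(eb$codon_start)]
  last_exon <- eb$exon_index[which.max(eb$codon_end)]
  base <- integer(0)
  kept <- integer(0)
  for (b in seq_len(nrow(el))) {
    idx <- seq(el$codon_start[b] + 1L, el$codon_end[b])
    base <- c(base, idx)
    trim5 <- spec$k
    trim3 <- spec$k
    if (spec$mode == "internal_edges_only") {
      if (el$exon_index[b] == first_exon) trim5 <- 0L
      if (el$exon_index[b] == last_exon) trim3 <- 0L
    }
    n <- length(idx)
    if (trim5 + trim3 >= n) next # exon contributes max(0, length - removed)
    kept <- c(kept, idx[seq(trim5 + 1L, n - trim3)])
  }
  list(base = base, kept = kept, removed = setdiff(base, kept))
}

#' Sequential edge trimming of a gene alignment
#'
#' Removes `spec$k` codons from each trimmed edge of every eligible exon and
#' concatenates the remainder. The result carries attribute `post_trim_ok`:
#' `FALSE` when fewer than `spec$min_post_trim_bases` bases (columns gap-free
#' in every species) remain, in which case the gene leaves the trimmed subset.
#'
#' @param g a [gene_alignment()]
#' @param spec a [trim_spec()]
#' @return trimmed [gene_alignment()] with attributes `post_trim_ok` and
#'   `n_removed`; when no codons survive, an empty marker of class
#'   `trimmed_empty` with the same attributes
#' @export
trim_edges <- function(g, spec) {
  plan <- trim_plan(g, spec)
  if (length(plan$kept) == 0L) {
    out <- structure(list(gene_id = g$gene_id, n_codons = 0L),
                     class = "trimmed_empty")
    attr(out, "post_trim_ok") <- FALSE
    attr(out, "n_removed") <- length(plan$removed)
    return(out)
  }
  out <- subset_codons(g, plan$kept)
  char_mat <- do.call(rbind, strsplit(unname(out$sequences), ""))
  ab_all <- sum(colSums(char_mat == GAP_CHAR) == 0L)
  attr(out, "post_trim_ok") <- ab_all >= spec$min_post_trim_bases
  attr(out, "n_removed") <- length(plan$removed)
  out
}

#' Matched random codon removal
#'
#' Removes `n_remove` codon columns chosen uniformly without replacement from
#' the untrimmed concatenation of the gene's eligible exons — the paired
#' control for [trim_edges()].
#'
#' @param g a [gene_alignment()]
#' @param n_remove number of codons to remove (the count the sequential
#'   treatment removed)
#' @param spec a [trim_spec()] (defines eligibility)
#' @return [gene_alignment()] of the surviving codons
#' @export
random_trim <- function(g, n_remove, spec = trim_spec(1)) {
  plan <- trim_plan(g, spec)
  base <- plan$base
  if (n_remove > length(base))
    stop("n_remove exceeds available codons (", length(base), ") for gene ",
         g$gene_id, call. = FALSE)
  keep <- if (n_remove == 0L) base else
    sort(sample(base, length(base) - n_remove))
  subset_codons(g, keep)
}

# ---- statistics on codon subsets -------------------------------------------

# Precompute per-gene material so each removal replicate reduces to sums.
trim_stat_context <- function(g, pair, snps = NULL, min_aligned = 150,
                              log_base = exp(1)) {
  prof <- pairwise_codon_profile(g, pair)
  ps_codon <- pn_codon <- numeric(g$n_codons)
  if (!is.null(snps)) {
    cls <- classify_snp_table(g, snps)
    if (nrow(cls)) {
      ci <- cls$cds_position %/% 3L + 1L
      for (r in seq_len(nrow(cls))) {
        if (cls$class[r] == "synonymous")
          ps_codon[ci[r]] <- ps_codon[ci[r]] + 1
        else if (cls$class[r] == "non-synonymous")
          pn_codon[ci[r]] <- pn_codon[ci[r]] + 1
      }
    }
  }
  list(prof = prof, ps_codon = ps_codon, pn_codon = pn_codon,
       min_aligned = min_aligned, log_base = log_base)
}

# One statistic on one codon subset; NA when the estimate is invalid.
trim_stat_value <- function(ctx, keep_idx, statistic) {
  if (statistic %in% c("dN", "dS", "omega")) {
    est <- estimate_from_profile(ctx$prof, keep_idx, ctx$min_aligned)
    if (statistic == "omega") return(if (est$valid) est$omega else NA_real_)
    if (!est$valid && est$reason %in% c("min_aligned", "internal_stop",
                                        "saturated"))
      return(NA_real_)
    return(est[[statistic]])
  }
  if (statistic == "NI") {
    use <- keep_idx[ctx$prof$usable[keep_idx]]
    if (sum(ctx$prof$ab[keep_idx]) < ctx$min_aligned) return(NA_real_)
    return(neutrality_index(sum(ctx$prof$sd[use]), sum(ctx$prof$nd[use]),
                            sum(ctx$ps_codon[keep_idx]),
                            sum(ctx$pn_codon[keep_idx]),
                            log_base = ctx$log_base))
  }
  stop("unknown statistic: ", statistic, call. = FALSE)
}

#' Per-gene randomization test of edge trimming
#'
#' Compares the statistic after sequential edge removal with `s` replicates of
#' matched random removal (same number of codons, drawn uniformly from the
#' eligible-exon concatenation). One shared removal set per replicate is used
#' for all requested statistics, so dN/dS and NI nulls are computed on the
#' same removals. With `q` the number of replicates in which the sequential
#' estimate exceeds the random estimate (strictly; is lower, for NI), the
#' numerical P-value is `p = (s - q + 1) / (s + 1)`. Replicates with an
#' invalid estimate are dropped from `s`; the result is flagged unreliable
#' when more than 10\% are invalid.
#'
#' @param g a [gene_alignment()]
#' @param spec a [trim_spec()]
#' @param statistics any of `"dN", "dS", "omega", "NI"`
#' @param pair species pair for divergence
#' @param snps SNP table (required for `"NI"`)
#' @param s number of randomizations (paper default 1000)
#' @param min_aligned,log_base estimation settings
#' @return data.frame, one row per statistic: `gene_id, statistic, k, mode,
#'   observed, q, s, p, n_invalid, unreliable, n_removed`
#' @export
randomization_test <- function(g, spec, statistics = c("dN", "dS", "omega",
                                                       "NI"),
                               pair = names(g$sequences)[1:2], snps = NULL,
                               s = 1000, min_aligned = 150,
                               log_base = exp(1)) {
  statistics <- match.arg(statistics, several.ok = TRUE)
  ctx <- trim_stat_context(g, pair, snps, min_aligned, log_base)
  plan <- trim_plan(g, spec)
  n_remove <- length(plan$removed)
  base <- plan$base
  n_keep <- length(base) - n_remove

  observed <- vapply(statistics, function(st)
    trim_stat_value(ctx, plan$kept, st), numeric(1))

  nulls <- matrix(NA_real_, nrow = s, ncol = length(statistics),
                  dimnames = list(NULL, statistics))
  for (r in seq_len(s)) {
    keep <- if (n_remove == 0L) base else sort(sample(base, n_keep))
    for (st in statistics)
      nulls[r, st] <- trim_stat_value(ctx, keep, st)
  }

  rows <- lapply(statistics, function(st) {
    obs <- observed[[st]]
    nv <- nulls[, st]
    ok <- !is.na(nv) & !is.na(obs)
    s_eff <- sum(ok)
    q <- if (s_eff == 0L) NA_integer_ else if (st == "NI")
      sum(obs < nv[ok]) else sum(obs > nv[ok])
    p <- if (s_eff == 0L) NA_real_ else (s_eff - q + 1) / (s_eff + 1)
    data.frame(gene_id = g$gene_id, statistic = st, k = spec$k,
               mode = spec$mode, observed = obs, q = q, s = s_eff, p = p,
               n_invalid = s - sum(!is.na(nv)),
               unreliable = is.na(obs) || (s - sum(!is.na(nv))) > 0.1 * s,
               n_removed = n_remove, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "null_values") <- nulls
  out
}

#' Randomization test on a cross-gene correlation strength
#'
#' Observed value: Spearman's rho between a per-gene covariate and the
#' sequentially trimmed statistic. Null values: rho recomputed with every gene
#' randomly trimmed (one matched random trim per gene per replicate). `q`
#' counts replicates with `|rho_sequential| < |rho_random|`, so small
#' `p = (s - q + 1)/(s + 1)` indicates significant attenuation of the
#' correlation by edge removal.
#'
#' @param genes list of [gene_alignment()]s
#' @param covariate per-gene values aligned with `genes`
#' @param spec a [trim_spec()]
#' @param statistic one of `"dN", "dS", "omega", "NI"`
#' @param snps SNP table (for `"NI"`)
#' @param s replicates
#' @param pair species pair (default: each gene's first two species)
#' @param min_aligned,log_base estimation settings
#' @param min_genes minimum genes with valid trimmed estimates (30)
#' @return list with `observed`, `null_values`, `q`, `s`, `p`, `n_genes`
#' @export
rho_randomization <- function(genes, covariate, spec, statistic = "omega",
                              snps = NULL, s = 200, pair = NULL,
                              min_aligned = 150, log_base = exp(1),
                              min_genes = 30) {
  stopifnot(length(genes) == length(covariate))
  if (length(unique(stats::na.omit(covariate))) < 2L)
    stop("degenerate (constant) covariate", call. = FALSE)
  ctxs <- vector("list", length(genes))
  plans <- vector("list", length(genes))
  seq_vals <- rep(NA_real_, length(genes))
  for (i in seq_along(genes)) {
    p <- if (is.null(pair)) names(genes[[i]]$sequences)[1:2] else pair
    ctxs[[i]] <- trim_stat_context(genes[[i]], p, snps, min_aligned, log_base)
    plans[[i]] <- trim_plan(genes[[i]], spec)
    if (length(plans[[i]]$kept))
      seq_vals[i] <- trim_stat_value(ctxs[[i]], plans[[i]]$kept, statistic)
  }
  usable <- !is.na(seq_vals) & !is.na(covariate)
  if (sum(usable) < min_genes)
    stop("fewer than ", min_genes, " genes with valid trimmed estimates",
         call. = FALSE)
  obs <- spearman(covariate[usable], seq_vals[usable])$rho

  null_rho <- numeric(s)
  for (r in seq_len(s)) {
    rv <- rep(NA_real_, length(genes))
    for (i in which(usable)) {
      plan <- plans[[i]]
      n_remove <- length(plan$removed)
      keep <- if (n_remove == 0L) plan$base else
        sort(sample(plan$base, length(plan$base) - n_remove))
      rv[i] <- trim_stat_value(ctxs[[i]], keep, statistic)
    }
    ok <- usable & !is.na(rv)
    null_rho[r] <- spearman(covariate[ok], rv[ok])$rho
  }
  q <- sum(abs(obs) < abs(null_rho))
  list(unit = paste0("rho:", statistic), statistic = statistic,
       observed = obs, null_values = null_rho, q = q, s = s,
       p = (s - q + 1) / (s + 1), n_genes = sum(usable))
}
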