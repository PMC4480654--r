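# Lineage-specific per-branch dN/dS on a three-taxon trio.
#
# The single internal node of the unrooted tree ((ingroup1, ingroup2),
# outgroup) is reconstructed per codon column by parsimony over the 61 sense
# codons (branch cost = nucleotide Hamming distance); ties are averaged with
# uniform weights when counting per-branch substitutions.

BRANCHES <- c("ingroup1", "ingroup2", "outgroup")

# Codon index matrix (n x 3) plus usability mask for a trio.
.trio_codon_idx <- function(t) {
  stopifnot(inherits(t, "trio_alignment"))
  cm <- codon_matrix(t)[, BRANCHES, drop = FALSE]
  codons <- all_codons()
  idx <- matrix(match(cm, codons), ncol = 3L,
                dimnames = list(NULL, BRANCHES))
  sense <- logical(64)
  sense[sense_codon_idx()] <- TRUE
  ok <- !is.na(idx[, 1]) & !is.na(idx[, 2]) & !is.na(idx[, 3])
  ok[ok] <- sense[idx[ok, 1]] & sense[idx[ok, 2]] & sense[idx[ok, 3]]
  list(idx = idx, usable = ok)
}

#' Most-parsimonious ancestral codons per column of a trio alignment
#'
#' For each gap-free, unambiguous codon column, returns the set of sense
#' codons at the internal node minimising the total nucleotide changes summed
#' over the three branches. Columns with gaps, ambiguity, or a stop codon in
#' any species are skipped and reported.
#'
#' @param t a [trio_alignment()]
#' @return list with `columns` (1-based usable codon indices), `ancestors`
#'   (list of character vectors of tied ancestral codons), `cost` (numeric,
#'   minimal change count per column), and `skipped` (indices of skipped
#'   columns)
#' @export
infer_ancestral_codons <- function(t) {
  ti <- .trio_codon_idx(t)
  tabs <- codon_diff_tables()
  sense <- sense_codon_idx()
  codons <- all_codons()
  H <- tabs$HAM[sense, , drop = FALSE] # 61 x 64
  cols <- which(ti$usable)
  ancestors <- vector("list", length(cols))
  cost <- numeric(length(cols))
  for (k in seq_along(cols)) {
    i <- cols[k]
    total <- H[, ti$idx[i, 1]] + H[, ti$idx[i, 2]] + H[, ti$idx[i, 3]]
    m <- min(total)
    cost[k] <- m
    ancestors[[k]] <- codons[sense[total == m]]
  }
  list(columns = cols, ancestors = ancestors, cost = cost,
       skipped = which(!ti$usable))
}

#' Per-branch substitution and site counts for a trio
#'
#' For each usable codon column the synonymous/non-synonymous difference
#' counts between the internal-node codon and each tip are averaged, with
#' uniform weights, over all tied most-parsimonious ancestors. Per-branch site
#' counts come from the tip sequence's codons.
#'
#' @param t a [trio_alignment()]
#' @return list per branch with fields `Sd, Nd, S, N`, plus `n_codons_used`
#'   and `aligned_bases` (columns gap-free in all three species, in bases)
#' @export
branch_counts <- function(t) {
  ti <- .trio_codon_idx(t)
  tabs <- codon_diff_tables()
  sense <- sense_codon_idx()
  ssite <- codon_site_table()
  H <- tabs$HAM[sense, , drop = FALSE]
  cols <- which(ti$usable)
  out <- lapply(BRANCHES, function(b) c(Sd = 0, Nd = 0, S = 0, N = 0))
  names(out) <- BRANCHES
  for (i in cols) {
    tips <- ti$idx[i, ]
    total <- H[, tips[1]] + H[, tips[2]] + H[, tips[3]]
    anc <- sense[total == min(total)]
    w <- 1 / length(anc)
    for (b in 1:3) {
      out[[b]]["Sd"] <- out[[b]]["Sd"] + w * sum(tabs$SD[anc, tips[b]])
      out[[b]]["Nd"] <- out[[b]]["Nd"] + w * sum(tabs$ND[anc, tips[b]])
      out[[b]]["S"] <- out[[b]]["S"] + ssite[tips[b]]
      out[[b]]["N"] <- out[[b]]["N"] + 3 - ssite[tips[b]]
    }
  }
  list(branches = out, n_codons_used = length(cols),
       aligned_bases = 3L * length(cols))
}

#' Branch filter decision for a dS/dN pair
#'
#' The standard exclusion rules for per-branch rate estimates: undefined
#' corrections, then `dS < ds_min`, `dS > ds_max`, `dN > dn_max`.
#' @param dS,dN Jukes-Cantor-corrected branch rates (NA when out of domain)
#' @param ds_min,ds_max,dn_max thresholds (defaults 0.02, 2, 2)
#' @return reason string: `"ok"`, `"undefined"`, `"dS_low"`, `"dS_high"`, or
#'   `"dN_high"`
#' @export
branch_filter_reason <- function(dS, dN, ds_min = 0.02, ds_max = 2,
                                 dn_max = 2) {
  if (is.na(dS) || is.na(dN)) return("undefined")
  if (dS < ds_min) return("dS_low")
  if (dS > ds_max) return("dS_high")
  if (dN > dn_max) return("dN_high")
  "ok"
}

#' Lineage-specific dN/dS with the standard branch filters
#'
#' Per-branch Jukes-Cantor-corrected dN, dS and omega with validity flags.
#' A branch is invalid when the gene has fewer than `min_aligned` bases
#' aligned across all three species (`too_short`), when a correction is out of
#' domain (`undefined`), or when `dS < ds_min` (`dS_low`), `dS > ds_max`
#' (`dS_high`) or `dN > dn_max` (`dN_high`) — unreliable ratios, non-bona-fide
#' orthologues, or saturation.
#'
#' @param t a [trio_alignment()]
#' @param ds_min,ds_max,dn_max branch filters (defaults 0.02, 2, 2)
#' @param min_aligned minimum aligned bases (150)
#' @return data.frame with one row per branch: `gene_id, branch, Sd, Nd, S, N,
#'   dS, dN, omega, valid, reason`
#' @export
estimate_lineage <- function(t, ds_min = 0.02, ds_max = 2, dn_max = 2,
                             min_aligned = 150) {
  bc <- branch_counts(t)
  rows <- lapply(BRANCHES, function(b) {
    x <- bc$branches[[b]]
    pS <- if (x["S"] > 0) x["Sd"] / x["S"] else NA_real_
    pN <- if (x["N"] > 0) x["Nd"] / x["N"] else NA_real_
    dS <- jukes_cantor(pS)
    dN <- jukes_cantor(pN)
    reason <- if (t$has_internal_stop || bc$aligned_bases < min_aligned)
      "too_short" else branch_filter_reason(dS, dN, ds_min, ds_max, dn_max)
    valid <- reason == "ok"
    omega <- if (valid && dS > 0) dN / dS else NA_real_
    data.frame(gene_id = t$gene_id, branch = b,
               Sd = unname(x["Sd"]), Nd = unname(x["Nd"]),
               S = unname(x["S"]), N = unname(x["N"]),
               dS = unname(dS), dN = unname(dN), omega = omega,
               n_codons_used = bc$n_codons_used,
               aligned_bases = bc$aligned_bases,
               valid = valid, reason = reason,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Lineage-specific dN/dS table for a list of trios
#' @param trios list of [trio_alignment()]s
#' @inheritParams estimate_lineage
#' @return data.frame, three rows per gene
#' @export
lineage_dnds_table <- function(trios, ds_min = 0.02, ds_max = 2, dn_max = 2,
                               min_aligned = 150) {
  do.call(rbind, lapply(trios, estimate_lineage, ds_min = ds_min,
                        ds_max = ds_max, dn_max = dn_max,
                        min_aligned = min_aligned))
}
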