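# Within-species polymorphism classification and the neutrality index.

#' Classify a SNP as synonymous or non-synonymous
#'
#' Substitutes the alternate base into the reference codon (ungapped reference
#' CDS of the alignment) and compares encoded amino acids. The SNP is
#' `unclassifiable` when the reference codon contains ambiguity or when the
#' edit creates or destroys a stop codon.
#'
#' @param g a [gene_alignment()]
#' @param cds_position 0-based nucleotide offset in the ungapped reference CDS
#' @param ref_base,alt_base single uppercase bases; `ref_base` must match the
#'   reference sequence
#' @return one of `"synonymous"`, `"non-synonymous"`, `"unclassifiable"`
#' @export
classify_snp <- function(g, cds_position, ref_base, alt_base) {
  if (cds_position < 0 || cds_position >= 3L * g$n_codons)
    stop("cds_position outside CDS for gene ", g$gene_id, call. = FALSE)
  if (ref_base == alt_base)
    stop("ref_base and alt_base must differ", call. = FALSE)
  ref <- gsub(GAP_CHAR, "", g$sequences[[g$reference_species]], fixed = TRUE)
  at <- substr(ref, cds_position + 1L, cds_position + 1L)
  if (at != ref_base)
    stop("SNP consistency error: ref_base ", ref_base, " != reference base ",
         at, " at position ", cds_position, " of gene ", g$gene_id,
         call. = FALSE)
  codon_i <- cds_position %/% 3L
  off <- cds_position %% 3L + 1L
  codon <- substr(ref, 3L * codon_i + 1L, 3L * codon_i + 3L)
  if (grepl("[^ACGT]", codon) || !alt_base %in% DNA_BASES)
    return("unclassifiable")
  mut <- codon
  substr(mut, off, off) <- alt_base
  aa0 <- translate_codons(codon)
  aa1 <- translate_codons(mut)
  if (aa0 == "*" || aa1 == "*") return("unclassifiable")
  if (aa0 == aa1) "synonymous" else "non-synonymous"
}

#' Classify a SNP table against a gene alignment
#'
#' @param g a [gene_alignment()]
#' @param snps data.frame with columns `gene_id, cds_position, ref_base,
#'   alt_base` (rows for other genes are ignored)
#' @return the gene's rows with an added `class` column
#' @export
classify_snp_table <- function(g, snps) {
  snps <- snps[snps$gene_id == g$gene_id, , drop = FALSE]
  if (nrow(snps) == 0L) {
    snps$class <- character(0)
    return(snps)
  }
  snps$class <- vapply(seq_len(nrow(snps)), function(i) {
    classify_snp(g, snps$cds_position[i], snps$ref_base[i], snps$alt_base[i])
  }, character(1))
  snps
}

#' Neutrality index with +1 pseudo-counts
#'
#' `NI = log[(2 Ds + 1)(2 Pn + 1) / ((2 Dn + 1)(2 Ps + 1))]`, finite for all
#' non-negative (possibly fractional) counts. Under the neutral null the
#' ratios of inter- and intraspecies non-synonymous to synonymous variation
#' are equal and NI is 0; NI > 0 is consistent with purifying selection, NI <
#' 0 with positive selection.
#'
#' @param Ds,Dn synonymous / non-synonymous divergence counts
#' @param Ps,Pn synonymous / non-synonymous polymorphism counts
#' @param log_base base of the logarithm (default natural); sign and ranks are
#'   base-invariant
#' @return NI value
#' @export
#' @examples
#' neutrality_index(4, 0, 0, 4) # log(81)
neutrality_index <- function(Ds, Dn, Ps, Pn, log_base = exp(1)) {
  counts <- c(Ds, Dn, Ps, Pn)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be non-negative and finite", call. = FALSE)
  log((2 * Ds + 1) * (2 * Pn + 1) / ((2 * Dn + 1) * (2 * Ps + 1)),
      base = log_base)
}

#' Divergence counts feeding the neutrality index
#'
#' Raw pathway-averaged difference counts (`Sd`, `Nd`) from a valid pairwise
#' divergence estimate, not the Jukes-Cantor-corrected rates.
#' @param est result of [estimate_pairwise()]
#' @return list with `Ds` and `Dn`
#' @export
divergence_counts_for_ni <- function(est) {
  if (!isTRUE(est$valid))
    stop("invalid divergence estimate (", est$reason, ") for gene ",
         est$gene_id, call. = FALSE)
  list(Ds = est$Sd, Dn = est$Nd)
}

#' Per-gene neutrality result
#'
#' Combines the pairwise divergence counts with classified SNPs.
#' @param g a [gene_alignment()]
#' @param snps SNP table (see [classify_snp_table()])
#' @param pair species pair for divergence (default first two)
#' @param min_aligned,log_base see [estimate_pairwise()], [neutrality_index()]
#' @return one-row data.frame `gene_id, Ds, Dn, Ps, Pn, NI, valid, reason`
#' @export
neutrality_for_gene <- function(g, snps, pair = names(g$sequences)[1:2],
                                min_aligned = 150, log_base = exp(1)) {
  est <- estimate_pairwise(g, pair, min_aligned)
  cls <- classify_snp_table(g, snps)
  Ps <- sum(cls$class == "synonymous")
  Pn <- sum(cls$class == "non-synonymous")
  if (!est$valid && est$reason %in% c("internal_stop", "min_aligned")) {
    return(data.frame(gene_id = g$gene_id, Ds = NA_real_, Dn = NA_real_,
                      Ps = Ps, Pn = Pn, NI = NA_real_, valid = FALSE,
                      reason = est$reason, stringsAsFactors = FALSE))
  }
  # NI only needs raw counts; saturation / dS = 0 of the rate estimate do not
  # preclude it
  data.frame(gene_id = g$gene_id, Ds = est$Sd, Dn = est$Nd, Ps = Ps, Pn = Pn,
             NI = neutrality_index(est$Sd, est$Nd, Ps, Pn, log_base),
             valid = TRUE, reason = "ok", stringsAsFactors = FALSE)
}

#' Neutrality table for a list of genes
#' @param genes list of [gene_alignment()]s
#' @param snps SNP table covering all genes
#' @inheritParams neutrality_for_gene
#' @return data.frame, one row per gene
#' @export
neutrality_table <- function(genes, snps, pair = NULL, min_aligned = 150,
                             log_base = exp(1)) {
  do.call(rbind, lapply(genes, function(g) {
    p <- if (is.null(pair)) names(g$sequences)[1:2] else pair
    neutrality_for_gene(g, snps, p, min_aligned, log_base)
  }))
}
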