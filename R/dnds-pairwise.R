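# Pairwise dN/dS by equal-weight Nei-Gojobori counting with Jukes-Cantor
# correction. Codon columns containing a gap, ambiguity character, or a stop
# codon in either species are skipped entirely.

# Per-codon contribution profile for a species pair: everything the estimator
# (and the trimming randomization machinery) needs, as vectors indexed by
# reference codon. Computing this once per gene makes any codon-subset
# re-estimate a handful of sums.
pairwise_codon_profile <- function(g, pair) {
  if (!all(pair %in% names(g$sequences)))
    stop("species not in alignment: ",
         paste(setdiff(pair, names(g$sequences)), collapse = ", "),
         call. = FALSE)
  cm <- codon_matrix(g)
  c1 <- cm[, pair[1]]
  c2 <- cm[, pair[2]]
  codons <- all_codons()
  i1 <- match(c1, codons)
  i2 <- match(c2, codons)
  sense <- logical(64)
  sense[sense_codon_idx()] <- TRUE
  usable <- !is.na(i1) & !is.na(i2)
  usable[usable] <- sense[i1[usable]] & sense[i2[usable]]
  tabs <- codon_diff_tables()
  ssite <- codon_site_table()
  n <- g$n_codons
  sd <- nd <- s <- nn <- numeric(n)
  pick <- which(usable)
  if (length(pick)) {
    ij <- cbind(i1[pick], i2[pick])
    sd[pick] <- tabs$SD[ij]
    nd[pick] <- tabs$ND[ij]
    s[pick] <- (ssite[i1[pick]] + ssite[i2[pick]]) / 2
    nn[pick] <- 3 - s[pick]
  }
  # aligned bases per codon: columns (of the codon's 3) where neither species
  # has a gap -- used for the >= 150 aligned-base rule after any trim
  m1 <- matrix(unlist(strsplit(c1, "")), nrow = 3L)
  m2 <- matrix(unlist(strsplit(c2, "")), nrow = 3L)
  ab <- colSums(m1 != GAP_CHAR & m2 != GAP_CHAR)
  list(gene_id = g$gene_id, pair = pair, n_codons = g$n_codons,
       sd = sd, nd = nd, s = s, n = nn, usable = usable, ab = ab,
       internal_stop = g$has_internal_stop)
}

# Aggregate a profile over a codon subset into a divergence estimate.
estimate_from_profile <- function(prof, keep_idx = seq_len(prof$n_codons),
                                  min_aligned = 150) {
  keep_idx <- as.integer(keep_idx)
  use <- keep_idx[prof$usable[keep_idx]]
  Sd <- sum(prof$sd[use]); Nd <- sum(prof$nd[use])
  S <- sum(prof$s[use]); N <- sum(prof$n[use])
  ab <- sum(prof$ab[keep_idx])
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  dS <- jukes_cantor(pS)
  dN <- jukes_cantor(pN)
  valid <- TRUE; reason <- "ok"
  if (prof$internal_stop) {
    valid <- FALSE; reason <- "internal_stop"
  } else if (ab < min_aligned) {
    valid <- FALSE; reason <- "min_aligned"
  } else if (is.na(dS) || is.na(dN)) {
    valid <- FALSE; reason <- "saturated"
  } else if (dS == 0) {
    valid <- FALSE; reason <- "dS_zero"
  }
  omega <- if (valid) dN / dS else NA_real_
  list(gene_id = prof$gene_id, Sd = Sd, Nd = Nd, S = S, N = N,
       pS = pS, pN = pN, dS = dS, dN = dN, omega = omega,
       n_codons_used = length(use), aligned_bases = ab,
       valid = valid, reason = reason)
}

#' Pairwise dN/dS for one gene
#'
#' Equal-weight Nei-Gojobori counting over all gap-free, fully determined
#' codon columns, with Jukes-Cantor correction
#' `d = -(3/4) log(1 - (4/3) p)`. Site counts are averaged between the two
#' sequences' codons. The estimate is flagged invalid when fewer than
#' `min_aligned` bases align, when a correction is out of domain
#' (`p >= 3/4`), when `dS = 0` (omega undefined), or when the reference
#' carries an internal stop codon.
#'
#' @param g a [gene_alignment()]
#' @param pair two species labels; defaults to the first two species
#' @param min_aligned minimum aligned bases for a valid estimate (150)
#' @return list: `gene_id, Sd, Nd, S, N, pS, pN, dS, dN, omega,
#'   n_codons_used, aligned_bases, valid, reason`
#' @export
estimate_pairwise <- function(g, pair = names(g$sequences)[1:2],
                              min_aligned = 150) {
  prof <- pairwise_codon_profile(g, pair)
  estimate_from_profile(prof, min_aligned = min_aligned)
}

#' Pairwise dN/dS table for a list of genes
#' @param genes list of [gene_alignment()]s
#' @inheritParams estimate_pairwise
#' @return data.frame, one row per gene
#' @export
pairwise_dnds_table <- function(genes, pair = NULL, min_aligned = 150) {
  rows <- lapply(genes, function(g) {
    p <- if (is.null(pair)) names(g$sequences)[1:2] else pair
    as.data.frame(estimate_pairwise(g, p, min_aligned))
  })
  do.call(rbind, rows)
}
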