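# Gene alignment data model.
#
# Coordinates are 0-based, half-open, in codon units over the ungapped
# reference CDS. Genomic coordinates never enter the pipeline; alignment
# construction is upstream of this package.

#' Construct a per-gene codon alignment
#'
#' @param gene_id gene identifier
#' @param sequences named character vector of gapped, uppercase DNA strings
#'   (one per species); all must share one alignment length and use `-` as the
#'   gap character
#' @param exon_blocks data.frame with columns `exon_index`, `codon_start`,
#'   `codon_end` (0-based, half-open, codon units on the ungapped reference
#'   CDS). Optional logical columns `in_frame` and `multiple_of_three` carry
#'   upstream eligibility; both default to `TRUE` since a codon-unit map is
#'   frame-consistent by construction. `fully_aligned` is always recomputed
#'   from the alignment.
#' @param reference_species species whose ungapped CDS defines the coordinate
#'   system (default: first sequence)
#' @return object of class `gene_alignment`
#' @export
gene_alignment <- function(gene_id, sequences, exon_blocks,
                           reference_species = names(sequences)[1]) {
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("`sequences` must be uniquely named by species", call. = FALSE)
  sequences <- toupper(sequences)
  widths <- nchar(sequences)
  if (length(unique(widths)) != 1L)
    stop("alignment format error: sequences of unequal gapped length for gene ",
         gene_id, call. = FALSE)
  if (!reference_species %in% names(sequences))
    stop("reference species ", reference_species, " not in alignment",
         call. = FALSE)

  ref_chars <- strsplit(sequences[[reference_species]], "")[[1]]
  ref_cols <- which(ref_chars != GAP_CHAR)
  if (length(ref_cols) %% 3L != 0L)
    stop("alignment format error: ungapped reference length not a multiple ",
         "of 3 for gene ", gene_id, call. = FALSE)
  n_codons <- length(ref_cols) %/% 3L

  eb <- as.data.frame(exon_blocks)
  req <- c("exon_index", "codon_start", "codon_end")
  if (!all(req %in% names(eb)))
    stop("exon map must have columns exon_index, codon_start, codon_end",
         call. = FALSE)
  eb <- eb[order(eb$codon_start), , drop = FALSE]
  rownames(eb) <- NULL
  if (any(eb$codon_start >= eb$codon_end))
    stop("exon map consistency error: codon_start >= codon_end", call. = FALSE)
  tiles <- unlist(Map(seq, eb$codon_start, eb$codon_end - 1L))
  if (length(tiles) != n_codons || !identical(as.integer(sort(tiles)),
                                              seq_len(n_codons) - 1L))
    stop("exon map consistency error: blocks do not tile [0, ", n_codons,
         ") for gene ", gene_id, call. = FALSE)

  if (is.null(eb$in_frame)) eb$in_frame <- TRUE
  if (is.null(eb$multiple_of_three)) eb$multiple_of_three <- TRUE

  # codon i (1-based) occupies alignment columns codon_cols[, i]
  codon_cols <- matrix(ref_cols, nrow = 3L)

  # fully_aligned: no gap in any species anywhere in the block's column span
  # (reference insertions inside the span also disqualify the block)
  char_mat <- do.call(rbind, strsplit(unname(sequences), ""))
  eb$fully_aligned <- vapply(seq_len(nrow(eb)), function(b) {
    first <- codon_cols[1L, eb$codon_start[b] + 1L]
    last <- codon_cols[3L, eb$codon_end[b]]
    !any(char_mat[, first:last] == GAP_CHAR)
  }, logical(1))

  ref_codons <- apply(matrix(ref_chars[ref_cols], nrow = 3L), 2, paste0,
                      collapse = "")
  aa <- suppressWarnings(translate_codons(ref_codons))
  internal_stop <- any(!is.na(aa[-n_codons]) & aa[-n_codons] == "*")

  structure(list(
    gene_id = gene_id,
    reference_species = reference_species,
    sequences = sequences,
    exon_blocks = eb[, c("exon_index", "codon_start", "codon_end",
                         "fully_aligned", "in_frame", "multiple_of_three")],
    n_codons = n_codons,
    codon_cols = codon_cols,
    has_internal_stop = internal_stop
  ), class = "gene_alignment")
}

#' @export
print.gene_alignment <- function(x, ...) {
  cat(sprintf("<gene_alignment> %s: %d species, %d codons, %d exon blocks%s\n",
              x$gene_id, length(x$sequences), x$n_codons, nrow(x$exon_blocks),
              if (x$has_internal_stop) " [internal stop: excluded]" else ""))
  invisible(x)
}

#' Construct a three-taxon ((ingroup1, ingroup2), outgroup) alignment
#'
#' A [gene_alignment()] whose species are exactly `ingroup1`, `ingroup2` and
#' `outgroup`; the unrooted topology is fixed by the labels.
#' @inheritParams gene_alignment
#' @return object of classes `trio_alignment`, `gene_alignment`
#' @export
trio_alignment <- function(gene_id, sequences, exon_blocks,
                           reference_species = "ingroup1") {
  if (!setequal(names(sequences), c("ingroup1", "ingroup2", "outgroup")))
    stop("trio alignment requires species ingroup1, ingroup2, outgroup",
         call. = FALSE)
  g <- gene_alignment(gene_id, sequences, exon_blocks, reference_species)
  class(g) <- c("trio_alignment", class(g))
  g
}

#' Read a per-gene alignment from FASTA plus an exon-map sidecar
#'
#' FASTA record ids are species labels. The exon map is a TSV with header
#' `gene_id, exon_index, codon_start, codon_end` (optionally `in_frame`,
#' `multiple_of_three`).
#'
#' @param fasta_path gapped multi-FASTA for one gene
#' @param exon_map_path exon map TSV (may contain several genes)
#' @param gene_id gene to select from the exon map; defaults to the single
#'   gene id present
#' @param reference_species defaults to the first FASTA record
#' @return a [gene_alignment()] (a `trio_alignment` when the records are
#'   labelled ingroup1/ingroup2/outgroup)
#' @export
read_gene_alignment <- function(fasta_path, exon_map_path, gene_id = NULL,
                                reference_species = NULL) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  sequences <- stats::setNames(as.character(seqs), names(seqs))
  emap <- utils::read.delim(exon_map_path, stringsAsFactors = FALSE)
  if (is.null(gene_id)) {
    ids <- unique(emap$gene_id)
    if (length(ids) != 1L)
      stop("exon map contains several genes; pass `gene_id`", call. = FALSE)
    gene_id <- ids
  }
  emap <- emap[emap$gene_id == gene_id, , drop = FALSE]
  if (nrow(emap) == 0L)
    stop("exon map consistency error: no rows for gene ", gene_id,
         call. = FALSE)
  if (is.null(reference_species)) reference_species <- names(sequences)[1]
  if (setequal(names(sequences), c("ingroup1", "ingroup2", "outgroup")))
    trio_alignment(gene_id, sequences, emap,
                   reference_species = reference_species)
  else
    gene_alignment(gene_id, sequences, emap,
                   reference_species = reference_species)
}

#' Write a gene alignment back to FASTA + exon-map TSV
#' @param g a [gene_alignment()]
#' @param fasta_path,exon_map_path output paths
#' @return invisibly, `g`
#' @export
write_gene_alignment <- function(g, fasta_path, exon_map_path) {
  set <- Biostrings::BStringSet(g$sequences)
  Biostrings::writeXStringSet(set, fasta_path)
  out <- cbind(gene_id = g$gene_id,
               g$exon_blocks[, c("exon_index", "codon_start", "codon_end",
                                 "in_frame", "multiple_of_three")])
  utils::write.table(out, exon_map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(g)
}

#' Number of aligned bases between two species
#'
#' Alignment columns where neither species carries a gap character.
#' @param g a [gene_alignment()]
#' @param pair character vector of two species labels
#' @return integer count
#' @export
aligned_bases <- function(g, pair) {
  if (!all(pair %in% names(g$sequences)))
    stop("species not in alignment: ",
         paste(setdiff(pair, names(g$sequences)), collapse = ", "),
         call. = FALSE)
  a <- strsplit(g$sequences[[pair[1]]], "")[[1]]
  b <- strsplit(g$sequences[[pair[2]]], "")[[1]]
  sum(a != GAP_CHAR & b != GAP_CHAR)
}

# Codon strings of each species at the reference codon positions
# (n_codons x n_species matrix; entries may contain gaps or ambiguity).
codon_matrix <- function(g) {
  cols <- g$codon_cols
  out <- vapply(g$sequences, function(s) {
    chars <- strsplit(s, "")[[1]]
    m <- matrix(chars[cols], nrow = 3L)
    paste0(m[1L, ], m[2L, ], m[3L, ])
  }, character(g$n_codons))
  if (g$n_codons == 1L) out <- matrix(out, nrow = 1L,
                                      dimnames = list(NULL, names(g$sequences)))
  out
}

# Subset a gene alignment to a set of reference codon indices (1-based,
# kept in ascending order). Alignment columns not covered by a kept codon --
# including insertion columns relative to the reference -- are dropped.
subset_codons <- function(g, keep_idx) {
  keep_idx <- sort(unique(as.integer(keep_idx)))
  if (length(keep_idx) == 0L)
    stop("empty-alignment error: no codons kept for gene ", g$gene_id,
         call. = FALSE)
  stopifnot(all(keep_idx >= 1L), all(keep_idx <= g$n_codons))
  cols <- as.vector(g$codon_cols[, keep_idx, drop = FALSE])
  new_seqs <- vapply(g$sequences, function(s) {
    paste0(strsplit(s, "")[[1]][cols], collapse = "")
  }, character(1))

  # rebuild exon blocks: contiguous runs of kept codons within each original
  # block, remapped to the new codon coordinates
  eb <- g$exon_blocks
  rows <- list()
  new_start <- 0L
  for (b in seq_len(nrow(eb))) {
    in_block <- keep_idx[keep_idx > eb$codon_start[b] &
                           keep_idx <= eb$codon_end[b]]
    if (length(in_block) == 0L) next
    len <- length(in_block)
    rows[[length(rows) + 1L]] <- data.frame(
      exon_index = eb$exon_index[b],
      codon_start = new_start, codon_end = new_start + len,
      in_frame = eb$in_frame[b], multiple_of_three = eb$multiple_of_three[b])
    new_start <- new_start + len
  }
  new_blocks <- do.call(rbind, rows)
  out <- gene_alignment(g$gene_id, new_seqs, new_blocks,
                        reference_species = g$reference_species)
  if (inherits(g, "trio_alignment")) class(out) <- c("trio_alignment",
                                                     class(out))
  out
}

#' Concatenate a subset of exon blocks into a new alignment
#'
#' Keeps only the alignment columns of the given blocks (which must be a
#' subset of the gene's blocks) and remaps coordinates.
#' @param g a [gene_alignment()]
#' @param keep data.frame of exon blocks to keep (rows of `g$exon_blocks`), or
#'   an integer vector of `exon_index` values
#' @return a new [gene_alignment()]
#' @export
concatenate_blocks <- function(g, keep) {
  if (is.data.frame(keep)) keep <- keep$exon_index
  eb <- g$exon_blocks
  if (!all(keep %in% eb$exon_index))
    stop("`keep` must be a subset of the gene's exon blocks", call. = FALSE)
  if (length(keep) == 0L)
    stop("empty-alignment error: no blocks kept for gene ", g$gene_id,
         call. = FALSE)
  sel <- eb[eb$exon_index %in% keep, , drop = FALSE]
  idx <- unlist(Map(function(s, e) seq(s + 1L, e), sel$codon_start,
                    sel$codon_end))
  subset_codons(g, idx)
}
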