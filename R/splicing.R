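# Transcript-number-normalised alternative-splicing index.
#
# Event detection is a deliberately minimal, fully specified detector over
# EST intron chains (gene-local, half-open coordinates): two kinds of event
# signature are counted, each once -
#   * boundary mismatch: an unordered pair of distinct, overlapping intron
#     intervals observed in different chains;
#   * intron retention: an intron fully contained in another chain's mapped
#     extent with no intron of that chain overlapping it (exonic coverage).
# Chains are compared only over overlapping mapped extents: absence of an
# intron outside an EST's extent is not evidence. The resampling
# normalisation (mean events over 100 random samples of 10 mapped ESTs) is
# the method of interest and is implemented exactly.

#' Build EST chains from a tidy intron table
#'
#' @param df data.frame with columns `gene_id, est_id, intron_start,
#'   intron_end, est_extent_start, est_extent_end`; an intronless EST is a row
#'   with NA intron coordinates
#' @return named list (by gene) of lists of chains; each chain has `est_id`,
#'   `extent = c(start, end)` and `introns` (2-column matrix, possibly empty)
#' @export
est_chains_from_table <- function(df) {
  req <- c("gene_id", "est_id", "intron_start", "intron_end",
           "est_extent_start", "est_extent_end")
  stopifnot(all(req %in% names(df)))
  out <- list()
  for (gid in unique(df$gene_id)) {
    sub <- df[df$gene_id == gid, , drop = FALSE]
    chains <- lapply(unique(sub$est_id), function(eid) {
      rows <- sub[sub$est_id == eid, , drop = FALSE]
      introns <- rows[!is.na(rows$intron_start),
                      c("intron_start", "intron_end"), drop = FALSE]
      introns <- as.matrix(introns[order(introns$intron_start), , drop = FALSE])
      if (nrow(introns) > 1L &&
          any(introns[-1L, 1L] < introns[-nrow(introns), 2L]))
        stop("overlapping introns within one chain: ", eid, call. = FALSE)
      list(est_id = eid,
           extent = c(rows$est_extent_start[1], rows$est_extent_end[1]),
           introns = introns)
    })
    out[[gid]] <- chains
  }
  out
}

.intervals_overlap <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

#' Count alternative-splicing event signatures among EST chains
#'
#' @param chains list of chains for one gene (see [est_chains_from_table()])
#' @return integer event count
#' @export
count_as_events <- function(chains) {
  if (length(chains) < 2L) return(0L)
  # collect all introns with their chain of origin
  introns <- list()
  for (ci in seq_along(chains)) {
    m <- chains[[ci]]$introns
    if (length(m) && nrow(m))
      for (r in seq_len(nrow(m)))
        introns[[length(introns) + 1L]] <- list(chain = ci, s = m[r, 1],
                                                e = m[r, 2])
  }
  signatures <- character(0)
  # boundary-mismatch pairs: distinct overlapping intervals in different chains
  if (length(introns) >= 2L) {
    for (i in seq_along(introns)) {
      for (j in seq_along(introns)) {
        if (j <= i) next
        a <- introns[[i]]; b <- introns[[j]]
        if (a$chain == b$chain) next
        if ((a$s != b$s || a$e != b$e) &&
            .intervals_overlap(a$s, a$e, b$s, b$e)) {
          # canonical unordered key on the two intervals
          iv <- rbind(c(a$s, a$e), c(b$s, b$e))
          iv <- iv[order(iv[, 1], iv[, 2]), , drop = FALSE]
          key <- paste("bm", paste(t(iv), collapse = ","))
          signatures <- c(signatures, key)
        }
      }
    }
  }
  # retention: an intron fully inside another chain's intron-free extent
  for (i in seq_along(introns)) {
    a <- introns[[i]]
    for (ci in seq_along(chains)) {
      if (ci == a$chain) next
      ch <- chains[[ci]]
      if (!(ch$extent[1] <= a$s && ch$extent[2] >= a$e)) next
      m <- ch$introns
      covered_by_intron <- length(m) && nrow(m) &&
        any(.intervals_overlap(m[, 1], m[, 2], a$s, a$e))
      if (!covered_by_intron)
        signatures <- c(signatures, paste("ret", a$s, a$e))
    }
  }
  length(unique(signatures))
}

#' Transcript-number-normalised alternative-splicing index
#'
#' Mean of [count_as_events()] over `n_resamples` uniform subsamples, without
#' replacement, of `sample_size` chains. Genes with fewer than `sample_size`
#' mapped ESTs are excluded (index NA, flag set).
#'
#' @param chains list of chains for one gene
#' @param sample_size ESTs per subsample (10)
#' @param n_resamples subsamples (100)
#' @return list `n_ests, index, n_resamples, sample_size, excluded`
#' @export
splicing_index <- function(chains, sample_size = 10, n_resamples = 100) {
  n <- length(chains)
  if (n < sample_size)
    return(list(n_ests = n, index = NA_real_, n_resamples = n_resamples,
                sample_size = sample_size, excluded = TRUE))
  counts <- vapply(seq_len(n_resamples), function(r) {
    sub <- chains[sample.int(n, sample_size)]
    count_as_events(sub)
  }, numeric(1))
  list(n_ests = n, index = mean(counts), n_resamples = n_resamples,
       sample_size = sample_size, excluded = FALSE)
}

#' Splicing-index table for all genes in an EST table
#'
#' @param est_df tidy EST intron table (see [est_chains_from_table()])
#' @inheritParams splicing_index
#' @return data.frame `gene_id, n_ests, index, excluded`
#' @export
splicing_index_table <- function(est_df, sample_size = 10, n_resamples = 100) {
  by_gene <- est_chains_from_table(est_df)
  rows <- lapply(names(by_gene), function(gid) {
    si <- splicing_index(by_gene[[gid]], sample_size, n_resamples)
    data.frame(gene_id = gid, n_ests = si$n_ests, index = si$index,
               excluded = si$excluded, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
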