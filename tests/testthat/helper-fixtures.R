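# Shared fixtures, built in code.

# A small two-species gene: 2 exons x 10 codons, a handful of substitutions,
# one gap codon in the second exon of species b.
make_two_species_gene <- function(gap = FALSE) {
  set.seed(401)
  codons <- exonedge:::all_codons()[exonedge:::sense_codon_idx()]
  a <- sample(codons, 20, replace = TRUE)
  b <- a
  b[c(3, 8, 14)] <- sample(codons, 3, replace = TRUE)
  seq_b <- b
  if (gap) seq_b[15] <- "---"
  gene_alignment(
    "toy1",
    c(sp1 = paste0(a, collapse = ""), sp2 = paste0(seq_b, collapse = "")),
    data.frame(exon_index = 0:1, codon_start = c(0, 10), codon_end = c(10, 20)))
}

# A trio gene with chosen codon columns (same length vectors per species).
make_trio_from_codons <- function(c1, c2, c3, exon_blocks = NULL) {
  n <- length(c1)
  if (is.null(exon_blocks))
    exon_blocks <- data.frame(exon_index = 0, codon_start = 0, codon_end = n)
  trio_alignment("trio1",
                 c(ingroup1 = paste0(c1, collapse = ""),
                   ingroup2 = paste0(c2, collapse = ""),
                   outgroup = paste0(c3, collapse = "")),
                 exon_blocks)
}

# Memoised small simulated dataset shared across tests.
.fixture_env <- new.env(parent = emptyenv())
shared_dataset <- function() {
  if (is.null(.fixture_env$ds))
    .fixture_env$ds <- simulate_dataset(sim_config(n_genes = 60), seed = 4242)
  .fixture_env$ds
}

# Independent oracle: enumerate the nine single-nucleotide neighbours of a
# codon against the genetic code (no shared code with count_sites beyond the
# code table itself).
oracle_sites <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  syn <- 0
  for (pos in 1:3) {
    for (b in bases) {
      if (b == substr(codon, pos, pos)) next
      mut <- codon
      substr(mut, pos, pos) <- b
      if (identical(unname(code[mut]), unname(code[codon]))) syn <- syn + 1 / 3
    }
  }
  c(S = syn, N = 3 - syn)
}

# Independent oracle: path-ordering enumeration of Sd/Nd between two codons,
# written against the raw code table with its own permutation logic.
oracle_differences <- function(a, b) {
  code <- Biostrings::GENETIC_CODE
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (!length(pos)) return(c(Sd = 0, Nd = 0))
  perms <- if (length(pos) == 1) list(pos) else {
    out <- list()
    rec <- function(prefix, rest) {
      if (!length(rest)) out[[length(out) + 1]] <<- prefix
      else for (i in seq_along(rest)) rec(c(prefix, rest[i]), rest[-i])
    }
    rec(integer(0), pos)
    out
  }
  res <- lapply(perms, function(ord) {
    cur <- a; syn <- 0; nonsyn <- 0; hit_stop <- FALSE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      if (identical(unname(code[nxt]), unname(code[cur]))) syn <- syn + 1
      else nonsyn <- nonsyn + 1
      if (unname(code[nxt]) == "*") hit_stop <- TRUE
      cur <- nxt
    }
    c(syn = syn, nonsyn = nonsyn, ok = !hit_stop)
  })
  m <- do.call(rbind, res)
  use <- if (any(m[, "ok"] == 1)) m[, "ok"] == 1 else rep(TRUE, nrow(m))
  c(Sd = mean(m[use, "syn"]), Nd = mean(m[use, "nonsyn"]))
}
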