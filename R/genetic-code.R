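# Internal cache for codon lookup tables. All tables are derived once, on first
# use, from the standard genetic code (Biostrings::GENETIC_CODE); the pairwise
# difference matrices are computed by explicit pathway enumeration so that the
# counting estimator and its test oracles share nothing but the code table.
.codon_env <- new.env(parent = emptyenv())

DNA_BASES <- c("A", "C", "G", "T")
GAP_CHAR <- "-"

#' All 64 codons in a fixed order
#' @return character vector of length 64
#' @keywords internal
all_codons <- function() {
  if (is.null(.codon_env$codons)) {
    g <- expand.grid(b3 = DNA_BASES, b2 = DNA_BASES, b1 = DNA_BASES,
                     stringsAsFactors = FALSE)
    .codon_env$codons <- paste0(g$b1, g$b2, g$b3)
  }
  .codon_env$codons
}

#' Amino acid translation of a codon vector ("*" for stop)
#' @param codons character vector of codons
#' @keywords internal
translate_codons <- function(codons) {
  if (is.null(.codon_env$code)) .codon_env$code <- Biostrings::GENETIC_CODE
  unname(.codon_env$code[codons])
}

#' Indices (into [all_codons()]) of the 61 sense codons
#' @keywords internal
sense_codon_idx <- function() {
  if (is.null(.codon_env$sense)) {
    .codon_env$sense <- which(translate_codons(all_codons()) != "*")
  }
  .codon_env$sense
}

is_sense_codon <- function(codon) {
  if (is.null(.codon_env$code)) .codon_env$code <- Biostrings::GENETIC_CODE
  aa <- .codon_env$code[codon]
  !is.na(aa) & aa != "*"
}

#' Synonymous and non-synonymous site counts for a sense codon
#'
#' Nei-Gojobori (1986) expected site counts: the synonymous site count of a
#' codon is, summed over its three positions, the fraction of the three
#' possible single-nucleotide changes at that position that leave the encoded
#' amino acid unchanged. Changes that create a stop codon count as
#' non-synonymous. For every sense codon `S + N == 3` exactly.
#'
#' @param codon a single sense codon (3 uppercase bases)
#' @return list with numeric fields `S` and `N`
#' @export
#' @examples
#' count_sites("TTT") # S = 1/3
#' count_sites("TGG") # Trp: S = 0
count_sites <- function(codon) {
  if (!is.character(codon) || length(codon) != 1L || nchar(codon) != 3L)
    stop("`codon` must be a single 3-base string", call. = FALSE)
  if (!is_sense_codon(codon))
    stop("`codon` must be a sense codon (no stops or ambiguity): ", codon,
         call. = FALSE)
  aa0 <- translate_codons(codon)
  syn <- 0
  for (pos in 1:3) {
    cur <- substr(codon, pos, pos)
    for (b in setdiff(DNA_BASES, cur)) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (translate_codons(mut) == aa0) syn <- syn + 1 / 3
    }
  }
  list(S = syn, N = 3 - syn)
}

# Classify one mutational step a -> b (codons differing at exactly one
# position): TRUE if synonymous. Steps to or from a stop codon are
# non-synonymous ("*" never equals a sense amino acid).
.step_synonymous <- function(a, b) {
  translate_codons(a) == translate_codons(b)
}

.path_permutations <- list(
  `1` = matrix(1L, 1, 1),
  `2` = rbind(c(1L, 2L), c(2L, 1L)),
  `3` = rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
              c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
)

#' Synonymous/non-synonymous difference counts between two sense codons
#'
#' For codons differing at `d` positions, all `d!` orderings of single-step
#' mutational pathways are enumerated; each step is classified synonymous or
#' non-synonymous by the genetic code and counts are averaged over pathways.
#' Pathways passing through a stop codon are excluded; if every pathway hits a
#' stop, the average is taken over all pathways with each step classified by
#' the code (stop steps are non-synonymous).
#'
#' @param a,b sense codons
#' @return list with numeric fields `Sd` and `Nd`; `Sd + Nd` equals the number
#'   of differing positions
#' @export
#' @examples
#' count_differences("TTT", "TTC") # Sd = 1, Nd = 0
#' count_differences("TTT", "GTA") # Sd = 0.5, Nd = 1.5 (two pathways)
count_differences <- function(a, b) {
  for (x in c(a, b)) {
    if (!is.character(x) || length(x) != 1L || nchar(x) != 3L ||
        grepl("[^ACGT]", x))
      stop("codons must be 3-base strings over ACGT", call. = FALSE)
    if (!is_sense_codon(x))
      stop("codons must be sense codons: ", x, call. = FALSE)
  }
  diff_pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  d <- length(diff_pos)
  if (d == 0L) return(list(Sd = 0, Nd = 0))
  perms <- .path_permutations[[as.character(d)]]
  paths_syn <- numeric(0)
  paths_nonsyn <- numeric(0)
  path_valid <- logical(0)
  for (r in seq_len(nrow(perms))) {
    order_pos <- diff_pos[perms[r, ]]
    cur <- a
    syn <- 0; nonsyn <- 0; valid <- TRUE
    for (pos in order_pos) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(b, pos, pos)
      if (.step_synonymous(cur, nxt)) syn <- syn + 1 else nonsyn <- nonsyn + 1
      if (translate_codons(nxt) == "*") valid <- FALSE
      cur <- nxt
    }
    paths_syn <- c(paths_syn, syn)
    paths_nonsyn <- c(paths_nonsyn, nonsyn)
    path_valid <- c(path_valid, valid)
  }
  use <- if (any(path_valid)) path_valid else rep(TRUE, length(path_valid))
  list(Sd = mean(paths_syn[use]), Nd = mean(paths_nonsyn[use]))
}

# ---- cached 64 x 64 lookup tables ------------------------------------------

#' Per-codon synonymous site counts, indexed like all_codons() (NA for stops)
#' @keywords internal
codon_site_table <- function() {
  if (is.null(.codon_env$S_sites)) {
    codons <- all_codons()
    s <- rep(NA_real_, 64)
    for (i in sense_codon_idx()) s[i] <- count_sites(codons[i])$S
    .codon_env$S_sites <- s
  }
  .codon_env$S_sites
}

# 64 x 64 matrices of pathway-averaged Sd / Nd between sense codon pairs
# (NA where either codon is a stop), plus nucleotide Hamming distances.
codon_diff_tables <- function() {
  if (is.null(.codon_env$SD)) {
    codons <- all_codons()
    sense <- sense_codon_idx()
    SD <- matrix(NA_real_, 64, 64, dimnames = list(codons, codons))
    ND <- SD
    for (i in sense) {
      for (j in sense) {
        if (j < i) {
          SD[i, j] <- SD[j, i]
          ND[i, j] <- ND[j, i]
        } else {
          cd <- count_differences(codons[i], codons[j])
          SD[i, j] <- cd$Sd
          ND[i, j] <- cd$Nd
        }
      }
    }
    chars <- matrix(unlist(strsplit(codons, "")), nrow = 3)
    HAM <- matrix(0L, 64, 64, dimnames = list(codons, codons))
    for (p in 1:3) HAM <- HAM + outer(chars[p, ], chars[p, ], "!=")
    .codon_env$SD <- SD
    .codon_env$ND <- ND
    .codon_env$HAM <- HAM
  }
  list(SD = .codon_env$SD, ND = .codon_env$ND, HAM = .codon_env$HAM)
}

# Integer mutation tables for the simulator: NEIGH[c, (pos-1)*3 + a] is the
# codon index after changing position `pos` of codon `c` to its a-th
# alternative base (alternatives in A,C,G,T order); SAME_AA is the 64 x 64
# synonymy table; IS_STOP flags stop codons.
codon_mutation_tables <- function() {
  if (is.null(.codon_env$NEIGH)) {
    codons <- all_codons()
    aa <- translate_codons(codons)
    NEIGH <- matrix(NA_integer_, 64, 9)
    for (ci in 1:64) {
      for (pos in 1:3) {
        cur <- substr(codons[ci], pos, pos)
        alts <- DNA_BASES[DNA_BASES != cur]
        for (a in 1:3) {
          mut <- codons[ci]
          substr(mut, pos, pos) <- alts[a]
          NEIGH[ci, (pos - 1L) * 3L + a] <- match(mut, codons)
        }
      }
    }
    .codon_env$NEIGH <- NEIGH
    .codon_env$SAME_AA <- outer(aa, aa, "==")
    .codon_env$IS_STOP <- aa == "*"
  }
  list(NEIGH = .codon_env$NEIGH, SAME_AA = .codon_env$SAME_AA,
       IS_STOP = .codon_env$IS_STOP)
}

#' Jukes-Cantor distance from an observed difference proportion
#'
#' `d = -(3/4) * log(1 - (4/3) * p)`; returns `NA` outside the domain
#' (`p >= 0.75`).
#' @param p observed proportion of differences per site
#' @export
jukes_cantor <- function(p) {
  ifelse(is.finite(p) & p >= 0 & p < 0.75, -0.75 * log(1 - 4 * p / 3), NA_real_)
}
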