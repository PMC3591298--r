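# Codon state space under the universal genetic code.
#
# Canonical ordering (frozen): the 61 sense codons sorted alphabetically
# by triplet, i.e. with TAA/TAG/TGA removed from the 64 lexicographic
# triplets. All rate matrices, frequency vectors and serialized outputs
# use this ordering. Indices are 1-based on the R side.

.codon_cache <- new.env(parent = emptyenv())

.genetic_code <- function() {
  if (is.null(.codon_cache$codons)) {
    gc <- Biostrings::GENETIC_CODE
    codons <- sort(names(gc)[gc != "*"])
    .codon_cache$codons <- codons
    .codon_cache$aa <- unname(gc[codons])
    .codon_cache$stops <- sort(names(gc)[gc == "*"])
    idx <- rep(NA_integer_, 64)
    all64 <- sort(names(gc))
    idx <- ifelse(all64 %in% codons, match(all64, codons), 0L)
    names(idx) <- all64
    .codon_cache$lookup <- idx
  }
  .codon_cache
}

#' The 61 sense codons in canonical order
#'
#' Alphabetical triplet order with the three stop codons removed. This
#' ordering is frozen: it defines the layout of every codon frequency
#' vector and rate matrix in the package.
#'
#' @return Character vector of length 61.
#' @export
sense_codons <- function() .genetic_code()$codons

#' Amino acid translated by each sense codon
#'
#' @return Character vector of length 61, aligned with [sense_codons()].
#' @export
codon_amino_acids <- function() .genetic_code()$aa

#' Encode nucleotide triplets as codon states
#'
#' Maps each 3-letter triplet to its index in the canonical sense-codon
#' ordering. `U` is silently mapped to `T` (RNA input is common). Any
#' triplet containing a gap, `N`, or another ambiguity code encodes as
#' missing (`NA`). Stop codons encode as `0`.
#'
#' @param triplet Character vector of 3-letter nucleotide strings.
#' @return Integer vector: 1..61 for sense codons, 0 for stop codons,
#'   `NA` for missing/ambiguous.
#' @examples
#' encode_codon(c("ATG", "TAA", "ATN", "AUG"))
#' @export
encode_codon <- function(triplet) {
  gcinfo <- .genetic_code()
  x <- chartr("U", "T", toupper(triplet))
  unname(gcinfo$lookup[x])
}

#' Decode codon states back to triplets
#'
#' @param state Integer vector of codon states (1..61, 0 = stop, NA =
#'   missing).
#' @param missing String used for missing states (default `"---"`).
#' @return Character vector of triplets.
#' @export
decode_codon <- function(state, missing = "---") {
  codons <- sense_codons()
  out <- rep(missing, length(state))
  ok <- !is.na(state) & state >= 1
  out[ok] <- codons[state[ok]]
  out[!is.na(state) & state == 0] <- "TAA" # canonical stop representative
  out
}

#' Amino-acid alphabet in PAML/Dayhoff order
#'
#' All 20-state machinery (exchangeability matrices, partial vectors,
#' simulators) uses this ordering; user-facing residue letters are
#' order-independent.
#' @export
AA_LETTERS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Encode amino-acid letters as states
#'
#' @param letter Character vector of 1-letter residue codes. Gaps and
#'   ambiguity codes (`-`, `.`, `X`, `B`, `Z`, `?`, `*`) encode as `NA`.
#' @return Integer vector of states in 1..20 (PAML residue order) or `NA`.
#' @export
encode_aa <- function(letter) {
  match(toupper(letter), AA_LETTERS)
}
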