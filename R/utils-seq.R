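#' @importFrom Biostrings DNAStringSet reverseComplement GENETIC_CODE
NULL

# Codon -> amino acid lookup from the standard genetic code ("*" = stop).
.codon_table <- function() Biostrings::GENETIC_CODE

#' Reverse complement of nucleotide strings
#'
#' Vectorized reverse complement over the DNA alphabet (A, C, G, T, N).
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector of reverse-complemented strings.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Translate a nucleotide sequence in frame 0
#'
#' Translates codon by codon with the standard genetic code. Stop codons are
#' rendered as \code{"*"}; codons containing any non-ACGT base become
#' \code{"X"}. A trailing partial codon is dropped.
#'
#' @param nt Single nucleotide string (5' to 3').
#' @return Single amino-acid string, possibly containing \code{"*"}.
#' @export
translate_nt <- function(nt) {
  stopifnot(is.character(nt), length(nt) == 1L)
  n <- nchar(nt) %/% 3L
  if (n == 0L) return("")
  starts <- seq.int(1L, by = 3L, length.out = n)
  codons <- substring(nt, starts, starts + 2L)
  aa <- unname(.codon_table()[codons])
  aa[is.na(aa)] <- "X"
  paste0(aa, collapse = "")
}

# Translate and cut at the first stop codon. Returns list(peptide, truncated):
# peptide is the prefix before the first "*" (empty if the first codon is a
# stop); truncated is TRUE when a stop codon was encountered.
translate_to_stop <- function(nt) {
  aa <- translate_nt(nt)
  hit <- regexpr("*", aa, fixed = TRUE)
  if (hit > 0L) {
    list(peptide = substr(aa, 1L, hit - 1L), truncated = TRUE)
  } else {
    list(peptide = aa, truncated = FALSE)
  }
}

.STOP_CODONS <- c("TAA", "TAG", "TGA")

# The nine single-substitution neighbours of ATG (near-cognate start codons).
.NEAR_COGNATE <- c("CTG", "GTG", "TTG", "ATA", "ATT", "ATC", "ACG", "AAG", "AGG")

`%||%` <- function(a, b) if (is.null(a)) b else a
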