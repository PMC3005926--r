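#' Reverse complement of DNA sequences
#'
#' @param x Character vector of DNA sequences (ACGTN).
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp(c("ACGT", "AAATTT"))
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Normalize sequences to the uppercase DNA alphabet
#'
#' Uppercases and converts U to T so RNA-style input can be compared against
#' genomic DNA.
#'
#' @param x Character vector of sequences.
#' @return Character vector over ACGTN.
#' @export
normalize_seq <- function(x) {
  chartr("U", "T", toupper(x))
}

# Round half away from zero, matching hand-computed percentages where .05
# rounds up (base round() rounds half to even).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

gc_fraction <- function(x) {
  n <- nchar(x)
  gc <- nchar(gsub("[^GCgc]", "", x))
  ifelse(n > 0, gc / n, NA_real_)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Stable content hash used for read ids.
read_hash <- function(x) {
  vapply(x, function(s) substr(rlang::hash(s), 1, 10), character(1),
         USE.NAMES = FALSE)
}

`%||%` <- rlang::`%||%`
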