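#' Genome container with soft-mask annotation
#'
#' A genome is stored as a named character vector of uppercase chromosome
#' sequences plus a tibble of masked intervals (0-based half-open). Lowercase
#' (soft-masked) runs in a FASTA are recorded in the mask table; `N` runs are
#' hard masks and stay in the sequence.
#'
#' @param seq Named character vector of chromosome sequences.
#' @param mask Tibble with columns `chrom`, `start`, `end` (0-based
#'   half-open) of soft-masked intervals. Defaults to no masking.
#' @return An object of class `mirna_genome`.
#' @export
mirna_genome <- function(seq, mask = NULL) {
  stopifnot(is.character(seq), !is.null(names(seq)))
  mask <- mask %||% tibble(chrom = character(0), start = integer(0),
                           end = integer(0))
  structure(
    list(seq = toupper(seq), mask = as_tibble(mask)),
    class = "mirna_genome"
  )
}

#' @export
print.mirna_genome <- function(x, ...) {
  cat("<mirna_genome> ", length(x$seq), " chromosome(s), ",
      format(sum(nchar(x$seq)), big.mark = ","), " bp, ",
      nrow(x$mask), " masked interval(s)\n", sep = "")
  invisible(x)
}

chrom_lengths <- function(genome) {
  setNames(nchar(genome$seq), names(genome$seq))
}

#' Read a genome FASTA with soft-mask detection
#'
#' Lowercase runs are recorded as soft-masked intervals; sequences are
#' uppercased for matching.
#'
#' @param path Path to a FASTA file.
#' @return A [mirna_genome()] object.
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  mask <- purrr::map2_dfr(names(seqs), seqs, function(chrom, s) {
    low <- gregexpr("[acgtn]+", s)[[1]]
    if (low[1] == -1) {
      return(tibble(chrom = character(0), start = integer(0),
                    end = integer(0)))
    }
    tibble(chrom = chrom,
           start = as.integer(low) - 1L,
           end = as.integer(low) - 1L + attr(low, "match.length"))
  })
  mirna_genome(seqs, mask)
}

#' Write a genome to FASTA with soft-masked intervals in lowercase
#'
#' @param genome A [mirna_genome()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  seqs <- genome$seq
  if (nrow(genome$mask) > 0) {
    for (i in seq_len(nrow(genome$mask))) {
      m <- genome$mask[i, ]
      s <- seqs[[m$chrom]]
      piece <- substr(s, m$start + 1L, m$end)
      substr(s, m$start + 1L, m$end) <- tolower(piece)
      seqs[[m$chrom]] <- s
    }
  }
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

# Extract genome subsequence [start, end) 0-based, optionally reverse
# complemented for minus-strand features.
genome_slice <- function(genome, chrom, start, end, strand = "+") {
  s <- substr(genome$seq[[chrom]], start + 1L, end)
  if (strand == "-") s <- revcomp(s)
  s
}
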