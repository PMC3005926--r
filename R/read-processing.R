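#' Collapse raw reads to unique sequences with copy numbers
#'
#' Classifies a read collection into unique reads and tabulates the copy
#' number of each, the standard first step of small-RNA analysis. Copy
#' number is the expression proxy carried through the whole pipeline.
#'
#' @param reads A tibble with a `sequence` column (one row per read), a
#'   character vector of reads, or a path to a FASTQ/FASTA file.
#' @return Tibble of unique reads with columns `read_id`, `sequence`,
#'   `copy_number`, ordered by descending copy number then sequence. Copy
#'   numbers sum to the input read count; an empty input gives an empty
#'   tibble.
#' @export
#' @examples
#' collapse_reads(c("ACGT", "ACGT", "TTTT"))
collapse_reads <- function(reads) {
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    reads <- read_small_rna(reads)
  }
  seqs <- if (is.data.frame(reads)) reads$sequence else reads
  if (length(seqs) == 0) {
    return(tibble(read_id = character(0), sequence = character(0),
                  copy_number = integer(0)))
  }
  seqs <- normalize_seq(seqs)
  tab <- dplyr::count(tibble(sequence = seqs), .data$sequence,
                      name = "copy_number")
  tab <- dplyr::arrange(tab, dplyr::desc(.data$copy_number), .data$sequence)
  tibble(read_id = paste0("read_", read_hash(tab$sequence)),
         sequence = tab$sequence,
         copy_number = as.integer(tab$copy_number))
}

#' Keep unique reads at or above a copy-number threshold
#'
#' Low-copy unique reads are removed before trimming and mapping to improve
#' analysis confidence; the default keeps copy number three or greater.
#'
#' @param unique_reads Tibble with `copy_number` column.
#' @param min_copies Minimum copy number kept (inclusive, >= 1).
#' @return The surviving rows, input order preserved.
#' @export
filter_copy_number <- function(unique_reads, min_copies = 3) {
  stopifnot(min_copies >= 1)
  dplyr::filter(unique_reads, .data$copy_number >= min_copies)
}

#' Trim the 3' adapter from unique reads
#'
#' Removes the longest read suffix that exactly matches a prefix of the
#' adapter (at least `min_overlap` nucleotides). Reads without an adapter
#' overlap pass through unchanged; reads trimmed to length zero are dropped.
#' Reads that become identical after trimming are re-aggregated.
#'
#' @param unique_reads Tibble with `sequence` and `copy_number` columns.
#' @param adapter Adapter sequence.
#' @param min_overlap Minimum suffix/prefix overlap (default 6).
#' @return Tibble of trimmed unique reads.
#' @export
trim_adapter <- function(unique_reads, adapter = default_adapter(),
                         min_overlap = 6) {
  adapter <- normalize_seq(adapter)
  stopifnot(nchar(adapter) >= min_overlap, min_overlap >= 1)
  trim_one <- function(s) {
    n <- nchar(s)
    for (l in seq(min(n, nchar(adapter)), min_overlap)) {
      if (substr(s, n - l + 1, n) == substr(adapter, 1, l)) {
        return(substr(s, 1, n - l))
      }
    }
    s
  }
  if (nrow(unique_reads) == 0) return(unique_reads)
  out <- unique_reads
  out$sequence <- vapply(out$sequence, trim_one, character(1),
                         USE.NAMES = FALSE)
  out <- dplyr::filter(out, nchar(.data$sequence) > 0)
  # distinct cores can share a trimmed sequence when a genomic 3' extension
  # happens to match the adapter prefix; merge them
  out <- dplyr::summarise(dplyr::group_by(out, .data$sequence),
                          copy_number = sum(.data$copy_number),
                          .groups = "drop")
  out <- dplyr::arrange(out, dplyr::desc(.data$copy_number), .data$sequence)
  tibble(read_id = paste0("read_", read_hash(out$sequence)),
         sequence = out$sequence,
         copy_number = as.integer(out$copy_number))
}

#' Keep unique reads within a length window
#'
#' Mature miRNAs are ~22 nt; the mapping contract keeps reads of 18 to 25 nt
#' inclusive.
#'
#' @param unique_reads Tibble with a `sequence` column.
#' @param min_len,max_len Inclusive length bounds.
#' @return The surviving rows, input order preserved.
#' @export
filter_read_length <- function(unique_reads, min_len = 18, max_len = 25) {
  stopifnot(min_len <= max_len)
  dplyr::filter(unique_reads, nchar(.data$sequence) >= min_len,
                nchar(.data$sequence) <= max_len)
}

#' Write collapsed reads as FASTA
#'
#' Headers follow the common collapsed-read dialect
#' `>read_<id>_x<copy_number>`.
#'
#' @param unique_reads Tibble with `read_id`, `sequence`, `copy_number`.
#' @param fasta Output FASTA path.
#' @param tsv Optional TSV path (sequence, copy_number).
#' @return Paths, invisibly.
#' @export
write_collapsed_fasta <- function(unique_reads, fasta, tsv = NULL) {
  ss <- Biostrings::DNAStringSet(unique_reads$sequence)
  names(ss) <- sprintf("%s_x%d", unique_reads$read_id,
                       unique_reads$copy_number)
  Biostrings::writeXStringSet(ss, fasta)
  if (!is.null(tsv)) {
    readr::write_tsv(unique_reads[, c("sequence", "copy_number")], tsv)
  }
  invisible(c(fasta, tsv))
}
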