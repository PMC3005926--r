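#' Default sequencing adapter used by the read simulator
#'
#' @return A single adapter sequence (3' adapter, DNA alphabet).
#' @export
default_adapter <- function() "CGCCTTGGCCGTACAGCAGAT"

# isomiR genomic interval after applying (shift5, shift3) in sense space.
shift_interval <- function(start, end, strand, shift5, shift3) {
  if (strand == "+") {
    c(start - shift5, end + shift3)
  } else {
    c(start - shift3, end + shift5)
  }
}

#' Simulate a small-RNA read set from a planted truth table
#'
#' Each planted miRNA emits `depth_per_mirna` reads distributed over its two
#' arms according to its arm weights and over isomiR end-variants according
#' to its offset distribution (multinomial). Each read is the isomiR
#' sequence followed by the adapter, truncated to the platform read length.
#' Reads are emitted error-free: downstream mapping is perfect-match, so
#' sequencing errors would only create discarded reads.
#'
#' Additional reads exercise the exclusion filters: reads drawn from each
#' repeat element (multi-locus), reads drawn from each coding decoy
#' (reference-transcript identity), and random noise reads verified absent
#' from the genome.
#'
#' @param genome A [mirna_genome()].
#' @param truth The matching `mirna_truth`.
#' @param depth_per_mirna Reads per planted miRNA.
#' @param noise_reads Number of distinct random noise reads.
#' @param adapter 3' adapter sequence (non-empty).
#' @param read_length Platform read length; mature + adapter is truncated to
#'   this many nucleotides.
#' @param repeat_read_copies,decoy_read_copies Copy number of the read drawn
#'   from each repeat element / decoy interval.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return Tibble with columns `name`, `sequence`, `quality` (one row per
#'   read), ready for [write_fastq()].
#' @export
simulate_reads <- function(genome, truth, depth_per_mirna = 600,
                           noise_reads = 150, adapter = default_adapter(),
                           read_length = 35, repeat_read_copies = 8,
                           decoy_read_copies = 6, seed) {
  stopifnot(nchar(adapter) >= 1, depth_per_mirna >= 1)
  withr::local_seed(seed)
  pad <- strrep(adapter, ceiling(read_length / nchar(adapter)) + 1)
  as_read <- function(core) substr(paste0(core, pad), 1, read_length)

  seqs <- character(0)
  mirnas <- truth$mirnas
  for (i in seq_len(nrow(mirnas))) {
    row <- mirnas[i, ]
    off <- row$offsets[[1]]
    arms <- tibble(arm = c("5p", "3p"), w = c(row$arm_w5, row$arm_w3))
    arms <- arms[arms$w > 0, , drop = FALSE]
    combos <- tidyr::crossing(arms, off)
    combos$p <- combos$w / sum(arms$w) * combos$prob
    counts <- as.integer(stats::rmultinom(1, depth_per_mirna, combos$p))
    for (j in seq_len(nrow(combos))) {
      if (counts[j] == 0) next
      if (combos$arm[j] == "5p") {
        iv <- shift_interval(row$m5_start, row$m5_end, row$strand,
                             combos$shift5[j], combos$shift3[j])
      } else {
        iv <- shift_interval(row$m3_start, row$m3_end, row$strand,
                             combos$shift5[j], combos$shift3[j])
      }
      core <- genome_slice(genome, row$chrom, iv[1], iv[2], row$strand)
      seqs <- c(seqs, rep(as_read(core), counts[j]))
    }
  }

  reps <- truth$repeats
  if (nrow(reps) > 0) {
    for (rid in unique(reps$repeat_id)) {
      unit <- reps$unit[reps$repeat_id == rid][1]
      core <- substr(unit, 11, 32)
      seqs <- c(seqs, rep(as_read(core), repeat_read_copies))
    }
  }
  decs <- truth$decoys
  if (nrow(decs) > 0) {
    for (i in seq_len(nrow(decs))) {
      core <- substr(decs$sequence[i], 21, 42)
      seqs <- c(seqs, rep(as_read(core), decoy_read_copies))
    }
  }

  made <- 0L
  guard <- 0L
  while (made < noise_reads && guard < noise_reads * 20L) {
    guard <- guard + 1L
    core <- random_dna(sample(20:24, 1))
    if (count_occurrences(genome, core) > 0) next
    made <- made + 1L
    seqs <- c(seqs, rep(as_read(core), sample(1:5, 1)))
  }

  seqs <- sample(seqs)
  tibble(
    name = sprintf("read_%06d", seq_along(seqs)),
    sequence = seqs,
    quality = strrep("I", nchar(seqs))
  )
}

#' Write reads to FASTQ
#'
#' @param reads Tibble with `name`, `sequence` and optionally `quality`
#'   columns (dummy "I" qualities are filled in).
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- reads$quality %||% strrep("I", nchar(reads$sequence))
  ss <- Biostrings::DNAStringSet(reads$sequence)
  names(ss) <- reads$name
  Biostrings::writeXStringSet(
    ss, path, format = "fastq",
    qualities = Biostrings::BStringSet(qual)
  )
  invisible(path)
}

#' Read small-RNA reads from FASTQ or FASTA
#'
#' @param path Input path; format detected from the first character.
#' @return Tibble with columns `name` and `sequence` (U converted to T).
#' @export
read_small_rna <- function(path) {
  first <- readLines(path, n = 1)
  fmt <- if (startsWith(first, "@")) "fastq" else "fasta"
  ss <- Biostrings::readDNAStringSet(path, format = fmt)
  tibble(name = names(ss), sequence = normalize_seq(as.character(ss)))
}
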