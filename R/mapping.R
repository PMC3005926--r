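#' Build an exact-match k-mer index over a genome
#'
#' Indexes every plus-strand k-mer position; queries on either strand are
#' answered by looking up the read (or its reverse complement) seeded on its
#' first k-mer and verifying the full-length match.
#'
#' @param genome A [mirna_genome()] or named character vector.
#' @param k Seed length; must not exceed the shortest query (default 18).
#' @return A `mirna_index` object.
#' @export
genome_index <- function(genome, k = 18) {
  if (!inherits(genome, "mirna_genome")) genome <- mirna_genome(genome)
  stopifnot(k >= 1)
  occ <- purrr::map2_dfr(names(genome$seq), genome$seq, function(chrom, s) {
    L <- nchar(s)
    if (L < k) {
      return(tibble(chrom = character(0), pos = integer(0),
                    kmer = character(0)))
    }
    starts <- seq_len(L - k + 1L)
    tibble(chrom = chrom, pos = starts - 1L,
           kmer = substring(s, starts, starts + k - 1L))
  })
  occ <- occ[grepl("^[ACGT]+$", occ$kmer), , drop = FALSE]
  groups <- split(seq_len(nrow(occ)), occ$kmer)
  structure(
    list(genome = genome, k = as.integer(k), occ = occ,
         keys = names(groups), groups = unname(groups)),
    class = "mirna_index"
  )
}

#' @export
print.mirna_index <- function(x, ...) {
  cat("<mirna_index> k=", x$k, ", ", length(x$keys), " distinct k-mers\n",
      sep = "")
  invisible(x)
}

index_lookup <- function(index, kmers) {
  hit <- match(kmers, index$keys)
  lapply(hit, function(h) if (is.na(h)) integer(0) else index$groups[[h]])
}

locus_masked <- function(index, chrom, start, end) {
  mask <- index$genome$mask
  if (nrow(mask) > 0) {
    m <- mask[mask$chrom == chrom, , drop = FALSE]
    if (nrow(m) > 0 && any(start < m$end & end > m$start)) return(TRUE)
  }
  grepl("N", substr(index$genome$seq[[chrom]], start + 1L, end), fixed = TRUE)
}

#' Map unique reads to the genome by perfect match
#'
#' Returns every locus on either strand where the read is completely
#' identical to the genome, with no mismatch or gap. Loci overlapping
#' soft-masked (lowercase) intervals or containing `N` are excluded. A
#' palindromic read matching both strands of one interval yields two loci,
#' as loci are strand-qualified.
#'
#' @param index A `mirna_index` from [genome_index()].
#' @param unique_reads Tibble with `read_id`, `sequence`, `copy_number`
#'   columns (reads must be ACGT only; 18-25 nt under the default seed
#'   length).
#' @return Tibble of loci: `read_id`, `sequence`, `copy_number`, `chrom`,
#'   `start`, `end` (0-based half-open), `strand`.
#' @export
map_reads <- function(index, unique_reads) {
  empty <- tibble(read_id = character(0), sequence = character(0),
                  copy_number = integer(0), chrom = character(0),
                  start = integer(0), end = integer(0), strand = character(0))
  if (nrow(unique_reads) == 0) return(empty)
  bad <- !grepl("^[ACGT]+$", unique_reads$sequence)
  if (any(bad)) {
    abort(paste0("read contains non-ACGT characters: ",
                 unique_reads$sequence[which(bad)[1]]),
          class = "mirstack_read_error")
  }
  if (any(nchar(unique_reads$sequence) < index$k)) {
    abort("read shorter than index seed length k")
  }
  k <- index$k
  genome <- index$genome
  rc <- revcomp(unique_reads$sequence)
  fwd_hits <- index_lookup(index, substr(unique_reads$sequence, 1, k))
  rev_hits <- index_lookup(index, substr(rc, 1, k))
  rows <- vector("list", nrow(unique_reads))
  for (i in seq_len(nrow(unique_reads))) {
    s <- unique_reads$sequence[i]
    len <- nchar(s)
    found <- list()
    for (pass in 1:2) {
      qry <- if (pass == 1) s else rc[i]
      strand <- if (pass == 1) "+" else "-"
      for (h in (if (pass == 1) fwd_hits[[i]] else rev_hits[[i]])) {
        chrom <- index$occ$chrom[h]
        start <- index$occ$pos[h]
        end <- start + len
        if (end > nchar(genome$seq[[chrom]])) next
        if (substr(genome$seq[[chrom]], start + 1L, end) != qry) next
        if (locus_masked(index, chrom, start, end)) next
        found[[length(found) + 1L]] <- tibble(
          read_id = unique_reads$read_id[i], sequence = s,
          copy_number = unique_reads$copy_number[i],
          chrom = chrom, start = start, end = end, strand = strand
        )
      }
    }
    rows[[i]] <- if (length(found)) dplyr::bind_rows(found) else NULL
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(empty)
  dplyr::arrange(out, .data$read_id, .data$chrom, .data$start, .data$strand)
}

#' Drop reads mapping to more than a maximum number of genomic loci
#'
#' Reads mappable to more than `max_loci` loci are discarded entirely
#' (likely unannotated repeats or assembly artifacts); a read with exactly
#' `max_loci` loci survives.
#'
#' @param loci Locus tibble from [map_reads()].
#' @param max_loci Maximum loci kept (default 10).
#' @return The surviving loci.
#' @export
filter_multimappers <- function(loci, max_loci = 10) {
  if (nrow(loci) == 0) return(loci)
  counts <- dplyr::count(loci, .data$read_id, name = "n_loci")
  keep <- counts$read_id[counts$n_loci <= max_loci]
  dplyr::filter(loci, .data$read_id %in% keep)
}

#' Best ungapped identity of reads against a decoy sequence set
#'
#' @param sequences Character vector of read sequences.
#' @param decoys Decoy sequences (character vector, `DNAStringSet`, or FASTA
#'   path).
#' @return Numeric vector: max over decoys and all alignment offsets of
#'   matches / read length (forward strand, partial overlaps allowed).
#' @export
best_decoy_identity <- function(sequences, decoys) {
  decoys <- load_decoys(decoys)
  if (length(decoys) == 0 || length(sequences) == 0) {
    return(rep(0, length(sequences)))
  }
  best_identity_cpp(sequences, decoys)
}

load_decoys <- function(decoys) {
  if (is.null(decoys)) return(character(0))
  if (inherits(decoys, "XStringSet")) return(as.character(decoys))
  if (is.data.frame(decoys)) return(decoys$sequence)
  if (is.character(decoys) && length(decoys) == 1 && file.exists(decoys)) {
    return(as.character(Biostrings::readDNAStringSet(decoys)))
  }
  as.character(decoys)
}

#' Exclude reads resembling reference coding transcripts
#'
#' A read is discarded iff its best ungapped alignment to any decoy
#' sequence exceeds `min_identity` (strictly greater than), with the read
#' length as denominator. With an empty decoy set this is the identity
#' operation.
#'
#' @param x Tibble with a `sequence` column (unique reads or loci).
#' @param decoys Decoy set, see [best_decoy_identity()].
#' @param min_identity Identity threshold (default 0.90).
#' @return The surviving rows.
#' @export
filter_coding_reads <- function(x, decoys, min_identity = 0.90) {
  decoys <- load_decoys(decoys)
  if (length(decoys) == 0 || nrow(x) == 0) return(x)
  seqs <- unique(x$sequence)
  ident <- best_decoy_identity(seqs, decoys)
  drop <- seqs[ident > min_identity]
  dplyr::filter(x, !(.data$sequence %in% drop))
}

#' Write loci as BED6
#'
#' Name is the read id, score the copy number.
#'
#' @param loci Locus tibble from [map_reads()].
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_loci_bed <- function(loci, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = loci$chrom,
    ranges = IRanges::IRanges(start = loci$start + 1L, end = loci$end),
    strand = loci$strand
  )
  gr$name <- loci$read_id
  gr$score <- loci$copy_number
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
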