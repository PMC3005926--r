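#' Write pre-miRNAs as GFF3
#'
#' One `miRNA_primary_transcript` feature per pre-miRNA plus one `miRNA`
#' feature per isomiR, registry style.
#'
#' @param premirnas Pre-miRNA tibble (annotated or not).
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_premirna_gff3 <- function(premirnas, path) {
  if (nrow(premirnas) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  prec <- GenomicRanges::GRanges(
    seqnames = premirnas$chrom,
    ranges = IRanges::IRanges(start = premirnas$start + 1L,
                              end = premirnas$end),
    strand = premirnas$strand,
    type = "miRNA_primary_transcript",
    ID = premirnas$mirna_id %||% premirnas$premirna_id
  )
  iso <- purrr::map_dfr(seq_len(nrow(premirnas)), function(i) {
    it <- premirnas$isomirs[[i]]
    if (nrow(it) == 0) return(NULL)
    tibble(chrom = premirnas$chrom[i], start = it$start, end = it$end,
           strand = premirnas$strand[i],
           id = sprintf("%s_iso%d",
                        (premirnas$mirna_id %||% premirnas$premirna_id)[i],
                        seq_len(nrow(it))),
           parent = (premirnas$mirna_id %||% premirnas$premirna_id)[i])
  })
  mat <- GenomicRanges::GRanges(
    seqnames = iso$chrom,
    ranges = IRanges::IRanges(start = iso$start + 1L, end = iso$end),
    strand = iso$strand, type = "miRNA", ID = iso$id, Parent = iso$parent
  )
  rtracklayer::export(c(prec, mat), path, format = "gff3")
  invisible(path)
}

#' Flat per-isomiR table of a pre-miRNA set
#'
#' Mirrors the per-candidate supplementary-table schema: one row per isomiR
#' with its copy number, p-value, arm, and the parent's set/ortholog/family
#' annotation when present.
#'
#' @param premirnas Pre-miRNA tibble.
#' @return A flat tibble.
#' @export
isomir_table <- function(premirnas) {
  if (nrow(premirnas) == 0) return(tibble())
  purrr::map_dfr(seq_len(nrow(premirnas)), function(i) {
    it <- premirnas$isomirs[[i]]
    base <- dplyr::select(premirnas[i, ], -dplyr::any_of(c(
      "isomirs", "n_isomirs"
    )))
    dplyr::bind_cols(base[rep(1, nrow(it)), ],
                     dplyr::rename_with(it, function(x) paste0("isomir_", x)))
  })
}

write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_collapsed_fasta(result$unique_reads,
                        file.path(outdir, "collapsed.fasta"),
                        file.path(outdir, "collapsed.tsv"))
  if (nrow(result$loci) > 0) {
    write_loci_bed(result$loci, file.path(outdir, "loci.bed"))
  }
  write_premirna_gff3(result$premirnas, file.path(outdir, "premirnas.gff3"))
  readr::write_tsv(isomir_table(result$premirnas),
                   file.path(outdir, "isomirs.tsv"))
  cl <- result$clusters
  if (nrow(cl) > 0) cl$members <- vapply(cl$members, paste, character(1),
                                         collapse = ",")
  readr::write_tsv(cl, file.path(outdir, "clusters.tsv"))
  readr::write_tsv(result$families, file.path(outdir, "families.tsv"))
  readr::write_tsv(result$log, file.path(outdir, "stage_log.tsv"))
  jsonlite::write_json(
    c(as.list(result$summary), as.list(result$percentages)),
    file.path(outdir, "summary.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(outdir)
}
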