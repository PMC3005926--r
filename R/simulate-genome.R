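#' Species codes used by the simulated known-miRNA catalog
#'
#' Three-letter prefixes in the style of the public miRNA registry.
#'
#' @return Character vector of species codes.
#' @export
mirbase_species_codes <- function() {
  c("dre", "tni", "fru", "gga", "hsa", "mmu", "ssc", "bta", "cfa", "eca",
    "ptr", "mml", "oan", "xtr", "tgu")
}

# Default isomiR end-variation distribution: most length variation at the
# 3' end, a small amount at the 5' end. shift5/shift3 are nucleotides added
# (positive) or removed (negative) at the mature 5'/3' ends in sense space.
default_isomir_offsets <- function() {
  tibble(shift5 = c(0L, 0L, 0L, 0L, 0L, -1L),
         shift3 = c(0L, -1L, 1L, -2L, 2L, 0L),
         prob = c(0.55, 0.15, 0.12, 0.08, 0.06, 0.04))
}

# Arm weight patterns cycled over planted miRNAs so all five arm-selection
# categories (5P only, 3P only, 5P dominant, 3P dominant, equal) occur.
default_arm_patterns <- function() {
  list(c(1, 0), c(0, 1), c(5, 1), c(1, 5), c(1, 1))
}

# Build one hairpin: a random 5' arm carrying the mature near the loop, a
# loop of 8-15 nt, and a 3' arm that is the reverse complement of the 5' arm
# with ~10% point mutations (bulges). At least one mutation is forced inside
# the mirrored mature window so the 5p mature cannot also match the 3p arm
# on the opposite strand. The stem must hold >= min_stem pairs when folded.
make_hairpin <- function(mature_len = 22L, mut_rate = 0.1, min_stem = 18L,
                         max_tries = 25L) {
  bases <- c("A", "C", "G", "T")
  for (try in seq_len(max_tries)) {
    arm_len <- sample(58:66, 1)
    loop_len <- sample(8:15, 1)
    gap <- sample(0:4, 1)
    arm5 <- sample(bases, arm_len, replace = TRUE)
    loop <- sample(bases, loop_len, replace = TRUE)
    arm3 <- strsplit(revcomp(paste(arm5, collapse = "")), "")[[1]]
    k <- stats::rbinom(1, arm_len, mut_rate)
    mut_pos <- if (k > 0) sample.int(arm_len, k) else integer(0)
    # Force >= 1 mutation into the central mirrored mature window (shared by
    # every isomiR end-variant up to +/-2 nt) so no mature or isomiR can
    # also match the opposite arm on the reverse strand.
    mir_lo <- gap + 4L
    mir_hi <- gap + mature_len - 3L
    if (!any(mut_pos >= mir_lo & mut_pos <= mir_hi)) {
      mut_pos <- c(mut_pos, sample(mir_lo:mir_hi, 1))
    }
    for (p in mut_pos) {
      arm3[p] <- sample(setdiff(bases, arm3[p]), 1)
    }
    seq <- paste(c(arm5, loop, arm3), collapse = "")
    n <- nchar(seq)
    # 0-based half-open intervals within the precursor
    m5 <- c(arm_len - mature_len - gap, arm_len - gap)
    m3 <- c(arm_len + loop_len + gap, arm_len + loop_len + gap + mature_len)
    fit <- fold_rna(seq)
    loop_iv <- locate_loop(fit$structure)
    if (is.na(loop_iv[1])) next
    if (loop_iv[3] < min_stem) next
    # the detected loop must sit between the two matures
    if (loop_iv[1] < m5[2] || loop_iv[2] > m3[1]) next
    return(list(seq = seq, length = n, m5 = m5, m3 = m3,
                loop = loop_iv[1:2]))
  }
  abort("hairpin construction failed: no foldable stem after retries",
        class = "mirstack_placement_error")
}

place_nonoverlapping <- function(occupied, chroms, lens, width, margin = 200L,
                                 what = "element", max_tries = 1000L) {
  for (try in seq_len(max_tries)) {
    chrom <- if (length(chroms) == 1) chroms else sample(chroms, 1)
    hi <- lens[[chrom]] - width - margin
    if (hi <= margin) next
    start <- sample(margin:hi, 1)
    end <- start + width
    occ <- occupied[occupied$chrom == chrom, , drop = FALSE]
    if (nrow(occ) == 0 ||
        all(start >= occ$end + margin | end <= occ$start - margin)) {
      return(list(chrom = chrom, start = start, end = end))
    }
  }
  abort(paste0("placement failure for ", what,
               " after bounded retries; increase chrom_len"),
        class = "mirstack_placement_error")
}

#' Simulate a genome with planted miRNA hairpins, repeats, and coding decoys
#'
#' Generates random chromosomes and plants (i) miRNA hairpin precursors on
#' both strands, singly and in genomic clusters, (ii) a repeat element copied
#' to many loci so that multi-locus reads arise, and (iii) coding-gene decoy
#' intervals (>= 200 nt) whose sequences act as a reference-transcript decoy
#' set. Every planted feature is recorded in a truth table.
#'
#' Non-clustered miRNAs are separated by more than the 10 kb cluster window;
#' clustered miRNAs are pairwise chainable within it. Repeat copies are
#' identical, so a k-mer drawn from the unit maps to every copy.
#'
#' @param n_chrom,chrom_len Number and length (bp) of chromosomes.
#' @param n_mirna Total planted miRNAs (clustered members included).
#' @param n_clusters,cluster_size Number of clusters and members per cluster.
#' @param n_repeats Number of distinct repeat elements.
#' @param repeat_copies Copies planted per repeat element (>= 12 by default
#'   so the more-than-ten-loci filter fires).
#' @param n_decoys Number of coding decoy intervals.
#' @param frac_conserved Fraction of planted miRNA families present in the
#'   simulated known-miRNA catalog (the rest are novel).
#' @param species_codes Species codes available to the catalog.
#' @param mask_repeats If `TRUE`, repeat intervals are soft-masked
#'   (lowercase in FASTA output and excluded from mapping).
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A list with elements `genome` (a [mirna_genome()]) and `truth`
#'   (class `mirna_truth`: tibbles `mirnas`, `repeats`, `decoys`, plus the
#'   seed).
#' @export
#' @examples
#' sim <- simulate_genome(n_chrom = 1, chrom_len = 50000, n_mirna = 3,
#'                        n_clusters = 0, n_repeats = 0, n_decoys = 0,
#'                        seed = 7)
#' sim$truth$mirnas
simulate_genome <- function(n_chrom = 2, chrom_len = 150000, n_mirna = 24,
                            n_clusters = 2, cluster_size = 3, n_repeats = 1,
                            repeat_copies = 15, n_decoys = 2,
                            frac_conserved = 2 / 3,
                            species_codes = mirbase_species_codes(),
                            mask_repeats = FALSE, seed) {
  stopifnot(n_chrom >= 1, chrom_len >= 1000)
  n_clustered <- n_clusters * cluster_size
  if (n_clustered > n_mirna) {
    abort("n_clusters * cluster_size exceeds n_mirna")
  }
  withr::local_seed(seed)
  chroms <- sprintf("chr%d", seq_len(n_chrom))
  lens <- setNames(rep(chrom_len, n_chrom), chroms)

  # ---- miRNA groups: clusters first, then singletons, round-robin ----
  n_single <- n_mirna - n_clustered
  groups <- c(
    lapply(seq_len(n_clusters), function(i) list(type = "cluster", size = cluster_size)),
    lapply(seq_len(n_single), function(i) list(type = "single", size = 1L))
  )
  group_chrom <- rep(chroms, length.out = length(groups))

  occupied <- tibble(chrom = character(0), start = integer(0), end = integer(0))
  mirna_rows <- list()
  patterns <- default_arm_patterns()
  plant_i <- 0L
  cluster_i <- 0L
  for (ci in seq_along(chroms)) {
    chrom <- chroms[ci]
    my_groups <- groups[group_chrom == chrom]
    if (length(my_groups) == 0) next
    cursor <- sample(500:1500, 1)
    for (g in my_groups) {
      gid <- if (g$type == "cluster") {
        cluster_i <- cluster_i + 1L
        sprintf("cluster_%d", cluster_i)
      } else {
        NA_character_
      }
      for (m in seq_len(g$size)) {
        plant_i <- plant_i + 1L
        hp <- make_hairpin()
        strand <- sample(c("+", "-"), 1)
        ps <- cursor
        pe <- ps + hp$length
        if (pe > chrom_len - 500) {
          abort(paste0("placement failure for miRNA element: chromosome ",
                       chrom, " too short for requested layout"),
                class = "mirstack_placement_error")
        }
        to_genomic <- function(iv) {
          if (strand == "+") c(ps + iv[1], ps + iv[2]) else c(pe - iv[2], pe - iv[1])
        }
        m5g <- to_genomic(hp$m5)
        m3g <- to_genomic(hp$m3)
        w <- patterns[[(plant_i - 1L) %% length(patterns) + 1L]]
        mirna_rows[[plant_i]] <- tibble(
          mirna_id = sprintf("plant_%02d", plant_i),
          family = as.character(100L + plant_i),
          chrom = chrom, strand = strand,
          prec_start = ps, prec_end = pe,
          m5_start = m5g[1], m5_end = m5g[2],
          m3_start = m3g[1], m3_end = m3g[2],
          arm_w5 = w[1], arm_w3 = w[2],
          cluster_id = gid,
          hairpin_seq = hp$seq
        )
        occupied <- dplyr::bind_rows(occupied,
                                     tibble(chrom = chrom, start = ps, end = pe))
        cursor <- pe + if (g$type == "cluster" && m < g$size) {
          sample(800:1800, 1)
        } else {
          0L
        }
      }
      cursor <- cursor + sample(11000:13000, 1)
    }
  }
  mirnas <- dplyr::bind_rows(mirna_rows)

  if (nrow(mirnas) > 0) {
    # conservation metadata: a deterministic 2/3-ish of plants are conserved
    conserved <- seq_len(n_mirna) %% round(1 / max(1 - frac_conserved, 1e-9)) != 0
    if (frac_conserved >= 1) conserved <- rep(TRUE, n_mirna)
    if (frac_conserved <= 0) conserved <- rep(FALSE, n_mirna)
    ns_cycle <- c(2L, 3L, 5L, 7L, 9L, 12L)
    ns_cycle <- pmin(ns_cycle, length(species_codes))
    mirnas$n_species <- ifelse(conserved,
                               ns_cycle[(seq_len(n_mirna) - 1L) %% length(ns_cycle) + 1L],
                               0L)
    mirnas$cat_arm_5p <- dplyr::case_when(
      mirnas$arm_w5 > 0 & mirnas$arm_w3 == 0 ~ "major",
      mirnas$arm_w5 == 0 ~ "absent",
      mirnas$arm_w5 / pmax(mirnas$arm_w3, 1e-9) >= 2 ~ "major",
      mirnas$arm_w3 / pmax(mirnas$arm_w5, 1e-9) >= 2 ~ "minor",
      TRUE ~ "major"
    )
    mirnas$cat_arm_3p <- dplyr::case_when(
      mirnas$arm_w3 > 0 & mirnas$arm_w5 == 0 ~ "major",
      mirnas$arm_w3 == 0 ~ "absent",
      mirnas$arm_w3 / pmax(mirnas$arm_w5, 1e-9) >= 2 ~ "major",
      mirnas$arm_w5 / pmax(mirnas$arm_w3, 1e-9) >= 2 ~ "minor",
      TRUE ~ "major"
    )
    mirnas$offsets <- rep(list(default_isomir_offsets()), n_mirna)
  }

  # ---- repeats ----
  repeat_rows <- list()
  repeat_units <- character(0)
  for (r in seq_len(n_repeats)) {
    unit <- random_dna(80L)
    repeat_units <- c(repeat_units, unit)
    for (cp in seq_len(repeat_copies)) {
      spot <- place_nonoverlapping(occupied, chroms, lens, 80L,
                                   what = "repeat element")
      repeat_rows[[length(repeat_rows) + 1L]] <- tibble(
        repeat_id = sprintf("rep_%d", r), copy_index = cp,
        chrom = spot$chrom, start = spot$start, end = spot$end
      )
      occupied <- dplyr::bind_rows(occupied,
                                   tibble(chrom = spot$chrom,
                                          start = spot$start, end = spot$end))
    }
  }
  repeats <- if (length(repeat_rows)) dplyr::bind_rows(repeat_rows) else
    tibble(repeat_id = character(0), copy_index = integer(0),
           chrom = character(0), start = integer(0), end = integer(0))
  repeats$unit <- if (nrow(repeats)) repeat_units[as.integer(sub("rep_", "", repeats$repeat_id))] else character(0)

  # ---- coding decoys (>= 200 nt) ----
  decoy_rows <- list()
  for (d in seq_len(n_decoys)) {
    w <- sample(240:400, 1)
    spot <- place_nonoverlapping(occupied, chroms, lens, w,
                                 what = "decoy element")
    decoy_rows[[d]] <- tibble(decoy_id = sprintf("decoy_%d", d),
                              chrom = spot$chrom, start = spot$start,
                              end = spot$end)
    occupied <- dplyr::bind_rows(occupied,
                                 tibble(chrom = spot$chrom,
                                        start = spot$start, end = spot$end))
  }
  decoys <- if (length(decoy_rows)) dplyr::bind_rows(decoy_rows) else
    tibble(decoy_id = character(0), chrom = character(0),
           start = integer(0), end = integer(0))

  # ---- assemble chromosome sequences ----
  seqs <- setNames(vapply(chroms, function(ch) random_dna(chrom_len),
                          character(1)), chroms)
  poke <- function(seqs, chrom, start, piece) {
    s <- seqs[[chrom]]
    substr(s, start + 1L, start + nchar(piece)) <- piece
    seqs[[chrom]] <- s
    seqs
  }
  for (i in seq_len(nrow(mirnas))) {
    row <- mirnas[i, ]
    piece <- if (row$strand == "+") row$hairpin_seq else revcomp(row$hairpin_seq)
    seqs <- poke(seqs, row$chrom, row$prec_start, piece)
  }
  for (i in seq_len(nrow(repeats))) {
    seqs <- poke(seqs, repeats$chrom[i], repeats$start[i], repeats$unit[i])
  }
  decoys$sequence <- vapply(seq_len(nrow(decoys)), function(i) {
    substr(seqs[[decoys$chrom[i]]], decoys$start[i] + 1L, decoys$end[i])
  }, character(1))

  mask <- if (mask_repeats && nrow(repeats) > 0) {
    dplyr::select(repeats, "chrom", "start", "end")
  } else {
    NULL
  }
  genome <- mirna_genome(seqs, mask)

  # every planted mature must occur exactly once genome-wide (both strands)
  if (nrow(mirnas) > 0) {
    for (i in seq_len(nrow(mirnas))) {
      row <- mirnas[i, ]
      for (arm in c("5", "3")) {
        iv <- c(row[[paste0("m", arm, "_start")]], row[[paste0("m", arm, "_end")]])
        mat <- genome_slice(genome, row$chrom, iv[1], iv[2], row$strand)
        if (count_occurrences(genome, mat) != 1L) {
          abort(paste0("placement failure for miRNA element: planted mature of ",
                       row$mirna_id, " is not unique in the genome"),
                class = "mirstack_placement_error")
        }
      }
    }
  }

  truth <- structure(
    list(mirnas = mirnas, repeats = repeats, decoys = decoys,
         seed = as.integer(seed)),
    class = "mirna_truth"
  )
  list(genome = genome, truth = truth)
}

# Count perfect occurrences of a pattern on both strands of a genome.
count_occurrences <- function(genome, pattern) {
  pat <- Biostrings::DNAString(pattern)
  rc <- Biostrings::reverseComplement(pat)
  sum(vapply(genome$seq, function(s) {
    subj <- Biostrings::DNAString(s)
    Biostrings::countPattern(pat, subj) + Biostrings::countPattern(rc, subj)
  }, numeric(1)))
}

#' @export
print.mirna_truth <- function(x, ...) {
  cat("<mirna_truth> ", nrow(x$mirnas), " planted miRNA(s), ",
      nrow(x$repeats), " repeat copy(ies), ", nrow(x$decoys),
      " decoy(s), seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Write / read a truth table
#'
#' The truth table is persisted as plain TSV files (one per element type)
#' with the isomiR offset distribution serialized as JSON, plus a JSON
#' sidecar holding the seed. The round trip is lossless.
#'
#' @param truth A `mirna_truth` object.
#' @param dir Directory to write into (created if needed).
#' @return `dir` (write) or the reloaded `mirna_truth` (read).
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- truth$mirnas
  offsets <- m$offsets
  m$offsets <- NULL
  readr::write_tsv(m, file.path(dir, "mirnas.tsv"))
  readr::write_tsv(truth$repeats, file.path(dir, "repeats.tsv"))
  readr::write_tsv(truth$decoys, file.path(dir, "decoys.tsv"))
  jsonlite::write_json(
    list(seed = truth$seed,
         offsets = setNames(offsets, m$mirna_id)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname write_truth
#' @export
read_truth <- function(dir) {
  m <- readr::read_tsv(
    file.path(dir, "mirnas.tsv"), show_col_types = FALSE,
    col_types = readr::cols(
      mirna_id = "c", family = "c", chrom = "c", strand = "c",
      prec_start = "i", prec_end = "i", m5_start = "i", m5_end = "i",
      m3_start = "i", m3_end = "i", arm_w5 = "d", arm_w3 = "d",
      cluster_id = "c", hairpin_seq = "c", n_species = "i",
      cat_arm_5p = "c", cat_arm_3p = "c"
    )
  )
  side <- jsonlite::read_json(file.path(dir, "truth.json"),
                              simplifyVector = TRUE)
  m$offsets <- if (nrow(m) > 0) {
    unname(lapply(side$offsets[m$mirna_id], as_tibble))
  } else {
    list()
  }
  structure(
    list(mirnas = as_tibble(m),
         repeats = readr::read_tsv(
           file.path(dir, "repeats.tsv"), show_col_types = FALSE,
           col_types = readr::cols(repeat_id = "c", copy_index = "i",
                                   chrom = "c", start = "i", end = "i",
                                   unit = "c")),
         decoys = readr::read_tsv(
           file.path(dir, "decoys.tsv"), show_col_types = FALSE,
           col_types = readr::cols(decoy_id = "c", chrom = "c", start = "i",
                                   end = "i", sequence = "c")),
         seed = as.integer(side$seed)),
    class = "mirna_truth"
  )
}
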