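#' Simulate a known-miRNA catalog from a truth table
#'
#' For every planted family with `n_species >= 1`, catalog entries are
#' created for that many species. Mature entries carry up to `mutate_max`
#' substitutions relative to the planted mature (so homolog matching at two
#' variations must succeed), and each precursor gets an arm annotation
#' (`major` / `minor` / `absent` per arm) taken from the truth table, which
#' makes the cross-species arm-difference classes constructible.
#'
#' Naming follows the registry dialect: matures `"<sp>-miR-<family>"` with a
#' `"*"` suffix for the minor arm, or `-5p`/`-3p` suffixes when both arms
#' are major; precursors `"<sp>-mir-<family>"`.
#'
#' @param truth A `mirna_truth` from [simulate_genome()].
#' @param genome The matching [mirna_genome()] (mature sequences are read
#'   from it).
#' @param species_codes Species codes to draw from; each family's
#'   `n_species` must not exceed their number.
#' @param mutate_max Maximum substitutions between catalog and planted
#'   mature (default 2).
#' @param seed Integer seed.
#' @return A `mirna_catalog`: list with tibbles `mature` (id, species,
#'   family, sequence) and `arms` (precursor_id, species, family,
#'   arm_5p_status, arm_3p_status).
#' @export
simulate_catalog <- function(truth, genome,
                             species_codes = mirbase_species_codes(),
                             mutate_max = 2, seed) {
  mirnas <- truth$mirnas
  if (nrow(mirnas) > 0 && max(mirnas$n_species) > length(species_codes)) {
    abort("a planted family needs more species than species_codes provides")
  }
  withr::local_seed(seed)
  bases <- c("A", "C", "G", "T")
  mutate_seq <- function(s, k) {
    if (k == 0) return(s)
    ch <- strsplit(s, "")[[1]]
    for (p in sample.int(length(ch), k)) {
      ch[p] <- sample(setdiff(bases, ch[p]), 1)
    }
    paste(ch, collapse = "")
  }
  mature_rows <- list()
  arm_rows <- list()
  for (i in seq_len(nrow(mirnas))) {
    row <- mirnas[i, ]
    if (row$n_species == 0) next
    sp <- sample(species_codes, row$n_species)
    m5 <- genome_slice(genome, row$chrom, row$m5_start, row$m5_end, row$strand)
    m3 <- genome_slice(genome, row$chrom, row$m3_start, row$m3_end, row$strand)
    for (s in sp) {
      arm_rows[[length(arm_rows) + 1L]] <- tibble(
        precursor_id = sprintf("%s-mir-%s", s, row$family),
        species = s, family = row$family,
        arm_5p_status = row$cat_arm_5p, arm_3p_status = row$cat_arm_3p
      )
      both_major <- row$cat_arm_5p == "major" && row$cat_arm_3p == "major"
      for (arm in c("5p", "3p")) {
        status <- if (arm == "5p") row$cat_arm_5p else row$cat_arm_3p
        if (status == "absent") next
        id <- if (both_major) {
          sprintf("%s-miR-%s-%s", s, row$family, arm)
        } else if (status == "minor") {
          sprintf("%s-miR-%s*", s, row$family)
        } else {
          sprintf("%s-miR-%s", s, row$family)
        }
        planted <- if (arm == "5p") m5 else m3
        mature_rows[[length(mature_rows) + 1L]] <- tibble(
          id = id, species = s, family = row$family,
          sequence = mutate_seq(planted, sample(0:mutate_max, 1))
        )
      }
    }
  }
  mature <- if (length(mature_rows)) dplyr::bind_rows(mature_rows) else
    tibble(id = character(0), species = character(0), family = character(0),
           sequence = character(0))
  arms <- if (length(arm_rows)) dplyr::bind_rows(arm_rows) else
    tibble(precursor_id = character(0), species = character(0),
           family = character(0), arm_5p_status = character(0),
           arm_3p_status = character(0))
  structure(list(mature = mature, arms = arms), class = "mirna_catalog")
}

#' @export
print.mirna_catalog <- function(x, ...) {
  cat("<mirna_catalog> ", nrow(x$mature), " mature entr(ies) across ",
      dplyr::n_distinct(x$mature$species), " species\n", sep = "")
  invisible(x)
}

#' Write / read a known-miRNA catalog
#'
#' The mature catalog is a FASTA with registry-dialect headers
#' (`>ssc-miR-140`); the precursor arm annotation is a TSV with columns
#' `precursor_id`, `arm_5p_status`, `arm_3p_status`.
#'
#' @param catalog A `mirna_catalog`.
#' @param fasta,arms_tsv Output paths (`arms_tsv = NULL` skips the table).
#' @return Paths, invisibly (write); a `mirna_catalog` (read).
#' @export
write_catalog <- function(catalog, fasta, arms_tsv = NULL) {
  ss <- Biostrings::DNAStringSet(catalog$mature$sequence)
  names(ss) <- catalog$mature$id
  Biostrings::writeXStringSet(ss, fasta)
  if (!is.null(arms_tsv)) {
    readr::write_tsv(catalog$arms, arms_tsv)
  }
  invisible(c(fasta, arms_tsv))
}

#' @rdname write_catalog
#' @export
read_catalog <- function(fasta, arms_tsv = NULL) {
  ss <- Biostrings::readDNAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(ss))
  mature <- tibble(
    id = ids,
    species = sub("^([A-Za-z]{3,4})-.*$", "\\1", ids),
    family = mirna_family(ids),
    sequence = normalize_seq(as.character(ss))
  )
  arms <- if (!is.null(arms_tsv)) {
    readr::read_tsv(arms_tsv, show_col_types = FALSE)
  } else {
    tibble(precursor_id = character(0), species = character(0),
           family = character(0), arm_5p_status = character(0),
           arm_3p_status = character(0))
  }
  structure(list(mature = mature, arms = as_tibble(arms)),
            class = "mirna_catalog")
}
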