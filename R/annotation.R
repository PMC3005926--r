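#' Family name of registry-dialect miRNA identifiers
#'
#' Strips the species prefix, normalizes capitalization, removes arm markers
#' (`-5p`, `-3p`, trailing `*`) and trailing numeric locus suffixes
#' (`-1`, `-2`), while keeping lettered paralog suffixes (`let-7b` stays
#' distinct from `let-7a`).
#'
#' @param ids Character vector of identifiers such as `"gga-mir-33-2"`.
#' @return Character vector of family names such as `"mir-33"`.
#' @export
#' @examples
#' mirna_family(c("gga-mir-33-2", "cfa-let-7b", "hsa-miR-205*"))
mirna_family <- function(ids) {
  x <- sub("^[A-Za-z]{3,4}-", "", ids)
  x <- sub("^miR-", "mir-", x)
  x <- sub("^Mir-", "mir-", x)
  x <- sub("\\*$", "", x)
  x <- sub("-[35]p$", "", x)
  # strip a trailing numeric locus suffix only when a numeric family core
  # remains (mir-33-2 -> mir-33, but mir-205 stays mir-205)
  x <- ifelse(grepl("^(mir|let)-[0-9]+[a-z]*-[0-9]+$", x),
              sub("-[0-9]+$", "", x), x)
  x
}

mirna_species <- function(ids) {
  sub("^([A-Za-z]{3,4})-.*$", "\\1", ids)
}

#' Match sequences against a known-miRNA catalog
#'
#' Finds, for each query, the catalog mature with minimum edit distance
#' (substitutions and indels), reported only when that distance is at most
#' `max_variations`. Ties are broken by lower distance, then lexicographic
#' catalog id. Variation is measured as edit distance because isomiRs vary
#' in length.
#'
#' @param sequences Character vector of mature/isomiR sequences (U or T).
#' @param catalog A `mirna_catalog` (or its `mature` tibble).
#' @param max_variations Maximum nucleotide variations (default 2).
#' @return Tibble with `sequence`, `catalog_id`, `distance` (`NA` when no
#'   hit within the threshold).
#' @export
match_known <- function(sequences, catalog, max_variations = 2) {
  mat <- if (inherits(catalog, "mirna_catalog")) catalog$mature else catalog
  out <- tibble(sequence = sequences, catalog_id = NA_character_,
                distance = NA_integer_)
  if (length(sequences) == 0 || nrow(mat) == 0) return(out)
  ord <- order(mat$id)
  ids <- mat$id[ord]
  d <- adist(normalize_seq(sequences), normalize_seq(mat$sequence[ord]))
  for (i in seq_along(sequences)) {
    j <- which.min(d[i, ])  # first minimum = lexicographically smallest id
    if (d[i, j] <= max_variations) {
      out$catalog_id[i] <- ids[j]
      out$distance[i] <- as.integer(d[i, j])
    }
  }
  out
}

#' Conservation level of miRNA families
#'
#' The conservation level of a family is the number of distinct species
#' whose catalog contains at least one entry of that family.
#'
#' @param families Character vector of family names (from [mirna_family()]).
#' @param catalog A `mirna_catalog`.
#' @return Integer vector of species counts (0 for absent families).
#' @export
conservation_level <- function(families, catalog) {
  mat <- if (inherits(catalog, "mirna_catalog")) catalog$mature else catalog
  if (nrow(mat) == 0) return(rep(0L, length(families)))
  per <- dplyr::summarise(
    dplyr::group_by(tibble(family = mirna_family(mat$id),
                           species = mirna_species(mat$id)),
                    .data$family),
    n_species = dplyr::n_distinct(.data$species), .groups = "drop"
  )
  lvl <- setNames(per$n_species, per$family)
  out <- unname(lvl[families])
  out[is.na(out)] <- 0L
  as.integer(out)
}

#' Split pre-miRNAs into homolog (Mh) and novel (Mn) sets
#'
#' A pre-miRNA belongs to the homolog set iff any of its isomiRs matches a
#' catalog mature within `max_variations` nucleotide variations; otherwise
#' it is novel. Homologs get their best ortholog id, its precursor id,
#' family, and the family's conservation level. Set-prefixed ids (`Mh1`,
#' `Mn1`, ...) are assigned in coordinate order within each set.
#'
#' @param premirnas Pre-miRNA tibble from [assemble_premirnas()].
#' @param catalog A `mirna_catalog`.
#' @param max_variations Maximum nucleotide variations (default 2).
#' @return `premirnas` with added `set`, `mirna_id`, `ortholog_id`,
#'   `ortholog_precursor`, `family`, `conservation_level`.
#' @export
annotate_premirnas <- function(premirnas, catalog, max_variations = 2) {
  n <- nrow(premirnas)
  if (n == 0) {
    return(dplyr::mutate(premirnas, set = character(0),
                         mirna_id = character(0), ortholog_id = character(0),
                         ortholog_precursor = character(0),
                         family = character(0),
                         conservation_level = integer(0)))
  }
  best <- purrr::map_dfr(premirnas$isomirs, function(iso) {
    hits <- match_known(iso$sequence, catalog, max_variations)
    hits <- dplyr::filter(hits, !is.na(.data$catalog_id))
    if (nrow(hits) == 0) {
      return(tibble(ortholog_id = NA_character_, distance = NA_integer_))
    }
    hits <- dplyr::arrange(hits, .data$distance, .data$catalog_id)
    tibble(ortholog_id = hits$catalog_id[1], distance = hits$distance[1])
  })
  out <- premirnas
  out$ortholog_id <- best$ortholog_id
  out$set <- ifelse(is.na(out$ortholog_id), "Mn", "Mh")
  out$family <- ifelse(is.na(out$ortholog_id), NA_character_,
                       mirna_family(out$ortholog_id))
  out$ortholog_precursor <- ifelse(
    is.na(out$ortholog_id), NA_character_,
    paste0(mirna_species(out$ortholog_id), "-", out$family)
  )
  out$conservation_level <- ifelse(
    is.na(out$family), NA_integer_,
    conservation_level(out$family, catalog)
  )
  out <- dplyr::arrange(out, .data$chrom, .data$start, .data$strand)
  out$mirna_id <- NA_character_
  for (s in c("Mh", "Mn")) {
    idx <- which(out$set == s)
    out$mirna_id[idx] <- paste0(s, seq_along(idx))
  }
  out
}

#' Per-family conservation and expression records of the homolog set
#'
#' The expression level of a family is the copy number of its most abundant
#' isomiR in this dataset; the conservation level is the number of catalog
#' species encoding the family.
#'
#' @param annotated Annotated pre-miRNA tibble from [annotate_premirnas()].
#' @return Tibble with `family`, `conservation_level`, `expression_level`,
#'   `n_premirna` (homolog set only).
#' @export
family_records <- function(annotated) {
  mh <- dplyr::filter(annotated, .data$set == "Mh")
  if (nrow(mh) == 0) {
    return(tibble(family = character(0), conservation_level = integer(0),
                  expression_level = integer(0), n_premirna = integer(0)))
  }
  mh$max_copy <- vapply(mh$isomirs, function(iso) max(iso$copy_number),
                        integer(1))
  dplyr::summarise(
    dplyr::group_by(mh, .data$family),
    conservation_level = max(.data$conservation_level),
    expression_level = max(.data$max_copy),
    n_premirna = dplyr::n(), .groups = "drop"
  )
}
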