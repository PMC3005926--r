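#' Detect genomic miRNA clusters
#'
#' Single-linkage chaining per chromosome, strand-agnostic: pre-miRNAs are
#' sorted by start and joined while the gap between the next start and the
#' running maximum end is at most `window` (the registry's 10,000 bp
#' inter-miRNA convention, inclusive). Clusters of size one are discarded.
#'
#' @param premirnas Pre-miRNA tibble with `premirna_id`, `chrom`, `start`,
#'   `end` (any strand mix).
#' @param window Maximum gap in bp (default 10000).
#' @return Tibble of clusters: `cluster_id`, `chrom`, `start`, `end`,
#'   `n_members`, list-column `members` (premirna ids in coordinate order).
#' @export
detect_clusters <- function(premirnas, window = 10000) {
  empty <- tibble(cluster_id = character(0), chrom = character(0),
                  start = integer(0), end = integer(0),
                  n_members = integer(0), members = list())
  if (nrow(premirnas) == 0) return(empty)
  out <- purrr::map_dfr(split(premirnas, premirnas$chrom), function(g) {
    g <- dplyr::arrange(g, .data$start, .data$end)
    comp <- integer(nrow(g))
    comp[1] <- 1L
    max_end <- g$end[1]
    for (i in seq_len(nrow(g))[-1]) {
      comp[i] <- if (g$start[i] - max_end <= window) comp[i - 1] else
        comp[i - 1] + 1L
      max_end <- max(max_end, g$end[i])
    }
    purrr::map_dfr(split(seq_len(nrow(g)), comp), function(idx) {
      if (length(idx) < 2) return(NULL)
      tibble(chrom = g$chrom[1], start = min(g$start[idx]),
             end = max(g$end[idx]), n_members = length(idx),
             members = list(g$premirna_id[idx]))
    })
  })
  if (nrow(out) == 0) return(empty)
  out <- dplyr::arrange(out, .data$chrom, .data$start)
  out$cluster_id <- sprintf("cluster_%d", seq_len(nrow(out)))
  dplyr::relocate(out, "cluster_id")
}

#' Arm-selection profile of pre-miRNAs
#'
#' Sums isomiR copy numbers per arm (loop-spanning isomiRs excluded) and
#' assigns one of five categories: `5P_only` / `3P_only` when one arm has no
#' reads, `5P_dominant` / `3P_dominant` when the copy ratio between arms
#' reaches `dominance_ratio`, and `equal` otherwise.
#'
#' @param premirnas Pre-miRNA tibble with the `isomirs` list-column.
#' @param dominance_ratio Ratio of arm totals at or above which the larger
#'   arm is called dominant (default 2).
#' @return `premirnas` with added `copies_5p`, `copies_3p`, `arm_category`.
#' @export
arm_profile <- function(premirnas, dominance_ratio = 2.0) {
  if (nrow(premirnas) == 0) {
    return(dplyr::mutate(premirnas, copies_5p = integer(0),
                         copies_3p = integer(0), arm_category = character(0)))
  }
  premirnas$copies_5p <- vapply(premirnas$isomirs, function(iso) {
    sum(iso$copy_number[iso$arm == "5p"])
  }, integer(1))
  premirnas$copies_3p <- vapply(premirnas$isomirs, function(iso) {
    sum(iso$copy_number[iso$arm == "3p"])
  }, integer(1))
  premirnas$arm_category <- arm_category(premirnas$copies_5p,
                                         premirnas$copies_3p,
                                         dominance_ratio)
  premirnas
}

#' @rdname arm_profile
#' @param copies_5p,copies_3p Integer vectors of per-arm copy totals.
#' @export
arm_category <- function(copies_5p, copies_3p, dominance_ratio = 2.0) {
  ratio <- pmax(copies_5p, copies_3p) / pmin(copies_5p, copies_3p)
  dplyr::case_when(
    copies_5p == 0 & copies_3p == 0 ~ "undetermined",
    copies_3p == 0 ~ "5P_only",
    copies_5p == 0 ~ "3P_only",
    ratio >= dominance_ratio & copies_5p > copies_3p ~ "5P_dominant",
    ratio >= dominance_ratio & copies_3p > copies_5p ~ "3P_dominant",
    TRUE ~ "equal"
  )
}

#' Classify cross-species differences in arm-selection preference
#'
#' Compares which arms a candidate pre-miRNA expresses against the arm
#' annotation of its orthologous precursor: class 1 -- candidate expresses
#' both arms, ortholog annotates only one; class 2 -- candidate expresses
#' one arm, ortholog annotates both; class 3 -- candidate and ortholog use
#' exactly opposite single arms; otherwise concordant. The classification is
#' symmetric under swapping the 5p/3p labels of both inputs.
#'
#' @param candidate_category Arm categories from [arm_profile()]
#'   (`5P_only`, `3P_only`, `5P_dominant`, `3P_dominant`, `equal`).
#' @param ortholog_5p,ortholog_3p Ortholog arm statuses, each in
#'   `major` / `minor` / `absent`.
#' @return Character vector in `c("class1", "class2", "class3",
#'   "concordant")` (`NA` where inputs are missing).
#' @export
arm_difference_class <- function(candidate_category, ortholog_5p,
                                 ortholog_3p) {
  cand_5p <- candidate_category %in% c("5P_only", "5P_dominant",
                                       "3P_dominant", "equal")
  cand_3p <- candidate_category %in% c("3P_only", "5P_dominant",
                                       "3P_dominant", "equal")
  orth_5p <- ortholog_5p != "absent"
  orth_3p <- ortholog_3p != "absent"
  out <- dplyr::case_when(
    cand_5p & cand_3p & xor(orth_5p, orth_3p) ~ "class1",
    xor(cand_5p, cand_3p) & orth_5p & orth_3p ~ "class2",
    cand_5p & !cand_3p & !orth_5p & orth_3p ~ "class3",
    !cand_5p & cand_3p & orth_5p & !orth_3p ~ "class3",
    TRUE ~ "concordant"
  )
  out[is.na(candidate_category) | is.na(ortholog_5p) |
        is.na(ortholog_3p) |
        candidate_category == "undetermined"] <- NA_character_
  out
}

#' Arm-difference classes of an annotated pre-miRNA set
#'
#' Joins arm profiles with the catalog's precursor arm annotation (via the
#' ortholog precursor id) and classifies each homolog pre-miRNA.
#'
#' @param profiled Annotated, arm-profiled pre-miRNA tibble.
#' @param catalog A `mirna_catalog` with an `arms` table.
#' @return `profiled` with added `ortholog_arm_5p`, `ortholog_arm_3p`,
#'   `difference_class`.
#' @export
classify_arm_difference <- function(profiled, catalog) {
  arms <- catalog$arms
  out <- dplyr::left_join(
    profiled,
    dplyr::select(arms, ortholog_precursor = "precursor_id",
                  ortholog_arm_5p = "arm_5p_status",
                  ortholog_arm_3p = "arm_3p_status"),
    by = "ortholog_precursor"
  )
  out$difference_class <- arm_difference_class(
    out$arm_category, out$ortholog_arm_5p, out$ortholog_arm_3p
  )
  out
}

#' Conservation-versus-expression quartile analysis
#'
#' Families are sorted by ascending conservation level (family name as a
#' deterministic tiebreak) and split into four contiguous quarters (any
#' remainder goes to the earlier quarters). Per family the statistic is
#' log10 of the expression level; adjacent quarters are compared with
#' Welch's two-sample t-test.
#'
#' @param families Family tibble from [family_records()] (needs `family`,
#'   `conservation_level`, `expression_level`; at least 8 rows).
#' @param n_groups Number of quantile groups (default 4).
#' @return A `conservation_expression` object: `quartiles` (per-quarter
#'   median, IQR, whiskers), `tests` (Welch t-test per adjacent pair), and
#'   the per-family `data` with quarter assignment.
#' @export
conservation_expression <- function(families, n_groups = 4) {
  if (nrow(families) < 2 * n_groups) {
    abort(sprintf("need at least %d families for %d groups",
                  2 * n_groups, n_groups))
  }
  d <- dplyr::arrange(families, .data$conservation_level, .data$family)
  n <- nrow(d)
  sizes <- rep(n %/% n_groups, n_groups)
  rem <- n %% n_groups
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  d$quartile <- paste0("Q", rep(seq_len(n_groups), sizes))
  d$log_expression <- log10(d$expression_level)
  quartiles <- dplyr::summarise(
    dplyr::group_by(d, .data$quartile),
    n = dplyr::n(),
    median = median(.data$log_expression),
    q1 = quantile(.data$log_expression, 0.25, names = FALSE),
    q3 = quantile(.data$log_expression, 0.75, names = FALSE),
    conservation_min = min(.data$conservation_level),
    conservation_max = max(.data$conservation_level),
    .groups = "drop"
  )
  iqr <- quartiles$q3 - quartiles$q1
  lo_lim <- quartiles$q1 - 1.5 * iqr
  hi_lim <- quartiles$q3 + 1.5 * iqr
  quartiles$whisker_lo <- purrr::map2_dbl(quartiles$quartile, lo_lim, function(q, l) {
    v <- d$log_expression[d$quartile == q]
    min(v[v >= l])
  })
  quartiles$whisker_hi <- purrr::map2_dbl(quartiles$quartile, hi_lim, function(q, h) {
    v <- d$log_expression[d$quartile == q]
    max(v[v <= h])
  })
  tests <- purrr::map_dfr(seq_len(n_groups - 1), function(i) {
    a <- d$log_expression[d$quartile == paste0("Q", i)]
    b <- d$log_expression[d$quartile == paste0("Q", i + 1)]
    tt <- tryCatch(t.test(b, a, var.equal = FALSE), error = function(e) NULL)
    tibble(pair = sprintf("Q%dQ%d", i, i + 1),
           estimate = mean(b) - mean(a),
           statistic = if (is.null(tt)) NA_real_ else unname(tt$statistic),
           df = if (is.null(tt)) NA_real_ else unname(tt$parameter),
           p_value = if (is.null(tt)) NA_real_ else tt$p.value)
  })
  structure(list(quartiles = quartiles, tests = tests, data = d),
            class = "conservation_expression")
}

#' @export
print.conservation_expression <- function(x, ...) {
  cat("<conservation_expression> ", nrow(x$data), " families in ",
      nrow(x$quartiles), " quarters\n", sep = "")
  print(x$quartiles)
  print(x$tests)
  invisible(x)
}

#' @export
tidy.conservation_expression <- function(x, ...) x$tests

#' @export
glance.conservation_expression <- function(x, ...) {
  tibble(n_families = nrow(x$data), n_groups = nrow(x$quartiles),
         min_p_value = min(x$tests$p_value),
         monotone_medians = !is.unsorted(x$quartiles$median))
}

#' Simulate per-family conservation/expression records
#'
#' Families get increasing conservation levels; log10 expression is a
#' linear gradient over the quarter index plus Gaussian noise. With
#' `gradient = 0` expression is independent of conservation (the null).
#'
#' @param n_families Number of families (default 98, a realistic homolog-set
#'   size).
#' @param gradient Log10 expression shift between adjacent quarters.
#' @param sigma Log10 expression standard deviation (default 0.5).
#' @param seed Integer seed.
#' @return A family tibble suitable for [conservation_expression()].
#' @export
simulate_family_records <- function(n_families = 98, gradient = 2,
                                    sigma = 0.5, seed) {
  withr::local_seed(seed)
  cons <- sort(sample(1:30, n_families, replace = TRUE))
  sizes <- rep(n_families %/% 4, 4)
  rem <- n_families %% 4
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  q <- rep(1:4, sizes)
  log_expr <- 1 + gradient * (q - 1) + stats::rnorm(n_families, 0, sigma)
  tibble(
    family = sprintf("mir-%03d", seq_len(n_families)),
    conservation_level = cons,
    expression_level = pmax(3, round(10^log_expr))
  )
}
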