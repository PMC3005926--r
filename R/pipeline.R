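#' Pipeline configuration
#'
#' Collects inputs and every method threshold in one object. Inputs may be
#' in-memory objects (from the simulators) or file paths. Missing required
#' inputs raise a configuration error before any computation.
#'
#' @param genome A [mirna_genome()] or FASTA path (required).
#' @param reads Read tibble, character vector, or FASTQ/FASTA path
#'   (required).
#' @param catalog A `mirna_catalog`, mature FASTA path, or `NULL`.
#' @param decoys Decoy sequences (vector, `DNAStringSet`, FASTA path) or
#'   `NULL`.
#' @param truth A `mirna_truth` (used to build classifier training data) or
#'   `NULL`.
#' @param min_copies,min_len,max_len,adapter,min_overlap Read-processing
#'   thresholds (copy >= 3, 18-25 nt, exact adapter suffix >= 6 nt).
#' @param k Index seed length (default 18).
#' @param max_loci,min_identity Exclusion thresholds (more than 10 loci;
#'   more than 90 percent decoy identity).
#' @param flank Precursor extension per side (default 60).
#' @param alpha Positive-call p-value threshold (default 0.05).
#' @param max_variations Homolog matching threshold (default 2).
#' @param cluster_window Cluster gap (default 10000 bp).
#' @param dominance_ratio Arm dominance ratio (default 2).
#' @param n_negative Random negative training windows (default 300).
#' @param seed Integer seed for training/calibration randomness.
#' @param outdir Optional directory; when set, every intermediate is
#'   persisted there in standard formats.
#' @return A `mirna_config` list.
#' @export
mirna_config <- function(genome, reads, catalog = NULL, decoys = NULL,
                         truth = NULL, min_copies = 3, min_len = 18,
                         max_len = 25, adapter = default_adapter(),
                         min_overlap = 6, k = 18, max_loci = 10,
                         min_identity = 0.90, flank = 60, alpha = 0.05,
                         max_variations = 2, cluster_window = 10000,
                         dominance_ratio = 2.0, n_negative = 300,
                         seed = 1L, outdir = NULL) {
  if (missing(genome) || is.null(genome)) {
    abort("config error: a genome is required", class = "mirstack_config_error")
  }
  if (missing(reads) || is.null(reads)) {
    abort("config error: reads are required", class = "mirstack_config_error")
  }
  for (p in c(genome = genome, reads = reads)[vapply(list(genome, reads), function(x)
    is.character(x) && length(x) == 1, logical(1))]) {
    if (!file.exists(p)) {
      abort(paste0("config error: input file not found: ", p),
            class = "mirstack_config_error")
    }
  }
  structure(
    list(genome = genome, reads = reads, catalog = catalog, decoys = decoys,
         truth = truth, min_copies = min_copies, min_len = min_len,
         max_len = max_len, adapter = adapter, min_overlap = min_overlap,
         k = k, max_loci = max_loci, min_identity = min_identity,
         flank = flank, alpha = alpha, max_variations = max_variations,
         cluster_window = cluster_window, dominance_ratio = dominance_ratio,
         n_negative = n_negative, seed = as.integer(seed), outdir = outdir),
    class = "mirna_config"
  )
}

# Classifier training data from the truth table: positives are planted
# precursor windows (plus jittered copies so the >= 50-per-class training
# contract holds at desk scale); negatives are random genomic windows away
# from any planted precursor, with a pseudo-mature at the canonical offset.
make_training_set <- function(genome, truth, flank = 60, n_negative = 300,
                              n_jitter = 2, seed = 1L) {
  withr::local_seed(seed)
  lens <- chrom_lengths(genome)
  mirnas <- truth$mirnas
  pos_rows <- list()
  for (i in seq_len(nrow(mirnas))) {
    row <- mirnas[i, ]
    shifts <- c(0L, sample(c(-12:-3, 3:12), n_jitter))
    dominant <- if (row$arm_w5 >= row$arm_w3) "5" else "3"
    ms <- row[[paste0("m", dominant, "_start")]]
    me <- row[[paste0("m", dominant, "_end")]]
    for (sh in shifts) {
      s <- max(0L, ms - flank + sh)
      e <- min(unname(lens[[row$chrom]]), me + flank + sh)
      pos_rows[[length(pos_rows) + 1L]] <- tibble(
        chrom = row$chrom, strand = row$strand,
        start = ms + sh, end = me + sh, prec_start = s, prec_end = e,
        sequence = genome_slice(genome, row$chrom, ms + sh, me + sh,
                                row$strand),
        precursor_seq = genome_slice(genome, row$chrom, s, e, row$strand),
        mature_offset = if (row$strand == "+") ms + sh - s else e - (me + sh)
      )
    }
  }
  # repeat positives until both classes can satisfy the training contract
  pos <- dplyr::bind_rows(pos_rows)
  while (nrow(pos) > 0 && nrow(pos) < 50) pos <- dplyr::bind_rows(pos, pos)
  forbidden <- dplyr::select(mirnas, "chrom", start = "prec_start",
                             end = "prec_end")
  neg_rows <- list()
  guard <- 0L
  while (length(neg_rows) < n_negative && guard < n_negative * 30L) {
    guard <- guard + 1L
    chrom <- sample(names(lens), 1)
    w <- sample(130:150, 1)
    mlen <- 22L
    s <- sample.int(lens[[chrom]] - w - 1L, 1)
    e <- s + w
    f <- forbidden[forbidden$chrom == chrom, , drop = FALSE]
    if (nrow(f) > 0 && any(s < f$end + 200 & e > f$start - 200)) next
    prec <- genome_slice(genome, chrom, s, e, "+")
    if (grepl("N", prec, fixed = TRUE)) next
    off <- 60L
    neg_rows[[length(neg_rows) + 1L]] <- tibble(
      chrom = chrom, strand = "+", start = s + off, end = s + off + mlen,
      prec_start = s, prec_end = e,
      sequence = substr(prec, off + 1L, off + mlen),
      precursor_seq = prec, mature_offset = off
    )
  }
  neg <- dplyr::bind_rows(neg_rows)
  list(
    positive = hairpin_features(fold_hairpins(pos)),
    negative = hairpin_features(fold_hairpins(neg))
  )
}

load_pipeline_inputs <- function(config) {
  genome <- config$genome
  if (is.character(genome)) genome <- read_genome(genome)
  reads <- config$reads
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    reads <- read_small_rna(reads)
  }
  catalog <- config$catalog
  if (is.character(catalog)) catalog <- read_catalog(catalog)
  truth <- config$truth
  if (is.character(truth)) truth <- read_truth(truth)
  list(genome = genome, reads = reads, catalog = catalog,
       decoys = load_decoys(config$decoys), truth = truth)
}

#' Run the full miRNA discovery pipeline
#'
#' Executes the stages in order: collapse, copy-number filter, adapter trim,
#' length filter, perfect-match mapping, coding-decoy and multi-locus
#' exclusions, precursor extraction, folding, feature computation, SVM
#' classification with calibrated p-values, pre-miRNA assembly, homolog
#' annotation, and the characterization analyses (clusters, arm profiles,
#' family records, conservation-expression quartiles when enough families
#' exist). A per-stage log records counts in and out.
#'
#' @param config A [mirna_config()].
#' @return A `mirna_pipeline_result` with the summary tibble, percentage
#'   table, all intermediates, and the stage log.
#' @export
run_mirna_pipeline <- function(config) {
  stopifnot(inherits(config, "mirna_config"))
  inp <- load_pipeline_inputs(config)
  log <- list()
  note <- function(stage, n_in, n_out, unit) {
    log[[length(log) + 1L]] <<- tibble(stage = stage, n_in = n_in,
                                       n_out = n_out, unit = unit)
  }
  n_raw <- if (is.data.frame(inp$reads)) nrow(inp$reads) else length(inp$reads)
  unique_reads <- collapse_reads(inp$reads)
  note("collapse", n_raw, nrow(unique_reads), "unique reads")
  kept <- filter_copy_number(unique_reads, config$min_copies)
  note("copy_filter", nrow(unique_reads), nrow(kept), "unique reads")
  trimmed <- trim_adapter(kept, config$adapter, config$min_overlap)
  note("adapter_trim", nrow(kept), nrow(trimmed), "unique reads")
  sized <- filter_read_length(trimmed, config$min_len, config$max_len)
  note("length_filter", nrow(trimmed), nrow(sized), "unique reads")

  index <- genome_index(inp$genome, config$k)
  loci <- map_reads(index, sized)
  note("map", nrow(sized), nrow(loci), "loci")
  n_before <- nrow(loci)
  loci <- filter_coding_reads(loci, inp$decoys, config$min_identity)
  note("coding_filter", n_before, nrow(loci), "loci")
  n_before <- nrow(loci)
  loci <- filter_multimappers(loci, config$max_loci)
  note("multimapper_filter", n_before, nrow(loci), "loci")

  mappable <- dplyr::distinct(loci, .data$read_id, .data$sequence,
                              .data$copy_number)
  n_mappable_reads <- sum(mappable$copy_number)
  n_mappable_unique <- nrow(mappable)
  n_mappable_loci <- nrow(loci)

  candidates <- extract_precursors(inp$genome, loci, config$flank)
  candidates <- hairpin_features(fold_hairpins(candidates))
  note("extract_fold", nrow(loci), nrow(candidates), "candidates")

  model <- NULL
  classified <- candidates
  if (nrow(candidates) > 0) {
    if (is.null(inp$truth)) {
      abort(paste0("config error: classifier training requires a truth ",
                   "table (or train and classify manually)"),
            class = "mirstack_config_error")
    }
    training <- make_training_set(inp$genome, inp$truth,
                                  flank = config$flank,
                                  n_negative = config$n_negative,
                                  seed = config$seed)
    model <- train_classifier(training$positive, training$negative,
                              seed = config$seed)
    classified <- classify_candidates(model, candidates, config$alpha)
  } else {
    classified$decision_score <- numeric(0)
    classified$p_value <- numeric(0)
    classified$positive <- logical(0)
  }
  note("classify", nrow(classified), sum(classified$positive), "positives")

  premirnas <- assemble_premirnas(classified)
  note("assemble", sum(classified$positive), nrow(premirnas), "pre-miRNAs")
  if (!is.null(inp$catalog)) {
    premirnas <- annotate_premirnas(premirnas, inp$catalog,
                                    config$max_variations)
  } else {
    n <- nrow(premirnas)
    premirnas$set <- rep("Mn", n)
    premirnas$mirna_id <- if (n) paste0("Mn", seq_len(n)) else character(0)
    premirnas$ortholog_id <- rep(NA_character_, n)
    premirnas$ortholog_precursor <- rep(NA_character_, n)
    premirnas$family <- rep(NA_character_, n)
    premirnas$conservation_level <- rep(NA_integer_, n)
  }
  premirnas <- arm_profile(premirnas, config$dominance_ratio)
  if (!is.null(inp$catalog) && nrow(premirnas) > 0) {
    premirnas <- classify_arm_difference(premirnas, inp$catalog)
  }
  clusters <- detect_clusters(premirnas, config$cluster_window)
  families <- if (!is.null(inp$catalog)) family_records(premirnas) else
    family_records(dplyr::mutate(premirnas[0, ], set = character(0)))
  conservation <- if (nrow(families) >= 8) {
    conservation_expression(families)
  } else {
    NULL
  }

  iso_counts <- function(set) {
    rows <- premirnas[!is.na(premirnas$set) & premirnas$set == set, ,
                      drop = FALSE]
    if (nrow(rows) == 0) return(c(premirna = 0L, isomir = 0L, reads = 0L))
    c(premirna = nrow(rows),
      isomir = sum(rows$n_isomirs),
      reads = sum(vapply(rows$isomirs, function(i) sum(i$copy_number),
                         integer(1))))
  }
  mh <- iso_counts("Mh")
  mn <- iso_counts("Mn")
  clustered_ids <- unlist(clusters$members)
  summary <- tibble(
    n_mappable_reads = n_mappable_reads,
    n_mappable_unique_reads = n_mappable_unique,
    n_mappable_loci = n_mappable_loci,
    n_premirna = nrow(premirnas),
    n_isomir = sum(premirnas$n_isomirs),
    n_premirna_mh = mh[["premirna"]], n_premirna_mn = mn[["premirna"]],
    n_isomir_mh = mh[["isomir"]], n_isomir_mn = mn[["isomir"]],
    n_reads_mh = mh[["reads"]], n_reads_mn = mn[["reads"]],
    n_premirna_multi_isomir = sum(premirnas$n_isomirs >= 2),
    n_premirna_clustered = length(clustered_ids),
    n_clusters = nrow(clusters)
  )
  result <- structure(
    list(summary = summary, percentages = summary_percentages(summary),
         unique_reads = unique_reads, loci = loci, classified = classified,
         premirnas = premirnas, clusters = clusters, families = families,
         conservation = conservation, model = model,
         log = dplyr::bind_rows(log), config = config),
    class = "mirna_pipeline_result"
  )
  if (!is.null(config$outdir)) write_pipeline_outputs(result, config$outdir)
  result
}

#' Summary percentages of a pipeline run
#'
#' Computes the three headline percentages, rounded half-up to one decimal:
#' the share of mappable read copies captured by positive miRNA candidates,
#' the share of pre-miRNAs encoding two or more isomiRs, and the share of
#' pre-miRNAs located in clusters. Also reports total pre-miRNA and positive
#' candidate counts from the per-set columns.
#'
#' @param summary One-row tibble (or named list) with columns
#'   `n_reads_mh`, `n_reads_mn`, `n_mappable_reads`, `n_premirna_mh`,
#'   `n_premirna_mn`, `n_isomir_mh`, `n_isomir_mn`,
#'   `n_premirna_multi_isomir`, `n_premirna_clustered`.
#' @return One-row tibble with `pct_mirna_reads`,
#'   `pct_premirna_with_isomirs`, `pct_clustered_premirna`, `n_premirna`,
#'   `n_positive_candidates`.
#' @export
#' @examples
#' summary_percentages(tibble::tibble(
#'   n_reads_mh = 469722, n_reads_mn = 389984, n_mappable_reads = 3030172,
#'   n_premirna_mh = 254, n_premirna_mn = 345, n_isomir_mh = 593,
#'   n_isomir_mn = 425, n_premirna_multi_isomir = 175,
#'   n_premirna_clustered = 194
#' ))
summary_percentages <- function(summary) {
  s <- as.list(summary)
  n_premirna <- s$n_premirna_mh + s$n_premirna_mn
  n_candidates <- s$n_isomir_mh + s$n_isomir_mn
  pct <- function(num, den) {
    if (is.na(den) || den == 0) return(NA_real_)
    round_half_up(100 * num / den, 1)
  }
  tibble(
    pct_mirna_reads = pct(s$n_reads_mh + s$n_reads_mn, s$n_mappable_reads),
    pct_premirna_with_isomirs = pct(s$n_premirna_multi_isomir, n_premirna),
    pct_clustered_premirna = pct(s$n_premirna_clustered, n_premirna),
    n_premirna = n_premirna,
    n_positive_candidates = n_candidates
  )
}

#' @export
print.mirna_pipeline_result <- function(x, ...) {
  cat("<mirna_pipeline_result>\n")
  print(x$summary)
  print(x$percentages)
  invisible(x)
}

#' @export
glance.mirna_pipeline_result <- function(x, ...) {
  dplyr::bind_cols(x$summary, x$percentages)
}

#' @export
tidy.mirna_pipeline_result <- function(x, ...) {
  p <- x$premirnas
  if (nrow(p) == 0) return(tibble())
  dplyr::select(p, -dplyr::any_of("isomirs"))
}

#' Compare a pipeline result against the planted truth
#'
#' Recall is the fraction of planted miRNAs overlapped (same chromosome and
#' strand) by a predicted pre-miRNA; precision the fraction of predictions
#' overlapping a planted precursor. Arm categories, cluster memberships, and
#' conservation levels of matched plants are scored against truth.
#'
#' @param result A `mirna_pipeline_result`.
#' @param truth The `mirna_truth` used to simulate the inputs.
#' @return One-row tibble: `recall`, `precision`, `arm_accuracy`,
#'   `cluster_recovery`, `conservation_exact`, `n_planted`, `n_predicted`.
#' @export
evaluate_discovery <- function(result, truth) {
  mirnas <- truth$mirnas
  pred <- result$premirnas
  overlaps <- function(i) {
    p <- mirnas[i, ]
    hit <- pred$chrom == p$chrom & pred$strand == p$strand &
      pred$start < p$prec_end & pred$end > p$prec_start
    which(hit)
  }
  match_idx <- lapply(seq_len(nrow(mirnas)), overlaps)
  recalled <- vapply(match_idx, function(ix) length(ix) > 0, logical(1))
  recall <- mean(recalled)
  precision <- if (nrow(pred) == 0) NA_real_ else {
    mean(vapply(seq_len(nrow(pred)), function(j) {
      any(mirnas$chrom == pred$chrom[j] & mirnas$strand == pred$strand[j] &
            mirnas$prec_start < pred$end[j] & mirnas$prec_end > pred$start[j])
    }, logical(1)))
  }
  expected_cat <- arm_category(mirnas$arm_w5, mirnas$arm_w3,
                               result$config$dominance_ratio)
  got_cat <- vapply(match_idx, function(ix) {
    if (length(ix) == 0) NA_character_ else pred$arm_category[ix[1]]
  }, character(1))
  arm_accuracy <- mean(got_cat == expected_cat, na.rm = FALSE)
  # cluster recovery: planted member sets must be exactly the detected ones
  plant_of_pred <- vapply(seq_len(nrow(pred)), function(j) {
    hit <- which(mirnas$chrom == pred$chrom[j] &
                   mirnas$strand == pred$strand[j] &
                   mirnas$prec_start < pred$end[j] &
                   mirnas$prec_end > pred$start[j])
    if (length(hit)) mirnas$mirna_id[hit[1]] else NA_character_
  }, character(1))
  truth_clusters <- split(mirnas$mirna_id[!is.na(mirnas$cluster_id)],
                          mirnas$cluster_id[!is.na(mirnas$cluster_id)])
  detected <- lapply(result$clusters$members, function(ids) {
    sort(stats::na.omit(plant_of_pred[match(ids, pred$premirna_id)]))
  })
  cluster_recovery <- if (length(truth_clusters) == 0) {
    as.numeric(length(detected) == 0)
  } else {
    mean(vapply(truth_clusters, function(tc) {
      any(vapply(detected, function(dc) identical(sort(tc), as.character(dc)),
                 logical(1)))
    }, logical(1)))
  }
  cons_ok <- NA_real_
  if ("family" %in% names(pred) && nrow(pred) > 0) {
    mh_pred <- pred[!is.na(pred$set) & pred$set == "Mh", , drop = FALSE]
    if (nrow(mh_pred) > 0) {
      plant <- mirnas[match(plant_of_pred[match(mh_pred$premirna_id,
                                                pred$premirna_id)],
                            mirnas$mirna_id), ]
      cons_ok <- mean(mh_pred$conservation_level == plant$n_species,
                      na.rm = TRUE)
    }
  }
  tibble(recall = recall, precision = precision,
         arm_accuracy = arm_accuracy, cluster_recovery = cluster_recovery,
         conservation_exact = cons_ok,
         n_planted = nrow(mirnas), n_predicted = nrow(pred))
}
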