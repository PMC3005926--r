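#' Train the candidate-miRNA SVM with an empirical calibration table
#'
#' Fits an RBF-kernel support vector machine on labeled feature vectors and
#' records the empirical distribution of decision scores on held-out
#' negatives. That calibration table turns a decision score into a p-value:
#' the probability that a candidate would be classified as a positive hit by
#' mistake.
#'
#' @param positive_features,negative_features Tibbles (or matrices) with the
#'   ten feature columns `f1` .. `f10`; at least 50 examples per class.
#' @param cost,gamma RBF SVM hyperparameters.
#' @param holdout Fraction of each class held out for accuracy estimation
#'   and score calibration (default 0.3).
#' @param seed Integer seed controlling the train/held-out split.
#' @return A `mirna_classifier`: the fitted SVM, the calibration scores, the
#'   held-out accuracy, and metadata.
#' @export
train_classifier <- function(positive_features, negative_features,
                             cost = 10, gamma = 0.1, holdout = 0.3,
                             seed = 1L) {
  pos <- as.matrix(as_tibble(positive_features)[, feature_cols()])
  neg <- as.matrix(as_tibble(negative_features)[, feature_cols()])
  if (nrow(pos) < 50 || nrow(neg) < 50) {
    abort("need at least 50 examples per class (positive and negative)",
          class = "mirstack_train_error")
  }
  withr::local_seed(seed)
  split_idx <- function(n) sample.int(n, max(1L, round(n * holdout)))
  pos_ho <- split_idx(nrow(pos))
  neg_ho <- split_idx(nrow(neg))
  x_tr <- rbind(pos[-pos_ho, , drop = FALSE], neg[-neg_ho, , drop = FALSE])
  y_tr <- factor(rep(c("positive", "negative"),
                     c(nrow(pos) - length(pos_ho), nrow(neg) - length(neg_ho))),
                 levels = c("positive", "negative"))
  keep <- apply(x_tr, 2, function(v) stats::sd(v) > 0)
  if (!any(keep)) abort("all features are constant; cannot train")
  fit <- e1071::svm(x_tr[, keep, drop = FALSE], y_tr, kernel = "radial",
                    cost = cost, gamma = gamma, scale = TRUE)
  raw_score <- function(m) {
    pr <- predict(fit, m[, keep, drop = FALSE], decision.values = TRUE)
    drop(attr(pr, "decision.values"))
  }
  # orient decision scores so positives score high
  sign_flip <- if (mean(raw_score(pos[-pos_ho, , drop = FALSE])) <
                   mean(raw_score(neg[-neg_ho, , drop = FALSE]))) -1 else 1
  x_ho <- rbind(pos[pos_ho, , drop = FALSE], neg[neg_ho, , drop = FALSE])
  y_ho <- rep(c("positive", "negative"), c(length(pos_ho), length(neg_ho)))
  ho_scores <- sign_flip * raw_score(x_ho)
  # held-out accuracy at the SVM's own decision boundary (score 0)
  accuracy <- mean((ho_scores > 0) == (y_ho == "positive"))
  calibration <- sign_flip * raw_score(neg[neg_ho, , drop = FALSE])
  structure(
    list(fit = fit, keep = keep, sign_flip = sign_flip,
         calibration = sort(calibration), accuracy = accuracy,
         n_pos = nrow(pos), n_neg = nrow(neg),
         cost = cost, gamma = gamma, seed = as.integer(seed),
         version = "mirstack-classifier-1"),
    class = "mirna_classifier"
  )
}

#' @export
print.mirna_classifier <- function(x, ...) {
  cat("<mirna_classifier> RBF SVM, held-out accuracy ",
      sprintf("%.3f", x$accuracy), ", ", length(x$calibration),
      " calibration negatives\n", sep = "")
  invisible(x)
}

#' Decision scores of a classifier on feature rows
#'
#' @param model A `mirna_classifier`.
#' @param features Tibble/matrix with columns `f1` .. `f10`.
#' @return Numeric vector of oriented decision scores (positives high).
#' @export
decision_scores <- function(model, features) {
  m <- as.matrix(as_tibble(features)[, feature_cols()])
  pr <- predict(model$fit, m[, model$keep, drop = FALSE],
                decision.values = TRUE)
  unname(model$sign_flip * drop(attr(pr, "decision.values")))
}

#' Classify candidates with calibrated p-values
#'
#' The p-value of a candidate is the add-one-smoothed fraction of
#' calibration negatives whose decision score is at least as high:
#' `p = (1 + #\{calibration >= score\}) / (n_calibration + 1)` -- the
#' empirical probability of the candidate being called positive by mistake.
#' A candidate is positive iff `p_value < alpha`.
#'
#' @param model A `mirna_classifier`.
#' @param candidates Feature tibble (any tibble containing `f1` .. `f10`).
#' @param alpha Positive-call threshold (default 0.05).
#' @return `candidates` with added `decision_score`, `p_value`, `positive`.
#' @export
classify_candidates <- function(model, candidates, alpha = 0.05) {
  if (nrow(candidates) == 0) {
    return(dplyr::mutate(candidates, decision_score = numeric(0),
                         p_value = numeric(0), positive = logical(0)))
  }
  s <- decision_scores(model, candidates)
  cal <- model$calibration
  n <- length(cal)
  ge <- n - findInterval(s, cal, left.open = TRUE)
  candidates$decision_score <- s
  candidates$p_value <- (1 + ge) / (n + 1)
  candidates$positive <- candidates$p_value < alpha
  candidates
}

#' Assemble positive candidates into pre-miRNAs with isomiR stacks
#'
#' Positive candidates whose precursor intervals overlap on the same strand
#' and chromosome are merged into one pre-miRNA (union interval). Every
#' retained unique read becomes one isomiR carrying its copy number and
#' p-value, assigned to the 5p or 3p arm by the side of its midpoint
#' relative to the terminal loop of the most abundant member's hairpin;
#' midpoints inside the loop are flagged `"loop"` (loop-spanning) and are
#' excluded from arm statistics.
#'
#' @param classified Classified candidate tibble (from
#'   [classify_candidates()] on folded, featurized candidates with locus
#'   columns).
#' @return Tibble of pre-miRNAs: `premirna_id`, `chrom`, `start`, `end`,
#'   `strand`, `n_isomirs`, and a list-column `isomirs` (per-isomiR tibbles
#'   sorted by descending copy number).
#' @export
assemble_premirnas <- function(classified) {
  empty <- tibble(premirna_id = character(0), chrom = character(0),
                  start = integer(0), end = integer(0), strand = character(0),
                  n_isomirs = integer(0), isomirs = list())
  pos <- dplyr::filter(classified, .data$positive)
  if (nrow(pos) == 0) return(empty)
  groups <- dplyr::group_split(dplyr::group_by(pos, .data$chrom, .data$strand))
  out <- purrr::map_dfr(groups, function(g) {
    ir <- IRanges::IRanges(start = g$prec_start + 1L, end = g$prec_end)
    red <- IRanges::reduce(ir)
    grp <- S4Vectors::subjectHits(IRanges::findOverlaps(ir, red))
    purrr::map_dfr(seq_along(red), function(m) {
      gg <- g[grp == m, , drop = FALSE]
      gg <- dplyr::arrange(gg, dplyr::desc(.data$copy_number), .data$start,
                           .data$read_id)
      rep_row <- gg[1, ]
      iso <- tibble(
        sequence = gg$sequence, copy_number = gg$copy_number,
        p_value = gg$p_value, start = gg$start, end = gg$end,
        arm = isomir_arm(gg$start, gg$end, rep_row)
      )
      iso <- dplyr::arrange(iso, dplyr::desc(.data$copy_number),
                            .data$sequence)
      tibble(
        chrom = rep_row$chrom,
        start = min(gg$prec_start), end = max(gg$prec_end),
        strand = rep_row$strand,
        n_isomirs = nrow(iso), isomirs = list(iso)
      )
    })
  })
  out <- dplyr::arrange(out, .data$chrom, .data$start, .data$strand)
  out$premirna_id <- sprintf("premir_%03d", seq_len(nrow(out)))
  dplyr::relocate(out, "premirna_id")
}

# Arm of isomiRs relative to the representative candidate's terminal loop.
isomir_arm <- function(start, end, rep_row) {
  if (is.na(rep_row$loop_start)) return(rep("loop", length(start)))
  off <- if (rep_row$strand == "+") {
    start - rep_row$prec_start
  } else {
    rep_row$prec_end - end
  }
  mid <- off + (end - start) / 2
  dplyr::case_when(
    mid < rep_row$loop_start ~ "5p",
    mid >= rep_row$loop_end ~ "3p",
    TRUE ~ "loop"
  )
}

#' @export
tidy.mirna_classifier <- function(x, ...) {
  tibble(
    statistic = c("calibration_min", "calibration_median", "calibration_max"),
    value = c(min(x$calibration), median(x$calibration), max(x$calibration))
  )
}

#' @export
glance.mirna_classifier <- function(x, ...) {
  tibble(accuracy = x$accuracy, n_pos = x$n_pos, n_neg = x$n_neg,
         n_calibration = length(x$calibration), cost = x$cost,
         gamma = x$gamma)
}
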