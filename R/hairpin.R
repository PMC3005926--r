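#' Extract candidate precursors around mapped loci
#'
#' Each mapped locus (candidate mature miRNA) is extended by `flank`
#' nucleotides upstream and downstream; the resulting ~140 nt fragment is
#' the candidate pre-miRNA. Minus-strand candidates are reverse-complemented
#' so the mature always appears in sense orientation, and `mature_offset`
#' gives its 0-based offset within the precursor. Flanks are clipped at
#' chromosome ends.
#'
#' @param genome A [mirna_genome()].
#' @param loci Locus tibble from [map_reads()].
#' @param flank Extension on each side (default 60).
#' @return The loci tibble with added columns `prec_start`, `prec_end`,
#'   `precursor_seq`, `mature_offset`.
#' @export
extract_precursors <- function(genome, loci, flank = 60) {
  if (nrow(loci) == 0) {
    return(dplyr::mutate(loci, prec_start = integer(0), prec_end = integer(0),
                         precursor_seq = character(0),
                         mature_offset = integer(0)))
  }
  lens <- chrom_lengths(genome)
  out <- loci
  out$prec_start <- pmax(0L, out$start - as.integer(flank))
  out$prec_end <- pmin(unname(lens[out$chrom]), out$end + as.integer(flank))
  out$precursor_seq <- vapply(seq_len(nrow(out)), function(i) {
    genome_slice(genome, out$chrom[i], out$prec_start[i], out$prec_end[i],
                 out$strand[i])
  }, character(1))
  out$mature_offset <- ifelse(out$strand == "+",
                              out$start - out$prec_start,
                              out$prec_end - out$end)
  out
}

#' Fold a sequence by weighted base-pair maximization
#'
#' A Nussinov-style dynamic program maximizing the total pair weight
#' (GC = 3, AU = 2, GU wobble = 1) with a minimum hairpin loop of
#' `min_loop` unpaired nucleotides. The traceback is deterministic (prefer
#' pairing the 5' base with its smallest admissible partner, then the
#' leftmost split), so one optimal structure is returned. The score is a
#' pairing score, not a free energy.
#'
#' @param sequence A single DNA/RNA sequence (U is converted to T; at most
#'   10 percent `N` allowed, other letters are an error).
#' @param min_loop Minimum unpaired loop length (default 3).
#' @return A list with `structure` (dot-bracket) and `score` (integer).
#' @export
#' @examples
#' fold_rna("GGGGAAAACCCC")
fold_rna <- function(sequence, min_loop = 3) {
  stopifnot(length(sequence) == 1)
  s <- normalize_seq(sequence)
  if (grepl("[^ACGTN]", s)) {
    abort("sequence contains characters outside ACGTUN")
  }
  n_frac <- if (nchar(s) > 0) {
    nchar(gsub("[^N]", "", s)) / nchar(s)
  } else {
    0
  }
  if (n_frac > 0.1) {
    abort("sequence has more than 10% N; refusing to fold")
  }
  res <- fold_nussinov_cpp(s, as.integer(min_loop))
  list(structure = res$structure, score = as.integer(res$score))
}

#' Fold the precursors of a candidate table
#'
#' @param candidates Tibble with a `precursor_seq` column (from
#'   [extract_precursors()]).
#' @param min_loop Passed to [fold_rna()].
#' @return The tibble with added `structure` and `pairing_score` columns.
#' @export
fold_hairpins <- function(candidates, min_loop = 3) {
  if (nrow(candidates) == 0) {
    return(dplyr::mutate(candidates, structure = character(0),
                         pairing_score = integer(0)))
  }
  folded <- lapply(candidates$precursor_seq, fold_rna, min_loop = min_loop)
  candidates$structure <- vapply(folded, `[[`, character(1), "structure")
  candidates$pairing_score <- vapply(folded, `[[`, integer(1), "score")
  candidates
}

# Pair table of a dot-bracket string: two-column matrix of 1-based (i, j).
parse_pairs <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  open <- integer(0)
  pi <- integer(0)
  pj <- integer(0)
  for (t in seq_along(ch)) {
    if (ch[t] == "(") {
      open <- c(open, t)
    } else if (ch[t] == ")") {
      pi <- c(pi, open[length(open)])
      pj <- c(pj, t)
      open <- open[-length(open)]
    }
  }
  cbind(i = pi, j = pj)
}

# Terminal loop of the best (most deeply stacked) hairpin.
# Returns c(loop_start, loop_end, stem_pairs) with the loop as a 0-based
# half-open interval of unpaired positions, or NAs when nothing pairs.
locate_loop <- function(structure) {
  pr <- parse_pairs(structure)
  if (nrow(pr) == 0) return(c(NA_integer_, NA_integer_, 0L))
  paired <- sort(c(pr[, 1], pr[, 2]))
  inner <- vapply(seq_len(nrow(pr)), function(r) {
    !any(paired > pr[r, 1] & paired < pr[r, 2])
  }, logical(1))
  cand <- pr[inner, , drop = FALSE]
  depth <- vapply(seq_len(nrow(cand)), function(r) {
    sum(pr[, 1] <= cand[r, 1] & pr[, 2] >= cand[r, 2])
  }, integer(1))
  best <- which(depth == max(depth))
  best <- best[which.min(cand[best, 1])]
  unname(c(cand[best, 1], cand[best, 2] - 1L, depth[best]))
}

#' Compute the ten classification features of folded candidates
#'
#' The feature set is a classical pre-miRNA description of the candidate
#' (mature, precursor) pair: `f1` precursor length; `f2` precursor GC
#' fraction; `f3` pairing score; `f4` pairing score per nucleotide; `f5`
#' fraction of precursor bases paired; `f6` fraction of mature bases paired;
#' `f7` terminal loop length of the best hairpin; `f8` longest unpaired run
#' inside the mature; `f9` mature GC fraction; `f10` arm position of the
#' mature (-1 fully on the 5' side of the loop, +1 fully on the 3' side).
#'
#' Loop coordinates of the best hairpin are also attached (`loop_start`,
#' `loop_end`, 0-based half-open within the precursor) for downstream arm
#' assignment.
#'
#' @param candidates Folded candidate tibble from [fold_hairpins()] with
#'   `sequence`, `precursor_seq`, `structure`, `pairing_score`,
#'   `mature_offset` columns.
#' @return The tibble with columns `f1` .. `f10`, `loop_start`, `loop_end`.
#' @export
hairpin_features <- function(candidates) {
  if (nrow(candidates) == 0) {
    for (col in c(paste0("f", 1:10), "loop_start", "loop_end")) {
      candidates[[col]] <- numeric(0)
    }
    return(candidates)
  }
  feats <- purrr::pmap_dfr(
    list(candidates$precursor_seq, candidates$structure,
         candidates$pairing_score, candidates$mature_offset,
         nchar(candidates$sequence)),
    function(prec, struct, score, off, mlen) {
      n <- nchar(prec)
      ch <- strsplit(struct, "")[[1]]
      paired <- ch != "."
      mat_idx <- (off + 1L):(off + mlen)
      mat_idx <- mat_idx[mat_idx >= 1 & mat_idx <= n]
      loop <- locate_loop(struct)
      f7 <- if (is.na(loop[1])) n else loop[2] - loop[1]
      runs <- rle(paired[mat_idx])
      f8 <- if (any(!runs$values)) max(runs$lengths[!runs$values]) else 0L
      loop_mid <- if (is.na(loop[1])) n / 2 else (loop[1] + loop[2]) / 2
      mat_mid <- off + mlen / 2
      f10 <- max(-1, min(1, (mat_mid - loop_mid) / (n / 2)))
      tibble(
        f1 = n,
        f2 = gc_fraction(prec),
        f3 = score,
        f4 = score / n,
        f5 = mean(paired),
        f6 = if (length(mat_idx)) mean(paired[mat_idx]) else 0,
        f7 = as.numeric(f7),
        f8 = as.numeric(f8),
        f9 = gc_fraction(substr(prec, off + 1L, off + mlen)),
        f10 = f10,
        loop_start = loop[1],
        loop_end = loop[2]
      )
    }
  )
  dplyr::bind_cols(candidates, feats)
}

feature_cols <- function() paste0("f", 1:10)
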