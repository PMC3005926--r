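# Independent oracles used across the suite. Each one deliberately takes a
# different route than the package implementation it checks.

# Naive full-genome scan for perfect matches on both strands.
oracle_scan <- function(genome, pattern) {
  pat <- Biostrings::DNAString(pattern)
  rc <- Biostrings::reverseComplement(pat)
  purrr::map_dfr(names(genome$seq), function(ch) {
    subj <- Biostrings::DNAString(genome$seq[[ch]])
    fwd <- Biostrings::matchPattern(pat, subj)
    rev <- Biostrings::matchPattern(rc, subj)
    dplyr::bind_rows(
      tibble::tibble(chrom = ch, start = BiocGenerics::start(fwd) - 1L,
                     end = BiocGenerics::end(fwd), strand = "+"),
      tibble::tibble(chrom = ch, start = BiocGenerics::start(rev) - 1L,
                     end = BiocGenerics::end(rev), strand = "-")
    )
  })
}

oracle_pair_weight <- function(a, b) {
  switch(paste0(a, b), GC = 3, CG = 3, AT = 2, TA = 2, GT = 1, TG = 1, 0)
}

# Exhaustive (memo-free) enumeration of the optimal weighted pairing score.
oracle_fold_score <- function(seq, min_loop = 3) {
  ch <- strsplit(seq, "")[[1]]
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0)
    best <- rec(i + 1, j)
    for (k in (i + min_loop + 1):j) {
      w <- oracle_pair_weight(ch[i], ch[k])
      if (w > 0) {
        left <- if (k - i - 1 > 0) rec(i + 1, k - 1) else 0
        right <- if (k < j) rec(k + 1, j) else 0
        best <- max(best, w + left + right)
      }
    }
    best
  }
  rec(1, length(ch))
}

# Score of a concrete dot-bracket structure; validates balance and min loop.
oracle_score_structure <- function(seq, structure, min_loop = 3) {
  ch <- strsplit(seq, "")[[1]]
  db <- strsplit(structure, "")[[1]]
  stopifnot(length(ch) == length(db))
  open <- integer(0)
  score <- 0
  for (t in seq_along(db)) {
    if (db[t] == "(") open <- c(open, t)
    if (db[t] == ")") {
      stopifnot(length(open) > 0)
      i <- open[length(open)]
      open <- open[-length(open)]
      stopifnot(t - i - 1 >= min_loop)
      w <- oracle_pair_weight(ch[i], ch[t])
      stopifnot(w > 0)
      score <- score + w
    }
  }
  stopifnot(length(open) == 0)
  score
}

# Levenshtein distance by explicit dynamic programming.
oracle_edit_distance <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  m <- length(x)
  n <- length(y)
  d <- matrix(0L, m + 1, n + 1)
  d[, 1] <- 0:m
  d[1, ] <- 0:n
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                             d[i, j] + (x[i] != y[j]))
    }
  }
  d[m + 1, n + 1]
}

# All-offset ungapped identity, plain R loops.
oracle_best_identity <- function(read, decoys) {
  rch <- strsplit(read, "")[[1]]
  m <- length(rch)
  best <- 0
  for (d in decoys) {
    dch <- strsplit(d, "")[[1]]
    L <- length(dch)
    for (off in (-(m - 1)):(L - 1)) {
      j <- off + seq_len(m)
      ok <- j >= 1 & j <= L
      matches <- sum(rch[ok] == dch[j[ok]])
      if (matches > best) best <- matches
    }
  }
  best / m
}

# O(n^2) all-pairs single-linkage chaining of intervals per chromosome.
# Returns a list of sorted member-id vectors (components of size >= 2).
oracle_clusters <- function(df, window) {
  out <- list()
  for (ch in unique(df$chrom)) {
    g <- df[df$chrom == ch, , drop = FALSE]
    n <- nrow(g)
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        gap <- max(g$start[i], g$start[j]) - min(g$end[i], g$end[j])
        adj[i, j] <- gap <= window
      }
    }
    comp <- rep(NA_integer_, n)
    c0 <- 0L
    for (i in seq_len(n)) {
      if (!is.na(comp[i])) next
      c0 <- c0 + 1L
      queue <- i
      while (length(queue)) {
        v <- queue[1]
        queue <- queue[-1]
        if (!is.na(comp[v])) next
        comp[v] <- c0
        queue <- c(queue, which(adj[v, ] & is.na(comp)))
      }
    }
    for (k in unique(comp)) {
      ids <- g$premirna_id[comp == k]
      if (length(ids) >= 2) out[[length(out) + 1L]] <- sort(ids)
    }
  }
  out
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
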