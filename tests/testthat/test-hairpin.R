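test_that("precursor extraction arithmetic, clipping, and strand handling", {
  withr::local_seed(40)
  s <- random_dna_str(1000)
  genome <- mirna_genome(c(chr1 = s))
  mid <- tibble::tibble(read_id = "r1", sequence = substr(s, 501, 522),
                        copy_number = 3L, chrom = "chr1", start = 500L,
                        end = 522L, strand = "+")
  out <- extract_precursors(genome, mid, flank = 60)
  expect_equal(nchar(out$precursor_seq), 142L)
  expect_equal(out$mature_offset, 60L)
  expect_equal(out$precursor_seq, substr(s, 441, 582))
  # left clipping at the chromosome start
  left <- dplyr::mutate(mid, start = 10L, end = 32L,
                        sequence = substr(s, 11, 32))
  outl <- extract_precursors(genome, left, flank = 60)
  expect_equal(outl$prec_start, 0L)
  expect_equal(outl$mature_offset, 10L)
  # minus strand equals the reverse complement of the plus extraction
  minus <- dplyr::mutate(mid, strand = "-",
                         sequence = revcomp(substr(s, 501, 522)))
  outm <- extract_precursors(genome, minus, flank = 60)
  expect_equal(outm$precursor_seq, revcomp(out$precursor_seq))
  expect_equal(outm$mature_offset, 60L)
})

test_that("folding reproduces forced structures and degenerate cases", {
  f <- fold_rna("GGGGAAAACCCC")
  expect_equal(f$structure, "((((....))))")
  expect_equal(f$score, 12L)
  f0 <- fold_rna("AAAAAAAAAA")
  expect_equal(f0$structure, "..........")
  expect_equal(f0$score, 0L)
  expect_error(fold_rna("ACGTXACGT"), "ACGTUN")
  expect_error(fold_rna(strrep("N", 30)), "10%")
  # U is accepted as RNA input
  expect_equal(fold_rna("GGGGAAAACCCC")$score,
               fold_rna("GGGGAAAACCCC")$score)
  expect_equal(fold_rna("GGGGUUUUCCCC")$score, 12L)
})

test_that("fold scores equal exhaustive structure enumeration up to 25 nt", {
  withr::local_seed(41)
  lengths <- c(8, 10, 12, 14, 16, 18, 20, 22, 25)
  for (n in lengths) {
    for (rep in 1:3) {
      s <- random_dna_str(n)
      f <- fold_rna(s)
      expect_equal(f$score, oracle_fold_score(s),
                   info = paste("sequence:", s))
      # the returned structure is well-formed and achieves the score
      expect_equal(oracle_score_structure(s, f$structure), f$score,
                   info = paste("sequence:", s))
    }
  }
})

test_that("fold score is reverse-complement invariant for Watson-Crick alphabets", {
  # exact invariance holds when no G:U wobble can form (AT-only and GC-only
  # alphabets); wobble pairs are not preserved by reverse complement
  withr::local_seed(43)
  for (rep in 1:5) {
    at <- paste(sample(c("A", "T"), 20, replace = TRUE), collapse = "")
    gc <- paste(sample(c("G", "C"), 20, replace = TRUE), collapse = "")
    expect_equal(fold_rna(at)$score, fold_rna(revcomp(at))$score)
    expect_equal(fold_rna(gc)$score, fold_rna(revcomp(gc))$score)
  }
})

test_that("features of a perfect stem hairpin match construction", {
  cand <- manual_candidate(perfect_hairpin(), mature_offset = 0,
                           mature_len = 22)
  expect_equal(cand$f1, 124)
  expect_equal(cand$f3, 180)           # 60 G:C pairs
  expect_equal(cand$f5, 120 / 124)     # all but the 4 nt loop paired
  expect_equal(cand$f6, 1)             # mature fully paired
  expect_equal(cand$f7, 4)             # terminal loop length
  expect_equal(cand$f8, 0)             # no bulge inside the mature
  expect_lt(cand$f10, 0)               # mature on the 5' side of the loop
  expect_equal(cand$loop_start, 60)
  expect_equal(cand$loop_end, 64)
  # GC fraction is a plain base count
  expect_equal(mirstack:::gc_fraction("GGCCAATT"), 0.5)
  expect_equal(cand$f2, 120 / 124)
})

test_that("features are deterministic and computed per candidate row", {
  sim <- tiny_sim(seed = 29)
  m <- sim$truth$mirnas[1, ]
  prec <- mirstack:::genome_slice(sim$genome, m$chrom, m$prec_start,
                                  m$prec_end, m$strand)
  a <- manual_candidate(prec, mature_offset = 38, mature_len = 22)
  b <- manual_candidate(prec, mature_offset = 38, mature_len = 22)
  expect_identical(a, b)
})

test_that("planted hairpins separate from random windows on normalized score", {
  skip_if_not_installed("pROC")
  sim <- tiny_sim(seed = 37)
  tr <- mirstack:::make_training_set(sim$genome, sim$truth, seed = 37)
  resp <- c(rep(1, nrow(tr$positive)), rep(0, nrow(tr$negative)))
  f4 <- c(tr$positive$f4, tr$negative$f4)
  auc <- suppressMessages(as.numeric(pROC::auc(resp, f4)))
  expect_gt(auc, 0.9)
})

test_that("shuffled precursors fold worse than planted hairpins", {
  sim <- tiny_sim(seed = 39)
  withr::local_seed(39)
  m <- sim$truth$mirnas
  planted <- vapply(seq_len(nrow(m)), function(i) {
    mirstack:::genome_slice(sim$genome, m$chrom[i], m$prec_start[i],
                            m$prec_end[i], m$strand[i])
  }, character(1))
  shuffled <- vapply(planted, function(s) {
    paste(sample(strsplit(s, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  f4_planted <- vapply(planted, function(s) {
    f <- fold_rna(s); f$score / nchar(s)
  }, numeric(1), USE.NAMES = FALSE)
  f4_shuffled <- vapply(shuffled, function(s) {
    f <- fold_rna(s); f$score / nchar(s)
  }, numeric(1), USE.NAMES = FALSE)
  expect_gt(mean(f4_planted), mean(f4_shuffled))
  expect_true(all(f4_planted > max(f4_shuffled) - 0.2))
})
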