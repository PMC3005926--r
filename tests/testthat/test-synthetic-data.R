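test_that("fixed seed gives byte-identical genomes, reads, and truth", {
  a <- simulate_genome(n_chrom = 1, chrom_len = 50000, n_mirna = 3,
                       n_clusters = 0, n_repeats = 0, n_decoys = 0, seed = 7)
  b <- simulate_genome(n_chrom = 1, chrom_len = 50000, n_mirna = 3,
                       n_clusters = 0, n_repeats = 0, n_decoys = 0, seed = 7)
  expect_identical(a$genome$seq, b$genome$seq)
  expect_identical(a$truth$mirnas, b$truth$mirnas)
  expect_equal(nrow(a$truth$mirnas), 3)
  # planted precursors do not overlap
  iv <- a$truth$mirnas
  expect_true(all(diff(sort(iv$prec_start)) > 140))
  fa <- withr::local_tempfile(fileext = ".fa")
  fb <- withr::local_tempfile(fileext = ".fa")
  write_genome_fasta(a$genome, fa)
  write_genome_fasta(b$genome, fb)
  expect_identical(readLines(fa), readLines(fb))
  ra <- simulate_reads(a$genome, a$truth, depth_per_mirna = 50,
                       noise_reads = 10, seed = 3)
  rb <- simulate_reads(b$genome, b$truth, depth_per_mirna = 50,
                       noise_reads = 10, seed = 3)
  expect_identical(ra, rb)
})

test_that("every planted mature occurs exactly at its truth interval", {
  sim <- tiny_sim(seed = 11)
  m <- sim$truth$mirnas
  for (i in seq_len(nrow(m))) {
    for (arm in c("5", "3")) {
      s <- m[[paste0("m", arm, "_start")]][i]
      e <- m[[paste0("m", arm, "_end")]][i]
      mat <- mirstack:::genome_slice(sim$genome, m$chrom[i], s, e,
                                     m$strand[i])
      hits <- oracle_scan(sim$genome, mat)
      expect_equal(nrow(hits), 1L)
      expect_equal(hits$start, s)
      expect_equal(hits$end, e)
      expect_equal(hits$strand, m$strand[i])
    }
  }
})

test_that("clustered plants are pairwise chainable within 10 kb", {
  sim <- simulate_genome(n_chrom = 1, chrom_len = 100000, n_mirna = 6,
                         n_clusters = 1, cluster_size = 6, n_repeats = 0,
                         n_decoys = 0, seed = 1)
  m <- dplyr::arrange(sim$truth$mirnas, prec_start)
  expect_true(all(!is.na(m$cluster_id)))
  gaps <- m$prec_start[-1] - m$prec_end[-nrow(m)]
  expect_true(all(gaps <= 10000))
})

test_that("a k-mer from a planted repeat maps to every copy by naive scan", {
  sim <- simulate_genome(n_chrom = 1, chrom_len = 50000, n_mirna = 0,
                         n_clusters = 0, n_repeats = 1, repeat_copies = 15,
                         n_decoys = 0, seed = 2)
  unit <- sim$truth$repeats$unit[1]
  kmer <- substr(unit, 11, 32)
  expect_equal(nrow(oracle_scan(sim$genome, kmer)), 15L)
})

test_that("arm read counts follow the arm ratio within sampling error", {
  sim <- simulate_genome(n_chrom = 1, chrom_len = 50000, n_mirna = 1,
                         n_clusters = 0, n_repeats = 0, n_decoys = 0,
                         seed = 5)
  truth <- sim$truth
  truth$mirnas$arm_w5 <- 3
  truth$mirnas$arm_w3 <- 1
  reads <- simulate_reads(sim$genome, truth, depth_per_mirna = 4000,
                          noise_reads = 0, seed = 5)
  u <- trim_adapter(collapse_reads(reads))
  m <- truth$mirnas[1, ]
  arm5 <- mirstack:::genome_slice(sim$genome, m$chrom, m$m5_start - 3,
                                  m$m5_end + 3, m$strand)
  from5 <- vapply(u$sequence, function(s) grepl(s, arm5, fixed = TRUE),
                  logical(1))
  frac5 <- sum(u$copy_number[from5]) / sum(u$copy_number)
  sigma <- sqrt(0.75 * 0.25 / 4000)
  expect_lt(abs(frac5 - 0.75), 3 * sigma)
})

test_that("a degenerate 1:0 arm ratio emits reads from the 5' arm only", {
  sim <- simulate_genome(n_chrom = 1, chrom_len = 50000, n_mirna = 1,
                         n_clusters = 0, n_repeats = 0, n_decoys = 0,
                         seed = 9)
  truth <- sim$truth
  truth$mirnas$arm_w5 <- 1
  truth$mirnas$arm_w3 <- 0
  reads <- simulate_reads(sim$genome, truth, depth_per_mirna = 100,
                          noise_reads = 0, seed = 9)
  u <- trim_adapter(collapse_reads(reads))
  m <- truth$mirnas[1, ]
  arm5 <- mirstack:::genome_slice(sim$genome, m$chrom, m$m5_start - 3,
                                  m$m5_end + 3, m$strand)
  expect_true(all(vapply(u$sequence, function(s)
    grepl(s, arm5, fixed = TRUE), logical(1))))
})

test_that("deep sequencing of one plant yields its isomiR variants with 3' variation", {
  sim <- simulate_genome(n_chrom = 1, chrom_len = 50000, n_mirna = 1,
                         n_clusters = 0, n_repeats = 0, n_decoys = 0,
                         seed = 4)
  truth <- sim$truth
  truth$mirnas$arm_w5 <- 1
  truth$mirnas$arm_w3 <- 0
  reads <- simulate_reads(sim$genome, truth, depth_per_mirna = 600,
                          noise_reads = 0, seed = 4)
  u <- trim_adapter(collapse_reads(reads))
  off <- truth$mirnas$offsets[[1]]
  m <- truth$mirnas[1, ]
  expected <- vapply(seq_len(nrow(off)), function(j) {
    iv <- mirstack:::shift_interval(m$m5_start, m$m5_end, m$strand,
                                    off$shift5[j], off$shift3[j])
    mirstack:::genome_slice(sim$genome, m$chrom, iv[1], iv[2], m$strand)
  }, character(1))
  expect_setequal(u$sequence, expected)
  expect_equal(nrow(u), 6L)
  # most end-variation is at the 3' end
  expect_gt(sum(off$prob[off$shift3 != 0]), sum(off$prob[off$shift5 != 0]))
})

test_that("catalog entries reflect n_species, naming dialect, and novelty", {
  sim <- tiny_sim(seed = 13)
  catalog <- simulate_catalog(sim$truth, sim$genome, seed = 13)
  m <- sim$truth$mirnas
  for (i in seq_len(nrow(m))) {
    fam_entries <- catalog$mature[catalog$mature$family == m$family[i], ]
    if (m$n_species[i] == 0) {
      expect_equal(nrow(fam_entries), 0L)
    } else {
      expect_equal(dplyr::n_distinct(fam_entries$species), m$n_species[i])
      expect_true(all(grepl("^[a-z]{3}-miR-", fam_entries$id)))
    }
  }
  # round trip through FASTA + arm TSV
  fa <- withr::local_tempfile(fileext = ".fa")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_catalog(catalog, fa, tsv)
  back <- read_catalog(fa, tsv)
  expect_setequal(back$mature$id, catalog$mature$id)
  expect_equal(nrow(back$arms), nrow(catalog$arms))
})

test_that("a catalog mature mutated beyond two substitutions is not matched", {
  sim <- simulate_genome(n_chrom = 1, chrom_len = 50000, n_mirna = 1,
                         n_clusters = 0, n_repeats = 0, n_decoys = 0,
                         seed = 21)
  m <- sim$truth$mirnas[1, ]
  mat <- mirstack:::genome_slice(sim$genome, m$chrom, m$m5_start, m$m5_end,
                                 m$strand)
  ch <- strsplit(mat, "")[[1]]
  for (p in c(3, 9, 15)) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  catalog <- tibble::tibble(id = "hsa-miR-999", sequence = paste(ch, collapse = ""))
  expect_true(is.na(match_known(mat, catalog)$catalog_id))
  expect_equal(oracle_edit_distance(mat, catalog$sequence), 3L)
})

test_that("truth tables survive a TSV/JSON round trip losslessly", {
  sim <- tiny_sim(seed = 17)
  dir <- withr::local_tempdir()
  write_truth(sim$truth, dir)
  back <- read_truth(dir)
  expect_equal(back$seed, sim$truth$seed)
  expect_equal(as.data.frame(back$mirnas), as.data.frame(sim$truth$mirnas))
  expect_equal(as.data.frame(back$repeats), as.data.frame(sim$truth$repeats))
  expect_equal(as.data.frame(back$decoys), as.data.frame(sim$truth$decoys))
})

test_that("placement failure raises an explicit error naming the element", {
  expect_error(
    simulate_genome(n_chrom = 1, chrom_len = 1500, n_mirna = 0,
                    n_clusters = 0, n_repeats = 1, repeat_copies = 40,
                    n_decoys = 0, seed = 1),
    "placement failure for repeat"
  )
})
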