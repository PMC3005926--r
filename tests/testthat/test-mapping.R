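test_that("exact-match mapping equals the naive full-genome scan", {
  sim <- tiny_sim(seed = 19)
  reads <- simulate_reads(sim$genome, sim$truth, depth_per_mirna = 100,
                          noise_reads = 20, seed = 19)
  u <- filter_read_length(trim_adapter(filter_copy_number(
    collapse_reads(reads))))
  idx <- genome_index(sim$genome)
  loci <- map_reads(idx, u)
  for (i in seq_len(nrow(u))) {
    got <- loci[loci$read_id == u$read_id[i],
                c("chrom", "start", "end", "strand")]
    want <- oracle_scan(sim$genome, u$sequence[i])
    expect_equal(dplyr::arrange(got, chrom, start, strand),
                 dplyr::arrange(want, chrom, start, strand),
                 ignore_attr = TRUE)
  }
})

test_that("planted matures map to exactly their truth loci", {
  sim <- simulate_genome(n_chrom = 1, chrom_len = 50000, n_mirna = 2,
                         n_clusters = 0, n_repeats = 0, n_decoys = 0,
                         seed = 6)
  idx <- genome_index(sim$genome)
  m <- sim$truth$mirnas
  for (i in seq_len(nrow(m))) {
    mat <- mirstack:::genome_slice(sim$genome, m$chrom[i], m$m5_start[i],
                                   m$m5_end[i], m$strand[i])
    u <- tibble::tibble(read_id = "r1", sequence = mat, copy_number = 1L)
    loci <- map_reads(idx, u)
    expect_equal(nrow(loci), 1L)
    expect_equal(loci$start, m$m5_start[i])
    expect_equal(loci$strand, m$strand[i])
    # reverse complement maps to the same interval on the other strand
    rc_loci <- map_reads(idx, tibble::tibble(read_id = "r2",
                                             sequence = revcomp(mat),
                                             copy_number = 1L))
    expect_equal(rc_loci$start, m$m5_start[i])
    expect_equal(rc_loci$strand, setdiff(c("+", "-"), m$strand[i]))
  }
})

test_that("absent reads, non-ACGT reads, and palindromes behave as specified", {
  genome <- mirna_genome(c(chr1 = paste0(
    random_dna_str(200), "GGGGGGAAATTTCCCCCC", random_dna_str(200)
  )))
  idx <- genome_index(genome)
  expect_equal(nrow(map_reads(idx, tibble::tibble(
    read_id = "r", sequence = strrep("AC", 10), copy_number = 1L))), 0L)
  expect_error(map_reads(idx, tibble::tibble(
    read_id = "r", sequence = "ACGTNACGTNACGTNACGTN", copy_number = 1L)),
    "non-ACGT")
  # a reverse-complement-palindromic read yields one locus per strand
  pal <- "GGGGGGAAATTTCCCCCC"
  expect_identical(pal, revcomp(pal))
  loci <- map_reads(idx, tibble::tibble(read_id = "r", sequence = pal,
                                        copy_number = 1L))
  expect_equal(nrow(loci), 2L)
  expect_setequal(loci$strand, c("+", "-"))
  expect_equal(unique(loci$start), 200L)
})

test_that("masked loci are excluded from mapping", {
  withr::local_seed(30)
  core <- random_dna_str(22)
  s <- paste0(random_dna_str(100), core, random_dna_str(100))
  masked <- mirna_genome(c(chr1 = s),
                         mask = tibble::tibble(chrom = "chr1", start = 100L,
                                               end = 122L))
  u <- tibble::tibble(read_id = "r", sequence = core, copy_number = 1L)
  expect_equal(nrow(map_reads(genome_index(masked), u)), 0L)
  open <- mirna_genome(c(chr1 = s))
  expect_equal(nrow(map_reads(genome_index(open), u)), 1L)
  # hard-masked (N) regions are excluded too
  s_n <- paste0(substr(s, 1, 110), "N", substr(s, 112, nchar(s)))
  expect_equal(nrow(map_reads(genome_index(mirna_genome(c(chr1 = s_n))), u)),
               0L)
})

test_that("the multi-locus filter keeps exactly ten and drops eleven", {
  withr::local_seed(31)
  core <- random_dna_str(22)
  make_genome <- function(copies) {
    mirna_genome(c(chr1 = paste0(
      paste(vapply(seq_len(copies), function(i)
        paste0(random_dna_str(50), core), character(1)), collapse = ""),
      random_dna_str(50))))
  }
  u <- tibble::tibble(read_id = "r", sequence = core, copy_number = 5L)
  ten <- map_reads(genome_index(make_genome(10)), u)
  expect_equal(nrow(ten), 10L)
  expect_equal(nrow(filter_multimappers(ten, 10)), 10L)
  eleven <- map_reads(genome_index(make_genome(11)), u)
  expect_equal(nrow(eleven), 11L)
  expect_equal(nrow(filter_multimappers(eleven, 10)), 0L)
})

test_that("repeat-derived reads are dropped while unique reads survive", {
  sim <- tiny_sim(seed = 23)
  reads <- simulate_reads(sim$genome, sim$truth, depth_per_mirna = 60,
                          noise_reads = 0, seed = 23)
  u <- filter_read_length(trim_adapter(filter_copy_number(
    collapse_reads(reads))))
  loci <- map_reads(genome_index(sim$genome), u)
  rep_read <- substr(sim$truth$repeats$unit[1], 11, 32)
  expect_equal(sum(loci$sequence == rep_read), 12L)
  kept <- filter_multimappers(loci, 10)
  expect_false(rep_read %in% kept$sequence)
  single <- loci$read_id[!duplicated(loci$read_id) &
                           !loci$sequence %in% rep_read]
  expect_true(all(single %in% kept$read_id))
})

test_that("coding-decoy identity filter matches the exhaustive oracle", {
  withr::local_seed(33)
  decoys <- vapply(1:3, function(i) random_dna_str(250), character(1))
  # exact 20-mer inside a decoy: identity 1.0 -> discarded
  inside <- substr(decoys[2], 100, 119)
  # 3 mismatches in 20 -> 0.85 -> kept
  ch <- strsplit(inside, "")[[1]]
  for (p in c(4, 10, 16)) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  mm3 <- paste(ch, collapse = "")
  u <- tibble::tibble(read_id = c("in", "mm"), sequence = c(inside, mm3),
                      copy_number = c(5L, 5L))
  out <- filter_coding_reads(u, decoys, 0.90)
  expect_equal(out$read_id, "mm")
  expect_equal(oracle_best_identity(inside, decoys), 1.0)
  expect_equal(oracle_best_identity(mm3, decoys), 0.85)
  # random reads: verdicts equal the exhaustive all-offset comparison
  reads <- vapply(1:25, function(i) random_dna_str(sample(18:25, 1)),
                  character(1))
  got <- best_decoy_identity(reads, decoys)
  want <- vapply(reads, oracle_best_identity, numeric(1), decoys = decoys,
                 USE.NAMES = FALSE)
  expect_equal(got, want)
  # empty decoy set is the identity operation
  expect_identical(filter_coding_reads(u, character(0)), u)
})
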