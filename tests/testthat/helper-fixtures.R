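# Shared fixtures, built in code at test time.

# Small simulation for module-level tests (fast: ~60 kb, 6 plants).
tiny_sim <- function(seed = 7, ...) {
  simulate_genome(n_chrom = 1, chrom_len = 60000, n_mirna = 4,
                  n_clusters = 1, cluster_size = 2, n_repeats = 1,
                  repeat_copies = 12, n_decoys = 1, seed = seed, ...)
}

# Cache one default-scale pipeline run per seed: several tests inspect it.
default_run <- local({
  cache <- list()
  function(seed = 7) {
    key <- as.character(seed)
    if (is.null(cache[[key]])) {
      sim <- simulate_genome(seed = seed)
      reads <- simulate_reads(sim$genome, sim$truth, seed = seed)
      catalog <- simulate_catalog(sim$truth, sim$genome, seed = seed)
      cfg <- mirna_config(genome = sim$genome, reads = reads,
                          catalog = catalog, decoys = sim$truth$decoys,
                          truth = sim$truth, seed = seed)
      cache[[key]] <<- list(sim = sim, reads = reads, catalog = catalog,
                            config = cfg,
                            result = run_mirna_pipeline(cfg))
    }
    cache[[key]]
  }
})

# A hairpin with a provably unique optimal structure: 60 G:C stem pairs
# around a 4 nt loop. The mature occupies the first 22 nt of the 5' arm.
perfect_hairpin <- function() {
  paste0(strrep("G", 60), "AAAA", strrep("C", 60))
}

# Build a folded/featurized candidate row by hand.
manual_candidate <- function(precursor, mature_offset, mature_len,
                             chrom = "chr1", strand = "+", prec_start = 1000,
                             copy_number = 10L, read_id = "read_x") {
  f <- fold_rna(precursor)
  cand <- tibble::tibble(
    read_id = read_id,
    sequence = substr(precursor, mature_offset + 1,
                      mature_offset + mature_len),
    copy_number = copy_number,
    chrom = chrom,
    start = prec_start + mature_offset,
    end = prec_start + mature_offset + mature_len,
    strand = strand,
    prec_start = prec_start,
    prec_end = prec_start + nchar(precursor),
    precursor_seq = precursor,
    mature_offset = mature_offset,
    structure = f$structure,
    pairing_score = f$score
  )
  hairpin_features(cand)
}
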