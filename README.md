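# mirstack

Genome-wide microRNA discovery and characterization from small-RNA
sequencing read stacks, for species without a curated miRNA catalog.

Short-read small-RNA libraries contain millions of ~22 nt reads. For a
model organism with no registered miRNAs, every mapped locus is a potential
miRNA and must be evaluated from sequence and structure alone. `mirstack`
implements that evaluation as a reusable, fully testable pipeline:

1. **Read processing** — reads are collapsed to unique sequences with copy
   numbers; unique reads with copy number ≥ 3 are kept, the 3' adapter is
   trimmed (exact suffix/prefix overlap), and reads of 18–25 nt survive.
2. **Mapping and exclusion** — reads are mapped to the genome by perfect
   match on both strands (k-mer index, no mismatch or gap). Reads with best
   ungapped identity > 90% to a coding-transcript decoy set, reads in
   soft/hard-masked intervals, and reads mapping to more than ten loci are
   discarded.
3. **Hairpin candidates** — each locus is extended ±60 nt into a ~140 nt
   candidate precursor and folded by a weighted base-pair maximization
   dynamic program (Nussinov recursion; GC = 3, AU = 2, GU = 1, minimum
   loop 3). Each (mature, precursor) pair yields ten structural features
   f₁…f₁₀ (length, GC content, pairing score and density, paired fractions,
   loop length, mature bulge, arm position).
4. **Classification** — an RBF-kernel SVM separates hairpin candidates from
   genomic background. Each candidate's p-value is the empirical
   probability of a positive call by mistake,
   p = (1 + #{calibration negatives ≥ score}) / (n + 1),
   and candidates with p < 0.05 are positive.
5. **Assembly and annotation** — overlapping positives on one strand merge
   into pre-miRNAs carrying per-arm **isomiR** stacks (5p/3p by midpoint
   side of the terminal loop). Pre-miRNAs split into a homolog set (**Mh**,
   any isomiR within edit distance 2 of a catalog mature) and a novel set
   (**Mn**).
6. **Characterization** — genomic clusters (inter-precursor gap ≤ 10 kb),
   arm-selection categories (5P only / 3P only / 5P dominant / 3P dominant /
   equal, dominance ratio 2), cross-species arm-difference classes 1–3, and
   the conservation-versus-expression analysis: families sorted by
   conservation level (number of catalog species), split into quarters
   Q1–Q4, log₁₀ expression compared between adjacent quarters by Welch
   t-tests.

A first-class **synthetic-data module** generates genomes with planted
hairpins (singly and in clusters), repeat elements, coding decoys, and
multinomial read stacks with configurable arm ratios and isomiR offset
distributions — with a lossless truth table, so every stage is testable
end to end without any download.

## Worked example

```r
library(mirstack)

sim     <- simulate_genome(seed = 7)                       # 24 planted miRNAs, 2 clusters
reads   <- simulate_reads(sim$genome, sim$truth, seed = 7) # ~600 reads per miRNA + noise
catalog <- simulate_catalog(sim$truth, sim$genome, seed = 7)

config <- mirna_config(genome = sim$genome, reads = reads, catalog = catalog,
                       decoys = sim$truth$decoys, truth = sim$truth, seed = 7)
result <- run_mirna_pipeline(config)

dplyr::select(result$summary, n_mappable_reads, n_mappable_unique_reads,
              n_mappable_loci, n_premirna, n_isomir)
#> # A tibble: 1 × 5
#>   n_mappable_reads n_mappable_unique_reads n_mappable_loci n_premirna n_isomir
#>              <int>                   <int>           <int>      <int>    <int>
#> 1            14398                     227             227         24      227
```

14,398 of the simulated reads survive all filters and map; the 227 unique
isomiR sequences collapse onto 24 predicted pre-miRNAs. Each pre-miRNA
carries its isomiR stack, homolog/novel label, family, and arm category:

```r
dplyr::select(result$premirnas, mirna_id, chrom, start, end, strand,
              n_isomirs, set, family, arm_category)[1:5, ]
#>   mirna_id chrom start   end strand n_isomirs set   family  arm_category
#> 1 Mh1      chr1    812   956 -              6 Mh    mir-101 5P_only
#> 2 Mh2      chr1   2644  2788 -              6 Mh    mir-102 3P_only
#> 3 Mn1      chr1   3858  4036 +             12 Mn    <NA>    5P_dominant
#> 4 Mh3      chr1  16863 17045 +             12 Mh    mir-104 3P_dominant
#> 5 Mh4      chr1  29825 30007 +             12 Mh    mir-105 equal

result$clusters
#>   cluster_id chrom start   end n_members
#> 1 cluster_1  chr1    812  4036         3
#> 2 cluster_2  chr2    964  4313         3

evaluate_discovery(result, sim$truth)
#>   recall precision arm_accuracy cluster_recovery conservation_exact
#> 1      1         1            1                1                  1
```

Every planted miRNA is recovered with no false positives; arm categories,
both planted clusters, and the planted conservation levels are recovered
exactly. The conservation-expression analysis on a simulated 2-log
expression gradient:

```r
ce <- conservation_expression(
  simulate_family_records(n_families = 98, gradient = 2, sigma = 0.5, seed = 7))
tidy(ce)
#>   pair  estimate statistic    df  p_value
#> 1 Q1Q2      1.98      16.0  47.7 7.29e-21
#> 2 Q2Q3      2.11      15.8  46.4 2.67e-20
#> 3 Q3Q4      1.88      14.7  44.4 1.27e-18
autoplot(ce)   # quartile box plot
```

Adjacent quarters differ by ~2 log units with overwhelming significance —
more conserved families are more abundant, as planted.

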