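---
title: "Methods: miRNA discovery and characterization with mirstack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA discovery and characterization with mirstack}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mirstack)
```

## The problem

MicroRNAs are ~22 nt endogenous regulators excised from ~60–140 nt
stem-loop precursors. In a species with no curated miRNA catalog, a
small-RNA sequencing library cannot be annotated by lookup: every genomic
locus that accumulates a stack of identical reads is a candidate, and the
call must be made from copy number, mapping behaviour, and hairpin
structure. `mirstack` implements that discovery pipeline together with the
downstream characterization analyses (isomiR stacks, genomic clusters,
arm-selection preference, conservation versus expression), and ships a
synthetic-data generator with a full truth table so that the whole chain is
verifiable without external data.

## Pipeline model and assumptions

The pipeline assumes error-free perfect-match evidence: a read supports a
locus only if it is completely identical to the genome there, with no
mismatch or gap. Reads that disagree with the genome are treated as noise
and discarded by construction, which also means RNA-editing variants are
not modelled. All coordinates are 0-based half-open (BED convention);
sequences are normalized to the DNA alphabet (U→T) on input.

Stage order matters and is fixed: collapse → copy-number filter → adapter
trim → length filter → mapping → coding-decoy exclusion → multi-locus
exclusion → precursor extraction → folding → features → classification →
assembly → annotation → characterization. The copy-number filter runs
*before* trimming, so abundance is measured on the raw unique read.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_copies` | 3 | minimum copy number of a unique read (inclusive) |
| `min_len`, `max_len` | 18, 25 | kept read lengths after trimming, nt (inclusive) |
| `min_overlap` | 6 | minimum exact adapter suffix/prefix overlap, nt |
| `min_identity` | 0.90 | reads strictly above this ungapped identity to any coding decoy are dropped |
| `max_loci` | 10 | reads mapping to more loci are dropped; exactly 10 survives |
| `flank` | 60 | precursor extension per side, nt (~140 nt windows) |
| `alpha` | 0.05 | positive-call p-value threshold |
| `max_variations` | 2 | edit distance defining the homolog (Mh) set |
| `cluster_window` | 10000 | maximum inter-precursor gap within a cluster, bp (inclusive) |
| `dominance_ratio` | 2.0 | arm copy ratio at which one arm is "dominant" |

The thresholds are the method: they are all surfaced in `mirna_config()`
with these defaults.

The adapter overlap minimum (6 nt) and the identity denominator (read
length, not alignment length; forward strand; ungapped, since reads are
≤ 25 nt) are configuration decisions of this package, not literature
constants; both are exposed as arguments.

## Folding and the ten features

Candidate precursors are folded with an in-package Nussinov-style dynamic
program maximizing the summed pair weight (GC = 3, AU = 2, GU wobble = 1)
with a minimum hairpin loop of 3 unpaired nt. The traceback is
deterministic: the 5' base pairs with its smallest admissible partner among
optimal choices, otherwise it stays unpaired; ties therefore never
introduce run-to-run variation. The score is a *pairing score*, not a free
energy; the backend is deliberately simple so that it can be verified
against exhaustive structure enumeration for sequences up to 25 nt (the
test suite does exactly that). One caveat follows from the wobble weight:
the optimal score is not invariant under reverse complement (a G:U pair
maps to an unpairable C:A), so the invariance property is only exact — and
only tested — on Watson–Crick-only alphabets. Sequences with more than 10%
`N` are refused; `N` never pairs.

The ten features of a (mature, precursor) pair are a classical structural
description: precursor length (f1), precursor GC fraction (f2), pairing
score (f3) and score per nucleotide (f4), fraction of precursor (f5) and
of mature (f6) bases paired, terminal-loop length of the most deeply
stacked hairpin (f7), longest unpaired run inside the mature (f8), mature
GC fraction (f9), and the mature's arm position relative to the loop
midpoint, scaled to [−1, 1] (f10). The set was fixed as part of this
package's design: the classifier architecture requires exactly ten
concrete, reproducible inputs, and these ten separate planted hairpins
from genomic background with AUC > 0.9 on f4 alone at default generator
settings.

## Classification and calibrated p-values

An RBF-kernel SVM (`e1071::svm`, cost 10, gamma 0.1, feature scaling on)
is trained on labeled feature vectors; 30% of each class is held out. The
held-out negatives' decision scores form the calibration table, and a
candidate's p-value is the add-one-smoothed fraction of calibration scores
at least as high as its own — the empirical probability that a candidate
would be classified positive by mistake. Positives are candidates with
p < `alpha`. This empirical definition needs no parametric assumption and
is exactly uniform for null candidates, which the suite checks with a
Kolmogorov–Smirnov test.

At desk scale, training data comes from the truth table: planted precursor
windows (each augmented with two ±3–12 nt jittered windows so that the
≥ 50-examples-per-class training contract holds with ~24 plants) against
random genomic windows that avoid planted precursors. With real data, any
labeled feature set can be supplied through the same
`train_classifier()` / `classify_candidates()` interface.

## Assembly, arms, and annotation

Positive candidates whose precursor windows overlap on the same chromosome
and strand merge into one pre-miRNA (union interval). Every retained
unique read becomes one isomiR with its copy number and p-value. Arms are
assigned against the terminal loop of the most abundant member's hairpin:
isomiRs whose midpoint falls left of the loop are 5p, right of it 3p, and
midpoints inside the loop are flagged loop-spanning and excluded from arm
statistics (a deliberate tie rule — they are rare and ambiguous).

Homology ("Mh") is defined per isomiR at mature level: a pre-miRNA is a
homolog iff any isomiR is within edit distance 2 of a catalog mature.
Edit distance (substitutions *and* indels) rather than Hamming distance is
used because isomiRs vary in length; matching at the mature rather than
precursor level follows from that definition operating on isomiRs. Ties
are broken by lower distance, then lexicographic catalog id, so annotation
is deterministic. Family names strip the species prefix, arm markers
(`-5p`/`-3p`/`*`) and trailing numeric locus suffixes while keeping
lettered paralogs (`let-7b` ≠ `let-7a`); conservation level is the number
of distinct catalog species carrying the family.

## Characterization decisions

*Clusters.* Membership is strand-agnostic (clusters may mix strands, each
member keeps its own strand) with the gap measured end-to-start against
the running maximum end, inclusive at 10,000 bp. This sweep is exactly
single-linkage over the "within 10 kb" graph, and the suite checks it
against an all-pairs O(n²) oracle. Single pre-miRNAs are not clusters.

*Arm preference.* Five categories partition profiled pre-miRNAs. The
boundary between "dominant" and "equal abundance" is not quantified in the
literature this implements; a copy ratio of ≥ 2 was declared (and exposed
as `dominance_ratio`) because the five categories are only computable with
a concrete threshold. Cross-species differences use the ortholog's
per-arm annotation (major/minor/absent): class 1 (candidate both arms,
ortholog one), class 2 (candidate one, ortholog both), class 3 (exactly
opposite single arms), else concordant; the classification is symmetric
under a global 5p/3p relabeling.

*Conservation versus expression.* Families are sorted by ascending
conservation level with the family name as a deterministic tiebreak and
split into four contiguous quarters, remainder to the earlier quarters.
The statistic is log₁₀ of the family's expression level (the copy number
of its most abundant isomiR; no pseudo-count is needed because the
copy-number filter guarantees expression ≥ 3). Adjacent quarters are
compared with Welch's two-sample t-test: the quarters have no reason to
share a variance, and Welch is the conservative default; log base 10 was
chosen to match how expression spans are usually reported. With four
groups the three tests are reported unadjusted, as a trend description
rather than a family of confirmatory hypotheses.

## The synthetic-data generator

`simulate_genome()` plants hairpins built as a random 5' arm (58–66 nt,
mature 18–25 nt adjacent to the loop), an 8–15 nt loop, and a 3' arm that
is the reverse complement of the 5' arm with ~10% point mutations
(realistic bulges). One mutation is forced into the central mirrored
mature window so no mature or end-variant can also match the opposite arm
on the reverse strand — planted matures are provably unique in the genome
(verified at generation time). Precursors land singly (> 10 kb apart) or
in clusters (members ~0.8–1.8 kb apart), on either strand. A repeat
element is copied identically to ≥ 12 loci so the multi-locus filter
fires, and coding decoys (≥ 200 nt genomic intervals) are exported as the
decoy transcript set. Repeats are *not* soft-masked by default: they stand
for repeat-like elements that a masker would miss, which is precisely what
the more-than-ten-loci filter exists for; `mask_repeats = TRUE` produces
lowercase (excluded) repeats instead.

`simulate_reads()` draws a multinomial stack per miRNA: arms weighted by
the planted arm ratio, end-variants by an isomiR offset distribution that
concentrates variation at the 3' end (55% canonical, ~40% 3'-shifted, 4%
5'-shifted). Reads are the isomiR plus adapter, truncated to the 35 nt
platform length, error-free (sequencing errors would only create discarded
reads under perfect-match mapping, so simulating them adds nothing the
filters do not already see via noise reads). Noise reads are random
sequences verified absent from the genome; repeat- and decoy-derived reads
exercise the exclusion filters. `simulate_catalog()` emits, for each
family with `n_species ≥ 1`, that many species' entries with ≤ 2
substitutions from the planted mature, named in the registry dialect, plus
the per-precursor arm annotation used by the difference-class analysis.
The RNA sample is modelled as a single pooled condition; tissue mixtures
and expression dynamics are out of scope.

What passing tests on this generator do **not** show: performance on real
genomes (repeat structure, base composition, and assembly artifacts are
far richer), robustness to sequencing error or adapter variants, behaviour
when most mappable reads are other non-coding RNA classes (the synthetic
read share captured by miRNA candidates is near 100%, where real libraries
sit far lower), and any coupling between conservation and expression —
the generator leaves them independent, which is why the quartile analysis
is validated on `simulate_family_records()` gradients instead.

## Numerical choices and degenerate inputs

Percentages are rounded half-up to one decimal (`29.25 → 29.3`), matching
hand-computed table arithmetic rather than banker's rounding. "Mappable"
counts (reads, unique reads, loci) are taken after the exclusion filters,
i.e. the set entering candidate extraction. Empty inputs propagate as
empty tibbles and an all-zero summary, never as errors; a missing genome
or read input is a configuration error raised before any compute.
Placement failures in the simulator (bounded retries) name the element
type. The degenerate folding inputs — sequences shorter than the minimum
loop span, all-`N` windows — return the empty structure or are refused as
described above.

## Problem sizes

The default study conditions are 24 planted miRNAs (two 3-member clusters)
on two 150 kb chromosomes, 600 reads per miRNA, one repeat at 15 copies,
two decoys, and three independent seeds — sizes at which every planted
structure is comfortably detectable and a full pipeline run takes well
under a minute. The quartile statistics are validated on 98-family tables
over 100 simulations (gradient 2 log units, σ = 0.5, versus the matching
null).

## Known limitations

The folder is a base-pair maximizer, not a thermodynamic model: it
over-pairs random sequence relative to an energy model, which the
classifier absorbs but which makes absolute pairing scores incomparable to
free energies. Multi-hairpin (polycistron-like) windows yield one terminal
loop (the most deeply stacked), so isomiRs of a secondary hairpin in the
same window would be arm-assigned against the primary one. Homology uses
global edit distance over full-length matures; seed-region (positions 2–8)
matching and phylogenetic family inference are out of scope, as are
mirtron discovery and colorspace data.
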