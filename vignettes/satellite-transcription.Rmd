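---
title: "Detecting satellite DNA and measuring its tissue-level transcription"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting satellite DNA and measuring its tissue-level transcription}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satscribe)
```

## What this package computes

Satellites are tandem head-to-tail arrays of a short DNA unit. In
nematode genomes they are abundant, mostly interspersed rather than
centromeric, and — as tissue-resolved RNA-seq has made visible — many of
them are transcribed, unevenly along the array and with strong tissue
bias. `satscribe` implements the complete computational path from a
genome FASTA and a set of single-end RNA-seq samples to per-satellite,
per-tissue transcription estimates:

1. **Detection** — find arrays with unit length 10–200 nt repeated at
   least four times, from clusters of repeated primitive decamers.
2. **Families** — group satellites whose repeat consensuses align above a
   normalized score threshold, allowing cyclic rotation and reverse
   complement, and name them `Fam_a_b_c`.
3. **Annotation** — classify each satellite as intergenic, intronic or
   exonic against gene models, and flag overlap with transposon
   (e.g. Helitron) annotation.
4. **Quantification** — match reads to satellite ± 250 nt windows at
   ≥ 97 % identity, keep only maximum-accuracy hits per read, count per
   sample, sum per tissue, and normalize as
   RPKM = hits · 10⁹ / (satellite length) / (library size).
5. **Coverage profiles** — per-nucleotide hit depth across
   flank–satellite–flank, one colored track per tissue.
6. **Synthetic scenes** — a seeded generator that plants satellites, gene
   models, Helitron-style loci and tissue-stratified reads with full
   ground truth, so each stage above is testable without any downloads.

## Detection model

The seed stage scans for decamers (`k = 10`) occurring at least
`min_copies = 4` times within some window of `window_nt = 800` bases.
Those bounds imply the detectable unit range: four copies of a 200-nt
unit just fit an 800-nt window, and units below 10 nt cannot carry a
primitive decamer in phase. Decamers that are whole-number tandems of a
shorter unit (period ≤ 5) are excluded as seeds — without this,
microsatellite-degenerate seeds such as poly-A or AC-dimers dominate the
cluster list. Overlapping seed windows from any decamer merge into one
candidate region.

Delimitation turns a candidate region into a satellite record:

* **Unit length** is the modal spacing between consecutive occurrences
  of the clustered decamers, ties broken toward the smaller length.
* **Phase** is anchored on the most frequent decamer, restricted to its
  dominant phase class (mod unit length); this keeps a chance occurrence
  of the anchor in flanking background from skewing the frame.
* A **consensus unit** is the per-column majority over the anchor-phase
  windows.
* **Boundaries** are first extended one unit at a time while the next
  unit-length window matches the consensus at
  `extension_min_identity = 0.7` (a value that tolerates the divergence
  observed inside real arrays yet stops quickly in random flank, where
  expected identity is 0.25), then refined to the first/last run of
  `min(10, L)` consecutively matching bases. The run rule makes
  boundaries exact on noise-free arrays, because a 10-base chance
  continuation in random sequence has probability ≈ 10⁻⁶, while at 5 %
  per-base noise it concedes at most a few bases (the fallback accepts a
  run with ≥ 80 % matches when no clean run exists near the coarse
  boundary).
* **Copies** are partitioned greedily; at each step the copy length may
  deviate from the unit by up to ±3 nt (indels), choosing the length
  that maximizes matches to the consensus *normalized by the longer of
  the two lengths compared*. The normalization matters: dividing by the
  compared length instead lets a single mutated trailing base favour a
  one-shorter copy and cascade the frame through the rest of the array.
* A record is kept when the unit is in 10–200 nt, at least 4 copies
  remain, and at least 60 % of copies have the modal length
  (`min_same_length_frac = 0.6`); the similarity statistic is the mean
  ungapped pairwise identity over same-length copies (N matches
  nothing).

Coordinates are 1-based inclusive throughout — the native convention of
IRanges/GenomicRanges, and also the style of reported satellite tables,
so no internal/external conversion exists to get wrong. Detection runs
on the forward strand only; a tandem array is its own
reverse-complement's array, and strand only becomes meaningful when
comparing units across satellites.

## Family model

Each satellite's repeat consensus is the per-column majority over the
unit-length windows obtained by chopping its sequence from the start.
Chopping (rather than re-using the detector's internal copy partition)
makes the consensus a deterministic function of the satellite table
alone, so families computed from a re-read TSV are identical.

The pairwise score of two units `a`, `b` is a global
Needleman–Wunsch alignment (match +1, mismatch −1, linear gap −2) of `a`
against every cyclic rotation of `b` and of its reverse complement; the
maximum raw score is divided by the maximum achievable score — a perfect
match of the shorter unit — and clamped to [0, 1]. This normalization
gives self-score 1 and pushes unrelated units toward 0. Arg-max ties
break toward the smallest rotation index, then the forward strand. Pairs
whose unit lengths differ by more than 25 % of the longer one are
assigned score 0 without alignment; the cutoff keeps the commonly
observed 31–35 nt within-family length spread mergeable while skipping
hopeless comparisons (e.g. 35 vs 94 nt) cheaply. The rotation loop runs
in C++ (Rcpp); an exhaustive R implementation on top of
`Biostrings::pairwiseAlignment` serves as the independent oracle in the
test suite.

Families are built by agglomerative average-linkage merging on the score
matrix, joining the best pair of clusters while its score is at least
`threshold = 0.6`, with deterministic lowest-index tie-breaks; the
partition coincides with cutting an average-linkage dendrogram of
`1 − score` at height 0.4, which is exactly how the suite cross-checks
it. Names follow `Fam_a_b_c`: rank `a` in decreasing member count (ties:
smaller repeat size, then genome position of the first member), `b` the
family consensus length, `c` the member count; `c = 1` marks a unique
satellite.

## Annotation

A satellite overlapping any exon by ≥ 1 nt is `exon`; otherwise
overlapping any gene span, `intron`; otherwise `intergenic`. Exons are
pooled across transcripts, which is equivalent to a per-gene exon union
under overlap queries. Satellites on chromosomes missing from the
annotation classify as intergenic with a warning. Repeat annotation
(BED) overlap is reported as the labels of all touching intervals.

## Quantification

Reference windows add 250 nt of genomic flank on each side of the
satellite (clipped at contig ends) to avoid edge artifacts: reads
straddling an array boundary still align fully. Read matching is
seed-and-extend: exact 12-mer seeds anchor a diagonal, the read is
extended ungapped along it, and a hit is kept when identity over the
aligned region is ≥ 0.97 and the aligned length covers ≥ 90 % of the
read. The coverage bound is needed because "matched part of a satellite"
otherwise sets no read-side limit; it is configurable. Both read
orientations are searched (libraries treated as unstranded, and the
profiled libraries were not polyA-selected). Gaps are not modeled in the
extension — the simulator's default error model is substitution-only,
and on such reads the ungapped optimum coincides with the full
dynamic-programming optimum (mismatch −1 beats two gaps at −2 each),
which the suite verifies read-by-read against a global-local
`pairwiseAlignment` oracle.

Because family members are near-identical, a read often matches several
windows. All hits tied at the per-read maximum identity are counted, one
per window: it cannot be known which of the tied satellites was
transcribed, so each candidate receives the count. Within one window a
read from a perfect array also ties at every unit offset; the matcher
reports the leftmost equivalent placement (deterministically), so
*positional* structure inside an array is only identifiable when copies
carry some divergence — which real satellites do, and which the
simulator reproduces via its per-copy substitution rate.

Per-sample RPKM uses the satellite length (flanks excluded) and the
sample's total read count as library size. Tissue totals are sums over
the tissue's samples, and tissue RPKM is the *sum* of per-sample RPKM
values, not a recomputation from pooled counts. A satellite counts as
positively transcribed in a tissue when its tissue RPKM exceeds that
tissue's mean RPKM over all satellites — a self-calibrating criterion
that avoids choosing an absolute noise floor.

Coverage profiles stack the retained hits per nucleotide and per tissue,
with the conventional palette: grey muscle, blue neurons, red intestine,
green hypodermis. Pooled counts (not per-sample means) form the
ordinate, matching how tissue totals are defined.

## The synthetic scene

`default_scene()` is the package's study condition generator. Three
family master units of 35, 45 and 94 nt spawn 9, 7 and 4 members; each
member's unit carries exactly round(0.05 · L) substitutions relative to
its master (at least 2), randomly rotated and strand-flipped. The fixed
substitution count, rather than a per-base Bernoulli draw, pins the
divergence the scene is meant to embody: members are distinguishable to
the read matcher (cross-member identity ≈ 0.90 < 0.97) while
within-family scores (≈ 0.8) stay far above the 0.6 clustering
threshold, with no heavy tail that could push an outlier member outside
its own family or leave two members identical. Twenty arrays
with 4–60 copies are planted 7 kb apart across two ~76 kb chromosomes,
with location classes 12 intergenic / 5 intron / 3 exon, at zero
within-array noise by default. Expression weights are neuron-biased
overall, with one hypodermis-dominant and one intestine-dominant
satellite, and the longest satellite's transcription concentrated on its
middle third; four tissues × two samples × 400 reads of 100 nt are
drawn, unstranded and error-free by default. These sizes keep a full
end-to-end run around half a minute on one CPU while leaving every
stage's statistics testable.

Two generator design points deserve note:

* **Family members are pairwise distinct.** Member units are redrawn
  until each differs from its siblings at ≥ 2 sites. Identical members
  would tie every read drawn from either of them, and the planted
  per-satellite counts would no longer be a well-defined truth (tied
  reads legitimately count toward every tied satellite).
* **Planted arrays are maximal.** After planting, the base on each side
  of an array is resampled if it happens to continue the periodic
  pattern. Without this, "the planted boundary" is not a well-defined
  ground truth — the true tandem array would genuinely extend one base
  further, and no detector could (or should) return the planted
  coordinate.
* **Everything is a pure function of (spec, seed).** Identical seeds
  give byte-identical FASTA/GFF3/FASTQ output, which the suite asserts.

What the scene does *not* emulate: chromosome-scale composition, real
Helitron sequence content (only the structural layout of a complete
element — 15-nt satellite, 32-nt satellite, 5′ conserved region, central
gene, 31-nt satellite abutting the gene, 3′ conserved region — is
reproduced), indel sequencing errors (configurable but off), polyA
selection effects, and spliced or paired-end reads. Passing tests
therefore demonstrate correctness of the algorithms under the stated
error model, not robustness to every artifact of real libraries.

## Numerical and degenerate-input choices

* Consensus votes break ties in the fixed base order A < C < G < T.
* `repeat_similarity` is undefined (NA) with fewer than two same-length
  copies.
* Empty genomes or windows yield empty results, not errors; zero
  satellite length or library size in the RPKM formula is an error.
* Best-hit ties compare identities with a 10⁻⁹ tolerance (identities are
  small-integer ratios, so genuine ties are exact).
* Nested or duplicate detections keep the longer span.
* K-mers containing N never seed; N never matches in any comparison.
* Agglomeration and naming are fully deterministic, so family tables are
  byte-identical across reruns.

## Worked example

```{r example, eval = FALSE}
sc <- default_scene(seed = 42)
sats <- detect_satellites(sc$truth$genome)
fam <- cluster_families(sats, threshold = 0.6)
fam$families[, c("family_name", "repeat_size", "n_members")]
#>  family_name repeat_size n_members
#>   Fam_1_35_9          35         9
#>   Fam_2_45_7          45         7
#>   Fam_3_94_4          94         4

w <- build_reference_windows(fam$satellites, sc$truth$genome)
ht <- quantify_samples(w, sc$samples, reads = sc$reads$reads)
ts <- summarize_by_tissue(ht)
ts$transcribed["chrI_3000", ]   # the planted hypodermis-dominant array
#> hypodermis  intestine    neurons     muscle
#>       TRUE      FALSE      FALSE      FALSE
```

## Known limitations

* The detector reports one satellite per merged seed region; two
  different-unit arrays closer than a seed window would merge, with the
  dominant spacing winning.
* Higher-order repeat structure is not modeled, and there is no
  repeat-library masking mode.
* Boundary refinement can concede up to about one unit at 5 % per-base
  divergence, occasionally trimming a heavily mutated terminal copy (the
  copy count is then one below truth).
* The read matcher is ungapped along its diagonal; reads with true
  indels would need the (configurable) oracle-style aligner instead.
* Counts of multi-mapped reads are intentionally duplicated across tied
  satellites; summed counts are therefore an upper bound on distinct
  retained reads.
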