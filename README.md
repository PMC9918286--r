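# satscribe

Satellite DNA — tandem head-to-tail arrays of a short repeat unit — makes
up a few percent of many genomes, and tissue-resolved RNA-seq shows that a
surprising number of these arrays are transcribed: unevenly along the
array, and with strong tissue bias. `satscribe` is an R package for
researchers who want to go from a genome FASTA plus single-end RNA-seq
samples to per-satellite, per-tissue transcription estimates, with every
stage testable on seeded synthetic data carrying planted ground truth.

The pipeline:

1. **Detect** satellites (unit 10–200 nt, ≥ 4 copies) from clusters of
   repeated primitive decamers in 800-nt windows, delimit each array,
   infer its unit length, copy number and a similarity statistic, and
   keep arrays with ≥ 60 % same-length copies.
2. **Cluster** satellites into families by cyclic-rotation- and
   reverse-complement-aware global alignment of their repeat consensuses
   (match +1, mismatch −1, gap −2, normalized by the shorter unit),
   merged by average linkage down to a 0.6 score threshold and named
   `Fam_a_b_c` (rank / repeat size / member count; `c = 1` = unique).
3. **Annotate** each satellite as intergenic / intron / exon against gene
   models (priority exon > intron > intergenic) and flag overlaps with
   transposon (Helitron) intervals.
4. **Quantify** transcription: reads are matched to satellite ± 250 nt
   windows at ≥ 97 % identity (seed-and-extend, both strands), only the
   hit(s) with maximum accuracy per read are counted, counts are summed
   per tissue, and normalized as

   RPKM = hits · 10⁹ / (satellite length in nt) / (library size)

5. **Profile** per-nucleotide hit depth over flank–satellite–flank, one
   colored track per tissue (grey muscle, blue neurons, red intestine,
   green hypodermis).
6. **Simulate** complete scenes — genomes with planted imperfect arrays,
   gene models, Helitron-style loci and tissue-stratified FASTQ reads —
   as pure functions of a seed, with full ground truth.

## Worked example

```r
library(satscribe)

sc   <- default_scene(seed = 42)          # synthetic study scene
sats <- detect_satellites(sc$truth$genome)
head(sats[, 1:8], 3)
#>  satellite_id chrom start   end length n_repeats repeat_length similarity
#>     chrI_3000  chrI  3000  5294   2295        51            45          1
#>    chrI_10000  chrI 10000 11014   1015        29            35          1
#>    chrI_17000  chrI 17000 18503   1504        16            94          1

fam <- cluster_families(sats, threshold = 0.6)
fam$families[, c("family_name", "repeat_size", "n_members")]
#>  family_name repeat_size n_members
#>   Fam_1_35_9          35         9
#>   Fam_2_45_7          45         7
#>   Fam_3_94_4          94         4

w  <- build_reference_windows(fam$satellites, sc$truth$genome)
ht <- quantify_samples(w, sc$samples, reads = sc$reads$reads)
ts <- summarize_by_tissue(ht)
ts$transcribed["chrI_3000", ]
#> hypodermis  intestine    neurons     muscle
#>       TRUE      FALSE      FALSE      FALSE
```

The detected table reproduces the planted coordinates exactly; the three
families are the three planted master units (9, 7 and 4 members); and the
`chrI_3000` array — planted with hypodermis-dominant expression — is the
one flagged transcribed in hypodermis (a satellite is flagged when its
tissue RPKM exceeds that tissue's mean over satellites).

Coverage figures:

```r
pr <- coverage_profile(w[1, ], do.call(rbind, ht$hits), sc$samples)
render_profile(pr, "chrI_3000.png")
```

A thin command-line wrapper is installed under `inst/cli/satscribe.R`
(subcommands `detect`, `families`, `annotate`, `quantify`, `profile`,
`simulate`).

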