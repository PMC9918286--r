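## The default synthetic study scene and the end-to-end pipeline wrapper.
## The scene parameters (20 satellites in 3 families across 2 chromosomes,
## units 35/45/94 nt, 4-60 copies, 12 intergenic / 5 intronic / 3 exonic,
## 4 tissues x 2 samples x 400 reads) echo, at desk scale, the diversity of
## satellite sizes, family structure and tissue bias seen in nematode
## satellite surveys.

#' Build the default synthetic scene
#'
#' Three family master units (35, 45 and 94 nt) spawn 9, 7 and 4 member
#' satellites; each member's unit is the master mutated at
#' `member_divergence`, randomly rotated and strand-flipped, so the planted
#' family partition is recoverable by cyclic alignment. Arrays are planted
#' at zero copy noise by default, spread over two chromosomes, with
#' location classes 12 intergenic / 5 intron / 3 exon. Expression weights
#' are neuron-biased overall with one hypodermis-dominant and one
#' intestine-dominant satellite; one satellite's transcription is
#' concentrated on its middle third.
#'
#' @param seed integer seed driving every random choice
#' @param sub_rate per-base substitution rate of the planted copies
#' @param indel_rate per-copy single-base indel rate
#' @param member_divergence per-base substitution rate between a family
#'   master unit and each member's unit
#' @param reads_per_sample reads per simulated sample
#' @param read_length read length in nt
#' @param error_rate per-base read error rate
#' @return list of class `satscribe_scene`: `truth` (a `planted_truth`),
#'   `expr`, `samples`, `reads` (the [simulate_reads()] output),
#'   `family_truth` (planted satellite -> family map) and
#'   `subregion_weights`
#' @export
default_scene <- function(seed = 42L, sub_rate = 0, indel_rate = 0,
                          member_divergence = 0.05,
                          reads_per_sample = 400L, read_length = 100L,
                          error_rate = 0) {
  set.seed(seed)
  masters <- list(famA = .random_unit(35L), famB = .random_unit(45L),
                  famC = .random_unit(94L))
  sizes <- c(famA = 9L, famB = 7L, famC = 4L)
  fam_of <- rep(names(sizes), times = sizes)
  # member units must be pairwise distinct (>= 2 differing sites in the
  # master frame): identical members would make the planted per-satellite
  # read counts ambiguous, since tied reads count toward every member
  seen <- stats::setNames(vector("list", length(sizes)), names(sizes))
  mutate_fixed <- function(seq, k) {
    v <- strsplit(seq, "")[[1]]
    at <- sample(length(v), k)
    v[at] <- vapply(v[at], function(b) sample(setdiff(.BASES, b), 1L), "")
    paste(v, collapse = "")
  }
  units <- vapply(fam_of, function(f) {
    L <- nchar(masters[[f]])
    k <- max(2L, round(member_divergence * L))
    repeat {
      u <- mutate_fixed(masters[[f]], k)
      dists <- vapply(seen[[f]], function(v)
        sum(strsplit(v, "")[[1]] != strsplit(u, "")[[1]]), 0L)
      if (all(dists >= 2L)) break
    }
    seen[[f]] <<- c(seen[[f]], u)
    u <- .rotate_str(u, sample(0:(nchar(u) - 1L), 1L))
    if (stats::runif(1) < 0.5) u <- .revcomp(u)
    u
  }, "", USE.NAMES = FALSE)
  n <- length(units)
  copies <- sample(c(4:8, 10:60), n, replace = TRUE)
  # interleave families along the slots so chromosomes/classes mix
  ord <- sample(n)
  units <- units[ord]; fam_of <- fam_of[ord]; copies <- copies[ord]
  chrom <- rep(c("chrI", "chrII"), length.out = n)
  slots_per_chrom <- ceiling(n / 2)
  pos <- integer(n)
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    pos[sel] <- 3000L + (seq_along(sel) - 1L) * 7000L
  }
  classes <- rep("intergenic", n)
  classes[seq_len(5L)] <- "intron"
  classes[6:8] <- "exon"
  classes <- classes[sample(n)]
  specs <- data.frame(chrom = chrom, pos = pos, unit = units,
                      n_copies = copies, sub_rate = sub_rate,
                      indel_rate = indel_rate, location_class = classes,
                      stringsAsFactors = FALSE)
  bg_len <- 3000L + slots_per_chrom * 7000L + 3000L
  truth <- simulate_genome(specs, background_length = bg_len, gc = 0.36,
                           seed = seed + 1L)

  tissues <- c("hypodermis", "intestine", "neurons", "muscle")
  sat_ids <- truth$satellites$satellite_id
  expr <- matrix(stats::runif(n * 4, 0.2, 1), n, 4,
                 dimnames = list(sat_ids, tissues))
  expr[, "neurons"] <- expr[, "neurons"] * 3      # neurons dominate overall
  expr[1L, ] <- c(6, 0.3, 0.5, 0.2)               # hypodermis-dominant
  expr[2L, ] <- c(0.3, 6, 0.5, 0.2)               # intestine-dominant
  samples <- data.frame(
    sample_id = paste0(rep(tissues, each = 2L), "_", 1:2),
    tissue = rep(tissues, each = 2L),
    stringsAsFactors = FALSE)
  longest <- sat_ids[which.max(truth$satellites$end -
                                 truth$satellites$start)]
  srw <- stats::setNames(list(c(0, 1, 0)), longest)
  reads <- simulate_reads(truth, expr, samples,
                          reads_per_sample = reads_per_sample,
                          read_length = read_length,
                          error_rate = error_rate, seed = seed + 2L,
                          subregion_weights = srw)
  structure(list(truth = truth, expr = expr, samples = reads$samples,
                 reads = reads,
                 family_truth = stats::setNames(fam_of, sat_ids),
                 subregion_weights = srw),
            class = "satscribe_scene")
}

#' Run the full satellite pipeline on a genome and read set
#'
#' Detection, family clustering, location classification, read
#' quantification and tissue summary in one call; the building blocks are
#' all exported individually.
#'
#' @param genome named character vector of chromosome sequences
#' @param samples sample sheet (`sample_id`, `tissue`, and `fastq_path`
#'   unless `reads` is given)
#' @param reads optional named list of per-sample read vectors
#' @param genes optional gene models for location classification
#' @param repeats optional repeat annotation `GRanges`
#' @param threshold family clustering score threshold
#' @param flank_nt window flank in nt
#' @param min_identity read-hit identity threshold
#' @return list with `satellites` (annotated, with family column),
#'   `families`, `windows`, `hit_table` and `tissue_summary`
#' @export
run_pipeline <- function(genome, samples, reads = NULL, genes = NULL,
                         repeats = NULL, threshold = 0.6, flank_nt = 250L,
                         min_identity = 0.97) {
  sats <- detect_satellites(genome)
  fam <- cluster_families(sats, threshold = threshold)
  sats <- fam$satellites
  if (!is.null(genes))
    sats <- annotate_satellites(sats, genes, repeats)
  windows <- build_reference_windows(sats, genome, flank_nt = flank_nt)
  ht <- quantify_samples(windows, samples, reads = reads,
                         min_identity = min_identity)
  ts <- summarize_by_tissue(ht)
  list(satellites = sats, families = fam$families, windows = windows,
       hit_table = ht, tissue_summary = ts)
}
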