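test_that("a zero-rate spec plants the unit repeated exactly n times", {
  u <- rand_unit(30, seed = 1)
  tr <- planted_genome(u, 8L, seed = 1)
  arr <- substr(tr$genome[["chr1"]], tr$satellites$start, tr$satellites$end)
  expect_identical(arr, strrep(u, 8))
  # identical seed, identical output
  tr2 <- planted_genome(u, 8L, seed = 1)
  expect_identical(tr$genome, tr2$genome)
  expect_identical(tr$satellites, tr2$satellites)
})

test_that("overlapping or out-of-bounds inserts are rejected", {
  u <- rand_unit(20, seed = 2)
  specs <- data.frame(chrom = "chr1", pos = c(1000L, 1050L), unit = u,
                      n_copies = 5L, sub_rate = 0, indel_rate = 0,
                      location_class = "intergenic")
  expect_error(simulate_genome(specs, 5000L, seed = 2), "overlapping")
  specs2 <- specs[1, ]; specs2$pos <- 4950L
  expect_error(simulate_genome(specs2, 5000L, seed = 2), "beyond")
})

test_that("observed substitution rate matches the spec (binomial check)", {
  # ~1e5 planted copy-bases at rate 0.05
  set.seed(21)
  u <- satscribe:::.random_unit(50)
  specs <- data.frame(chrom = paste0("c", 1:5), pos = 2000L, unit = u,
                      n_copies = 40L, sub_rate = 0.05, indel_rate = 0,
                      location_class = "intergenic")
  tr <- simulate_genome(specs, background_length = 6000L, seed = 21L)
  nmut <- 0L; nbase <- 0L
  for (i in 1:5) {
    arr <- substr(tr$genome[[specs$chrom[i]]], tr$satellites$start[i],
                  tr$satellites$end[i])
    a <- strsplit(arr, "")[[1]]
    ref <- strsplit(strrep(u, 40L), "")[[1]]
    nmut <- nmut + sum(a != ref)
    nbase <- nbase + length(a)
  }
  p_hat <- nmut / nbase
  se <- sqrt(0.05 * 0.95 / nbase)
  expect_lt(abs(p_hat - 0.05), 3 * se)
})

test_that("noiseless truth coordinates round-trip through detection", {
  sc <- cached_scene()
  sats <- detect_satellites(sc$truth$genome)
  tc <- sc$truth$satellites
  m <- merge(sats, tc, by = "satellite_id")
  expect_identical(nrow(m), nrow(tc))
  expect_identical(m$start.x, m$start.y)
  expect_identical(m$end.x, m$end.y)
})

test_that("Helitron loci follow the canonical layout on both strands", {
  loc <- simulate_helitron_locus(gene_length = 4874L, sat31_len = 1179L,
                                 sat32_len = 351L, sat15_len = 76L,
                                 orientation = "+", seed = 3L)
  p <- loc$parts
  expect_identical(p$name[match(sort(p$start[p$name != "locus"]),
                                p$start[p$name != "locus"])],
                   c("sat15", "sat32", "utr5", "transposon_gene",
                     "sat31", "utr3"))
  widths <- p$end - p$start + 1L
  expect_identical(widths[p$name == "transposon_gene"], 4874L)
  expect_identical(widths[p$name == "sat31"], 1179L)
  expect_identical(widths[p$name == "sat32"], 351L)
  expect_identical(widths[p$name == "sat15"], 76L)
  # the 31-nt satellite is in direct contact with the end of the gene
  expect_identical(p$start[p$name == "sat31"],
                   p$end[p$name == "transposon_gene"] + 1L)

  minus <- simulate_helitron_locus(gene_length = 4874L, sat31_len = 1179L,
                                   sat32_len = 351L, sat15_len = 76L,
                                   orientation = "-", seed = 3L)
  expect_identical(minus$sequence, satscribe:::.revcomp(loc$sequence))
  # part widths are preserved under the strand flip
  wm <- minus$parts$end - minus$parts$start + 1L
  expect_identical(sort(wm), sort(widths))
})

test_that("reads from one satellite match it at full identity end to end", {
  fx <- planted_genome(rand_unit(36, seed = 9), 20L, seed = 9)
  sats <- detect_satellites(fx$genome)
  w <- build_reference_windows(sats, fx$genome)
  samples <- data.frame(sample_id = "n1", tissue = "neurons")
  expr <- matrix(1, 1, 1, dimnames = list(sats$satellite_id, "neurons"))
  sim <- simulate_reads(fx, expr, samples, reads_per_sample = 80L,
                        read_length = 90L, error_rate = 0, seed = 9L)
  hits <- assign_best_hits(match_reads(sim$reads$n1, w))
  expect_identical(sort(unique(hits$read_id)), sort(names(sim$reads$n1)))
  expect_true(all(hits$identity == 1))
  expect_true(all(hits$satellite_id == sats$satellite_id))

  bad_expr <- matrix(0, 1, 1, dimnames = list(sats$satellite_id, "neurons"))
  expect_error(simulate_reads(fx, bad_expr, samples, seed = 1L),
               "all-zero")
})

test_that("3:1 expression weights give 3:1 counts within 3 s.e.", {
  set.seed(17)
  u1 <- satscribe:::.random_unit(40); u2 <- satscribe:::.random_unit(60)
  specs <- data.frame(chrom = "chr1", pos = c(2000L, 8000L),
                      unit = c(u1, u2), n_copies = c(12L, 10L),
                      sub_rate = 0, indel_rate = 0,
                      location_class = "intergenic")
  tr <- simulate_genome(specs, background_length = 14000L, seed = 17L)
  samples <- data.frame(sample_id = "n1", tissue = "neurons")
  expr <- matrix(c(3, 1), 2, 1,
                 dimnames = list(tr$satellites$satellite_id, "neurons"))
  n <- 10000L
  sim <- simulate_reads(tr, expr, samples, reads_per_sample = n,
                        read_length = 80L, seed = 17L)
  k <- sim$true_counts[1, "n1"]
  se <- sqrt(n * 0.75 * 0.25)
  expect_lt(abs(k - n * 0.75), 3 * se)
})

test_that("sub-region weights localize coverage to the chosen block", {
  # copies carry 5% planted divergence so that read placement inside the
  # array is identifiable (in a perfect array all unit offsets tie)
  fx <- planted_genome(rand_unit(45, seed = 27), 60L, seed = 27,
                       bg = 12000L, sub_rate = 0.05)
  sats <- detect_satellites(fx$genome)
  w <- build_reference_windows(sats, fx$genome)
  samples <- data.frame(sample_id = "n1", tissue = "neurons")
  tid <- fx$satellites$satellite_id      # sampling frame is the truth
  expr <- matrix(1, 1, 1, dimnames = list(tid, "neurons"))
  srw <- stats::setNames(list(c(0, 1, 0)), tid)
  sim <- simulate_reads(fx, expr, samples, reads_per_sample = 200L,
                        read_length = 80L, seed = 27L,
                        subregion_weights = srw)
  ht <- quantify_samples(w, sim$samples, reads = sim$reads)
  pr <- coverage_profile(w[1, ], do.call(rbind, ht$hits), samples)
  slen <- sats$end - sats$start + 1L
  rel <- function(gpos) gpos - w$wstart + 1L
  third <- function(i) rel(sats$start + floor((i - 1) * slen / 3)):
    rel(sats$start + floor(i * slen / 3) - 1L)
  d <- pr$depth["neurons", ]
  # middle third carries the peak; the outer-third interiors (outside one
  # read length of the block) stay flat at zero
  expect_gt(mean(d[third(2)]), 10)
  far_left <- seq_len(rel(sats$start) + floor(slen / 3) - 80L)
  far_right <- (rel(sats$start) + floor(2 * slen / 3) + 80L):length(d)
  expect_identical(sum(d[far_left]), 0L)
  expect_identical(sum(d[far_right]), 0L)
})

test_that("FASTQ and sample-sheet output round-trips through the matcher", {
  fx <- planted_genome(rand_unit(33, seed = 12), 10L, seed = 12)
  sats <- detect_satellites(fx$genome)
  w <- build_reference_windows(sats, fx$genome)
  samples <- data.frame(sample_id = c("h1", "h2"),
                        tissue = c("hypodermis", "hypodermis"))
  expr <- matrix(1, 1, 1,
                 dimnames = list(sats$satellite_id, "hypodermis"))
  dir <- tempfile(); dir.create(dir)
  sim <- simulate_reads(fx, expr, samples, reads_per_sample = 30L,
                        read_length = 70L, seed = 12L, dir = dir)
  sheet <- read_sample_sheet(file.path(dir, "samples.tsv"))
  expect_identical(sheet$sample_id, c("h1", "h2"))
  ht <- quantify_samples(w, sheet)      # reads loaded from FASTQ files
  expect_identical(unname(ht$counts[1, ]), c(30L, 30L))
  expect_identical(ht$samples$total_reads, c(30L, 30L))
})
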