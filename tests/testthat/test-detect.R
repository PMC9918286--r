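test_that("k-mer primitivity rejects tandem-degenerate decamers", {
  expect_false(is_primitive_kmer("ACACACACAC"))  # period 2
  expect_false(is_primitive_kmer("AAAAAAAAAA"))  # period 1
  expect_false(is_primitive_kmer("ACGTAACGTA"))  # period 5
  expect_true(is_primitive_kmer("ACGTACGTTG"))   # period 4 does not divide 10
  expect_error(is_primitive_kmer("ACGT"), "10-character")
  expect_error(is_primitive_kmer("ACGTACGTAN"), "A/C/G/T")

  # brute force over every period p that divides 10, on random decamers
  set.seed(7)
  for (i in 1:50) {
    km <- paste(sample(c("A", "C", "G", "T"), 10, replace = TRUE),
                collapse = "")
    tiled <- FALSE
    for (p in 1:5) {
      if (10 %% p == 0 && km == strrep(substr(km, 1, p), 10 / p))
        tiled <- TRUE
    }
    expect_identical(is_primitive_kmer(km), !tiled)
  }
})

test_that("seed clustering finds planted arrays and nothing in random DNA", {
  g0 <- c(chr1 = rand_dna(10000, seed = 0))
  expect_identical(find_seed_clusters(g0), list())
  expect_identical(nrow(census_oracle(g0)), 0L)  # oracle agrees: no cluster

  # five exact copies of a primitive 40-mer at position 2000
  unit <- rand_unit(40, seed = 11)
  g <- g0
  substr(g[["chr1"]], 2000, 2000 + 200 - 1) <- strrep(unit, 5)
  cl <- find_seed_clusters(g)
  expect_length(cl, 1L)
  expect_lte(abs(cl[[1]]$start - 2000), 15)
  expect_lte(abs(cl[[1]]$end - 2199), 15)

  # empty genome is an empty result, not an error
  expect_identical(find_seed_clusters(c(chr1 = "ACGT")), list())
})

test_that("seed clusters equal the brute-force census on small genomes", {
  for (sd in c(3, 17)) {
    set.seed(sd)
    g <- c(chr1 = rand_dna(30000))
    for (i in 1:4) {
      u <- rand_unit(sample(12:80, 1))
      nc <- sample(4:12, 1)
      pos <- 2000 + (i - 1) * 7000
      substr(g[["chr1"]], pos, pos + nc * nchar(u) - 1) <- strrep(u, nc)
    }
    got <- find_seed_clusters(g)
    exp <- census_oracle(g)
    expect_identical(length(got), nrow(exp))
    expect_identical(vapply(got, `[[`, 0L, "start"), exp$start)
    expect_identical(vapply(got, `[[`, 0L, "end"), exp$end)
  }
})

test_that("arrays of over-long units are not reported as satellites", {
  # 4 copies of a 250-mer: seeds may fire, but the unit is out of range
  set.seed(23)
  g <- c(chr1 = rand_dna(10000))
  u <- rand_unit(250)
  substr(g[["chr1"]], 3000, 3000 + 1000 - 1) <- strrep(u, 4)
  expect_identical(nrow(detect_satellites(g)), 0L)
})

test_that("a perfect planted array is delimited exactly", {
  unit <- rand_unit(45, seed = 5)
  tr <- planted_genome(unit, 6, seed = 5)
  cl <- find_seed_clusters(tr$genome)
  expect_length(cl, 1L)
  rec <- delimit_satellite(cl[[1]], tr$genome)
  expect_identical(rec$start, tr$satellites$start)
  expect_identical(rec$end, tr$satellites$end)
  expect_identical(rec$repeat_length, 45L)
  expect_identical(rec$n_repeats, 6L)
  expect_identical(rec$similarity, 1)
  expect_identical(rec$same_length_frac, 1)
  expect_identical(sum(nchar(rec$repeats)), rec$length)
})

test_that("perfect-array identity holds across unit lengths and copy numbers", {
  cases <- data.frame(L = c(10L, 23L, 45L, 102L, 200L),
                      n = c(12L, 7L, 4L, 5L, 4L),
                      seed = c(31, 32, 33, 34, 35))
  for (i in seq_len(nrow(cases))) {
    unit <- rand_unit(cases$L[i], seed = cases$seed[i])
    tr <- planted_genome(unit, cases$n[i], bg = 12000L,
                         seed = cases$seed[i])
    s <- detect_satellites(tr$genome)
    expect_identical(nrow(s), 1L)
    expect_identical(s$start, tr$satellites$start)
    expect_identical(s$end, tr$satellites$end)
    expect_identical(s$repeat_length, cases$L[i])
    expect_identical(s$n_repeats, cases$n[i])
    expect_equal(s$similarity, 1)
    expect_equal(s$same_length_frac, 1)
  }
})

test_that("a long 134 x 45 nt array keeps exact repeat geometry", {
  # same repeat geometry as the long unique X-chromosome satellite
  # (134 repeats of 45 nt); the reported length matches the planted span
  # and n_repeats x repeat_length
  unit <- rand_unit(45, seed = 134)
  tr <- planted_genome(unit, 134, bg = 16000L, seed = 134)
  s <- detect_satellites(tr$genome)
  expect_identical(s$repeat_length, 45L)
  expect_identical(s$n_repeats, 134L)
  expect_identical(s$length, 134L * 45L)
})

test_that("noisy arrays are recovered near the planted truth", {
  # 5% substitutions: unit exact, boundaries within one unit
  unit <- rand_unit(45, seed = 7)
  tr <- planted_genome(unit, 12, seed = 7, sub_rate = 0.05)
  s <- detect_satellites(tr$genome)
  expect_identical(nrow(s), 1L)
  expect_identical(s$repeat_length, 45L)
  expect_identical(s$n_repeats, 12L)
  expect_lte(abs(s$start - tr$satellites$start), 45)
  expect_lte(abs(s$end - tr$satellites$end), 45)

  # recovery rate over replicates at n >= 8 copies
  hit <- 0L; reps <- 25L
  for (sd in seq_len(reps)) {
    set.seed(4000 + sd)
    L <- sample(15:100, 1); nc <- sample(8:30, 1)
    tr <- planted_genome(satscribe:::.random_unit(L), nc, bg = 9000L,
                         seed = sd, sub_rate = 0.05)
    s <- detect_satellites(tr$genome)
    if (nrow(s) == 1L && s$repeat_length == L) hit <- hit + 1L
  }
  expect_gte(hit / reps, 0.95)
})

test_that("repeat similarity is the mean pairwise identity of same-length copies", {
  expect_equal(repeat_similarity(rep("ACGTACGTAA", 5), 10), 1)
  expect_equal(repeat_similarity(c("ACGTACGTAA", "ACGTACGTAT"), 10), 0.9)
  expect_true(is.na(repeat_similarity(c("ACGTACGTAA"), 10)))
  expect_true(is.na(repeat_similarity(c("ACGTACGTAA", "ACGTA"), 10)))

  # 10 mutated copies vs brute-force mean over all 45 pairs
  set.seed(3)
  unit <- satscribe:::.random_unit(30)
  copies <- vapply(1:10, function(i) satscribe:::.mutate_subs(unit, 0.05),
                   "")
  brute <- c()
  for (i in 1:9) for (j in (i + 1):10) {
    a <- strsplit(copies[i], "")[[1]]; b <- strsplit(copies[j], "")[[1]]
    brute <- c(brute, mean(a == b))
  }
  expect_equal(repeat_similarity(copies, 30), mean(brute))

  # N matches nothing
  expect_equal(repeat_similarity(c("ANAA", "ANAA"), 4), 0.75)
})

test_that("the regularity filter keeps >= 60% same-length records, sorted", {
  rec <- function(chrom, start, slf, n = 10L, rl = 20L) {
    data.frame(satellite_id = paste0(chrom, "_", start), chrom = chrom,
               start = start, end = start + 200L, length = 201L,
               n_repeats = n, repeat_length = rl, similarity = 0.9,
               same_length_frac = slf, sequence = "A")
  }
  recs <- rbind(rec("chr2", 500, 0.7), rec("chr1", 900, 0.5),
                rec("chr1", 100, 0.6), rec("chr1", 300, 1, n = 3L),
                rec("chr1", 700, 1, rl = 250L))
  out <- filter_satellites(recs)
  expect_identical(out$satellite_id, c("chr1_100", "chr2_500"))
  expect_identical(filter_satellites(recs, min_same_length_frac = 0.5,
                                     min_copies = 4L)$start[1], 100)
})

test_that("monotonicity: stricter seeding never adds satellites", {
  sc <- cached_scene()
  g <- sc$truth$genome
  base <- nrow(detect_satellites(g))
  expect_lte(nrow(detect_satellites(g, min_copies = 6L)), base)
  expect_lte(nrow(detect_satellites(g, window_nt = 400L)), base)
})

test_that("the satellite table round-trips through TSV field-for-field", {
  sc <- cached_scene()
  sats <- detect_satellites(sc$truth$genome)
  path <- tempfile(fileext = ".tsv")
  write_satellite_table(sats, path)
  back <- read_satellite_table(path)
  expect_identical(back$satellite_id, sats$satellite_id)
  expect_identical(back$start, sats$start)
  expect_identical(back$end, sats$end)
  expect_identical(back$n_repeats, sats$n_repeats)
  expect_identical(back$repeat_length, sats$repeat_length)
  expect_equal(back$similarity, sats$similarity)
  expect_equal(back$same_length_frac, sats$same_length_frac)
  expect_identical(back$sequence, sats$sequence)

  bed <- tempfile(fileext = ".bed")
  write_satellite_bed(sats, bed)
  lines <- strsplit(readLines(bed), "\t")
  expect_true(all(lengths(lines) == 6L))
  expect_identical(lines[[1]][4], paste0("SAT_", sats$chrom[1], "_",
                                         sats$start[1]))
})
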