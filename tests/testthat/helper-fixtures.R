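# Fixture builders shared across test files. Everything is generated in
# code at test time from fixed seeds.

rand_dna <- function(n, seed = NULL, gc = 0.36) {
  if (!is.null(seed)) set.seed(seed)
  satscribe:::.random_dna(n, gc)
}

rand_unit <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  satscribe:::.random_unit(len)
}

# one planted (maximal) satellite in background, via the generator
planted_genome <- function(unit, n_copies, pos = 2000L, bg = 10000L,
                           seed = 1L, sub_rate = 0, indel_rate = 0,
                           location_class = "intergenic", chrom = "chr1") {
  specs <- data.frame(chrom = chrom, pos = pos, unit = unit,
                      n_copies = n_copies, sub_rate = sub_rate,
                      indel_rate = indel_rate,
                      location_class = location_class,
                      stringsAsFactors = FALSE)
  simulate_genome(specs, background_length = bg, seed = seed)
}

# the default scene is used by several files; build it once per session
cached_scene <- local({
  env <- new.env()
  function(seed = 42L) {
    key <- paste0("s", seed)
    if (is.null(env[[key]])) env[[key]] <- default_scene(seed = seed)
    env[[key]]
  }
})

scene_gene_models <- function(scene) {
  g <- scene$truth$genes
  list(genes = g[g$type == "gene"], exons = g[g$type == "exon"])
}

# small two-satellite universe used in several blocks
quant_fixture <- local({
  env <- new.env()
  function() {
    if (is.null(env$fx)) {
      set.seed(19)
      u1 <- satscribe:::.random_unit(40)
      u2 <- satscribe:::.random_unit(55)
      specs <- data.frame(chrom = "chr1", pos = c(2000L, 6000L),
                          unit = c(u1, u2), n_copies = c(20L, 15L),
                          sub_rate = 0, indel_rate = 0,
                          location_class = "intergenic")
      tr <- simulate_genome(specs, background_length = 12000L, seed = 19L)
      sats <- detect_satellites(tr$genome)
      env$fx <- list(truth = tr, sats = sats,
                     windows = build_reference_windows(sats, tr$genome))
    }
    env$fx
  }
})

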