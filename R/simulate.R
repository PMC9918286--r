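## Synthetic scenes with planted ground truth: genomes with imperfect
## tandem arrays, gene models realizing chosen location classes,
## Helitron-style loci, and tissue-stratified reads. Every generator output
## is a pure function of its arguments and the seed.

.BASES <- c("A", "C", "G", "T")

.random_dna <- function(n, gc = 0.36) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(.BASES, n, replace = TRUE, prob = p), collapse = "")
}

# per-base substitutions to a different base
.mutate_subs <- function(seq, rate) {
  if (rate <= 0) return(seq)
  v <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(v)) < rate)
  for (i in hit) v[i] <- sample(setdiff(.BASES, v[i]), 1L)
  paste(v, collapse = "")
}

# a random primitive unit (not a whole-number tandem of a shorter unit)
.random_unit <- function(len, gc = 0.5) {
  repeat {
    u <- .random_dna(len, gc)
    ok <- TRUE
    for (p in seq_len(len %/% 2L)) {
      if (len %% p == 0L && u == strrep(substr(u, 1L, p), len %/% p)) {
        ok <- FALSE; break
      }
    }
    if (ok) return(u)
  }
}

# one tandem array: n_copies of unit with per-base substitutions and
# per-copy single-base indels
.make_array <- function(unit, n_copies, sub_rate = 0, indel_rate = 0) {
  copies <- character(n_copies)
  for (i in seq_len(n_copies)) {
    cp <- .mutate_subs(unit, sub_rate)
    if (indel_rate > 0 && stats::runif(1) < indel_rate) {
      v <- strsplit(cp, "")[[1]]
      pos <- sample(length(v), 1L)
      if (stats::runif(1) < 0.5) {
        v <- append(v, sample(.BASES, 1L), after = pos)       # insertion
      } else if (length(v) > 1L) {
        v <- v[-pos]                                          # deletion
      }
      cp <- paste(v, collapse = "")
    }
    copies[i] <- cp
  }
  paste(copies, collapse = "")
}

#' Simulate a genome with planted satellites and gene models
#'
#' Builds i.i.d. background at the requested GC, plants each satellite by
#' mutating copies of its unit per its rates and overwriting the background
#' at the given position, and writes gene models so that each spec's
#' location class holds (an exon covering the satellite for `exon`, a gene
#' whose exons flank the satellite for `intron`, nothing for `intergenic`).
#' Planted arrays are made maximal: the bases immediately flanking each
#' array are resampled if they happen to continue the periodic pattern, so
#' ground-truth boundaries are well defined.
#'
#' @param specs data frame with columns `chrom`, `pos` (1-based insert
#'   start), `unit`, `n_copies`, `sub_rate`, `indel_rate`,
#'   `location_class` (`intergenic`/`intron`/`exon`)
#' @param background_length background length per chromosome, in nt
#' @param gc background GC fraction
#' @param seed integer seed; identical seeds give identical output
#' @param dir if non-NULL, write `genome.fa`, `genes.gff3` and
#'   `truth_satellites.tsv` there
#' @return list of class `planted_truth`: `genome` (named character),
#'   `satellites` (truth coordinates/units), `genes` (`GRanges` with
#'   `type`), and `files` (paths, when `dir` was given)
#' @export
simulate_genome <- function(specs, background_length = 60000L, gc = 0.36,
                            seed = 1L, dir = NULL) {
  set.seed(seed)
  chroms <- unique(specs$chrom)
  genome <- stats::setNames(
    vapply(chroms, function(x) .random_dna(background_length, gc), ""),
    chroms)

  arrays <- vapply(seq_len(nrow(specs)), function(i)
    .make_array(specs$unit[i], specs$n_copies[i],
                specs$sub_rate[i], specs$indel_rate[i]), "")
  ends <- specs$pos + nchar(arrays) - 1L
  for (ch in chroms) {
    sel <- which(specs$chrom == ch)
    if (length(sel) > 1L) {
      o <- sel[order(specs$pos[sel])]
      if (any(specs$pos[o][-1L] <= ends[o][-length(o)]))
        stop("overlapping satellite inserts on ", ch)
    }
    if (any(ends[sel] > background_length))
      stop("satellite insert(s) beyond chromosome end on ", ch)
  }

  for (i in seq_len(nrow(specs))) {
    ch <- specs$chrom[i]
    s <- specs$pos[i]; e <- ends[i]
    substr(genome[[ch]], s, e) <- arrays[i]
    unit <- specs$unit[i]; L <- nchar(unit)
    # maximality: the flanking bases must break the periodic continuation
    if (s > 1L) {
      cont <- substr(unit, L, L)
      if (substr(genome[[ch]], s - 1L, s - 1L) == cont)
        substr(genome[[ch]], s - 1L, s - 1L) <-
          sample(setdiff(.BASES, cont), 1L)
    }
    if (e < nchar(genome[[ch]])) {
      cont <- substr(unit, ((e - s + 1L) %% L) + 1L, ((e - s + 1L) %% L) + 1L)
      if (substr(genome[[ch]], e + 1L, e + 1L) == cont)
        substr(genome[[ch]], e + 1L, e + 1L) <-
          sample(setdiff(.BASES, cont), 1L)
    }
  }

  truth <- data.frame(
    satellite_id = paste0(specs$chrom, "_", specs$pos),
    chrom = specs$chrom, start = specs$pos, end = ends,
    unit = specs$unit, unit_length = nchar(specs$unit),
    n_copies = specs$n_copies,
    location_class = specs$location_class,
    stringsAsFactors = FALSE)

  gene_rows <- list()
  gi <- 0L
  for (i in seq_len(nrow(specs))) {
    lc <- specs$location_class[i]
    if (lc == "intergenic") next
    gi <- gi + 1L
    ch <- specs$chrom[i]
    s <- specs$pos[i]; e <- ends[i]
    gid <- sprintf("gene%03d", gi)
    gspan <- c(max(1L, s - 200L), min(nchar(genome[[ch]]), e + 200L))
    if (lc == "exon") {
      exons <- list(c(max(1L, s - 50L), min(nchar(genome[[ch]]), e + 50L)))
    } else {
      exons <- list(c(gspan[1], s - 50L), c(e + 50L, gspan[2]))
    }
    gene_rows[[length(gene_rows) + 1L]] <-
      data.frame(chrom = ch, start = gspan[1], end = gspan[2],
                 type = "gene", ID = gid, Parent = NA_character_)
    for (k in seq_along(exons)) {
      gene_rows[[length(gene_rows) + 1L]] <-
        data.frame(chrom = ch, start = exons[[k]][1], end = exons[[k]][2],
                   type = "exon", ID = paste0(gid, ".e", k), Parent = gid)
    }
  }
  genes_df <- if (length(gene_rows)) do.call(rbind, gene_rows) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               type = character(0), ID = character(0),
               Parent = character(0))
  if (nrow(genes_df)) {
    genes <- GenomicRanges::GRanges(
      genes_df$chrom, IRanges::IRanges(genes_df$start, genes_df$end),
      strand = "+")
    genes$type <- genes_df$type
    genes$ID <- genes_df$ID
    genes$Parent <- ifelse(is.na(genes_df$Parent), "", genes_df$Parent)
  } else {
    genes <- GenomicRanges::GRanges()
    genes$type <- character(0)
    genes$ID <- character(0)
    genes$Parent <- character(0)
  }

  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    fa <- file.path(dir, "genome.fa")
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), fa)
    gff <- file.path(dir, "genes.gff3")
    .write_gff3(genes_df, gff)
    tr <- file.path(dir, "truth_satellites.tsv")
    utils::write.table(truth, tr, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(genome = fa, genes = gff, truth = tr)
  }
  structure(list(genome = genome, satellites = truth, genes = genes,
                 genes_df = genes_df, files = files),
            class = "planted_truth")
}

# minimal GFF3 writer for the simulated gene/exon records
.write_gff3 <- function(genes_df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(genes_df)) {
    attr_col <- ifelse(is.na(genes_df$Parent) | genes_df$Parent == "",
                       paste0("ID=", genes_df$ID),
                       paste0("ID=", genes_df$ID, ";Parent=",
                              genes_df$Parent))
    writeLines(paste(genes_df$chrom, "satscribe", genes_df$type,
                     genes_df$start, genes_df$end, ".", "+", ".",
                     attr_col, sep = "\t"), con)
  }
  invisible(path)
}

#' Simulate a complete Helitron-style locus
#'
#' Emits a locus laid out as in complete nematode Helitrons: a short 15-nt
#' satellite, a 32-nt satellite, the 5' conserved region, the central
#' transposon gene, a 31-nt satellite in direct contact with the end of the
#' gene, and the 3' conserved region. With orientation `-` the whole locus
#' is reverse-complemented (and part coordinates flipped).
#'
#' @param gene_length transposon gene length in nt
#' @param sat31_len,sat32_len,sat15_len satellite lengths in nt (31/32/15-nt
#'   repeat units; the last copy is truncated to reach the exact length)
#' @param orientation `"+"` or `"-"`
#' @param seed integer seed
#' @param utr5_len,utr3_len conserved-region lengths in nt
#' @return list with `sequence` and `parts` (BED-style data frame `name
#'   start end label`, 1-based inclusive coordinates on the emitted
#'   sequence; includes a whole-locus `Helitron1_CE` row)
#' @export
simulate_helitron_locus <- function(gene_length = 4874L, sat31_len = 1179L,
                                    sat32_len = 351L, sat15_len = 76L,
                                    orientation = c("+", "-"), seed = 1L,
                                    utr5_len = 917L, utr3_len = 679L) {
  orientation <- match.arg(orientation)
  stopifnot(gene_length > 0, sat31_len > 0, sat32_len > 0, sat15_len > 0)
  set.seed(seed)
  sat_block <- function(unit_len, total) {
    u <- .random_unit(unit_len)
    substr(strrep(u, ceiling(total / unit_len)), 1L, total)
  }
  parts_seq <- list(
    sat15 = sat_block(15L, sat15_len),
    sat32 = sat_block(32L, sat32_len),
    utr5 = .random_dna(utr5_len, 0.40),
    transposon_gene = .random_dna(gene_length, 0.42),
    sat31 = sat_block(31L, sat31_len),
    utr3 = .random_dna(utr3_len, 0.40))
  lens <- vapply(parts_seq, nchar, 0L)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  seqn <- paste(unlist(parts_seq), collapse = "")
  parts <- data.frame(name = names(parts_seq), start = starts, end = ends,
                      label = paste0("Helitron1_CE_", names(parts_seq)),
                      stringsAsFactors = FALSE)
  parts <- rbind(parts,
                 data.frame(name = "locus", start = 1L, end = nchar(seqn),
                            label = "Helitron1_CE"))
  if (orientation == "-") {
    n <- nchar(seqn)
    seqn <- .revcomp(seqn)
    new_start <- n - parts$end + 1L
    parts$end <- n - parts$start + 1L
    parts$start <- new_start
    parts <- parts[order(parts$start), , drop = FALSE]
    rownames(parts) <- NULL
  }
  list(sequence = seqn, parts = parts, orientation = orientation)
}

#' Simulate tissue-stratified RNA-seq reads from planted satellites
#'
#' Each sample draws `reads_per_sample` reads: a satellite is chosen with
#' probability proportional to the expression weights of the sample's
#' tissue, a start position is chosen uniformly inside the satellite
#' (optionally restricted by sub-region weights over equal-width blocks, to
#' emulate non-uniform transcription), substitution errors are applied at
#' `error_rate`, and the strand is random (unstranded libraries). True
#' per-satellite per-sample counts are recorded.
#'
#' @param truth a `planted_truth` from [simulate_genome()]
#' @param expr satellite x tissue matrix of non-negative expression weights
#'   (rownames are satellite ids)
#' @param samples data frame with `sample_id` and `tissue`
#' @param reads_per_sample reads drawn per sample
#' @param read_length read length in nt
#' @param error_rate per-base substitution error rate
#' @param seed integer seed
#' @param subregion_weights optional named list: for a satellite id, a
#'   numeric vector of weights over equal-width blocks of the array
#' @param dir if non-NULL, write one plain FASTQ per sample plus
#'   `samples.tsv` there
#' @return list: `reads` (named list of per-sample read vectors),
#'   `true_counts` (satellite x sample), `read_truth` (per-read origin),
#'   `samples` (with `fastq_path` and `total_reads`)
#' @export
simulate_reads <- function(truth, expr, samples, reads_per_sample = 400L,
                           read_length = 100L, error_rate = 0,
                           seed = 1L, subregion_weights = NULL,
                           dir = NULL) {
  set.seed(seed)
  sats <- truth$satellites
  expr <- as.matrix(expr)
  for (t in unique(samples$tissue)) {
    if (!t %in% colnames(expr) || sum(expr[, t]) <= 0)
      stop("all-zero (or missing) expression for requested tissue: ", t)
  }
  sat_ids <- rownames(expr)
  true_counts <- matrix(0L, length(sat_ids), nrow(samples),
                        dimnames = list(sat_ids, samples$sample_id))
  read_list <- list()
  truth_rows <- list()
  for (s in seq_len(nrow(samples))) {
    sid <- samples$sample_id[s]
    tis <- samples$tissue[s]
    p <- expr[, tis] / sum(expr[, tis])
    pick <- sample(sat_ids, reads_per_sample, replace = TRUE, prob = p)
    seqs <- character(reads_per_sample)
    strands <- character(reads_per_sample)
    starts <- integer(reads_per_sample)
    for (r in seq_len(reads_per_sample)) {
      row <- sats[sats$satellite_id == pick[r], ]
      slen <- row$end - row$start + 1L
      w <- subregion_weights[[pick[r]]]
      if (!is.null(w)) {
        nb <- length(w)
        blk <- sample(nb, 1L, prob = w)
        bs <- row$start + floor((blk - 1L) * slen / nb)
        be <- row$start + floor(blk * slen / nb) - 1L
        lo <- bs
        hi <- max(bs, min(be, row$end - read_length + 1L))
      } else if (slen >= read_length) {
        lo <- row$start; hi <- row$end - read_length + 1L
      } else {
        lo <- row$end - read_length + 1L; hi <- row$start
      }
      lo <- max(1L, lo)
      hi <- min(hi, nchar(truth$genome[[row$chrom]]) - read_length + 1L)
      st <- if (hi > lo) sample(lo:hi, 1L) else lo
      rd <- substr(truth$genome[[row$chrom]], st, st + read_length - 1L)
      rd <- .mutate_subs(rd, error_rate)
      if (stats::runif(1) < 0.5) {
        rd <- .revcomp(rd)
        strands[r] <- "-"
      } else strands[r] <- "+"
      seqs[r] <- rd
      starts[r] <- st
    }
    ids <- sprintf("%s_read%05d", sid, seq_len(reads_per_sample))
    read_list[[sid]] <- stats::setNames(seqs, ids)
    tb <- table(factor(pick, levels = sat_ids))
    true_counts[, s] <- as.integer(tb)
    truth_rows[[sid]] <- data.frame(read_id = ids, sample_id = sid,
                                    tissue = tis, satellite_id = pick,
                                    start = starts, strand = strands,
                                    stringsAsFactors = FALSE)
  }
  samples$total_reads <- reads_per_sample
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    samples$fastq_path <- file.path(dir, paste0(samples$sample_id, ".fastq"))
    for (s in seq_len(nrow(samples))) {
      rd <- read_list[[samples$sample_id[s]]]
      dss <- Biostrings::DNAStringSet(rd)
      qual <- Biostrings::BStringSet(strrep("I", nchar(rd)))
      Biostrings::writeXStringSet(dss, samples$fastq_path[s],
                                  format = "fastq", qualities = qual)
    }
    utils::write.table(samples, file.path(dir, "samples.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(reads = read_list, true_counts = true_counts,
       read_truth = do.call(rbind, unname(truth_rows)), samples = samples)
}
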