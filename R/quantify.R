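## RNA-seq quantification of satellites: reads are matched to satellite +/-
## flank windows by a seed-and-extend aligner (12-mer exact seeds, ungapped
## diagonal extension), retained at >= 97% identity over the aligned region,
## multi-hits resolved by maximum accuracy, counted per satellite per
## sample, summed per tissue, and normalized as
## RPKM = hits * 1e9 / satellite length / library size.

#' Build satellite reference windows
#'
#' One window per satellite spanning the satellite plus `flank_nt` on each
#' side (clipped at contig ends), with the window sequence extracted from
#' the genome. The flanks absorb reads that start or end just outside the
#' array.
#'
#' @param sats satellite data frame
#' @param genome named character vector (or `DNAStringSet`)
#' @param flank_nt flank width in nt on each side
#' @return data frame `satellite_id chrom wstart wend sstart send
#'   sat_length sequence`
#' @export
build_reference_windows <- function(sats, genome, flank_nt = 250L) {
  genome <- .as_genome(genome)
  if (!"satellite_id" %in% names(sats))
    sats$satellite_id <- paste0(sats$chrom, "_", sats$start)
  bad <- !(sats$chrom %in% names(genome))
  if (any(bad))
    stop("satellite(s) on chromosomes absent from the genome: ",
         paste(sats$satellite_id[bad], collapse = ", "))
  clen <- nchar(genome)[sats$chrom]
  if (any(sats$start < 1L | sats$end > clen)) {
    off <- sats$satellite_id[sats$start < 1L | sats$end > clen]
    stop("satellite(s) outside genome bounds: ", paste(off, collapse = ", "))
  }
  wstart <- pmax(1L, sats$start - flank_nt)
  wend <- pmin(clen, sats$end + flank_nt)
  data.frame(satellite_id = sats$satellite_id,
             chrom = sats$chrom,
             wstart = wstart, wend = wend,
             sstart = sats$start, send = sats$end,
             sat_length = sats$end - sats$start + 1L,
             sequence = substring(genome[sats$chrom], wstart, wend),
             stringsAsFactors = FALSE)
}

# exact k-mer index over all window sequences
.window_index <- function(windows, seed_size = 12L) {
  pieces <- lapply(seq_len(nrow(windows)), function(i) {
    s <- windows$sequence[i]
    n <- nchar(s)
    if (n < seed_size) return(NULL)
    pos <- seq_len(n - seed_size + 1L)
    data.table::data.table(kmer = substring(s, pos, pos + seed_size - 1L),
                           win = i, wpos = pos)
  })
  idx <- data.table::rbindlist(pieces)
  idx <- idx[!grepl("N", idx$kmer, fixed = TRUE)]
  data.table::setkey(idx, kmer)
  idx
}

# ungapped identity of read vs window along one diagonal; returns NULL or a
# one-row data.frame
.extend_hit <- function(read_seq, win_seq, diag, min_identity, min_cov) {
  rlen <- nchar(read_seq); wlen <- nchar(win_seq)
  roff <- max(1L, 2L - diag)              # first read base that fits
  wstart <- diag + roff - 1L
  alen <- min(rlen - roff + 1L, wlen - wstart + 1L)
  if (alen < min_cov * rlen) return(NULL)
  rch <- strsplit(substr(read_seq, roff, roff + alen - 1L), "")[[1]]
  wch <- strsplit(substr(win_seq, wstart, wstart + alen - 1L), "")[[1]]
  matches <- sum(rch == wch & rch != "N" & wch != "N")
  identity <- matches / alen
  if (identity < min_identity) return(NULL)
  data.frame(identity = identity, wstart = wstart,
             wend = wstart + alen - 1L, alen = alen)
}

#' Match reads against satellite windows
#'
#' Seed-and-extend: exact `seed_size`-mer matches between read and window
#' anchor a diagonal, the read is extended ungapped along it, and hits are
#' retained when identity over the aligned region is at least
#' `min_identity` and the aligned length covers at least `min_cov` of the
#' read. Both read orientations are searched (libraries are treated as
#' unstranded); each window contributes at most one hit per read (the best
#' diagonal). Hits landing entirely in the flank still count and are
#' flagged `flank_only`.
#'
#' @param reads named character vector of read sequences
#' @param windows reference windows from [build_reference_windows()]
#' @param min_identity minimum identity over the aligned region
#' @param min_cov minimum aligned fraction of the read
#' @param seed_size exact-match seed length
#' @return data frame `read_id satellite_id identity wstart wend strand
#'   alen flank_only` (window-relative 1-based coordinates)
#' @export
match_reads <- function(reads, windows, min_identity = 0.97,
                        min_cov = 0.9, seed_size = 12L) {
  empty <- data.frame(read_id = character(0), satellite_id = character(0),
                      identity = numeric(0), wstart = integer(0),
                      wend = integer(0), strand = character(0),
                      alen = integer(0), flank_only = logical(0))
  if (!length(reads) || !nrow(windows)) return(empty)
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  idx <- .window_index(windows, seed_size)
  if (!nrow(idx)) return(empty)

  cand <- list()
  for (strand in c("+", "-")) {
    rs <- if (strand == "+") reads else
      stats::setNames(.revcomp(reads), names(reads))
    pieces <- lapply(seq_along(rs), function(i) {
      s <- rs[[i]]
      n <- nchar(s)
      if (n < seed_size) return(NULL)
      pos <- seq_len(n - seed_size + 1L)
      data.table::data.table(kmer = substring(s, pos, pos + seed_size - 1L),
                             read = i, rpos = pos)
    })
    rk <- data.table::rbindlist(pieces)
    if (!nrow(rk)) next
    hitdt <- idx[rk, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
    if (!nrow(hitdt)) next
    hitdt[, `:=`(diag = wpos - rpos + 1L, strand = strand)]
    cand[[strand]] <-
      hitdt[, list(support = .N), by = c("read", "win", "diag", "strand")]
  }
  cand <- data.table::rbindlist(cand)
  if (!is.data.frame(cand) || !nrow(cand)) return(empty)
  # the true diagonal carries the most exact seeds; cap extensions per
  # (read, window, strand) at the best-supported diagonals
  data.table::setorderv(cand, c("read", "win", "strand", "support", "diag"),
                        order = c(1L, 1L, 1L, -1L, 1L))
  cand <- cand[, utils::head(.SD, 8L), by = c("read", "win", "strand")]

  rows <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    rid <- cand$read[i]
    rseq <- if (cand$strand[i] == "+") reads[[rid]] else .revcomp(reads[[rid]])
    h <- .extend_hit(rseq, windows$sequence[cand$win[i]], cand$diag[i],
                     min_identity, min_cov)
    if (is.null(h)) next
    h$read <- rid; h$win <- cand$win[i]; h$strand <- cand$strand[i]
    h$diag <- cand$diag[i]
    rows[[i]] <- h
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  hits <- do.call(rbind, rows)

  # one hit per (read, window): keep the best identity, then smallest
  # diagonal (a read from a tandem matches at every unit offset)
  hits <- hits[order(hits$read, hits$win, -hits$identity,
                     hits$strand != "+", hits$diag), , drop = FALSE]
  hits <- hits[!duplicated(hits[, c("read", "win")]), , drop = FALSE]

  core_s <- windows$sstart - windows$wstart + 1L
  core_e <- windows$send - windows$wstart + 1L
  data.frame(read_id = names(reads)[hits$read],
             satellite_id = windows$satellite_id[hits$win],
             identity = hits$identity,
             wstart = hits$wstart, wend = hits$wend,
             strand = hits$strand, alen = hits$alen,
             flank_only = hits$wend < core_s[hits$win] |
               hits$wstart > core_e[hits$win],
             stringsAsFactors = FALSE)
}

#' @rdname match_reads
#' @param read a single read sequence
#' @export
match_read <- function(read, windows, min_identity = 0.97, min_cov = 0.9,
                       seed_size = 12L) {
  match_reads(stats::setNames(read, "read1"), windows,
              min_identity = min_identity, min_cov = min_cov,
              seed_size = seed_size)
}

#' Keep only maximum-accuracy hits per read
#'
#' Satellites of one family are near-identical, so a read can match several
#' windows; since it cannot be known which satellite was transcribed, every
#' hit tied at the per-read maximum identity is kept, and each retained hit
#' contributes one count to its satellite.
#'
#' @param hits hit data frame from [match_reads()]
#' @return subset of `hits` with only per-read maximum-identity rows
#' @export
assign_best_hits <- function(hits) {
  if (!nrow(hits)) return(hits)
  mx <- stats::ave(hits$identity, hits$read_id, FUN = max)
  out <- hits[hits$identity >= mx - 1e-9, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' RPKM of a satellite
#'
#' `RPKM = hits * 1e9 / satellite_length_nt / total_reads`: the hit count
#' normalized to the satellite length and the library size. Vectorized.
#'
#' @param hits number of retained read hits
#' @param satellite_length_nt satellite length in nt (flanks excluded)
#' @param total_reads library size of the sample
#' @return RPKM value(s)
#' @examples
#' rpkm(100, 1000, 1e7)  # 10
#' @export
rpkm <- function(hits, satellite_length_nt, total_reads) {
  if (any(satellite_length_nt <= 0)) stop("satellite length must be > 0")
  if (any(total_reads <= 0)) stop("library size must be > 0")
  hits * 1e9 / satellite_length_nt / total_reads
}

#' Quantify satellite transcription across samples
#'
#' For each sample, reads are loaded (FASTQ path from the sample sheet, or
#' in-memory reads), matched against the windows, resolved to
#' maximum-accuracy hits, and counted per satellite. Per-sample RPKM uses
#' the sample's total read count as library size.
#'
#' @param windows reference windows from [build_reference_windows()]
#' @param samples data frame with `sample_id`, `tissue` and either
#'   `fastq_path` or reads supplied via `reads`
#' @param reads optional named list: `reads[[sample_id]]` is a named
#'   character vector of read sequences (overrides `fastq_path`)
#' @inheritParams match_reads
#' @return list of class `hit_table`: `counts` and `rpkm` (satellite x
#'   sample matrices), `samples` (with `total_reads`), `windows`, and
#'   `hits` (per-sample best-hit data frames)
#' @export
quantify_samples <- function(windows, samples, reads = NULL,
                             min_identity = 0.97, min_cov = 0.9,
                             seed_size = 12L) {
  nsat <- nrow(windows); nsamp <- nrow(samples)
  counts <- matrix(0L, nsat, nsamp,
                   dimnames = list(windows$satellite_id, samples$sample_id))
  rpkm_m <- counts * 0
  hit_list <- vector("list", nsamp)
  names(hit_list) <- samples$sample_id
  total_reads <- integer(nsamp)
  for (s in seq_len(nsamp)) {
    sid <- samples$sample_id[s]
    rd <- if (!is.null(reads)) reads[[sid]] else {
      x <- Biostrings::readDNAStringSet(samples$fastq_path[s],
                                        format = "fastq")
      stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
    }
    total_reads[s] <- length(rd)
    hits <- assign_best_hits(match_reads(rd, windows,
                                         min_identity = min_identity,
                                         min_cov = min_cov,
                                         seed_size = seed_size))
    hits$sample_id <- rep(sid, nrow(hits))
    hit_list[[s]] <- hits
    if (nrow(hits)) {
      tb <- table(factor(hits$satellite_id, levels = windows$satellite_id))
      counts[, s] <- as.integer(tb)
    }
    rpkm_m[, s] <- rpkm(counts[, s], windows$sat_length, total_reads[s])
  }
  samples$total_reads <- total_reads
  structure(list(counts = counts, rpkm = rpkm_m, samples = samples,
                 windows = windows, hits = hit_list),
            class = "hit_table")
}

#' Sum hits and RPKM per tissue and flag transcribed satellites
#'
#' Per-tissue hit totals are the sums over that tissue's samples, and
#' per-tissue RPKM is the sum of the per-sample RPKM values (summed, not
#' recomputed from pooled counts). A satellite is flagged positively
#' transcribed in a tissue when its tissue RPKM exceeds that tissue's mean
#' RPKM over satellites.
#'
#' @param table a `hit_table` from [quantify_samples()]
#' @param samples optional sample sheet overriding `table$samples`
#' @return list of class `tissue_summary`: `counts`, `rpkm`, `transcribed`
#'   (satellite x tissue matrices) and `tissue_means`
#' @export
summarize_by_tissue <- function(table, samples = NULL) {
  samples <- samples %||% table$samples
  if (any(is.na(samples$tissue)) || any(!nzchar(samples$tissue)))
    stop("sample(s) with unknown tissue")
  tissues <- unique(samples$tissue)
  nsat <- nrow(table$counts)
  counts <- matrix(0L, nsat, length(tissues),
                   dimnames = list(rownames(table$counts), tissues))
  rpkm_t <- counts * 0
  for (t in tissues) {
    cols <- samples$sample_id[samples$tissue == t]
    counts[, t] <- as.integer(rowSums(table$counts[, cols, drop = FALSE]))
    rpkm_t[, t] <- rowSums(table$rpkm[, cols, drop = FALSE])
  }
  means <- colMeans(rpkm_t)
  transcribed <- sweep(rpkm_t, 2L, means, `>`)
  structure(list(counts = counts, rpkm = rpkm_t,
                 transcribed = transcribed, tissue_means = means),
            class = "tissue_summary")
}
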