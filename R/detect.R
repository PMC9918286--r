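## Satellite detection: primitive decamer seed clusters -> array delimitation
## -> regularity filter. Coordinates are 1-based inclusive throughout (the
## IRanges convention), which is also the style of the reported tables.

#' Test whether a k-mer is primitive (no internal repetition)
#'
#' A k-mer is primitive when no exact period p with p <= k/2 tiles the whole
#' string, i.e. it is not a whole-number tandem of a shorter unit. Seeding on
#' primitive decamers keeps microsatellite-degenerate seeds (poly-A, AC
#' dimers, ...) from flooding the cluster stage.
#'
#' @param kmer a 10-character DNA string over A/C/G/T
#' @return `TRUE` if the k-mer is primitive
#' @examples
#' is_primitive_kmer("ACACACACAC")  # FALSE, period 2
#' is_primitive_kmer("ACGTACGTTG")  # TRUE
#' @export
is_primitive_kmer <- function(kmer) {
  if (!is.character(kmer) || length(kmer) != 1L || nchar(kmer) != 10L)
    stop("kmer must be a single 10-character string")
  if (grepl("[^ACGT]", kmer)) stop("kmer must be over the alphabet A/C/G/T")
  .primitive_vec(kmer, 10L)
}

# vectorized primitivity over k-mers of common length k (no validation)
.primitive_vec <- function(kmers, k) {
  out <- rep(TRUE, length(kmers))
  for (p in seq_len(k %/% 2L)) {
    if (k %% p != 0L) next
    tiled <- strrep(substr(kmers, 1L, p), k %/% p)
    out <- out & (kmers != tiled)
  }
  out
}

#' Find seed clusters of repeated primitive decamers
#'
#' Scans each sequence for primitive k-mers that occur at least `min_copies`
#' times with all occurrences fitting inside a window of `window_nt` bases
#' (maximal sliding windows). Qualifying windows of all k-mers are merged
#' into candidate regions; k-mers containing N never seed.
#'
#' @param genome named character vector (or `DNAStringSet`) of chromosome
#'   sequences
#' @param k seed length in nt
#' @param min_copies minimum k-mer occurrences within one window
#' @param window_nt window size in nt
#' @return list of seed clusters; each is a list with elements `chrom`,
#'   `start`, `end` and `seeds` (a named list mapping each qualifying k-mer
#'   to its occurrence start positions inside the region)
#' @export
find_seed_clusters <- function(genome, k = 10L, min_copies = 4L,
                               window_nt = 800L) {
  genome <- .as_genome(genome)
  stopifnot(window_nt >= k * min_copies)
  out <- list()
  for (chrom in names(genome)) {
    seq <- genome[[chrom]]
    n <- nchar(seq)
    if (n < k * min_copies) next
    starts <- seq_len(n - k + 1L)
    kmers <- substring(seq, starts, starts + k - 1L)
    ok <- !grepl("N", kmers, fixed = TRUE)
    pos_by_kmer <- split(starts[ok], kmers[ok])
    pos_by_kmer <- pos_by_kmer[lengths(pos_by_kmer) >= min_copies]
    if (!length(pos_by_kmer)) next
    prim <- .primitive_vec(names(pos_by_kmer), k)
    pos_by_kmer <- pos_by_kmer[prim]
    if (!length(pos_by_kmer)) next

    ivs_start <- integer(0); ivs_end <- integer(0)
    seed_kmer <- character(0)
    seed_pos <- list()
    for (km in names(pos_by_kmer)) {
      p <- sort(pos_by_kmer[[km]])
      np <- length(p)
      i <- seq_len(np - min_copies + 1L)
      hit <- which(p[i + min_copies - 1L] - p[i] <= window_nt - k)
      if (!length(hit)) next
      ws <- p[hit]
      we <- p[hit + min_copies - 1L] + k - 1L
      red <- IRanges::reduce(IRanges::IRanges(ws, we))
      keep <- p[p >= min(ws) & p <= max(we)]
      for (j in seq_along(red)) {
        ivs_start <- c(ivs_start, IRanges::start(red)[j])
        ivs_end <- c(ivs_end, IRanges::end(red)[j])
        seed_kmer <- c(seed_kmer, km)
        inreg <- keep[keep >= IRanges::start(red)[j] &
                        keep <= IRanges::end(red)[j]]
        seed_pos[[length(seed_pos) + 1L]] <- inreg
      }
    }
    if (!length(ivs_start)) next
    merged <- IRanges::reduce(IRanges::IRanges(ivs_start, ivs_end))
    ov <- IRanges::findOverlaps(IRanges::IRanges(ivs_start, ivs_end), merged)
    for (m in seq_along(merged)) {
      idx <- S4Vectors::queryHits(ov)[S4Vectors::subjectHits(ov) == m]
      seeds <- stats::setNames(seed_pos[idx], seed_kmer[idx])
      # a k-mer can contribute several sub-windows; pool its positions
      seeds <- lapply(split(seeds, names(seeds)),
                      function(x) sort(unique(unlist(x))))
      out[[length(out) + 1L]] <- list(chrom = chrom,
                                      start = IRanges::start(merged)[m],
                                      end = IRanges::end(merged)[m],
                                      seeds = seeds)
    }
  }
  out
}

# per-column majority vote over a character matrix; ties broken A < C < G < T
.majority_consensus <- function(mat) {
  bases <- c("A", "C", "G", "T")
  apply(mat, 2L, function(col) {
    col <- col[col %in% bases]
    if (!length(col)) return("N")
    tab <- table(factor(col, levels = bases))
    bases[which.max(tab)]
  })
}

.rotate_chr <- function(v, k) {
  n <- length(v)
  if (n == 0L || k %% n == 0L) return(v)
  k <- k %% n
  c(v[(k + 1L):n], v[seq_len(k)])
}

#' Delimit a satellite array from a seed cluster
#'
#' Infers the repeat unit length as the modal spacing between consecutive
#' occurrences of the clustered k-mers (ties broken toward the smaller
#' length), builds a consensus unit at the anchor phase, extends the array
#' boundaries while unit-length windows match the consensus at
#' `extension_min_identity`, refines boundaries to the first/last run of
#' consecutively matching bases, and partitions the span into tandem copies
#' (copy lengths may deviate by small indels).
#'
#' @param cluster one element of [find_seed_clusters()] output
#' @param genome named character vector of chromosome sequences
#' @param min_copies minimum copy number for a reported satellite
#' @param extension_min_identity per-unit identity needed to keep extending
#' @param unit_range allowed repeat unit lengths, inclusive
#' @return a list of class `satellite_record` (fields `chrom`, `start`,
#'   `end`, `length`, `repeat_length`, `n_repeats`, `similarity`,
#'   `same_length_frac`, `repeats`), or `NULL` when the inferred unit is
#'   outside `unit_range` or fewer than `min_copies` copies remain
#' @export
delimit_satellite <- function(cluster, genome, min_copies = 4L,
                              extension_min_identity = 0.7,
                              unit_range = c(10L, 200L)) {
  genome <- .as_genome(genome)
  seq <- genome[[cluster$chrom]]
  n <- nchar(seq)

  spac_by_seed <- lapply(cluster$seeds, function(p) diff(sort(p)))
  spac <- unlist(spac_by_seed, use.names = FALSE)
  spac <- spac[spac >= unit_range[1] & spac <= unit_range[2]]
  if (!length(spac)) return(NULL)
  tab <- table(spac)
  L <- min(as.integer(names(tab)[tab == max(tab)]))

  n_at_L <- vapply(spac_by_seed, function(d) sum(d == L), integer(1))
  anchor <- names(cluster$seeds)[which.max(n_at_L)]
  ap <- sort(cluster$seeds[[anchor]])
  ap_full <- ap[ap + L - 1L <= n]
  if (!length(ap_full)) return(NULL)
  # keep only occurrences in the dominant phase class (mod L), so a chance
  # occurrence of the anchor in flanking background cannot skew the frame
  ph <- ap_full %% L
  tabp <- table(ph)
  modal_ph <- as.integer(names(tabp)[which.max(tabp)])
  ap_full <- ap_full[ph == modal_ph]
  a0 <- ap_full[1L]

  win_chars <- strsplit(substring(seq, ap_full, ap_full + L - 1L), "")
  cons <- .majority_consensus(do.call(rbind, win_chars))

  # periodic match vector around the cluster, phase anchored at a0
  lo <- max(1L, cluster$start - 2L * L - 50L)
  hi <- min(n, cluster$end + 2L * L + 50L)
  gch <- strsplit(substr(seq, lo, hi), "")[[1]]
  idx <- ((seq(lo, hi) - a0) %% L) + 1L
  m <- gch == cons[idx] & gch != "N"
  len <- length(m)

  # sliding unit-window identity via cumsum
  cs <- c(0, cumsum(m))
  nwin <- len - L + 1L
  if (nwin < 1L) return(NULL)
  wid <- (cs[(L + 1L):(len + 1L)] - cs[seq_len(nwin)]) / L

  i0 <- a0 - lo + 1L                      # index of anchor in m
  if (i0 < 1L || i0 > nwin) i0 <- max(1L, min(i0, nwin))
  cl <- i0
  while (cl - L >= 1L && wid[cl - L] >= extension_min_identity) cl <- cl - L
  cr <- i0
  while (cr + L <= nwin && wid[cr + L] >= extension_min_identity) cr <- cr + L
  right_edge <- cr + L - 1L               # index of last base of last window

  r <- min(10L, L)
  runlen <- function(i) sum(m[i:(i + r - 1L)])   # forward run at i
  # left boundary: smallest i near cl whose next r bases all match;
  # fall back to >= 0.8 r when mutations break the clean run
  cand <- seq(max(1L, cl - L), min(len - r + 1L, cl + 2L * L))
  rl <- vapply(cand, runlen, numeric(1))
  ileft <- cand[m[cand] & rl == r][1L]
  if (is.na(ileft)) ileft <- cand[m[cand] & rl >= ceiling(0.8 * r)][1L]
  if (is.na(ileft)) ileft <- cl

  runlen_rev <- function(i) sum(m[(i - r + 1L):i])
  cand_r <- seq(min(len, right_edge + L), max(r, right_edge - 2L * L))
  rr <- vapply(cand_r, runlen_rev, numeric(1))
  iright <- cand_r[m[cand_r] & rr == r][1L]
  if (is.na(iright)) iright <- cand_r[m[cand_r] & rr >= ceiling(0.8 * r)][1L]
  if (is.na(iright)) iright <- right_edge

  sat_start <- lo + ileft - 1L
  sat_end <- lo + iright - 1L
  if (sat_end - sat_start + 1L < 2L * L) return(NULL)

  # consensus rotated to the boundary phase, then greedy copy partition
  cons_b <- .rotate_chr(cons, (sat_start - a0) %% L)
  sat_chars <- gch[ileft:iright]
  copies <- character(0)
  cur <- 1L
  total <- length(sat_chars)
  while (cur <= total) {
    rem <- total - cur + 1L
    if (rem <= L + floor(L / 2)) {
      if (rem <= floor(L / 2) && length(copies)) {
        copies[length(copies)] <- paste0(copies[length(copies)],
          paste(sat_chars[cur:total], collapse = ""))
      } else {
        copies <- c(copies, paste(sat_chars[cur:total], collapse = ""))
      }
      break
    }
    dls <- c(0L, -1L, 1L, -2L, 2L, -3L, 3L)
    dls <- dls[L + dls >= 1L & L + dls <= rem]
    best_dl <- 0L; best_id <- -1
    for (dl in dls) {
      w <- sat_chars[cur:(cur + L + dl - 1L)]
      cmp <- min(L, L + dl)
      # length deviation counts as mismatch, so indel-free copies keep
      # their frame even when the unit's last bases are mutated
      id <- sum(w[seq_len(cmp)] == cons_b[seq_len(cmp)] &
                  w[seq_len(cmp)] != "N") / max(L, L + dl)
      if (id > best_id + 1e-12) { best_id <- id; best_dl <- dl }
    }
    copies <- c(copies, paste(sat_chars[cur:(cur + L + best_dl - 1L)],
                              collapse = ""))
    cur <- cur + L + best_dl
  }

  clens <- nchar(copies)
  tabc <- table(clens)
  rep_len <- min(as.integer(names(tabc)[tabc == max(tabc)]))
  if (length(copies) < min_copies) return(NULL)
  if (rep_len < unit_range[1] || rep_len > unit_range[2]) return(NULL)

  structure(list(
    chrom = cluster$chrom,
    start = sat_start,
    end = sat_end,
    length = sat_end - sat_start + 1L,
    repeat_length = rep_len,
    n_repeats = length(copies),
    similarity = repeat_similarity(copies, rep_len),
    same_length_frac = mean(clens == rep_len),
    repeats = copies
  ), class = "satellite_record")
}

#' Mean pairwise identity among same-length repeat copies
#'
#' The similarity parameter of a satellite: the mean ungapped position-wise
#' identity over all pairs of copies whose length equals `repeat_length`.
#' Copies of other lengths are excluded; N matches nothing. With fewer than
#' two same-length copies the similarity is undefined and `NA` is returned.
#'
#' @param repeats character vector of copy sequences
#' @param repeat_length the modal unit length in nt
#' @return fraction in `[0, 1]`, or `NA_real_`
#' @export
repeat_similarity <- function(repeats, repeat_length) {
  same <- repeats[nchar(repeats) == repeat_length]
  nc <- length(same)
  if (nc < 2L) return(NA_real_)
  mat <- do.call(rbind, strsplit(same, ""))
  bases <- c("A", "C", "G", "T")
  # pairs matching at a column = sum over bases of choose(count, 2)
  match_pairs <- sum(apply(mat, 2L, function(col) {
    tabs <- tabulate(factor(col, levels = bases), nbins = 4L)
    sum(choose(tabs, 2L))
  }))
  match_pairs / (choose(nc, 2L) * repeat_length)
}

#' Filter satellites on regularity
#'
#' Keeps records with `same_length_frac >= min_same_length_frac`, at least
#' `min_copies` repeats, and a unit length within `unit_range`; the result
#' is sorted by chromosome and start.
#'
#' @param records satellite data frame
#' @param min_same_length_frac minimum fraction of copies at the modal
#'   length
#' @param min_copies minimum number of repeats
#' @param unit_range allowed unit lengths
#' @return filtered, sorted satellite data frame
#' @export
filter_satellites <- function(records, min_same_length_frac = 0.6,
                              min_copies = 4L, unit_range = c(10L, 200L)) {
  if (!nrow(records)) return(records)
  keep <- records$same_length_frac >= min_same_length_frac &
    records$n_repeats >= min_copies &
    records$repeat_length >= unit_range[1] &
    records$repeat_length <= unit_range[2]
  out <- records[keep, , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect satellites in a genome
#'
#' Full detection pass: seed clustering, array delimitation, removal of
#' nested duplicates (the longer span wins), and the regularity filter.
#'
#' @inheritParams find_seed_clusters
#' @inheritParams delimit_satellite
#' @inheritParams filter_satellites
#' @return data frame with columns `satellite_id chrom start end length
#'   n_repeats repeat_length similarity same_length_frac sequence`; copy
#'   sequences are kept in the list attribute `repeats` keyed by
#'   `satellite_id`
#' @export
detect_satellites <- function(genome, k = 10L, min_copies = 4L,
                              window_nt = 800L, min_same_length_frac = 0.6,
                              extension_min_identity = 0.7,
                              unit_range = c(10L, 200L)) {
  genome <- .as_genome(genome)
  clusters <- find_seed_clusters(genome, k = k, min_copies = min_copies,
                                 window_nt = window_nt)
  recs <- lapply(clusters, delimit_satellite, genome = genome,
                 min_copies = min_copies,
                 extension_min_identity = extension_min_identity,
                 unit_range = unit_range)
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (!length(recs)) {
    empty <- data.frame(satellite_id = character(0), chrom = character(0),
                        start = integer(0), end = integer(0),
                        length = integer(0), n_repeats = integer(0),
                        repeat_length = integer(0), similarity = numeric(0),
                        same_length_frac = numeric(0),
                        sequence = character(0))
    attr(empty, "repeats") <- list()
    return(empty)
  }
  df <- data.frame(
    chrom = vapply(recs, `[[`, "", "chrom"),
    start = vapply(recs, `[[`, 0L, "start"),
    end = vapply(recs, `[[`, 0L, "end"),
    length = vapply(recs, `[[`, 0L, "length"),
    n_repeats = vapply(recs, `[[`, 0L, "n_repeats"),
    repeat_length = vapply(recs, `[[`, 0L, "repeat_length"),
    similarity = vapply(recs, `[[`, 0, "similarity"),
    same_length_frac = vapply(recs, `[[`, 0, "same_length_frac"),
    stringsAsFactors = FALSE
  )
  copies <- lapply(recs, `[[`, "repeats")

  # drop records nested inside a longer record on the same chromosome
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
  ov <- GenomicRanges::findOverlaps(gr, gr, type = "within")
  q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
  nested <- unique(q[q != s & df$length[q] <= df$length[s] &
                       !(df$length[q] == df$length[s] & q < s)])
  if (length(nested)) {
    df <- df[-nested, , drop = FALSE]
    copies <- copies[-nested]
  }

  df$sequence <- substring(genome[df$chrom], df$start, df$end)
  df <- cbind(satellite_id = paste0(df$chrom, "_", df$start), df,
              stringsAsFactors = FALSE)
  names(copies) <- df$satellite_id
  df <- filter_satellites(df, min_same_length_frac, min_copies, unit_range)
  attr(df, "repeats") <- copies[df$satellite_id]
  df
}
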