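# Independent oracles used across the suite. These deliberately take a
# different route than the package: Biostrings pairwiseAlignment for
# alignment scores, hclust for clustering, and plain brute-force scans for
# seed censuses and coverage stacking.

.submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                    baseOnly = TRUE)

# global Needleman-Wunsch score, linear gap -2, end gaps penalized
bios_nw <- function(a, b) {
  Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                Biostrings::DNAString(b),
                                substitutionMatrix = .submat,
                                gapOpening = 0, gapExtension = 2,
                                type = "global", scoreOnly = TRUE)
}

str_rots <- function(s) {
  n <- nchar(s)
  vapply(0:(n - 1), function(k) paste0(substr(s, k + 1, n), substr(s, 1, k)),
         "")
}

str_rc <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# exhaustive rotation x strand cyclic score, normalized like the package
cyclic_oracle <- function(a, b) {
  best <- -Inf
  for (bb in c(str_rots(b), str_rots(str_rc(b)))) {
    best <- max(best, bios_nw(a, bb))
  }
  min(1, max(0, best) / min(nchar(a), nchar(b)))
}

# brute-force decamer census: every primitive N-free k-mer whose i-th and
# (i+m-1)-th occurrences span <= window_nt marks the covered interval;
# intervals are merged by a sort-and-sweep
census_oracle <- function(genome, k = 10L, min_copies = 4L,
                          window_nt = 800L) {
  out <- list()
  for (chrom in names(genome)) {
    seq <- genome[[chrom]]
    n <- nchar(seq)
    if (n < k) next
    dict <- new.env(hash = TRUE)
    for (i in seq_len(n - k + 1L)) {
      km <- substr(seq, i, i + k - 1L)
      if (grepl("N", km, fixed = TRUE)) next
      dict[[km]] <- c(dict[[km]], i)
    }
    ivs <- NULL
    for (km in ls(dict)) {
      p <- dict[[km]]
      if (length(p) < min_copies) next
      prim <- TRUE
      for (per in seq_len(k %/% 2L)) {
        if (k %% per == 0L &&
            km == strrep(substr(km, 1, per), k %/% per)) prim <- FALSE
      }
      if (!prim) next
      for (i in seq_len(length(p) - min_copies + 1L)) {
        j <- i + min_copies - 1L
        if (p[j] + k - 1L - p[i] + 1L <= window_nt)
          ivs <- rbind(ivs, c(p[i], p[j] + k - 1L))
      }
    }
    if (is.null(ivs)) next
    ivs <- ivs[order(ivs[, 1], ivs[, 2]), , drop = FALSE]
    cur <- ivs[1, ]
    for (i in seq_len(nrow(ivs))[-1]) {
      if (ivs[i, 1] <= cur[2] + 1L) cur[2] <- max(cur[2], ivs[i, 2])
      else { out[[length(out) + 1L]] <- c(chrom, cur); cur <- ivs[i, ] }
    }
    out[[length(out) + 1L]] <- c(chrom, cur)
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  }
  df <- as.data.frame(do.call(rbind, out), stringsAsFactors = FALSE)
  names(df) <- c("chrom", "start", "end")
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  df[order(df$chrom, df$start), , drop = FALSE]
}

# full-DP read-vs-window oracle: the entire read is fit into the window
# (global-local), identity = matches / alignment columns
dp_match_oracle <- function(reads, windows, min_identity = 0.97,
                            min_cov = 0.9) {
  rows <- list()
  for (w in seq_len(nrow(windows))) {
    subj <- Biostrings::DNAString(windows$sequence[w])
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") reads else
        vapply(reads, str_rc, "", USE.NAMES = TRUE)
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAStringSet(pat), subj,
        substitutionMatrix = .submat, gapOpening = 0, gapExtension = 2,
        type = "global-local")
      cols <- Biostrings::nchar(aln)
      ident <- Biostrings::nmatch(aln) / cols
      keep <- which(ident >= min_identity & cols >= min_cov * nchar(reads))
      if (length(keep))
        rows[[length(rows) + 1L]] <- data.frame(
          read_id = names(reads)[keep],
          satellite_id = windows$satellite_id[w],
          identity = ident[keep], strand = strand,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(read_id = character(0), satellite_id = character(0),
                      identity = numeric(0), strand = character(0)))
  }
  hits <- do.call(rbind, rows)
  # one row per (read, window): best identity
  hits <- hits[order(hits$read_id, hits$satellite_id, -hits$identity), ]
  hits[!duplicated(hits[, c("read_id", "satellite_id")]), , drop = FALSE]
}

# O(hits x positions) coverage stacking
stacking_oracle <- function(hits, wlen, tissues, samples) {
  depth <- matrix(0L, length(tissues), wlen, dimnames = list(tissues, NULL))
  for (i in seq_len(nrow(hits))) {
    t <- samples$tissue[samples$sample_id == hits$sample_id[i]]
    for (pos in seq_len(wlen)) {
      if (pos >= hits$wstart[i] && pos <= hits$wend[i])
        depth[t, pos] <- depth[t, pos] + 1L
    }
  }
  depth
}

# independent average-linkage partition at a score threshold
avg_linkage_oracle <- function(S, threshold) {
  if (nrow(S) == 1L) return(stats::setNames(1L, rownames(S)))
  hc <- stats::hclust(stats::as.dist(1 - S), method = "average")
  stats::cutree(hc, h = 1 - threshold)
}

# canonical form of a partition for set comparison
partition_sets <- function(members_list) {
  sets <- unname(lapply(members_list, function(x) sort(unname(unlist(x)))))
  sets[order(vapply(sets, paste, "", collapse = ","))]
}
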