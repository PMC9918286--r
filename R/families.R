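## Satellite families: cyclic- and strand-aware alignment of repeat
## consensuses, agglomerative clustering at a normalized-score threshold,
## Fam_a_b_c naming.

.revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", vapply(s, function(x)
    paste(rev(strsplit(x, "")[[1]]), collapse = ""), "", USE.NAMES = FALSE))
}

.rotate_str <- function(s, k) {
  n <- nchar(s)
  k <- k %% n
  if (k == 0L) return(s)
  paste0(substr(s, k + 1L, n), substr(s, 1L, k))
}

#' Majority-rule repeat consensus of one satellite
#'
#' Chops the satellite sequence into consecutive unit-length windows and
#' takes a per-column majority vote (ties broken A < C < G < T). This is
#' deterministic from the satellite table alone, so consensuses survive a
#' table round trip.
#'
#' @param sequence full satellite sequence
#' @param repeat_length unit length in nt
#' @return consensus unit as a character string
#' @export
repeat_consensus <- function(sequence, repeat_length) {
  n <- nchar(sequence)
  nfull <- n %/% repeat_length
  if (nfull < 1L) stop("sequence shorter than one repeat unit")
  starts <- (seq_len(nfull) - 1L) * repeat_length + 1L
  wins <- substring(sequence, starts, starts + repeat_length - 1L)
  paste(.majority_consensus(do.call(rbind, strsplit(wins, ""))),
        collapse = "")
}

#' Cyclic- and strand-aware alignment score of two repeat units
#'
#' Globally aligns `a` (match +1, mismatch -1, linear gap -2) against every
#' cyclic rotation of `b` and of its reverse complement, takes the maximum
#' raw score, and normalizes by the maximum possible score -- a perfect
#' match of the shorter sequence -- clamping into `[0, 1]`. Ties in the
#' arg-max are broken toward the smallest rotation index, then the forward
#' strand.
#'
#' @param a,b DNA strings (repeat units, 1-200 nt)
#' @return list with `score` (normalized fraction), `strand` (`"+"` or
#'   `"-"`) and `rotation` (0-based left rotation of `b` achieving the
#'   maximum)
#' @export
cyclic_alignment_score <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  if (nchar(a) > 200L || nchar(b) > 200L) stop("units longer than 200 nt")
  best <- .cyclic_nw_best(a, b)
  norm <- max(0, best$score) / min(nchar(a), nchar(b))
  list(score = min(1, norm), strand = best$strand, rotation = best$rotation)
}

#' All-vs-all cyclic alignment score matrix
#'
#' Pairs whose unit lengths differ by more than `max_length_ratio` of the
#' longer unit are assigned score 0 without alignment. The matrix is
#' symmetric with unit diagonal.
#'
#' @param consensuses named character vector of repeat consensuses
#'   (names are satellite ids)
#' @param max_length_ratio length pre-filter fraction
#' @return list of class `score_matrix` with elements `ids` and `scores`
#' @export
build_score_matrix <- function(consensuses, max_length_ratio = 0.25) {
  ids <- names(consensuses)
  if (is.null(ids)) ids <- paste0("sat", seq_along(consensuses))
  n <- length(consensuses)
  S <- diag(1, n)
  lens <- nchar(consensuses)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (abs(lens[i] - lens[j]) / max(lens[i], lens[j]) > max_length_ratio) {
        S[i, j] <- S[j, i] <- 0
      } else {
        sc <- cyclic_alignment_score(consensuses[[i]], consensuses[[j]])$score
        S[i, j] <- S[j, i] <- sc
      }
    }
  }
  dimnames(S) <- list(ids, ids)
  structure(list(ids = ids, scores = S), class = "score_matrix")
}

#' Agglomerative clustering of the score matrix
#'
#' Repeatedly joins the pair of clusters with the highest inter-cluster
#' score (average linkage over member pairs) while that score is at least
#' `threshold`. Remaining singletons become single-member families. Ties
#' are broken toward the lowest pair of cluster indices, so the output is
#' deterministic.
#'
#' @param matrix a `score_matrix` from [build_score_matrix()]
#' @param threshold normalized-score threshold for merging
#' @return list of unnamed families, each a character vector of member ids
#' @export
progressive_cluster <- function(matrix, threshold = 0.6) {
  S <- matrix$scores
  ids <- matrix$ids
  n <- length(ids)
  if (n == 1L) return(list(ids))
  members <- as.list(seq_len(n))
  sizes <- rep(1L, n)
  A <- S
  diag(A) <- -Inf
  active <- rep(TRUE, n)
  repeat {
    Aact <- A
    Aact[!active, ] <- -Inf
    Aact[, !active] <- -Inf
    mx <- max(Aact)
    if (!is.finite(mx) || mx < threshold) break
    hit <- which(Aact == mx, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    i <- hit[1, 1]; j <- hit[1, 2]
    # average-linkage update: weighted mean of the two merged rows
    newrow <- (sizes[i] * A[i, ] + sizes[j] * A[j, ]) / (sizes[i] + sizes[j])
    A[i, ] <- newrow; A[, i] <- newrow
    A[i, i] <- -Inf
    active[j] <- FALSE
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- sizes[i] + sizes[j]
  }
  lapply(members[active], function(ix) ids[sort(ix)])
}

#' Consensus sequence of a satellite family
#'
#' Each member is strand-flipped and rotated into the frame of the first
#' member (the highest-scoring rotation from [cyclic_alignment_score()]),
#' then members of the modal unit length vote per column.
#'
#' @param members named character vector of member repeat consensuses
#' @return family consensus DNA string (length = modal member length)
#' @export
family_consensus <- function(members) {
  if (!length(members)) stop("empty family")
  if (length(members) == 1L) return(unname(members[[1]]))
  ref <- members[[1]]
  framed <- vapply(seq_along(members), function(i) {
    if (i == 1L) return(members[[i]])
    al <- cyclic_alignment_score(ref, members[[i]])
    b <- members[[i]]
    if (al$strand == "-") b <- .revcomp(b)
    .rotate_str(b, al$rotation)
  }, "")
  lens <- nchar(framed)
  tab <- table(lens)
  modal <- min(as.integer(names(tab)[tab == max(tab)]))
  voting <- framed[lens == modal]
  paste(.majority_consensus(do.call(rbind, strsplit(voting, ""))),
        collapse = "")
}

#' Assign Fam_a_b_c names to clustered families
#'
#' Rank `a` runs from 1 in descending member count; ties are broken by
#' ascending repeat size, then by the genome position of the first member.
#' `b` is the length of the family consensus and `c` the member count; a
#' family with `c = 1` is a unique satellite.
#'
#' @param families list of character vectors of member satellite ids
#' @param consensuses named character vector of per-satellite repeat
#'   consensuses
#' @param sats satellite data frame (for member genome positions)
#' @return data frame `family_name rank repeat_size n_members member_ids
#'   consensus`, one row per family, ordered by rank
#' @export
assign_family_names <- function(families, consensuses, sats) {
  n_members <- lengths(families)
  fam_cons <- vapply(families, function(mem)
    family_consensus(consensuses[mem]), "")
  repeat_size <- nchar(fam_cons)
  first_pos <- vapply(families, function(mem) {
    rows <- sats[match(mem, sats$satellite_id), , drop = FALSE]
    rows <- rows[order(rows$chrom, rows$start), , drop = FALSE]
    paste(rows$chrom[1], formatC(rows$start[1], width = 12, flag = "0"))
  }, "")
  ord <- order(-n_members, repeat_size, first_pos)
  data.frame(
    family_name = paste0("Fam_", seq_along(ord), "_",
                         repeat_size[ord], "_", n_members[ord]),
    rank = seq_along(ord),
    repeat_size = repeat_size[ord],
    n_members = n_members[ord],
    member_ids = vapply(families[ord], paste, "", collapse = ","),
    consensus = fam_cons[ord],
    stringsAsFactors = FALSE
  )
}

#' Cluster satellites into families
#'
#' Computes per-satellite repeat consensuses, the all-vs-all cyclic score
#' matrix, the agglomerative partition at `threshold`, and Fam_a_b_c names.
#'
#' @param sats satellite data frame from [detect_satellites()] or
#'   [read_satellite_table()]
#' @inheritParams build_score_matrix
#' @inheritParams progressive_cluster
#' @return list with `families` (family table), `satellites` (`sats` with a
#'   `family` column appended) and `scores` (the `score_matrix`)
#' @export
cluster_families <- function(sats, threshold = 0.6, max_length_ratio = 0.25) {
  if (!nrow(sats)) stop("no satellites to cluster")
  if (!"satellite_id" %in% names(sats))
    sats$satellite_id <- paste0(sats$chrom, "_", sats$start)
  cons <- stats::setNames(
    mapply(repeat_consensus, sats$sequence, sats$repeat_length,
           USE.NAMES = FALSE),
    sats$satellite_id)
  S <- build_score_matrix(cons, max_length_ratio = max_length_ratio)
  fams <- progressive_cluster(S, threshold = threshold)
  fam_table <- assign_family_names(fams, cons, sats)
  assign <- rep(NA_character_, nrow(sats))
  for (i in seq_len(nrow(fam_table))) {
    mem <- strsplit(fam_table$member_ids[i], ",")[[1]]
    assign[match(mem, sats$satellite_id)] <- fam_table$family_name[i]
  }
  sats$family <- assign
  list(families = fam_table, satellites = sats, scores = S)
}
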