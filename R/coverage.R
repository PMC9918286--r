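## Per-nucleotide transcription profiles over satellite +/- flank, one
## track per tissue, with the figure palette: grey muscle, blue neurons,
## red intestine, green hypodermis.

#' Per-nucleotide coverage profile of one satellite window
#'
#' For each tissue, `depth[pos]` is the number of retained (maximum-
#' accuracy) hits from that tissue's samples whose aligned span covers the
#' position; positions covered by no hit are 0 (zero ordinate means no
#' transcription).
#'
#' @param window one-row reference window (from
#'   [build_reference_windows()])
#' @param hits best-hit data frame restricted to this window's satellite,
#'   with a `sample_id` column (e.g. pooled rows of `hit_table$hits`)
#' @param samples sample sheet mapping `sample_id` to `tissue`
#' @return list of class `coverage_profile`: `satellite_id`, `wstart`,
#'   `wend`, `sstart`, `send`, and `depth`, a tissue x position integer
#'   matrix
#' @export
coverage_profile <- function(window, hits, samples) {
  stopifnot(nrow(window) == 1L)
  wlen <- window$wend - window$wstart + 1L
  tissues <- unique(samples$tissue)
  depth <- matrix(0L, length(tissues), wlen,
                  dimnames = list(tissues, NULL))
  hits <- hits[hits$satellite_id == window$satellite_id, , drop = FALSE]
  if (nrow(hits)) {
    hits$tissue <- samples$tissue[match(hits$sample_id, samples$sample_id)]
    for (t in tissues) {
      h <- hits[hits$tissue == t, , drop = FALSE]
      if (!nrow(h)) next
      # difference-array stacking: +1 at each span start, -1 after its end
      d <- integer(wlen + 1L)
      s <- pmax(1L, h$wstart); e <- pmin(wlen, h$wend)
      for (i in seq_len(nrow(h))) {
        d[s[i]] <- d[s[i]] + 1L
        d[e[i] + 1L] <- d[e[i] + 1L] - 1L
      }
      depth[t, ] <- cumsum(d[seq_len(wlen)])
    }
  }
  structure(list(satellite_id = window$satellite_id,
                 wstart = window$wstart, wend = window$wend,
                 sstart = window$sstart, send = window$send,
                 depth = depth),
            class = "coverage_profile")
}

#' Long-format table of a coverage profile
#'
#' @param profile a `coverage_profile`
#' @return data frame `position tissue depth` with 1-based genomic
#'   positions
#' @export
profile_table <- function(profile) {
  tissues <- rownames(profile$depth)
  pos <- seq(profile$wstart, profile$wend)
  data.frame(position = rep(pos, times = length(tissues)),
             tissue = rep(tissues, each = length(pos)),
             depth = as.integer(t(profile$depth)),
             stringsAsFactors = FALSE)
}

#' Render a coverage profile to an image file
#'
#' Line plot of hit depth per nucleotide across flank-satellite-flank, one
#' colored track per tissue (grey muscle, blue neurons, red intestine,
#' green hypodermis; other tissue names get default colors), with the
#' satellite boundaries marked. Output format follows the file extension
#' (png, svg, pdf).
#'
#' @param profile a `coverage_profile`
#' @param out_path image file to write
#' @param shared_scale force the same y-scale ceiling across tissues is the
#'   default (tracks share one panel); set a number to fix the ceiling
#' @return `out_path`, invisibly
#' @export
render_profile <- function(profile, out_path, shared_scale = NULL) {
  df <- profile_table(profile)
  known <- intersect(unique(df$tissue), names(TISSUE_COLORS))
  pal <- TISSUE_COLORS[known]
  extra <- setdiff(unique(df$tissue), known)
  if (length(extra))
    pal <- c(pal, stats::setNames(grDevices::palette()[seq_along(extra)],
                                  extra))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$depth,
                                        color = .data$tissue)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::geom_vline(xintercept = c(profile$sstart, profile$send),
                        linetype = "dashed", color = "grey30",
                        linewidth = 0.3) +
    ggplot2::scale_color_manual(values = pal) +
    ggplot2::labs(x = "genomic position", y = "RNA-seq hits",
                  title = profile$satellite_id, color = "tissue") +
    ggplot2::theme_minimal()
  if (!is.null(shared_scale))
    p <- p + ggplot2::coord_cartesian(ylim = c(0, shared_scale))
  ggplot2::ggsave(out_path, p, width = 8, height = 3, dpi = 150)
  invisible(out_path)
}
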