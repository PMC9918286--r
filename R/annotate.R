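## Genomic context of satellites: intergenic / intron / exon against gene
## models, plus overlap with transposon (Helitron) annotation intervals.

#' Read gene models from GFF3/GTF
#'
#' Only `gene` and `exon` records are used; exons are pooled across
#' transcripts (union per gene is implied by overlap-based classification).
#'
#' @param path GFF3 or GTF file
#' @return list with `genes` and `exons`, both `GRanges`
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  type <- as.character(gr$type)
  list(genes = gr[type == "gene"], exons = gr[type == "exon"])
}

#' Read repeat (e.g. Helitron) annotation from BED
#'
#' @param path BED file with at least chrom/start/end/name
#' @return `GRanges` with a `name` column
#' @export
read_repeat_annotation <- function(path) {
  rtracklayer::import(path, format = "BED")
}

.sat_granges <- function(sats) {
  GenomicRanges::GRanges(sats$chrom, IRanges::IRanges(sats$start, sats$end))
}

#' Classify satellite genomic context
#'
#' A satellite is `exon` if it overlaps any exon by at least 1 nt, else
#' `intron` if it overlaps any gene span, else `intergenic` (priority
#' exon > intron > intergenic). Satellites on chromosomes absent from the
#' annotation are classified intergenic with a warning.
#'
#' @param sats satellite data frame (or a single-row record)
#' @param genes list with `genes`/`exons` `GRanges`, as from
#'   [read_gene_models()]
#' @return character vector, one of `"intergenic"`, `"intron"`, `"exon"`
#'   per satellite
#' @export
classify_location <- function(sats, genes) {
  if (!is.data.frame(sats)) sats <- as.data.frame(sats)
  gr <- .sat_granges(sats)
  known <- unique(c(as.character(GenomicRanges::seqnames(genes$genes)),
                    as.character(GenomicRanges::seqnames(genes$exons))))
  missing <- setdiff(unique(sats$chrom), known)
  if (length(missing))
    warning("chromosome(s) absent from gene annotation, classified ",
            "intergenic: ", paste(missing, collapse = ", "))
  out <- rep("intergenic", nrow(sats))
  if (length(genes$genes)) {
    in_gene <- suppressWarnings(
      IRanges::overlapsAny(gr, genes$genes, ignore.strand = TRUE))
    out[in_gene] <- "intron"
  }
  if (length(genes$exons)) {
    in_exon <- suppressWarnings(
      IRanges::overlapsAny(gr, genes$exons, ignore.strand = TRUE))
    out[in_exon] <- "exon"
  }
  out
}

#' Overlap satellites with repeat annotation intervals
#'
#' @param sats satellite data frame
#' @param repeats `GRanges` with a `name` column (e.g. Helitron intervals)
#' @return list of character vectors: labels of all intervals overlapping
#'   each satellite by at least 1 nt (empty when none)
#' @export
overlap_repeat_annotation <- function(sats, repeats) {
  if (!is.data.frame(sats)) sats <- as.data.frame(sats)
  gr <- .sat_granges(sats)
  out <- replicate(nrow(sats), character(0), simplify = FALSE)
  if (!length(repeats)) return(out)
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(gr, repeats, ignore.strand = TRUE))
  labs <- as.character(repeats$name)
  for (i in seq_along(out)) {
    hit <- S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == i]
    out[[i]] <- labs[hit]
  }
  out
}

#' Annotate satellites with location class and repeat labels
#'
#' Appends `location` and `repeat_labels` (comma-joined) columns to the
#' satellite table; optionally restricts to intergenic satellites.
#'
#' @param sats satellite data frame
#' @param genes gene models (list of `GRanges`, or a GFF3/GTF path)
#' @param repeats repeat annotation (`GRanges`, a BED path, or `NULL`)
#' @param only_intergenic drop intron/exon satellites from the result
#' @return annotated satellite data frame
#' @export
annotate_satellites <- function(sats, genes, repeats = NULL,
                                only_intergenic = FALSE) {
  if (is.character(genes)) genes <- read_gene_models(genes)
  if (is.character(repeats)) repeats <- read_repeat_annotation(repeats)
  sats$location <- classify_location(sats, genes)
  if (!is.null(repeats)) {
    labs <- overlap_repeat_annotation(sats, repeats)
    sats$repeat_labels <- vapply(labs, paste, "", collapse = ",")
  } else {
    sats$repeat_labels <- ""
  }
  if (only_intergenic)
    sats <- sats[sats$location == "intergenic", , drop = FALSE]
  rownames(sats) <- NULL
  sats
}
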