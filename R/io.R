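#' Read a genome FASTA into a named character vector
#'
#' Sequences are uppercased and any letter outside A/C/G/T is mapped to N.
#' Record names are truncated at the first whitespace. Gzipped FASTA is
#' accepted.
#'
#' @param path path to a (optionally gzipped) FASTA file
#' @return named character vector, one element per sequence record
#' @export
read_genome <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  if (length(dss) == 0L) stop("no sequences in ", path)
  nm <- sub("\\s.*$", "", names(dss))
  seqs <- toupper(as.character(dss))
  seqs <- gsub("[^ACGT]", "N", seqs)
  stats::setNames(seqs, nm)
}

.as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    g <- toupper(as.character(genome))
    g <- gsub("[^ACGT]", "N", g)
    names(g) <- sub("\\s.*$", "", names(genome))
    return(g)
  }
  if (is.character(genome)) {
    if (is.null(names(genome))) names(genome) <- paste0("chr", seq_along(genome))
    return(genome)
  }
  stop("genome must be a named character vector or DNAStringSet")
}

#' Write / read the satellite table
#'
#' Tab-separated, one row per satellite, 1-based inclusive coordinates.
#' Core columns are `chrom start end length n_repeats repeat_length
#' similarity same_length_frac sequence`; any extra annotation columns
#' (family, location, ...) are preserved.
#'
#' @param sats satellite data frame as returned by [detect_satellites()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_satellite_table <- function(sats, path) {
  utils::write.table(sats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_satellite_table
#' @export
read_satellite_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = NA, stringsAsFactors = FALSE)
  df$chrom <- as.character(df$chrom)
  df$sequence <- as.character(df$sequence)
  df
}

#' Export satellites as BED6
#'
#' One interval per satellite with name `SAT_<chrom>_<start>`, score
#' `round(1000 * similarity)` and strand `+` (a tandem array is its own
#' reverse complement's array; strand only matters in family alignment).
#'
#' @inheritParams write_satellite_table
#' @export
write_satellite_bed <- function(sats, path) {
  score <- round(1000 * ifelse(is.na(sats$similarity), 0, sats$similarity))
  bed <- data.frame(chrom = sats$chrom,
                    start = sats$start - 1L,   # BED is 0-based half-open
                    end = sats$end,
                    name = paste0("SAT_", sats$chrom, "_", sats$start),
                    score = score,
                    strand = "+")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' Expects tab-separated columns `sample_id`, `tissue`, `fastq_path`.
#'
#' @param path path to the sample sheet TSV
#' @return data frame with one row per sample
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "tissue", "fastq_path")
  if (!all(need %in% names(df)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  df
}
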