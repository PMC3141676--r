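#' Reverse complement of DNA character vectors
#'
#' Thin wrapper around [Biostrings::reverseComplement()] returning plain
#' character vectors, used throughout for strand bookkeeping.
#'
#' @param x character vector of DNA sequences (A/C/G/T).
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Round half up
#'
#' Base R's `round()` rounds half to even; summary tables in this package
#' follow the report convention of rounding half away from zero.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage helpers for report tables
#'
#' `pct2()` renders a proportion as a percentage with two decimals
#' (category and overlap tables); `pct_whole()` to the nearest whole
#' percent (library summary table). Both round half up.
#'
#' @param num,den numerator and denominator counts.
#' @return numeric percentage.
#' @export
pct2 <- function(num, den) round_half_up(100 * num / den, 2)

#' @rdname pct2
#' @export
pct_whole <- function(num, den) round_half_up(100 * num / den, 0)

#' Render a genomic location string
#'
#' `chrom:start:end:strand` with 1-based inclusive coordinates.
#'
#' @param chrom,start,end,strand location components.
#' @return character vector.
#' @export
location_string <- function(chrom, start, end, strand) {
  paste(chrom, start, end, strand, sep = ":")
}

#' Write tags as collapsed FASTA
#'
#' Collapsed small-RNA FASTA dialect: one record per unique tag with header
#' `tagN_xCOUNT`, where COUNT is the tag's total redundant read count.
#'
#' @param tags tag table from [collapse_reads()].
#' @param path output file.
#' @param lib library id whose counts to use; `NULL` sums all libraries.
#' @return `path`, invisibly.
#' @export
write_collapsed_fasta <- function(tags, path, lib = NULL) {
  counts <- if (is.null(lib)) tag_totals(tags) else tags[[lib]]
  keep <- counts > 0
  seqs <- Biostrings::DNAStringSet(tags$seq[keep])
  names(seqs) <- sprintf("tag%d_x%d", seq_len(sum(keep)), counts[keep])
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read collapsed FASTA back into a tag table
#'
#' @param path collapsed FASTA file with `tagN_xCOUNT` headers.
#' @param lib library id to assign the counts to.
#' @return tag table (`seq` plus one count column).
#' @export
read_collapsed_fasta <- function(path, lib = "lib1") {
  seqs <- Biostrings::readDNAStringSet(path)
  counts <- as.integer(sub(".*_x(\\d+)$", "\\1", names(seqs)))
  out <- data.frame(seq = as.character(seqs), stringsAsFactors = FALSE)
  out[[lib]] <- counts
  out
}

# total redundant count per tag across all library columns
tag_totals <- function(tags) {
  libcols <- setdiff(names(tags), "seq")
  if (length(libcols) == 0) return(integer(nrow(tags)))
  as.integer(rowSums(as.matrix(tags[, libcols, drop = FALSE])))
}

# library ids (count columns) of a tag table
tag_libs <- function(tags) setdiff(names(tags), "seq")
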