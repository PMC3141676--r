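#' Build an exact-match genome index
#'
#' Prepares both strands of the reference for all-hits, zero-mismatch
#' lookup (the mapping policy is: report every hit, allow no mismatch).
#' Matching is delegated to Biostrings' exact string matching; the index
#' object holds the forward sequences and chromosome lengths.
#'
#' @param genome DNAStringSet (or named character vector).
#' @return object of class `genome_index`.
#' @export
build_index <- function(genome) {
  if (!methods::is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(genome)
  if (is.null(names(genome))) stop("genome sequences must be named")
  structure(list(genome = genome,
                 lengths = setNames(Biostrings::width(genome), names(genome))),
            class = "genome_index")
}

#' Map one tag to the genome, all hits, both strands, no mismatches
#'
#' A minus-strand hit means the tag equals the reverse complement of the
#' genome interval.  Hits are sorted by (chrom, start, strand).
#'
#' @param tag tag sequence (A/C/G/T only; N is rejected).
#' @param index a [build_index()] object.
#' @return data.frame with columns chrom, strand, start, end (1-based
#'   inclusive); zero rows if unmapped.
#' @export
map_tag <- function(tag, index) {
  stopifnot(inherits(index, "genome_index"))
  if (grepl("[^ACGT]", tag))
    stop("tag contains a non-ACGT character; the index is defined over ACGT")
  pat <- Biostrings::DNAString(tag)
  rcp <- Biostrings::reverseComplement(pat)
  hits <- list()
  for (chrom in names(index$genome)) {
    subj <- index$genome[[chrom]]
    for (strand in c("+", "-")) {
      m <- Biostrings::matchPattern(if (strand == "+") pat else rcp, subj)
      if (length(m))
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = chrom, strand = strand,
          start = Biostrings::start(m), end = Biostrings::end(m),
          stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(chrom = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out[order(out$chrom, out$start, out$strand), , drop = FALSE]
}

#' Map every tag of a tag table
#'
#' @param tags tag table (column `seq`).
#' @param index a [build_index()] object.
#' @return data.frame of hits with a `seq` column identifying the tag.
#' @export
map_tags <- function(tags, index) {
  empty <- data.frame(chrom = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      seq = character(0), stringsAsFactors = FALSE)
  if (!nrow(tags)) return(empty)
  if (any(grepl("[^ACGT]", tags$seq)))
    stop("tags contain non-ACGT characters; the index is defined over ACGT")
  chrom_str <- as.character(index$genome)
  res <- list()
  # batched exact matching: hash every genome substring of each tag
  # length against the tag set (plus strand) and its reverse
  # complements (minus strand)
  for (L in sort(unique(nchar(tags$seq)))) {
    fwd <- tags$seq[nchar(tags$seq) == L]
    rc <- revcomp(fwd)
    for (chrom in names(chrom_str)) {
      n <- index$lengths[[chrom]]
      if (n < L) next
      subs <- substring(chrom_str[[chrom]], 1:(n - L + 1), L:n)
      for (strand in c("+", "-")) {
        m <- match(subs, if (strand == "+") fwd else rc)
        pos <- which(!is.na(m))
        if (!length(pos)) next
        res[[length(res) + 1L]] <- data.frame(
          chrom = chrom, strand = strand, start = pos, end = pos + L - 1L,
          seq = fwd[m[pos]], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out[order(out$seq, out$chrom, out$start, out$strand), , drop = FALSE]
}

#' Per-chromosome, per-strand redundant read profile
#'
#' With `weighting = "all"` every hit receives the tag's full redundant
#' count (matching the all-hits mapping policy); with `"fractional"`,
#' count divided by the tag's hit number.
#'
#' @param tags tag table with library count columns.
#' @param hits hit table from [map_tags()].
#' @param weighting `"all"` or `"fractional"`.
#' @param lib library id; `NULL` sums all libraries.
#' @return data.frame chrom x strand with read weights.
#' @export
strand_profile <- function(tags, hits, weighting = c("all", "fractional"),
                           lib = NULL) {
  weighting <- match.arg(weighting)
  counts <- if (is.null(lib)) tag_totals(tags) else tags[[lib]]
  names(counts) <- tags$seq
  if (!nrow(hits))
    return(data.frame(chrom = character(0), strand = character(0),
                      reads = numeric(0), stringsAsFactors = FALSE))
  w <- counts[hits$seq]
  if (weighting == "fractional") {
    nh <- table(hits$seq)
    w <- w / as.numeric(nh[hits$seq])
  }
  agg <- stats::aggregate(w, by = list(chrom = hits$chrom,
                                       strand = hits$strand), FUN = sum)
  names(agg)[3] <- "reads"
  agg[order(agg$chrom, agg$strand), , drop = FALSE]
}

#' Sliding-window read hotspots
#'
#' Windows of `window_len` advanced by `step` along each chromosome and
#' strand; windows whose redundant read count (tag 5'-end within the
#' window, full count per hit) reaches `min_reads` are merged into
#' maximal runs, re-counted, and returned sorted by read count
#' descending (ties by coordinate order).
#'
#' @param tags tag table.
#' @param hits hit table from [map_tags()].
#' @param index genome index (for chromosome lengths).
#' @param window_len,step window geometry (nt).
#' @param min_reads window threshold; default 1% of the total redundant
#'   reads in `tags`.
#' @param lib library id; `NULL` sums all libraries.
#' @return data.frame chrom, strand, start, end, reads.
#' @export
find_hotspots <- function(tags, hits, index, window_len = 1000, step = 500,
                          min_reads = NULL, lib = NULL) {
  counts <- if (is.null(lib)) tag_totals(tags) else tags[[lib]]
  names(counts) <- tags$seq
  if (is.null(min_reads)) min_reads <- 0.01 * sum(counts)
  if (!nrow(hits))
    return(data.frame(chrom = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      reads = numeric(0), stringsAsFactors = FALSE))
  # tag 5' end: start on +, end on -
  p5 <- ifelse(hits$strand == "+", hits$start, hits$end)
  w <- as.numeric(counts[hits$seq])
  out <- list()
  for (chrom in unique(hits$chrom)) {
    L <- index$lengths[[chrom]]
    starts <- seq(1, max(1, L - window_len + 1), by = step)
    for (strand in c("+", "-")) {
      sel <- hits$chrom == chrom & hits$strand == strand
      if (!any(sel)) next
      pp <- p5[sel]; ww <- w[sel]
      win_reads <- vapply(starts, function(s)
        sum(ww[pp >= s & pp <= s + window_len - 1]), numeric(1))
      hot <- win_reads >= min_reads
      if (!any(hot)) next
      # merge consecutive hot windows into maximal runs
      r <- rle(hot)
      endsI <- cumsum(r$lengths); startsI <- endsI - r$lengths + 1
      for (k in which(r$values)) {
        s <- starts[startsI[k]]
        e <- min(L, starts[endsI[k]] + window_len - 1)
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, strand = strand, start = s, end = e,
          reads = sum(ww[pp >= s & pp <= e]), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      reads = numeric(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(-res$reads, res$chrom, res$start, res$strand), , drop = FALSE]
}

#' Compare two loci by best local alignment
#'
#' Smith-Waterman local alignment (match +1, mismatch -1, gap -2) via
#' Biostrings; identity is computed over aligned columns excluding gaps.
#' Used to ask whether two hotspot loci are homologous (e.g. the two
#' copies of an organellar inverted repeat).
#'
#' @param seqA,seqB character sequences.
#' @return list with `identity` (in `[0,1]`), `gap_fraction`,
#'   `aligned_length` and `coverage` (aligned length over the shorter
#'   input; near 0 for unrelated sequences, 1 for full-length homology).
#' @export
align_loci <- function(seqA, seqB) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = TRUE)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seqA), Biostrings::DNAString(seqB),
    type = "local", substitutionMatrix = sm,
    gapOpening = 0, gapExtension = 2)
  nm <- Biostrings::nmatch(al)
  nmm <- Biostrings::nmismatch(al)
  alen <- Biostrings::nchar(al)  # alignment length including gaps
  gaps <- alen - (nm + nmm)
  list(identity = if (nm + nmm > 0) nm / (nm + nmm) else 0,
       gap_fraction = if (alen > 0) gaps / alen else 0,
       aligned_length = alen,
       coverage = alen / min(nchar(seqA), nchar(seqB)))
}
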