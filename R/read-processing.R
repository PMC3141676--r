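#' Trim adapters and filter raw small-RNA reads
#'
#' The 3' adapter is located by an exact match of its first 8 nt anywhere
#' in the read, trimming at the leftmost occurrence; reads with no
#' detectable 3' adapter are dropped as unligated artifacts (a genuine
#' 18-28 nt insert must read through into the adapter on this platform).
#' If the 5' adapter's terminal 8 nt prefix the read it is removed.
#' Reads with any base below the quality threshold or any N, and inserts
#' outside `[min_len, max_len]`, are dropped and counted.
#'
#' @param reads named character vector of raw reads; a `quality`
#'   attribute (phred33 strings, as from [read_fastq_reads()]) is used if
#'   present, otherwise quality filtering is skipped.
#' @param adapter3 3' adapter sequence (required, non-empty).
#' @param adapter5 5' adapter sequence or `NULL`.
#' @param min_len,max_len retained insert length bounds.
#' @param min_quality minimum per-base phred score.
#' @return list with `inserts` (named character vector of clean inserts)
#'   and `dropped` (named integer vector: no_adapter, low_quality,
#'   too_short, too_long).
#' @export
trim_and_filter <- function(reads, adapter3, adapter5 = NULL,
                            min_len = 18, max_len = 30, min_quality = 20) {
  if (is.null(adapter3) || !nzchar(adapter3))
    stop("adapter3 must be a non-empty sequence")
  qual <- attr(reads, "quality")
  seqs <- toupper(as.character(reads))
  n <- length(seqs)
  drop_reason <- character(n)

  key <- substr(adapter3, 1, 8)
  pos <- regexpr(key, seqs, fixed = TRUE)
  drop_reason[pos < 0] <- "no_adapter"
  inserts <- ifelse(pos > 0, substr(seqs, 1, pos - 1), "")

  if (!is.null(adapter5) && nzchar(adapter5)) {
    tail5 <- substr(adapter5, max(1, nchar(adapter5) - 7), nchar(adapter5))
    has5 <- startsWith(inserts, tail5)
    inserts[has5] <- substr(inserts[has5], nchar(tail5) + 1,
                            nchar(inserts[has5]))
  }

  # quality: any call below threshold, or any N in the insert
  bad_q <- grepl("N", inserts, fixed = TRUE)
  if (!is.null(qual)) {
    minchar <- rawToChar(as.raw(33 + min_quality))
    low <- vapply(seq_len(n), function(i) {
      ins_len <- nchar(inserts[i])
      if (ins_len == 0 || drop_reason[i] != "") return(FALSE)
      q <- substr(qual[i], 1, ins_len)
      any(utf8ToInt(q) < 33 + min_quality)
    }, logical(1))
    bad_q <- bad_q | low
  }
  drop_reason[drop_reason == "" & bad_q] <- "low_quality"

  len <- nchar(inserts)
  drop_reason[drop_reason == "" & len < min_len] <- "too_short"
  drop_reason[drop_reason == "" & len > max_len] <- "too_long"

  keep <- drop_reason == ""
  dropped <- c(no_adapter = sum(drop_reason == "no_adapter"),
               low_quality = sum(drop_reason == "low_quality"),
               too_short = sum(drop_reason == "too_short"),
               too_long = sum(drop_reason == "too_long"))
  list(inserts = setNames(inserts[keep], names(seqs)[keep]),
       dropped = dropped)
}

#' Collapse clean reads into unique tags with per-library counts
#'
#' @param clean_by_lib named list: library id -> character vector of
#'   clean insert sequences.
#' @return tag table: data.frame with column `seq` plus one redundant
#'   count column per library; the count columns re-sum to the clean
#'   read totals.
#' @export
collapse_reads <- function(clean_by_lib) {
  all_seqs <- sort(unique(unlist(clean_by_lib, use.names = FALSE)))
  out <- data.frame(seq = all_seqs, stringsAsFactors = FALSE)
  for (lib in names(clean_by_lib)) {
    tab <- table(clean_by_lib[[lib]])
    out[[lib]] <- as.integer(tab[out$seq])
    out[[lib]][is.na(out[[lib]])] <- 0L
  }
  out
}

#' Per-library summary of a tag table
#'
#' Totals, unique and singleton tag counts (singletons as a whole-percent
#' share of unique tags, the library-table convention), and length
#' histograms over 10-30 nt for unique tags and redundant reads.
#'
#' @param tags tag table from [collapse_reads()].
#' @param lib library id (a count column of `tags`).
#' @return list with `total_reads`, `unique_tags`, `singleton_tags`,
#'   `singleton_pct`, `length_hist` (matrix: unique/total x 10-30).
#' @export
summarize_library <- function(tags, lib) {
  cnt <- tags[[lib]]
  present <- cnt > 0
  len <- nchar(tags$seq[present])
  bins <- 10:30
  h_unique <- vapply(bins, function(L) sum(len == L), integer(1))
  h_total <- vapply(bins, function(L) sum(cnt[present][len == L]), numeric(1))
  hist <- rbind(unique = h_unique, total = h_total)
  colnames(hist) <- bins
  unique_tags <- sum(present)
  singleton <- sum(cnt == 1)
  list(total_reads = sum(cnt),
       unique_tags = unique_tags,
       singleton_tags = singleton,
       singleton_pct = pct_whole(singleton, unique_tags),
       length_hist = hist)
}

#' Positionwise base composition of tags
#'
#' Fraction of A/C/G/T at read positions 1-24; tags shorter than a
#' position do not contribute there.  `mode = "total"` weights each tag
#' by its redundant read count, `"unique"` counts each tag once.
#'
#' @param tags tag table.
#' @param mode `"unique"` or `"total"`.
#' @param positions positions to report (default 1-24).
#' @return 4 x length(positions) matrix of fractions (columns sum to 1).
#' @export
position_base_bias <- function(tags, mode = c("unique", "total"),
                               positions = 1:24) {
  mode <- match.arg(mode)
  w <- if (mode == "total") tag_totals(tags) else rep(1L, nrow(tags))
  keep <- w > 0
  seqs <- tags$seq[keep]; w <- w[keep]
  lens <- nchar(seqs)
  out <- matrix(0, 4, length(positions),
                dimnames = list(c("A", "C", "G", "T"), positions))
  for (pi in seq_along(positions)) {
    p <- positions[pi]
    sel <- lens >= p
    if (!any(sel)) next
    base <- substr(seqs[sel], p, p)
    tw <- tapply(w[sel], factor(base, levels = c("A", "C", "G", "T")), sum)
    tw[is.na(tw)] <- 0
    out[, pi] <- tw / sum(tw)
  }
  out
}

#' Common and specific tags between two libraries
#'
#' Overlap report in the pairwise-comparison table shape: unique-tag and
#' redundant-read counts for the shared and library-specific fractions,
#' with percentages to two decimals.  The unique denominator is the union
#' (`uniqueA + uniqueB - common`); the total denominator is
#' `totalA + totalB`; shared redundant reads count all copies of shared
#' tag sequences in both libraries.
#'
#' @param tags tag table containing both libraries' count columns.
#' @param libA,libB library ids.
#' @return data.frame with rows Total, common, A-specific, B-specific.
#' @export
compare_samples <- function(tags, libA, libB) {
  a <- tags[[libA]]; b <- tags[[libB]]
  inA <- a > 0; inB <- b > 0
  uniqueA <- sum(inA); uniqueB <- sum(inB)
  common_unique <- sum(inA & inB)
  union_unique <- uniqueA + uniqueB - common_unique
  totalA <- sum(a); totalB <- sum(b)
  common_total <- sum(a[inA & inB]) + sum(b[inA & inB])
  a_spec_total <- sum(a[inA & !inB])
  b_spec_total <- sum(b[inB & !inA])
  grand_total <- totalA + totalB
  cls <- c("Total_sRNAs", paste0(libA, "_&_", libB),
           paste0(libA, "_specific"), paste0(libB, "_specific"))
  u <- c(union_unique, common_unique, uniqueA - common_unique,
         uniqueB - common_unique)
  t <- c(grand_total, common_total, a_spec_total, b_spec_total)
  data.frame(class = cls,
             unique_srna = u,
             unique_pct = pct2(u, union_unique),
             total_srna = t,
             total_pct = pct2(t, grand_total),
             stringsAsFactors = FALSE)
}
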