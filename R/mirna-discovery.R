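#' Select candidate tags for precursor structure filtering
#'
#' Kept iff the tag's total redundant read count across libraries is
#' greater than one and it has between 1 and `max_hits` genome hits.
#'
#' @param tags tag table.
#' @param hits hit table from [map_tags()].
#' @param max_hits maximum genome hit count (default 20).
#' @return logical vector over rows of `tags`.
#' @export
select_candidates <- function(tags, hits, max_hits = 20) {
  nh <- table(hits$seq)
  hitcount <- as.integer(nh[tags$seq])
  hitcount[is.na(hitcount)] <- 0L
  tag_totals(tags) > 1 & hitcount >= 1 & hitcount <= max_hits
}

#' Extract the folding window around a genome hit
#'
#' `flank` nt upstream and downstream of the hit, clipped at chromosome
#' ends; for minus-strand hits the window is reverse-complemented so the
#' mature tag always reads 5' to 3' left to right within the window.
#'
#' @param hit one-row hit data.frame (chrom, strand, start, end).
#' @param genome DNAStringSet.
#' @param flank window flank (nt), default 300.
#' @return list: `seq`, `mature_start`, `mature_end` (1-based within the
#'   window), plus the genomic window interval.
#' @export
extract_window <- function(hit, genome, flank = 300) {
  L <- Biostrings::width(genome)[match(hit$chrom, names(genome))]
  ws <- max(1L, hit$start - flank)
  we <- min(L, hit$end + flank)
  s <- as.character(Biostrings::subseq(genome[[hit$chrom]], ws, we))
  if (hit$strand == "-") {
    s <- revcomp(s)
    m_start <- we - hit$end + 1L
  } else {
    m_start <- hit$start - ws + 1L
  }
  m_end <- m_start + (hit$end - hit$start)
  list(seq = s, mature_start = m_start, mature_end = m_end,
       chrom = hit$chrom, strand = hit$strand,
       win_start = ws, win_end = we)
}

#' Evaluate the hairpin precursor criteria at a candidate locus
#'
#' Folds the window (unless a fold is supplied), locates the star arm as
#' the positions paired to the mature arm, and accepts iff: the mature
#' pairs to the star with at least `min_pairs` base pairs; at most
#' `max_bulges` asymmetric interruptions (bulges); mature length within
#' `mature_len`; the mature does not span the terminal loop (partners on
#' both sides); and the precursor -- mature + star + loop extended by
#' `precursor_flank` nt each side -- folds at or below `max_energy`
#' kcal/mol.  Symmetric interruptions are counted separately as
#' mismatches (reported, not thresholded, matching the distinction the
#' characteristics table draws between bulges and mismatched positions).
#'
#' @param window output of [extract_window()].
#' @param fold_res optional precomputed [fold()] of `window$seq`.
#' @param max_energy,min_pairs,max_bulges,mature_len,precursor_flank
#'   acceptance thresholds (-18 kcal/mol, 16 bp, 4, 18-25 nt, 20 nt).
#' @return list with `accepted`, `reason` (NA if accepted), and the
#'   candidate fields: paired_bases, bulges, mismatches, star and
#'   precursor intervals (window coordinates), precursor_mfe,
#'   precursor_seq.
#' @export
hairpin_check <- function(window, fold_res = NULL, max_energy = -18,
                          min_pairs = 16, max_bulges = 4,
                          mature_len = c(18, 25), precursor_flank = 20) {
  m1 <- window$mature_start; m2 <- window$mature_end
  mlen <- m2 - m1 + 1L
  rej <- function(reason) list(accepted = FALSE, reason = reason)
  if (mlen < mature_len[1] || mlen > mature_len[2])
    return(rej("mature-length"))
  if (is.null(fold_res)) fold_res <- fold(window$seq)

  # stage 1: locate the star arm in the window fold
  d <- duplex_stats(fold_res$partner, m1, m2)
  if (!d$ok) return(rej(d$reason))
  if (d$paired_bases < min_pairs) return(rej("pairs"))
  if (d$bulges > max_bulges) return(rej("bulges"))

  # excise the precursor: duplex plus terminal loop, extended by the
  # retained flank
  pre1 <- max(1L, min(m1, d$star[1]) - precursor_flank)
  pre2 <- min(nchar(window$seq), max(m2, d$star[2]) + precursor_flank)
  pre_seq <- substr(window$seq, pre1, pre2)

  # stage 2: the excised precursor must itself fold into the reported
  # stem-loop (this is what checking a candidate precursor with a
  # folding program means); all reported characteristics come from the
  # precursor's own fold
  pf <- fold(pre_seq)
  if (pf$mfe > max_energy) return(rej("energy"))
  dp <- duplex_stats(pf$partner, m1 - pre1 + 1L, m2 - pre1 + 1L)
  if (!dp$ok) return(rej(paste0("refold-", dp$reason)))
  if (dp$paired_bases < min_pairs) return(rej("refold-pairs"))
  if (dp$bulges > max_bulges) return(rej("refold-bulges"))

  list(accepted = TRUE, reason = NA_character_,
       paired_bases = dp$paired_bases, bulges = dp$bulges,
       mismatches = dp$mismatches,
       star_start = pre1 + dp$star[1] - 1L, star_end = pre1 + dp$star[2] - 1L,
       precursor_start = pre1, precursor_end = pre2,
       precursor_mfe = pf$mfe, precursor_seq = pre_seq)
}

# Locate the star arm paired to the mature interval [m1, m2] in a
# pairing vector, and walk the mature:star duplex.  The star is the
# dominant pairing side (a few stray pairs to the other side are
# ignored; substantial pairing on both sides means the mature straddles
# the terminal loop).  Interruptions larger than `max_gap` bases on
# either side disqualify the duplex (miRNA:miRNA* bulges and loops span
# a few bases at most).
duplex_stats <- function(partner, m1, m2, max_gap = 3L) {
  mp <- partner[m1:m2]
  # positions pairing back into the mature itself are the hairpin apex:
  # more than a few means the mature contains the terminal loop
  n_intra <- sum(!is.na(mp) & mp >= m1 & mp <= m2)
  if (n_intra / 2 > 4)
    return(list(ok = FALSE, reason = "loop-spanning"))
  paired_idx <- which(!is.na(mp) & (mp < m1 | mp > m2))
  if (length(paired_idx) == 0)
    return(list(ok = FALSE, reason = "pairs", paired_bases = 0L))
  partners <- mp[paired_idx]
  n_down <- sum(partners > m2); n_up <- sum(partners < m1)
  if (min(n_down, n_up) > 4)
    return(list(ok = FALSE, reason = "loop-spanning"))
  star_side <- if (n_down >= n_up) partners > m2 else partners < m1
  paired_idx <- paired_idx[star_side]
  partners <- partners[star_side]
  mat_pos <- (m1:m2)[paired_idx]
  bulges <- 0L; mismatches <- 0L
  for (k in seq_len(length(mat_pos) - 1)) {
    gm <- mat_pos[k + 1] - mat_pos[k] - 1L
    gs <- abs(partners[k + 1] - partners[k]) - 1L
    if (gm > max_gap || gs > max_gap)
      return(list(ok = FALSE, reason = "discontinuous"))
    if (gm == gs) mismatches <- mismatches + gm
    else bulges <- bulges + 1L
  }
  list(ok = TRUE, reason = NA_character_,
       paired_bases = length(paired_idx), bulges = bulges,
       mismatches = mismatches, star = range(partners))
}

#' 5'-end homogeneity of reads over a precursor
#'
#' Numerator: redundant reads whose genome hit lies on the mature strand
#' with the exact mature 5' end; denominator: all redundant reads whose
#' hit lies within the precursor interval on that strand.  Fraction 0/0
#' when no reads map (flagged by the zero denominator).
#'
#' @param tags tag table with library count columns.
#' @param hits hit table (with `seq`).
#' @param precursor list/row with chrom, strand, start, end (genomic).
#' @param mature_p5 genomic position of the mature 5' end (start on the
#'   plus strand, end on the minus strand).
#' @param lib library id.
#' @return list `num`, `den`, `fraction` (0 if den is 0).
#' @export
five_prime_homogeneity <- function(tags, hits, precursor, mature_p5, lib) {
  counts <- setNames(tags[[lib]], tags$seq)
  sel <- hits$chrom == precursor$chrom &
    hits$strand == precursor$strand &
    hits$start >= precursor$start & hits$end <= precursor$end
  h <- hits[sel, , drop = FALSE]
  if (!nrow(h)) return(list(num = 0L, den = 0L, fraction = 0))
  w <- as.integer(counts[h$seq]); w[is.na(w)] <- 0L
  p5 <- if (precursor$strand == "+") h$start else h$end
  num <- sum(w[p5 == mature_p5])
  den <- sum(w)
  list(num = num, den = den,
       fraction = if (den > 0) num / den else 0)
}

#' Accept or reject a candidate from its p-value and 5' homogeneity
#'
#' For precursors with shuffle-test p <= 0.05 the best library's
#' homogeneity must exceed 0.5; for p > 0.05 it must reach 0.75.
#' Monotone in homogeneity.
#'
#' @param p_value shuffle-test p-value.
#' @param homogeneity named numeric vector, one fraction per library.
#' @return list `accepted`, `best_lib`, `best_fraction`, `rule`.
#' @export
decide_mirna <- function(p_value, homogeneity) {
  best <- which.max(homogeneity)
  f <- homogeneity[[best]]
  if (p_value <= 0.05) {
    list(accepted = f > 0.5, best_lib = names(homogeneity)[best],
         best_fraction = f, rule = "p<=0.05: homogeneity > 0.5")
  } else {
    list(accepted = f >= 0.75, best_lib = names(homogeneity)[best],
         best_fraction = f, rule = "p>0.05: homogeneity >= 0.75")
  }
}

#' Discover miRNAs from candidate tags
#'
#' The full discovery chain: candidate selection (reads > 1, 1-20 genome
#' hits), 300-nt flank window extraction at every hit, folding, hairpin
#' criteria, dinucleotide-shuffle stability test on the precursor, 5'
#' homogeneity per library, and the p-value/homogeneity decision.  When
#' several hits of one tag yield accepted hairpins, the most stable
#' precursor (lowest MFE) is reported, reflecting the expectation of a
#' single precursor per miRNA.  Candidates within 10% of any threshold
#' are flagged `needs_review` (the mechanical residue of manual
#' rechecking).
#'
#' @param tags tag table (the non-annotated and known-miRNA homolog
#'   tags are the intended input).
#' @param hits hit table for those tags.
#' @param genome DNAStringSet.
#' @param n_shuffles shuffle count for the stability test.
#' @param flank extraction flank (300 nt).
#' @param params optional overrides passed to [hairpin_check()].
#' @return data.frame report, one row per accepted candidate, with
#'   attribute `rejected` (data.frame of rejected candidates + reasons).
#' @export
discover_mirnas <- function(tags, hits, genome, n_shuffles = 199,
                            flank = 300, params = list()) {
  keep <- select_candidates(tags, hits)
  cand <- tags[keep, , drop = FALSE]
  # process by descending read count: the best-supported tag at a locus
  # defines its precursor; lesser tags inside an accepted precursor are
  # reads of the same hairpin (a miRNA has one precursor), not
  # independent candidates
  cand <- cand[order(-tag_totals(cand), cand$seq), , drop = FALSE]
  accepted_loci <- list()
  libs <- tag_libs(tags)
  rows <- list(); rejected <- list()
  for (i in seq_len(nrow(cand))) {
    s <- cand$seq[i]
    h_all <- hits[hits$seq == s, , drop = FALSE]
    subsumed <- FALSE
    for (al in accepted_loci) {
      inside <- h_all$chrom == al$chrom & h_all$strand == al$strand &
        h_all$start >= al$start & h_all$end <= al$end
      if (any(inside)) { subsumed <- TRUE; break }
    }
    if (subsumed) {
      rejected[[length(rejected) + 1L]] <- data.frame(
        seq = s, stage = "locus",
        reason = "within an accepted precursor",
        stringsAsFactors = FALSE)
      next
    }
    h <- hits[hits$seq == s, , drop = FALSE]
    best <- NULL
    reasons <- character(0)
    for (r in seq_len(nrow(h))) {
      # full search window first; if the global fold buries the arm in
      # flank structure, retry tighter excisions around the locus
      for (fl in unique(pmin(flank, c(flank, 100, 50)))) {
        win <- extract_window(h[r, ], genome, fl)
        hc <- do.call(hairpin_check, c(list(window = win), params))
        if (hc$accepted) break
      }
      if (!hc$accepted) { reasons <- c(reasons, hc$reason); next }
      if (is.null(best) || hc$precursor_mfe < best$hc$precursor_mfe)
        best <- list(hc = hc, win = win, hit = h[r, ])
    }
    if (is.null(best)) {
      rejected[[length(rejected) + 1L]] <- data.frame(
        seq = s, stage = "hairpin",
        reason = paste(unique(reasons), collapse = ";"),
        stringsAsFactors = FALSE)
      next
    }
    hc <- best$hc; win <- best$win; hit <- best$hit
    rf <- randfold_p(hc$precursor_seq, n_shuffles)
    # precursor interval in genomic coordinates
    if (hit$strand == "+") {
      g1 <- win$win_start + hc$precursor_start - 1L
      g2 <- win$win_start + hc$precursor_end - 1L
      mature_p5 <- hit$start
    } else {
      g1 <- win$win_end - hc$precursor_end + 1L
      g2 <- win$win_end - hc$precursor_start + 1L
      mature_p5 <- hit$end
    }
    precursor <- list(chrom = hit$chrom, strand = hit$strand,
                      start = g1, end = g2)
    hom <- lapply(setNames(libs, libs), function(lib)
      five_prime_homogeneity(tags, hits, precursor, mature_p5, lib))
    fr <- vapply(hom, `[[`, numeric(1), "fraction")
    dec <- decide_mirna(rf$p_value, fr)
    if (!dec$accepted) {
      rejected[[length(rejected) + 1L]] <- data.frame(
        seq = s, stage = "decision",
        reason = sprintf("p=%.3f best homogeneity=%.3f", rf$p_value,
                         dec$best_fraction),
        stringsAsFactors = FALSE)
      next
    }
    accepted_loci[[length(accepted_loci) + 1L]] <- precursor
    needs_review <- (abs(rf$p_value - 0.05) < 0.005) ||
      (hc$paired_bases <= 17) || (hc$precursor_mfe > -19.8) ||
      (abs(dec$best_fraction - if (rf$p_value <= 0.05) 0.5 else 0.75) < 0.05)
    row <- data.frame(
      seq = s,
      location = location_string(hit$chrom, g1, g2, hit$strand),
      mfe = round(hc$precursor_mfe, 1),
      len = g2 - g1 + 1L,
      p_value = rf$p_value,
      bulges = hc$bulges,
      mismatches = hc$mismatches,
      needs_review = needs_review,
      stringsAsFactors = FALSE)
    for (lib in libs)
      row[[lib]] <- sprintf("%d/%d", hom[[lib]]$num, hom[[lib]]$den)
    row$best_lib <- dec$best_lib
    row$precursor_seq <- hc$precursor_seq
    rows[[length(rows) + 1L]] <- row
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seq = character(0), location = character(0),
               mfe = numeric(0), len = integer(0), p_value = numeric(0),
               bulges = integer(0), mismatches = integer(0),
               needs_review = logical(0), stringsAsFactors = FALSE)
  attr(out, "rejected") <- if (length(rejected)) do.call(rbind, rejected)
    else data.frame(seq = character(0), stage = character(0),
                    reason = character(0), stringsAsFactors = FALSE)
  out
}

#' Summary statistics of a precursor characteristics table
#'
#' Length range and floor-of-mean, MFE range and two-decimal mean -- the
#' summary conventions of the characteristics table (mean length is the
#' integer part of the arithmetic mean).
#'
#' @param report data.frame with `len` and `mfe` columns.
#' @return list: n, len_min, len_max, len_mean (floored), mfe_min,
#'   mfe_max, mfe_mean (2 dp).
#' @export
precursor_summary <- function(report) {
  if (!nrow(report)) return(list(n = 0L))
  list(n = nrow(report),
       len_min = min(report$len), len_max = max(report$len),
       len_mean = floor(mean(report$len)),
       mfe_min = min(report$mfe), mfe_max = max(report$mfe),
       mfe_mean = round_half_up(mean(report$mfe), 2))
}

#' Write a discovery report: TSV table, precursor FASTA + structures, GFF3
#'
#' @param report output of [discover_mirnas()].
#' @param dir output directory.
#' @param prefix file name prefix.
#' @return `dir`, invisibly.
#' @export
write_mirna_report <- function(report, dir, prefix = "mirna") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- report[, setdiff(names(report), "precursor_seq"), drop = FALSE]
  write.table(tab, file.path(dir, paste0(prefix, "_report.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(report)) {
    pre <- Biostrings::DNAStringSet(report$precursor_seq)
    names(pre) <- report$location
    Biostrings::writeXStringSet(pre, file.path(dir, paste0(prefix, "_precursors.fa")))
    db <- vapply(report$precursor_seq, function(s) fold(s)$structure, "")
    writeLines(paste0(">", report$location, "\n", report$precursor_seq,
                      "\n", db),
               file.path(dir, paste0(prefix, "_structures.txt")))
    loc <- strsplit(report$location, ":")
    gr <- GenomicRanges::GRanges(
      vapply(loc, `[`, "", 1),
      IRanges::IRanges(as.integer(vapply(loc, `[`, "", 2)),
                       as.integer(vapply(loc, `[`, "", 3))),
      strand = vapply(loc, `[`, "", 4),
      type = "miRNA_primary_transcript")
    rtracklayer::export(gr, file.path(dir, paste0(prefix, "_precursors.gff3")),
                        format = "gff3")
  }
  invisible(dir)
}
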