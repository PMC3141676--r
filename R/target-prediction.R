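#' Duplex scoring parameters
#'
#' Alignment scores for miRNA:target duplexes: Watson-Crick +5, G:U
#' wobble +1, mismatch -3, gap -9, with match/mismatch contributions at
#' seed positions 2-8 (from the miRNA 5' end) multiplied by `scaling`.
#' Candidate sites must reach `min_score` and a duplex energy at or
#' below `max_energy` kcal/mol.
#'
#' @param min_score alignment score threshold S (default 90).
#' @param max_energy duplex free-energy threshold (default -20 kcal/mol).
#' @param scaling seed weight multiplier (default 2, must be >= 1).
#' @param match,gu,mm,gap position scores.
#' @param seed seed position range (miRNA 5'-based).
#' @return parameter list of class `duplex_params`.
#' @export
duplex_params <- function(min_score = 90, max_energy = -20, scaling = 2,
                          match = 5, gu = 1, mm = -3, gap = -9,
                          seed = c(2, 8)) {
  if (scaling < 1) stop("scaling must be >= 1")
  if (min_score <= 0) stop("min_score must be positive")
  structure(list(min_score = min_score, max_energy = max_energy,
                 scaling = scaling, match = match, gu = gu, mm = mm,
                 gap = gap, seed = seed), class = "duplex_params")
}

#' Align a miRNA against one target window
#'
#' The miRNA (5' to 3') is aligned to the antiparallel target window;
#' every miRNA position receives a state: `WC` (A:U/G:C), `GU` (wobble),
#' `MM` (mismatch) or `GAP` (miRNA base opposite a target gap).
#' Unaligned target overhangs are free.  Duplex energy is the stacking
#' energy over consecutive paired positions, computed with the same
#' nearest-neighbour table as the folding engine, so the energy ratio
#' against the perfect complement is internally consistent.
#'
#' @param mirna miRNA sequence (5' to 3').
#' @param target target window sequence (5' to 3').
#' @param params a [duplex_params()].
#' @return list of class `duplex`: mirna, target, score, states
#'   (character vector along the miRNA), tpartner (target position
#'   paired to each miRNA position), energy.
#' @export
duplex_align <- function(mirna, target, params = duplex_params()) {
  res <- duplex_align_cpp(toupper(mirna), toupper(target),
                          params$match, params$gu, params$mm, params$gap,
                          params$scaling, params$seed[1], params$seed[2])
  states <- c("WC", "GU", "MM", "GAP")[res$states + 1]
  d <- list(mirna = toupper(mirna), target = toupper(target),
            score = res$score, states = states, tpartner = res$tpartner)
  d$energy <- duplex_energy(d)
  class(d) <- "duplex"
  d
}

# stacking energy of a duplex alignment: consecutive miRNA positions
# both paired (WC or GU) to adjacent target positions
duplex_energy <- function(duplex, stack = rna_stacking_energies()) {
  mb <- chartr("T", "U", strsplit(duplex$mirna, "")[[1]])
  tb <- chartr("T", "U", strsplit(duplex$target, "")[[1]])
  ptab <- c(AU = 1, CG = 2, GC = 3, UA = 4, GU = 5, UG = 6)
  L <- length(mb)
  e <- 0
  for (i in seq_len(L - 1)) {
    if (duplex$states[i] %in% c("WC", "GU") &&
        duplex$states[i + 1] %in% c("WC", "GU") &&
        !is.na(duplex$tpartner[i]) && !is.na(duplex$tpartner[i + 1]) &&
        duplex$tpartner[i] - duplex$tpartner[i + 1] == 1) {
      p1 <- ptab[[paste0(mb[i], tb[duplex$tpartner[i]])]]
      p2 <- ptab[[paste0(mb[i + 1], tb[duplex$tpartner[i + 1]])]]
      e <- e + stack[p1, p2]
    }
  }
  e
}

# energy of the miRNA bound to its exact complement
perfect_complement_energy <- function(mirna,
                                      stack = rna_stacking_energies()) {
  comp <- chartr("ACGTU", "UGCAA", chartr("T", "U", toupper(mirna)))
  mb <- strsplit(chartr("T", "U", toupper(mirna)), "")[[1]]
  cb <- strsplit(comp, "")[[1]]
  ptab <- c(AU = 1, CG = 2, GC = 3, UA = 4, GU = 5, UG = 6)
  e <- 0
  for (i in seq_len(length(mb) - 1))
    e <- e + stack[ptab[[paste0(mb[i], cb[i])]],
                   ptab[[paste0(mb[i + 1], cb[i + 1])]]]
  e
}

#' Scan a transcript for candidate miRNA target sites
#'
#' Slides a window of `nchar(mirna) + 3` along the transcript, aligns
#' the miRNA to each window, and returns every site whose best duplex
#' reaches the score threshold and whose duplex energy is at or below
#' the energy threshold; overlapping passing windows are collapsed to
#' the best-scoring one.
#'
#' @param mirna miRNA sequence.
#' @param transcript transcript sequence.
#' @param params a [duplex_params()].
#' @return list of `duplex` objects, each with `site_start`/`site_end`
#'   (1-based transcript coordinates).
#' @export
scan_targets <- function(mirna, transcript, params = duplex_params()) {
  Lm <- nchar(mirna); Lt <- nchar(transcript)
  wlen <- Lm + 3
  if (Lt < wlen) return(list())
  if (!is.finite(params$min_score)) return(list())
  starts <- seq_len(Lt - wlen + 1)
  cands <- list()
  for (s in starts) {
    win <- substr(transcript, s, s + wlen - 1)
    d <- duplex_align(mirna, win, params)
    if (d$score >= params$min_score && d$energy <= params$max_energy) {
      d$site_start <- s; d$site_end <- s + wlen - 1
      cands[[length(cands) + 1L]] <- d
    }
  }
  if (!length(cands)) return(list())
  # collapse overlapping windows: keep the best score per cluster
  ord <- order(vapply(cands, `[[`, numeric(1), "site_start"))
  cands <- cands[ord]
  out <- list(cands[[1]])
  for (d in cands[-1]) {
    last <- out[[length(out)]]
    if (d$site_start <= last$site_end) {
      if (d$score > last$score) out[[length(out)]] <- d
    } else out[[length(out) + 1L]] <- d
  }
  out
}

#' Per-position states and weighted mismatch counts of a duplex
#'
#' G:U wobbles count 0.5 mismatches; mismatches and gaps count 1.
#'
#' @param duplex a `duplex` object (or a bare state vector).
#' @return list: `states`, and `weighted(range)` closure-free helper
#'   fields `w_2_21`, `w_1_12` (weighted counts over those miRNA
#'   position ranges).
#' @export
classify_positions <- function(duplex) {
  states <- if (is.list(duplex)) duplex$states else duplex
  wt <- function(range) {
    idx <- intersect(range, seq_along(states))
    sum((states[idx] %in% c("MM", "GAP")) + 0.5 * (states[idx] == "GU"))
  }
  list(states = states, w_2_21 = wt(2:21), w_1_12 = wt(1:12))
}

# TRUE if any `run_len` consecutive positions in `idx` are all MM/GAP
has_adjacent_mm <- function(states, idx, run_len = 2) {
  mm <- states %in% c("MM", "GAP")
  idx <- intersect(idx, seq_along(states))
  for (i in idx) {
    hi <- i + run_len - 1
    if (hi <= max(idx) && all(mm[i:hi])) return(TRUE)
  }
  FALSE
}

#' Strict target-site rules
#'
#' The six-rule filter: weighted mismatches <= 4 at positions 2-21; no
#' run of 3 consecutive mismatches anywhere (at most 2 adjacent); no two
#' adjacent mismatches in positions 2-12; strict Watson-Crick at
#' positions 10-11; weighted mismatches <= 2.5 at positions 1-12 (G:U =
#' 0.5 throughout); and duplex energy above 74% of the energy of the
#' miRNA bound to its perfect complement.  Positions count from the
#' miRNA 5' end; gaps count as mismatches.
#'
#' @param duplex a `duplex` object from [duplex_align()].
#' @return list of per-rule logicals (`mm_2_21`, `adjacent_total`,
#'   `adjacent_2_12`, `perfect_10_11`, `weighted_1_12`, `mfe_ratio`),
#'   the `ratio` itself, weighted count `w_1_12`, and `pass`.
#' @export
rule_filter_strict <- function(duplex) {
  cp <- classify_positions(duplex)
  states <- cp$states
  L <- length(states)
  perfect <- perfect_complement_energy(duplex$mirna)
  ratio <- if (perfect < 0) duplex$energy / perfect else 0
  v <- list(
    mm_2_21 = cp$w_2_21 <= 4,
    adjacent_total = !has_adjacent_mm(states, 1:L, run_len = 3),
    adjacent_2_12 = !has_adjacent_mm(states, 2:12, run_len = 2),
    perfect_10_11 = all(states[intersect(10:11, 1:L)] == "WC"),
    weighted_1_12 = cp$w_1_12 <= 2.5,
    mfe_ratio = ratio > 0.74)
  v$ratio <- ratio
  v$w_1_12 <- cp$w_1_12
  v$pass <- all(unlist(v[c("mm_2_21", "adjacent_total", "adjacent_2_12",
                           "perfect_10_11", "weighted_1_12", "mfe_ratio")]))
  v
}

#' Relaxed target-site rules
#'
#' Only the positions 2-21 rule is enforced (weighted mismatches <= 4);
#' position 1 and positions beyond 21 are ignored entirely.  Any duplex
#' passing the strict filter passes the relaxed one.
#'
#' @param duplex a `duplex` object (or bare state vector).
#' @return list with `mm_2_21` and `pass`.
#' @export
rule_filter_relaxed <- function(duplex) {
  cp <- classify_positions(duplex)
  list(mm_2_21 = cp$w_2_21 <= 4, pass = cp$w_2_21 <= 4)
}

#' Predict targets of a miRNA set over a transcript set
#'
#' @param mirnas named character vector of miRNA sequences.
#' @param transcripts named character vector of transcript sequences.
#' @param params a [duplex_params()].
#' @param rules `"strict"` or `"relaxed"`.
#' @return data.frame: mirna, transcript, site coordinates, score,
#'   energy, ratio, per-rule verdicts, pass.
#' @export
predict_targets <- function(mirnas, transcripts, params = duplex_params(),
                            rules = c("strict", "relaxed")) {
  rules <- match.arg(rules)
  rows <- list()
  for (mn in names(mirnas)) {
    for (tn in names(transcripts)) {
      sites <- scan_targets(mirnas[[mn]], transcripts[[tn]], params)
      for (d in sites) {
        v <- rule_filter_strict(d)
        vr <- rule_filter_relaxed(d)
        pass <- if (rules == "strict") v$pass else vr$pass
        rows[[length(rows) + 1L]] <- data.frame(
          mirna = mn, transcript = tn,
          site_start = d$site_start, site_end = d$site_end,
          score = d$score, energy = d$energy, ratio = v$ratio,
          mm_2_21 = v$mm_2_21, adjacent_total = v$adjacent_total,
          adjacent_2_12 = v$adjacent_2_12,
          perfect_10_11 = v$perfect_10_11,
          weighted_1_12 = v$weighted_1_12, mfe_ratio = v$mfe_ratio,
          pass = pass, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(mirna = character(0), transcript = character(0),
                      site_start = integer(0), site_end = integer(0),
                      score = numeric(0), energy = numeric(0),
                      ratio = numeric(0), pass = logical(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
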