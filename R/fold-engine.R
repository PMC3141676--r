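#' Nearest-neighbour stacking free energies
#'
#' The 6x6 table of helix stacking free-energy increments (kcal/mol at
#' 37 degrees C) used by the folding engine.  Rows index the pair closing
#' the stack on the 5' side, columns the enclosed pair; pair types are
#' `AU, CG, GC, UA, GU, UG`.  Values follow the standard RNA
#' nearest-neighbour parameterisation including G:U wobbles (the two
#' destabilising wobble-on-wobble stacks are positive and are simply never
#' selected by the energy minimisation).
#'
#' @return numeric 6x6 matrix with dimnames.
#' @export
rna_stacking_energies <- function() {
  p <- c("AU", "CG", "GC", "UA", "GU", "UG")
  m <- matrix(c(
    # AU     CG     GC     UA     GU     UG
    -0.93, -2.24, -2.08, -1.10, -0.55, -1.36,   # AU
    -2.11, -3.26, -2.36, -2.08, -1.41, -2.11,   # CG
    -2.35, -3.42, -3.26, -2.24, -1.53, -2.51,   # GC
    -1.33, -2.35, -2.11, -0.93, -1.00, -1.27,   # UA
    -1.27, -2.51, -2.11, -1.36, -0.50,  1.29,   # GU
    -1.00, -1.53, -1.41, -0.55,  0.30, -0.50),  # UG
    nrow = 6, byrow = TRUE, dimnames = list(p, p))
  m
}

#' Loop penalties of the folding energy model
#'
#' Destabilising free-energy penalties (kcal/mol) for loops, sized the
#' way thermodynamic folders size them: a hairpin loop of `s` unpaired
#' bases costs `hairpin + hairpin_log * log(s / minloop)`
#' (Jacobson-Stockmayer entropy form); an interior or bulge loop of `s`
#' total unpaired bases costs `interior + interior_per_nt * s`; a
#' multiloop costs a flat `multiloop`.  Together with the stacking
#' table these define the engine's nearest-neighbour model: helices are
#' stabilising, every loop costs and grows costlier with size, unpaired
#' external bases are free.
#'
#' @return named numeric vector (hairpin, hairpin_log, interior,
#'   interior_per_nt, multiloop).
#' @export
fold_loop_penalties <- function() {
  c(hairpin = 5.0, hairpin_log = 1.1, interior = 2.0,
    interior_per_nt = 0.5, multiloop = 4.6)
}

#' Fold an RNA (or DNA) sequence
#'
#' Minimum-free-energy secondary structure over all pseudoknot-free
#' structures, by dynamic programming under a nearest-neighbour model:
#' adjacent base pairs contribute stacking energies, hairpin, interior/
#' bulge and multiloops incur the flat penalties of
#' [fold_loop_penalties()], and unpaired external bases are free.
#' Watson-Crick and G:U pairs are admissible; hairpin loops span at
#' least `minloop` unpaired bases; interior/bulge loops are capped at
#' `maxloop` total unpaired bases (the standard folding restriction).
#' T is mapped to U on input.
#'
#' The engine is deterministic and self-contained; an alternative
#' thermodynamic backend can be substituted anywhere a fold result is
#' consumed, since downstream code only uses the structure string, the
#' partner vector and the energy.
#'
#' @param seq a single sequence (character).
#' @param minloop minimum hairpin loop length (unpaired bases), default 3.
#' @param maxloop maximum total unpaired bases in an interior loop.
#' @param stack stacking-energy table, see [rna_stacking_energies()].
#' @param penalties loop penalties, see [fold_loop_penalties()].
#' @return list with `structure` (dot-bracket), `mfe` (kcal/mol, <= 0) and
#'   `partner` (1-based pairing partner per position, NA if unpaired).
#' @export
#' @examples
#' fold("GGGGAAAACCCC")
fold <- function(seq, minloop = 3, maxloop = 10,
                 stack = rna_stacking_energies(),
                 penalties = fold_loop_penalties()) {
  stopifnot(is.character(seq), length(seq) == 1)
  if (nchar(seq) > 1000) stop("fold() accepts sequences up to 1000 nt")
  fold_dp_cpp(seq, stack, as.integer(minloop), as.integer(maxloop),
              penalties[["hairpin"]], penalties[["hairpin_log"]],
              penalties[["interior"]], penalties[["interior_per_nt"]],
              penalties[["multiloop"]])
}

#' Minimum free energy for many sequences
#'
#' Batch version of [fold()] returning energies only (no traceback);
#' used by the shuffle significance test.
#'
#' @param seqs character vector of sequences.
#' @inheritParams fold
#' @return numeric vector of MFEs.
#' @export
fold_mfe <- function(seqs, minloop = 3, maxloop = 10,
                     stack = rna_stacking_energies(),
                     penalties = fold_loop_penalties()) {
  fold_mfe_batch_cpp(as.character(seqs), stack, as.integer(minloop),
                     as.integer(maxloop), penalties[["hairpin"]],
                     penalties[["hairpin_log"]], penalties[["interior"]],
                     penalties[["interior_per_nt"]],
                     penalties[["multiloop"]])
}

#' Exhaustive-enumeration folding reference
#'
#' Independent reference for [fold()]: enumerates every pseudoknot-free
#' structure of a short sequence recursively, scores each under the same
#' stacking model, and returns the minimum.  Exponential; intended for
#' sequences of at most ~14 nt in cross-checks.
#'
#' @inheritParams fold
#' @return list with `mfe` and `n_structures` enumerated.
#' @export
fold_exhaustive <- function(seq, minloop = 3,
                            stack = rna_stacking_energies(),
                            penalties = fold_loop_penalties()) {
  s <- chartr("Tt", "Uu", toupper(seq))
  b <- strsplit(s, "")[[1]]
  n <- length(b)
  if (n > 16) stop("exhaustive enumeration is limited to 16 nt")
  pidx <- function(i, j) {
    key <- paste0(b[i], b[j])
    switch(key, AU = 1, CG = 2, GC = 3, UA = 4, GU = 5, UG = 6, 0L)
  }
  # enumerate pair lists on [i, j]
  enum <- function(i, j) {
    if (j - i < minloop + 1) return(list(list()))
    out <- enum(i + 1, j)                  # i unpaired
    for (k in (i + minloop + 1):j) {
      if (pidx(i, k) > 0) {
        inner <- enum(i + 1, k - 1)
        outer <- enum(k + 1, j)
        for (a in inner) for (z in outer) {
          out[[length(out) + 1L]] <- c(list(c(i, k)), a, z)
        }
      }
    }
    out
  }
  structs <- if (n >= minloop + 2) enum(1, n) else list(list())
  # energy of a pair set: per pair, classify its loop by the directly
  # enclosed branches (none = hairpin; the immediately nested pair =
  # stack; one distant branch = interior/bulge; several = multiloop)
  energy <- function(pairs) {
    if (!length(pairs)) return(0)
    m <- do.call(rbind, pairs)
    e <- 0
    for (r in seq_len(nrow(m))) {
      i <- m[r, 1]; j <- m[r, 2]
      inside <- m[m[, 1] > i & m[, 2] < j, , drop = FALSE]
      if (nrow(inside)) {
        # direct children: pairs inside (i,j) not nested in another
        # pair inside (i,j)
        direct <- vapply(seq_len(nrow(inside)), function(q) {
          !any(inside[, 1] < inside[q, 1] & inside[, 2] > inside[q, 2])
        }, logical(1))
        ch <- inside[direct, , drop = FALSE]
      } else ch <- inside
      if (nrow(ch) == 0) {
        e <- e + penalties[["hairpin"]] +
          penalties[["hairpin_log"]] * log((j - i - 1) / minloop)
      } else if (nrow(ch) == 1) {
        if (ch[1, 1] == i + 1 && ch[1, 2] == j - 1) {
          e <- e + stack[pidx(i, j), pidx(ch[1, 1], ch[1, 2])]
        } else {
          sz <- (ch[1, 1] - i - 1) + (j - ch[1, 2] - 1)
          e <- e + penalties[["interior"]] +
            penalties[["interior_per_nt"]] * sz
        }
      } else {
        e <- e + penalties[["multiloop"]]
      }
    }
    e
  }
  es <- vapply(structs, energy, numeric(1))
  list(mfe = min(0, es), n_structures = length(structs))
}

#' Dinucleotide-preserving shuffle
#'
#' Altschul-Erickson shuffle: returns a random permutation of `seq` with
#' the identical dinucleotide (and hence mononucleotide) multiset and the
#' same first and last base, drawn by randomising the Eulerian path
#' through the dinucleotide multigraph.  This is the null model for the
#' hairpin stability test: shuffles keep base composition and
#' neighbour statistics but destroy long-range complementarity.
#'
#' @param seq single character sequence.
#' @return shuffled sequence (character).
#' @export
dinucleotide_shuffle <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  n <- length(ch)
  if (n <= 2 || length(unique(ch)) == 1) return(paste(ch, collapse = ""))
  verts <- unique(ch)
  last <- ch[n]
  # outgoing-edge target lists per vertex
  edges <- split(ch[-1], factor(ch[-n], levels = verts))
  # choose, per vertex except `last`, a designated final edge such that the
  # final-edge graph leads every vertex into `last` (no cycles); rejection
  # sample as in the Altschul-Erickson algorithm
  nonlast <- setdiff(verts, last)
  repeat {
    lastEdge <- vapply(nonlast, function(v) {
      outs <- edges[[v]]
      outs[sample.int(length(outs), 1)]
    }, character(1))
    names(lastEdge) <- nonlast
    ok <- TRUE
    for (v in nonlast) {
      seen <- character(0); cur <- v
      while (cur != last) {
        if (cur %in% seen) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- lastEdge[[cur]]
      }
      if (!ok) break
    }
    if (ok) break
  }
  # permute the remaining edges uniformly, append the designated last edge
  walk <- lapply(setNames(verts, verts), function(v) {
    outs <- edges[[v]]
    if (v %in% nonlast) {
      i <- match(lastEdge[[v]], outs)
      rest <- outs[-i]
      c(rest[sample.int(length(rest))], outs[i])
    } else {
      outs[sample.int(length(outs))]
    }
  })
  ptr <- setNames(rep(1L, length(verts)), verts)
  out <- character(n)
  out[1] <- ch[1]
  cur <- ch[1]
  for (i in 2:n) {
    nxt <- walk[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

#' Shuffle significance test for hairpin stability
#'
#' Folds `seq` and `n_shuffles` dinucleotide-preserving shuffles of it,
#' and reports `p = (1 + #\{shuffled MFE <= observed MFE\}) / (N + 1)`:
#' the probability that a composition-matched random sequence is at least
#' as stable as the observed one.
#'
#' @param seq precursor sequence.
#' @param n_shuffles number of shuffles N (default 199).
#' @param ... further arguments to [fold_mfe()].
#' @return list with `observed_mfe`, `n_shuffles`, `p_value`.
#' @export
randfold_p <- function(seq, n_shuffles = 199, ...) {
  obs <- fold_mfe(seq, ...)
  if (n_shuffles <= 0) {
    warning("n_shuffles = 0: degenerate test, p = 1")
    return(list(observed_mfe = obs, n_shuffles = 0L, p_value = 1))
  }
  shuf <- vapply(seq_len(n_shuffles), function(i) dinucleotide_shuffle(seq),
                 character(1))
  e <- fold_mfe(shuf, ...)
  list(observed_mfe = obs,
       n_shuffles = as.integer(n_shuffles),
       p_value = (1 + sum(e <= obs + 1e-9)) / (n_shuffles + 1))
}
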