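#' Index a labeled noncoding-RNA reference set for tag matching
#'
#' Hashes every 8-mer of every reference so that candidate ungapped
#' alignments between a tag and a reference can be restricted to
#' diagonals sharing an exact 8-mer (any >= 16 nt segment at >= 90%
#' identity necessarily contains one).
#'
#' @param refs list with `seqs` (named character) and `meta` (name,
#'   class, source), as from [load_ncrna_refs()].
#' @return object of class `ncrna_index`.
#' @export
index_ncrna <- function(refs) {
  k <- 8L
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (nm in names(refs$seqs)) {
    s <- refs$seqs[[nm]]
    n <- nchar(s)
    if (n < k) next
    for (i in seq_len(n - k + 1)) {
      km <- substr(s, i, i + k - 1)
      cur <- if (exists(km, envir = env)) get(km, envir = env) else NULL
      assign(km, rbind(cur, c(nm, i)), envir = env)
    }
  }
  structure(list(kmers = env, k = k, refs = refs), class = "ncrna_index")
}

# best ungapped segment of >= min_len with identity >= min_ident on the
# diagonal aligning tag position 1 to ref position `off + 1`
best_ungapped_segment <- function(tag, ref, off, min_len, min_ident) {
  Lt <- nchar(tag); Lr <- nchar(ref)
  t_from <- max(1, 1 - off); t_to <- min(Lt, Lr - off)
  if (t_to - t_from + 1 < min_len) return(NULL)
  tb <- strsplit(substr(tag, t_from, t_to), "")[[1]]
  rb <- strsplit(substr(ref, t_from + off, t_to + off), "")[[1]]
  cm <- c(0, cumsum(tb == rb))
  n <- length(tb)
  for (len in n:min_len) {           # longest qualifying segment wins
    s <- 1:(n - len + 1)
    id <- (cm[s + len] - cm[s]) / len
    k <- which(id >= min_ident)
    if (length(k)) {
      k <- k[which.max(id[k])]
      return(list(length = len, identity = id[k],
                  tag_start = t_from + k - 1))
    }
  }
  NULL
}

#' Match a tag against the noncoding-RNA reference set
#'
#' A hit requires an ungapped local alignment of at least `min_len` nt at
#' at least `min_ident` identity (a deterministic criterion standing in
#' for a database-size-dependent E-value cutoff).  Ties are broken by
#' source priority (genbank over rfam), then by identity.
#'
#' @param tag tag sequence.
#' @param index an [index_ncrna()] object.
#' @param min_len,min_ident alignment thresholds (16 nt, 0.9).
#' @return NULL or list: `name`, `class`, `source`, `identity`, `length`.
#' @export
match_ncrna <- function(tag, index, min_len = 16, min_ident = 0.9) {
  stopifnot(inherits(index, "ncrna_index"))
  k <- index$k
  Lt <- nchar(tag)
  if (Lt < min_len) return(NULL)
  diags <- list()
  for (i in seq_len(Lt - k + 1)) {
    km <- substr(tag, i, i + k - 1)
    if (!exists(km, envir = index$kmers)) next
    hits <- get(km, envir = index$kmers)
    for (r in seq_len(nrow(hits))) {
      key <- paste(hits[r, 1], as.integer(hits[r, 2]) - i)
      diags[[key]] <- c(hits[r, 1], as.integer(hits[r, 2]) - i)
    }
  }
  if (!length(diags)) return(NULL)
  best <- NULL
  meta <- index$refs$meta
  for (d in diags) {
    nm <- d[1]; off <- as.integer(d[2])
    seg <- best_ungapped_segment(tag, index$refs$seqs[[nm]], off,
                                 min_len, min_ident)
    if (is.null(seg)) next
    src <- meta$source[meta$name == nm][1]
    cand <- list(name = nm, class = meta$class[meta$name == nm][1],
                 source = src, identity = seg$identity, length = seg$length)
    better <- is.null(best) ||
      (src == "genbank" && best$source != "genbank") ||
      (src == best$source && seg$identity > best$identity)
    if (better) best <- cand
  }
  best
}

#' Match a tag against known mature miRNAs
#'
#' Full-length, gapless comparison against each mature miRNA, sliding to
#' absorb a length difference of at most 2; a homolog requires <= 2
#' mismatches or >= 90% identity over the shorter sequence.
#'
#' @param tag tag sequence.
#' @param mirnas named character vector of mature miRNAs.
#' @return NULL or list: `name`, `mismatches`, `identity`.
#' @export
match_known_mirna <- function(tag, mirnas) {
  Lt <- nchar(tag)
  best <- NULL
  ta <- strsplit(tag, "")[[1]]
  for (nm in names(mirnas)) {
    m <- mirnas[[nm]]
    Lm <- nchar(m)
    if (abs(Lt - Lm) > 2) next
    ma <- strsplit(m, "")[[1]]
    if (Lt <= Lm) { a <- ta; bfull <- ma } else { a <- ma; bfull <- ta }
    Ls <- length(a); Ll <- length(bfull)
    for (off in 0:(Ll - Ls)) {
      mm <- sum(a != bfull[(off + 1):(off + Ls)])
      id <- (Ls - mm) / Ls
      if (mm <= 2 || id >= 0.9) {
        cand <- list(name = nm, mismatches = mm, identity = id)
        if (is.null(best) || mm < best$mismatches) best <- cand
      }
    }
  }
  best
}

#' Classify a tag's genome hits against gene models
#'
#' A tag is exonic if any hit lies entirely within an annotated exon
#' ("perfect overlap" = full containment; boundary-straddling hits
#' contribute nothing), sense if the hit strand matches the transcript
#' strand; intronic likewise.  Exon evidence outranks intron evidence,
#' and sense outranks antisense within each.
#'
#' @param hits hit data.frame for one tag (chrom, strand, start, end).
#' @param gene_models GRanges with `type` (exon/intron) and strand.
#' @return one of exon_sense, exon_antisense, intron_sense,
#'   intron_antisense, or NULL.
#' @export
classify_gene_overlap <- function(hits, gene_models) {
  if (!nrow(hits) || !length(gene_models)) return(NULL)
  gr <- GenomicRanges::GRanges(hits$chrom,
                               IRanges::IRanges(hits$start, hits$end))
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(gr, gene_models, type = "within",
                                ignore.strand = TRUE))
  if (!length(ov)) return(NULL)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  type <- gene_models$type[sh]
  sense <- hits$strand[qh] == as.character(GenomicRanges::strand(gene_models))[sh]
  cats <- paste0(type, ifelse(sense, "_sense", "_antisense"))
  pri <- c("exon_sense", "exon_antisense", "intron_sense", "intron_antisense")
  pri[min(match(cats, pri))]
}

# batch version over a full hit table: named vector seq -> category
gene_overlap_categories <- function(hits, gene_models) {
  if (!nrow(hits) || !length(gene_models)) return(character(0))
  gr <- GenomicRanges::GRanges(hits$chrom,
                               IRanges::IRanges(hits$start, hits$end))
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(gr, gene_models, type = "within",
                                ignore.strand = TRUE))
  if (!length(ov)) return(character(0))
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  type <- gene_models$type[sh]
  sense <- hits$strand[qh] == as.character(GenomicRanges::strand(gene_models))[sh]
  cats <- paste0(type, ifelse(sense, "_sense", "_antisense"))
  pri <- c("exon_sense", "exon_antisense", "intron_sense", "intron_antisense")
  r <- tapply(match(cats, pri), hits$seq[qh], min)
  setNames(pri[as.integer(r)], names(r))
}

#' Detect siRNA duplex pairs among tags
#'
#' Two tags form a duplex when they are perfectly complementary over all
#' but their 3'-terminal dinucleotides, i.e. equal length L with
#' `A[1..L-2] == revcomp(B[1..L-2])`, leaving a 2-nt 3' overhang on both
#' strands.  A blunt full-length reverse complement is not a duplex.
#' Each unordered pair is reported once; self-pairs are excluded.
#'
#' @param tags tag table (column `seq`).
#' @return data.frame with `tagA`, `tagB` sequences.
#' @export
find_sirna_pairs <- function(tags) {
  seqs <- tags$seq
  L <- nchar(seqs)
  # partner's paired region is determined by A: B[1..L-2] = revcomp(A[1..L-2])
  paired_region <- substr(seqs, 1, L - 2)
  want <- revcomp(paired_region)      # required partner prefix
  out <- list()
  by_len <- split(seq_along(seqs), L)
  for (grp in by_len) {
    pref <- paired_region[grp]
    lookup <- split(grp, pref)
    for (i in grp) {
      cand <- lookup[[want[i]]]
      if (is.null(cand)) next
      for (j in cand) {
        if (j <= i) next  # report each unordered pair once
        out[[length(out) + 1L]] <- data.frame(
          tagA = seqs[i], tagB = seqs[j], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(tagA = character(0), tagB = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Predicate: do two tags satisfy the siRNA duplex geometry?
#'
#' @param a,b tag sequences.
#' @return logical.
#' @export
is_sirna_duplex <- function(a, b) {
  La <- nchar(a); Lb <- nchar(b)
  if (La != Lb || La < 4) return(FALSE)
  if (a == b) return(FALSE)
  substr(a, 1, La - 2) == revcomp(substr(b, 1, Lb - 2))
}

#' Assign every tag to exactly one category by the priority rule
#'
#' Priority chain: noncoding RNA classes (rRNA/tRNA/snRNA/snoRNA, with
#' genbank outranking rfam within the match) > known miRNA > exon >
#' intron > siRNA > non-annotated.  Deterministic for identical
#' evidence; the output is a partition of the tags.
#'
#' @param tags tag table.
#' @param hits hit table from [map_tags()].
#' @param ncrna_index an [index_ncrna()] object.
#' @param known_mirnas named character vector of mature miRNAs.
#' @param gene_models GRanges of exons and introns.
#' @return data.frame: seq, category, evidence (matched reference id or
#'   partner tag; NA for non_annotated).
#' @export
classify_tags <- function(tags, hits, ncrna_index, known_mirnas,
                          gene_models) {
  sirna <- find_sirna_pairs(tags)
  sirna_member <- unique(c(sirna$tagA, sirna$tagB))
  sirna_partner <- c(setNames(sirna$tagB, sirna$tagA),
                     setNames(sirna$tagA, sirna$tagB))
  gene_cat <- gene_overlap_categories(hits, gene_models)
  cat <- character(nrow(tags)); ev <- rep(NA_character_, nrow(tags))
  for (i in seq_len(nrow(tags))) {
    s <- tags$seq[i]
    nc <- match_ncrna(s, ncrna_index)
    if (!is.null(nc)) {
      cat[i] <- nc$class; ev[i] <- nc$name; next
    }
    km <- match_known_mirna(s, known_mirnas)
    if (!is.null(km)) {
      cat[i] <- "known_miRNA"; ev[i] <- km$name; next
    }
    g <- if (length(gene_cat)) unname(gene_cat[s]) else NA_character_
    if (!is.na(g)) {
      cat[i] <- g; ev[i] <- "gene_model"; next
    }
    if (s %in% sirna_member) {
      cat[i] <- "siRNA"; ev[i] <- sirna_partner[[s]]; next
    }
    cat[i] <- "non_annotated"
  }
  data.frame(seq = tags$seq, category = cat, evidence = ev,
             stringsAsFactors = FALSE)
}

#' Category summary table (per library, unique and total, percentages)
#'
#' @param calls output of [classify_tags()].
#' @param tags tag table with library count columns.
#' @return data.frame: one row per category (plus Total), per library
#'   unique/total counts and two-decimal percentages. Category counts
#'   partition each library (columns re-sum to the totals).
#' @export
summarize_categories <- function(calls, tags) {
  stopifnot(identical(calls$seq, tags$seq))
  cats <- c("exon_antisense", "exon_sense", "intron_antisense",
            "intron_sense", "known_miRNA", "rRNA", "siRNA", "snRNA",
            "snoRNA", "tRNA", "non_annotated")
  libs <- tag_libs(tags)
  out <- data.frame(category = c("Total", cats), stringsAsFactors = FALSE)
  for (lib in libs) {
    cnt <- tags[[lib]]
    present <- cnt > 0
    u_tot <- sum(present); t_tot <- sum(cnt)
    u <- vapply(cats, function(cc) sum(present & calls$category == cc),
                integer(1))
    t <- vapply(cats, function(cc) sum(cnt[calls$category == cc]),
                numeric(1))
    out[[paste0(lib, "_unique")]] <- c(u_tot, u)
    out[[paste0(lib, "_unique_pct")]] <- c(100, pct2(u, u_tot))
    out[[paste0(lib, "_total")]] <- c(t_tot, t)
    out[[paste0(lib, "_total_pct")]] <- c(100, pct2(t, t_tot))
  }
  out
}

#' Register concentration (phasing) statistic for siRNA 5' ends
#'
#' Score = the largest fraction of 5' ends falling into a single residue
#' class modulo `phase_len`; minus-strand 5' positions are shifted by +2
#' before register assignment (duplex-overhang correction).  Significance
#' by permutation: start positions are redrawn uniformly within the
#' locus span.
#'
#' @param hits hit table of the locus' tags (chrom, strand, start, end).
#' @param phase_len phase register length (nt), default 21.
#' @param n_perm permutations for the p-value.
#' @return list with `score` (in `[0,1]`), `p_value`, `n`.
#' @export
phasing_statistic <- function(hits, phase_len = 21, n_perm = 999) {
  p5 <- ifelse(hits$strand == "+", hits$start, hits$end + 2L)
  n <- length(p5)
  if (n == 0) return(list(score = NA_real_, p_value = NA_real_, n = 0L))
  score_of <- function(x) max(table(x %% phase_len)) / length(x)
  obs <- score_of(p5)
  span <- range(p5)
  perm <- vapply(seq_len(n_perm), function(i)
    score_of(sample(span[1]:span[2], n, replace = TRUE)), numeric(1))
  list(score = obs,
       p_value = (1 + sum(perm >= obs - 1e-12)) / (n_perm + 1),
       n = n)
}

#' Count tags with a hit fully inside a repeat interval
#'
#' Containment only: hits overlapping a repeat boundary do not count.
#' Each distinct tag counts once however many repeat hits it has.
#'
#' @param hits hit table (with `seq` column).
#' @param repeats GRanges of repeat intervals.
#' @return integer count of distinct tags.
#' @export
repeat_overlap <- function(hits, repeats) {
  if (!nrow(hits) || !length(repeats)) return(0L)
  gr <- GenomicRanges::GRanges(hits$chrom,
                               IRanges::IRanges(hits$start, hits$end))
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(gr, repeats, type = "within",
                                ignore.strand = TRUE))
  length(unique(hits$seq[unique(S4Vectors::queryHits(ov))]))
}
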