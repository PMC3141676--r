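#' Configuration for the synthetic small-RNA study
#'
#' Builds the parameter list consumed by [make_genome()] and
#' [make_libraries()].  Defaults describe the emulated study design: three
#' libraries (a normal-growth analogue and two nutrient-limited analogues)
#' of adapter-flanked 18-28 nt inserts drawn from planted hairpin loci
#' (with controllable 5'-end jitter), noncoding-RNA degradation fragments,
#' mRNA fragments, complementary siRNA duplexes with 2-nt 3' overhangs, a
#' read hotspot, and random background.  Per-locus read counts are
#' negative binomial, reproducing the heavy-tailed libraries in which most
#' distinct tags are sequenced once.
#'
#' @param seed integer seed; regeneration with the same seed is
#'   byte-identical.
#' @param n_chromosomes number of reference sequences; the last one is
#'   named `chloroplast` to emulate an organellar sequence, the others
#'   `chr_1`, `chr_2`, ...
#' @param chrom_length length of each reference sequence (nt).
#' @param n_hairpin_loci planted miRNA hairpin loci.
#' @param mature_len_range length range of the planted mature miRNA
#'   (must lie within 18-25).
#' @param stem_pairs_range range of planted stem length (base pairs before
#'   mismatch injection).
#' @param stem_mismatches symmetric mismatches injected into each stem.
#' @param loop_len_range hairpin terminal loop length range.
#' @param n_ncrna_loci named integer vector: planted copies per noncoding
#'   RNA class (names among rRNA, tRNA, snRNA, snoRNA).
#' @param n_gene_models planted two-exon gene models.
#' @param n_sirna_pairs planted siRNA duplex loci.
#' @param n_repeat_copies planted copies of the repeat family.
#' @param inverted_repeat plant two exactly reverse-complementary copies
#'   of a 300-nt sequence on the organellar entry.
#' @param hotspot_len,hotspot_reads length of the planted minus-strand
#'   read hotspot and redundant reads drawn from it per library.
#' @param nb_mean,nb_size negative-binomial mean and dispersion for
#'   per-locus per-library read counts at hairpin loci.
#' @param five_prime_jitter probability that a hairpin-locus read is
#'   shifted by one base at its 5' end (in `[0,1]`).
#' @param n_background genome-derived background tags per library.
#' @param background_dup fraction of background tags emitted 2-3 times.
#' @param n_ncrna_frags,n_mrna_frags,n_known_mirna_reads,n_random_reads
#'   degradation fragments, mRNA fragments, known-miRNA homolog reads and
#'   non-genomic random reads per library.
#' @param adapter3,adapter5 adapter sequences (arbitrary but configurable;
#'   the emulated platform's adapters are not part of the study design).
#' @param read_length raw read length; inserts read through into the 3'
#'   adapter.
#' @param libraries library identifiers.
#' @return validated configuration list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1,
                             n_chromosomes = 2,
                             chrom_length = 8000,
                             n_hairpin_loci = 3,
                             mature_len_range = c(20, 24),
                             stem_pairs_range = c(22, 26),
                             stem_mismatches = 1,
                             loop_len_range = c(8, 12),
                             n_ncrna_loci = c(rRNA = 2, tRNA = 1,
                                              snRNA = 1, snoRNA = 1),
                             n_gene_models = 2,
                             n_sirna_pairs = 2,
                             n_repeat_copies = 2,
                             inverted_repeat = TRUE,
                             hotspot_len = 1200,
                             hotspot_reads = 80,
                             nb_mean = 25,
                             nb_size = 8,
                             five_prime_jitter = 0.1,
                             n_background = 50,
                             background_dup = 0.1,
                             n_ncrna_frags = 40,
                             n_mrna_frags = 30,
                             n_known_mirna_reads = 8,
                             n_random_reads = 8,
                             adapter3 = "TCGTATGCCGTCTTCTGCTTG",
                             adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                             read_length = 36,
                             libraries = c("PT1", "PT2", "PT3")) {
  cfg <- as.list(environment())
  counts <- c(n_chromosomes = n_chromosomes, chrom_length = chrom_length,
              n_hairpin_loci = n_hairpin_loci, n_gene_models = n_gene_models,
              n_sirna_pairs = n_sirna_pairs, n_repeat_copies = n_repeat_copies,
              n_ncrna_loci, n_background = n_background)
  if (any(counts < 0)) stop("all feature counts must be >= 0")
  if (five_prime_jitter < 0 || five_prime_jitter > 1)
    stop("five_prime_jitter must lie in [0, 1]")
  if (mature_len_range[1] < 18 || mature_len_range[2] > 25)
    stop("mature_len_range must lie within [18, 25]")
  if (nchar(adapter3) == 0) stop("adapter3 must be non-empty")
  class(cfg) <- "synthetic_config"
  cfg
}

#' Bundled miniature noncoding-RNA reference set
#'
#' Loads the package's synthetic rRNA/tRNA/snRNA/snoRNA reference
#' fragments (FASTA headers `name|class|source`, with source either
#' `genbank` or `rfam`).  These stand in for the public noncoding-RNA
#' databases so annotation is testable offline; they are synthetic
#' sequences, not copies of any real database record.
#'
#' @return list with `seqs` (named character vector) and `meta`
#'   (data.frame: name, class, source).
#' @export
load_ncrna_refs <- function() {
  path <- system.file("extdata", "ncrna_refs_synthetic.fasta",
                      package = "srnapipe", mustWork = TRUE)
  ss <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(ss), "|", fixed = TRUE)
  meta <- data.frame(name = vapply(parts, `[`, "", 1),
                     class = vapply(parts, `[`, "", 2),
                     source = vapply(parts, `[`, "", 3),
                     stringsAsFactors = FALSE)
  seqs <- as.character(ss)
  names(seqs) <- meta$name
  list(seqs = seqs, meta = meta)
}

#' Bundled synthetic mature miRNA set
#'
#' Known mature miRNAs used for homology annotation, with miRBase-style
#' headers.  Synthetic stand-ins, not real miRBase records.
#'
#' @return named character vector of mature sequences.
#' @export
load_known_mirnas <- function() {
  path <- system.file("extdata", "mature_mirnas_synthetic.fasta",
                      package = "srnapipe", mustWork = TRUE)
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- vapply(strsplit(names(ss), " "), `[`, "", 1)
  seqs
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# Build one hairpin payload: 5' arm (mature at its start) + loop +
# reverse-complement arm with `n_mm` injected symmetric mismatches.
# Criteria satisfaction is by construction: the arms pair
# stem - n_mm >= 16 bases and the stacked stem folds far below the
# energy threshold.
build_hairpin <- function(stem, mature_len, loop_len, n_mm) {
  # GC-lean arms fold weakly; bias composition slightly toward G/C
  arm <- paste(sample(c("A", "C", "G", "T"), stem, replace = TRUE,
                      prob = c(.2, .3, .3, .2)), collapse = "")
  arm2 <- revcomp(arm)
  if (n_mm > 0) {
    # inject symmetric mismatches away from both stem ends
    ok <- 3:(stem - 3)
    pos <- sample(ok, n_mm)
    a2 <- strsplit(arm2, "")[[1]]
    a1 <- strsplit(arm, "")[[1]]
    for (p in pos) {
      # position p of arm pairs position stem - p + 1 of arm2
      q <- stem - p + 1
      comp <- chartr("ACGT", "TGCA", a1[p])
      a2[q] <- sample(setdiff(c("A", "C", "G", "T"), comp), 1)
    }
    arm2 <- paste(a2, collapse = "")
  }
  loop <- rand_dna(loop_len)
  list(seq = paste0(arm, loop, arm2),
       mature_start = 1L, mature_end = as.integer(mature_len),
       stem = stem, n_mm = n_mm)
}

#' Generate the synthetic genome with planted, truth-annotated features
#'
#' Background sequence is i.i.d. uniform over A/C/G/T; planted features
#' overwrite background and never overlap each other.  Hairpin loci are
#' guaranteed by construction to satisfy the precursor criteria (>= 16
#' arm-arm pairs after mismatch injection, stacked stem energy far below
#' -18 kcal/mol); noncoding-RNA loci are copies of the bundled reference
#' sequences; the inverted-repeat pair consists of two intervals whose
#' sequences are exact reverse complements of each other.  All
#' coordinates are 1-based inclusive; minus-strand payloads equal the
#' reverse complement of the genome substring.
#'
#' @param config a [synthetic_config()].
#' @return list with `genome` (DNAStringSet), `truth` (data.frame),
#'   `gene_models` (GRanges of exons and introns), `ncrna_refs`,
#'   `known_mirnas`, `repeats` (GRanges).
#' @export
make_genome <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  nchrom <- config$n_chromosomes
  chroms <- if (nchrom == 1) "chr_1" else
    c(paste0("chr_", seq_len(nchrom - 1)), "chloroplast")
  seqs <- lapply(chroms, function(x)
    sample(c("A", "C", "G", "T"), config$chrom_length, replace = TRUE))
  names(seqs) <- chroms

  refs <- load_ncrna_refs()
  known <- load_known_mirnas()

  # ----- feature plan ------------------------------------------------------
  feats <- list()
  add <- function(kind, payload, strand = "+", margin = 40, extra = list()) {
    feats[[length(feats) + 1L]] <<- c(list(kind = kind, payload = payload,
                                           strand = strand, margin = margin),
                                      extra)
  }
  for (i in seq_len(config$n_hairpin_loci)) {
    stem <- sample(config$stem_pairs_range[1]:config$stem_pairs_range[2], 1)
    mlen <- sample(config$mature_len_range[1]:config$mature_len_range[2], 1)
    mlen <- min(mlen, stem)
    loop <- sample(config$loop_len_range[1]:config$loop_len_range[2], 1)
    hp <- build_hairpin(stem, mlen, loop, config$stem_mismatches)
    add("hairpin", hp$seq, "+", margin = 320,
        extra = list(name = sprintf("hairpin_%d", i),
                     mature_start = hp$mature_start, mature_end = hp$mature_end))
  }
  for (cls in names(config$n_ncrna_loci)) {
    n <- config$n_ncrna_loci[[cls]]
    pool <- refs$meta$name[refs$meta$class == cls]
    for (i in seq_len(n)) {
      nm <- pool[((i - 1) %% length(pool)) + 1]
      add(cls, refs$seqs[[nm]], "+", extra = list(name = nm))
    }
  }
  for (i in seq_len(config$n_gene_models)) {
    strand <- sample(c("+", "-"), 1)
    e1 <- 250; intr <- 120; e2 <- 250
    add("gene", rand_dna(e1 + intr + e2), strand,
        extra = list(name = sprintf("gene_%d", i),
                     exon_len = c(e1, e2), intron_len = intr))
  }
  for (i in seq_len(config$n_sirna_pairs)) {
    add("siRNA_pair", rand_dna(23), "+",
        extra = list(name = sprintf("sirna_%d", i)))
  }
  rep_seq <- rand_dna(150)
  for (i in seq_len(config$n_repeat_copies)) {
    add("repeat", rep_seq, "+", extra = list(name = sprintf("repeat_%d", i)))
  }
  ir_seq <- if (config$inverted_repeat) rand_dna(300) else NULL

  # ----- placement ---------------------------------------------------------
  # round-robin over chromosomes; sequential cursors with random gaps
  truth <- list()
  cursors <- setNames(rep(150L, nchrom), chroms)
  # reserve the chr_1 tail for the read hotspot so sequence features and
  # the hotspot sampling region never overlap
  hs_start <- config$chrom_length - 150 - config$hotspot_len
  limits <- setNames(rep(config$chrom_length - 100L, nchrom), chroms)
  limits[[chroms[1]]] <- hs_start - 60L
  chrom_of <- rep(chroms, length.out = length(feats))
  ord <- sample(length(feats))
  gm_exons <- list(); rep_iv <- list()
  place <- function(chrom, len, margin) {
    start <- cursors[[chrom]] + margin + sample(40:120, 1)
    end <- start + len - 1L
    if (end + margin > limits[[chrom]]) return(NULL)
    cursors[[chrom]] <<- end + margin
    c(start, end)
  }
  for (k in seq_along(ord)) {
    f <- feats[[ord[k]]]
    chrom <- chrom_of[k]
    len <- nchar(f$payload)
    iv <- place(chrom, len, f$margin)
    if (is.null(iv))
      stop(sprintf("chromosome %s too short to host feature '%s' (%s)",
                   chrom, f$name, f$kind))
    s <- iv[1]; e <- iv[2]
    pay <- if (f$strand == "-") revcomp(f$payload) else f$payload
    seqs[[chrom]][s:e] <- strsplit(pay, "")[[1]]

    if (f$kind == "hairpin") {
      truth[[length(truth) + 1L]] <- data.frame(
        kind = "hairpin", chrom = chrom, strand = "+",
        start = s, end = e, payload = f$payload,
        expected_category = "non_annotated", name = f$name,
        mature_start = s + f$mature_start - 1L,
        mature_end = s + f$mature_end - 1L, stringsAsFactors = FALSE)
    } else if (f$kind %in% c("rRNA", "tRNA", "snRNA", "snoRNA")) {
      truth[[length(truth) + 1L]] <- data.frame(
        kind = f$kind, chrom = chrom, strand = "+", start = s, end = e,
        payload = f$payload, expected_category = f$kind, name = f$name,
        mature_start = NA_integer_, mature_end = NA_integer_,
        stringsAsFactors = FALSE)
    } else if (f$kind == "gene") {
      e1 <- f$exon_len[1]; intr <- f$intron_len; e2 <- f$exon_len[2]
      # exon/intron genomic order follows the strand
      parts <- if (f$strand == "+")
        list(exon1 = c(s, s + e1 - 1), intron = c(s + e1, s + e1 + intr - 1),
             exon2 = c(s + e1 + intr, e))
      else
        list(exon2 = c(s, s + e2 - 1), intron = c(s + e2, s + e2 + intr - 1),
             exon1 = c(s + e2 + intr, e))
      for (p in names(parts)) {
        kind <- if (grepl("exon", p)) "exon" else "intron"
        iv2 <- parts[[p]]
        truth[[length(truth) + 1L]] <- data.frame(
          kind = kind, chrom = chrom, strand = f$strand,
          start = iv2[1], end = iv2[2],
          payload = if (f$strand == "-")
            revcomp(paste(seqs[[chrom]][iv2[1]:iv2[2]], collapse = ""))
          else paste(seqs[[chrom]][iv2[1]:iv2[2]], collapse = ""),
          expected_category = if (kind == "exon") "exon_sense" else "intron_sense",
          name = paste0(f$name, "_", p),
          mature_start = NA_integer_, mature_end = NA_integer_,
          stringsAsFactors = FALSE)
        gm_exons[[length(gm_exons) + 1L]] <- data.frame(
          chrom = chrom, start = iv2[1], end = iv2[2], strand = f$strand,
          type = kind, gene_id = f$name, stringsAsFactors = FALSE)
      }
    } else if (f$kind == "siRNA_pair") {
      # duplex geometry: plus tag at [s+2, e], minus tag at [s, e-2]
      truth[[length(truth) + 1L]] <- data.frame(
        kind = "siRNA_pair", chrom = chrom, strand = "+",
        start = s + 2L, end = e, payload =
          paste(seqs[[chrom]][(s + 2):e], collapse = ""),
        expected_category = "siRNA", name = paste0(f$name, "_plus"),
        mature_start = NA_integer_, mature_end = NA_integer_,
        stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        kind = "siRNA_pair", chrom = chrom, strand = "-",
        start = s, end = e - 2L, payload =
          revcomp(paste(seqs[[chrom]][s:(e - 2)], collapse = "")),
        expected_category = "siRNA", name = paste0(f$name, "_minus"),
        mature_start = NA_integer_, mature_end = NA_integer_,
        stringsAsFactors = FALSE)
    } else if (f$kind == "repeat") {
      truth[[length(truth) + 1L]] <- data.frame(
        kind = "repeat", chrom = chrom, strand = "+", start = s, end = e,
        payload = f$payload, expected_category = NA_character_, name = f$name,
        mature_start = NA_integer_, mature_end = NA_integer_,
        stringsAsFactors = FALSE)
      rep_iv[[length(rep_iv) + 1L]] <- data.frame(
        chrom = chrom, start = s, end = e, name = f$name,
        stringsAsFactors = FALSE)
    }
  }

  # inverted repeat: both copies on the organellar entry
  if (config$inverted_repeat) {
    cp <- chroms[length(chroms)]
    for (copy in 1:2) {
      pay <- if (copy == 1) ir_seq else revcomp(ir_seq)
      iv <- place(cp, nchar(pay), 40)
      if (is.null(iv))
        stop(sprintf("chromosome %s too short to host feature 'IR%s' (inverted_repeat)",
                     cp, c("a", "b")[copy]))
      s <- iv[1]; e <- iv[2]
      seqs[[cp]][s:e] <- strsplit(pay, "")[[1]]
      truth[[length(truth) + 1L]] <- data.frame(
        kind = "inverted_repeat", chrom = cp, strand = "+",
        start = s, end = e, payload = pay,
        expected_category = NA_character_, name = c("IRa", "IRb")[copy],
        mature_start = NA_integer_, mature_end = NA_integer_,
        stringsAsFactors = FALSE)
    }
  }

  # hotspot: an interval on the minus strand of chr_1 (no sequence edit;
  # the hotspot is a read-sampling region, not a sequence feature)
  truth[[length(truth) + 1L]] <- data.frame(
    kind = "hotspot", chrom = chroms[1], strand = "-",
    start = hs_start, end = hs_start + config$hotspot_len - 1L,
    payload = revcomp(paste(
      seqs[[chroms[1]]][hs_start:(hs_start + config$hotspot_len - 1L)],
      collapse = "")),
    expected_category = NA_character_, name = "hotspot_1",
    mature_start = NA_integer_, mature_end = NA_integer_,
    stringsAsFactors = FALSE)

  truth <- do.call(rbind, truth)
  genome <- Biostrings::DNAStringSet(vapply(seqs, paste, "", collapse = ""))
  gene_models <- if (length(gm_exons)) {
    df <- do.call(rbind, gm_exons)
    GenomicRanges::GRanges(df$chrom,
                           IRanges::IRanges(df$start, df$end),
                           strand = df$strand, type = df$type,
                           gene_id = df$gene_id)
  } else GenomicRanges::GRanges()
  repeats <- if (length(rep_iv)) {
    df <- do.call(rbind, rep_iv)
    GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                           name = df$name)
  } else GenomicRanges::GRanges()

  list(genome = genome, truth = truth, gene_models = gene_models,
       ncrna_refs = refs, known_mirnas = known, repeats = repeats)
}
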