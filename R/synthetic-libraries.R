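#' Simulate the three small-RNA libraries from a synthetic genome
#'
#' Emits, per library, raw reads that are 18-28 nt inserts read through
#' into the 3' adapter (truncated at `read_length`), together with a
#' per-read truth assignment table.  Hairpin-locus reads carry the exact
#' mature 5' end with probability `1 - five_prime_jitter`, otherwise they
#' are shifted one base; siRNA loci emit the two duplex tags with 2-nt 3'
#' overhangs; noncoding-RNA and mRNA loci shed degradation fragments;
#' hotspot and background reads complete the mixture.  A handful of
#' adapter-free artifact reads and sub-18-nt inserts exercise the
#' cleaning stage.
#'
#' @param sim output of [make_genome()].
#' @param config the same [synthetic_config()].
#' @return list with `reads` (per-library character vectors of raw
#'   reads) and `truth_reads` (data.frame: library, read_id, source kind,
#'   feature name, insert, shifted flag).
#' @export
make_libraries <- function(sim, config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 7L)
  genome <- as.character(sim$genome)
  truth <- sim$truth
  getseq <- function(chrom, s, e, strand = "+") {
    x <- substr(genome[[chrom]], s, e)
    if (strand == "-") revcomp(x) else x
  }
  chrom_len <- nchar(genome)
  # per-chromosome occupancy masks for background placement
  occ <- lapply(chrom_len, function(n) logical(n))
  for (r in seq_len(nrow(truth)))
    occ[[truth$chrom[r]]][truth$start[r]:truth$end[r]] <- TRUE

  out_reads <- list(); out_truth <- list()
  for (lib in config$libraries) {
    n_alloc <- 0L
    inserts <- character(4096); kinds <- character(4096)
    feat <- character(4096); shifted <- logical(4096)
    emit <- function(ins, kind, name, shift = FALSE) {
      n_alloc <<- n_alloc + 1L
      if (n_alloc > length(inserts)) {
        length(inserts) <<- 2L * length(inserts)
        length(kinds) <<- 2L * length(kinds)
        length(feat) <<- 2L * length(feat)
        length(shifted) <<- 2L * length(shifted)
      }
      inserts[n_alloc] <<- ins; kinds[n_alloc] <<- kind
      feat[n_alloc] <<- name; shifted[n_alloc] <<- shift
    }

    # hairpin mature reads with 5' jitter
    hp <- truth[truth$kind == "hairpin", , drop = FALSE]
    for (i in seq_len(nrow(hp))) {
      n <- rnbinom(1, mu = config$nb_mean, size = config$nb_size)
      if (n == 0) next
      sh <- runif(n) < config$five_prime_jitter
      off <- ifelse(sh, sample(c(-1L, 1L), n, replace = TRUE), 0L)
      for (r in seq_len(n)) {
        s <- hp$mature_start[i] + off[r]
        e <- hp$mature_end[i] + off[r]
        emit(getseq(hp$chrom[i], s, e), "mature", hp$name[i], sh[r])
      }
    }

    # noncoding-RNA degradation fragments
    nc <- truth[truth$kind %in% c("rRNA", "tRNA", "snRNA", "snoRNA"), ,
                drop = FALSE]
    for (r in seq_len(config$n_ncrna_frags)) {
      i <- sample(nrow(nc), 1)
      len <- sample(18:28, 1)
      s <- truthsub <- sample(nc$start[i]:(nc$end[i] - len + 1), 1)
      emit(getseq(nc$chrom[i], s, s + len - 1), "ncrna_frag", nc$name[i])
    }

    # mRNA degradation fragments (mostly sense, some antisense, few intron)
    ex <- truth[truth$kind == "exon", , drop = FALSE]
    intr <- truth[truth$kind == "intron", , drop = FALSE]
    for (r in seq_len(config$n_mrna_frags)) {
      from_intron <- r %% 6 == 0 && nrow(intr) > 0
      src <- if (from_intron) intr else ex
      i <- sample(nrow(src), 1)
      len <- sample(18:28, 1)
      s <- sample(src$start[i]:(src$end[i] - len + 1), 1)
      anti <- r %% 5 == 0
      strand <- if (anti) setdiff(c("+", "-"), src$strand[i]) else src$strand[i]
      emit(getseq(src$chrom[i], s, s + len - 1, strand),
           if (from_intron) "intron_frag" else "mrna_frag", src$name[i])
    }

    # siRNA duplex tags
    si <- truth[truth$kind == "siRNA_pair", , drop = FALSE]
    for (i in seq_len(nrow(si))) {
      n <- 1 + rnbinom(1, mu = 3, size = 5)
      for (r in seq_len(n))
        emit(si$payload[i], "sirna", si$name[i])
    }

    # known-miRNA homolog reads (foreign sequences; need not map)
    km <- sim$known_mirnas
    for (r in seq_len(config$n_known_mirna_reads)) {
      emit(unname(km[sample(length(km), 1)]), "known_mirna", "miRBase_homolog")
    }

    # hotspot reads (minus strand of chr_1)
    hs <- truth[truth$kind == "hotspot", , drop = FALSE]
    for (r in seq_len(config$hotspot_reads)) {
      len <- sample(18:28, 1)
      s <- sample(hs$start[1]:(hs$end[1] - len + 1), 1)
      emit(getseq(hs$chrom[1], s, s + len - 1, "-"), "hotspot", hs$name[1])
    }

    # genome-derived background from feature-free space
    for (r in seq_len(config$n_background)) {
      for (try in 1:50) {
        chrom <- sample(names(genome), 1)
        len <- sample(18:28, 1)
        s <- sample(chrom_len[[chrom]] - len, 1)
        if (!any(occ[[chrom]][s:(s + len - 1)])) break
      }
      strand <- sample(c("+", "-"), 1)
      dup <- if (runif(1) < config$background_dup) sample(2:3, 1) else 1
      for (d in seq_len(dup))
        emit(getseq(chrom, s, s + len - 1, strand), "background", "bg")
    }

    # non-genomic random reads and cleaning-stage artifacts
    for (r in seq_len(config$n_random_reads))
      emit(rand_dna(sample(18:28, 1)), "random", "random")
    short_ins <- vapply(1:3, function(i) rand_dna(sample(12:16, 1)), "")
    for (x in short_ins) emit(x, "too_short", "artifact")

    length(inserts) <- n_alloc; length(kinds) <- n_alloc
    length(feat) <- n_alloc; length(shifted) <- n_alloc
    raw <- paste0(inserts, config$adapter3)
    raw <- substr(raw, 1, config$read_length)
    # adapter-free artifacts (unligated): random full-length reads
    art <- vapply(1:4, function(i) rand_dna(config$read_length), "")
    raw <- c(raw, art)
    kinds <- c(kinds, rep("no_adapter", 4))
    feat <- c(feat, rep("artifact", 4))
    shifted <- c(shifted, rep(FALSE, 4))
    inserts <- c(inserts, art)

    ids <- sprintf("%s_read_%05d", lib, seq_along(raw))
    out_reads[[lib]] <- setNames(raw, ids)
    out_truth[[lib]] <- data.frame(library = lib, read_id = ids,
                                   kind = kinds, feature = feat,
                                   insert = inserts, shifted = shifted,
                                   stringsAsFactors = FALSE)
  }
  list(reads = out_reads, truth_reads = do.call(rbind, out_truth))
}

#' Write a simulated study to disk
#'
#' Genome as multi-FASTA, reads as FASTQ (phred33, constant quality),
#' gene models as GFF3, repeats as BED, truth tables as TSV.
#'
#' @param sim output of [make_genome()].
#' @param libs output of [make_libraries()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, libs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  for (lib in names(libs$reads)) {
    r <- Biostrings::DNAStringSet(libs$reads[[lib]])
    q <- Biostrings::PhredQuality(
      vapply(nchar(libs$reads[[lib]]), function(n)
        paste(rep("I", n), collapse = ""), ""))
    qr <- Biostrings::QualityScaledDNAStringSet(r, q)
    suppressWarnings(Biostrings::writeQualityScaledXStringSet(
      qr, file.path(dir, paste0(lib, ".fastq"))))
  }
  if (length(sim$gene_models))
    rtracklayer::export(sim$gene_models, file.path(dir, "genes.gff3"),
                        format = "gff3")
  if (length(sim$repeats))
    rtracklayer::export(sim$repeats, file.path(dir, "repeats.bed"),
                        format = "bed")
  write.table(sim$truth, file.path(dir, "truth_features.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(libs$truth_reads, file.path(dir, "truth_reads.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read raw FASTQ reads back as named character vectors
#'
#' @param path FASTQ file.
#' @return named character vector of read sequences, with qualities in
#'   attribute `quality`.
#' @export
read_fastq_reads <- function(path) {
  ss <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  out <- as.character(ss)
  attr(out, "quality") <- as.character(Biostrings::quality(ss))
  out
}
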