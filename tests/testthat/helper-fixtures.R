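# Shared fixtures, built in code.  The small simulated study is cached
# per test run since several files exercise different stages of it.

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

.sim_cache <- new.env(parent = emptyenv())

small_sim <- function(seed = 101) {
  key <- as.character(seed)
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  cfg <- synthetic_config(seed = seed)
  sim <- make_genome(cfg)
  libs <- make_libraries(sim, cfg)
  .sim_cache[[key]] <- list(cfg = cfg, sim = sim, libs = libs)
  .sim_cache[[key]]
}

# a tag table from bare sequences with given per-library counts
tag_table <- function(seqs, ...) {
  counts <- list(...)
  out <- data.frame(seq = seqs, stringsAsFactors = FALSE)
  for (lib in names(counts)) out[[lib]] <- counts[[lib]]
  out
}

# construct a perfect hairpin sequence: arm + loop + revcomp(arm)
perfect_hairpin <- function(arm_len = 24, loop_len = 10) {
  arm <- rand_seq(arm_len)
  list(seq = paste0(arm, rand_seq(loop_len), revcomp(arm)),
       arm = arm, arm_len = arm_len, loop_len = loop_len)
}

# independent naive mapper: full scan of both strands with gregexpr
naive_map <- function(tag, genome_chars) {
  out <- list()
  for (chrom in names(genome_chars)) {
    g <- genome_chars[[chrom]]
    for (strand in c("+", "-")) {
      q <- if (strand == "+") tag else revcomp(tag)
      # rescan from each match + 1 so overlapping matches are found
      pos <- integer(0); from <- 1L
      while (TRUE) {
        p <- regexpr(q, substr(g, from, nchar(g)), fixed = TRUE)
        if (p < 0) break
        pos <- c(pos, from + as.integer(p) - 1L)
        from <- from + as.integer(p)
      }
      if (length(pos))
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, strand = strand, start = pos,
          end = pos + nchar(tag) - 1L, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start, res$strand), , drop = FALSE]
}

# dinucleotide count table of a sequence
dinuc_counts <- function(s) {
  ch <- strsplit(s, "")[[1]]
  if (length(ch) < 2) return(table(character(0)))
  table(paste0(ch[-length(ch)], ch[-1]))
}
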