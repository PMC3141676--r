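#!/usr/bin/env Rscript

# Stage 3: exact all-hits mapping and chromosome profiles.
#
# Maps every tag to the genome (both strands, zero mismatches, all hits
# reported), writes the hit table, the per-chromosome strand profile of
# redundant reads, the sliding-window hotspots, and the pairwise local
# alignments between the top hotspot loci (the question being whether
# read hotspots are copies of one another, as inverted-repeat regions
# are).

suppressMessages(library(srnapipe))

genome <- Biostrings::readDNAStringSet("results/sim/genome.fa")
tags <- read.delim("results/tags.tsv", stringsAsFactors = FALSE)
index <- build_index(genome)
hits <- map_tags(tags, index)
write.table(hits, "results/hits.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("%d of %d tags map (%d hits)\n",
            length(unique(hits$seq)), nrow(tags), nrow(hits)))

prof <- strand_profile(tags, hits, "all")
write.table(prof, "results/strand_profile.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(prof)

hot <- find_hotspots(tags, hits, index, window_len = 1000, step = 500)
write.table(hot, "results/hotspots.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("hotspots (read-richest first):\n"); print(head(hot, 5))

if (nrow(hot) >= 2) {
  g <- as.character(genome)
  locus_seq <- function(r) {
    s <- substr(g[[hot$chrom[r]]], hot$start[r], hot$end[r])
    if (hot$strand[r] == "-") revcomp(s) else s
  }
  al <- align_loci(locus_seq(1), locus_seq(2))
  cat(sprintf("top two hotspots: identity %.2f over %d aligned nt (coverage %.2f)\n",
              al$identity, al$aligned_length, al$coverage))
}
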