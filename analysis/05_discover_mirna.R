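#!/usr/bin/env Rscript

# Stage 5: hairpin miRNA discovery.
#
# Takes the non-annotated and known-miRNA homolog tags with more than
# one read and 1-20 genome hits, extracts 300-nt flanked windows at each
# hit, applies the hairpin precursor criteria (>= 16 mature:star pairs,
# <= 4 bulges, precursor MFE <= -18 kcal/mol, mature 18-25 nt, 20-nt
# retained flank), tests precursor stability by dinucleotide shuffling
# (N = 199), evaluates per-library 5'-end homogeneity, and applies the
# p-value/homogeneity decision.  Writes the characteristics table,
# precursor FASTA with dot-bracket structures, and precursor GFF3.

suppressMessages(library(srnapipe))

set.seed(as.integer(Sys.getenv("SRNA_SEED", "101")))
genome <- Biostrings::readDNAStringSet("results/sim/genome.fa")
tags <- read.delim("results/tags.tsv", stringsAsFactors = FALSE)
hits <- read.delim("results/hits.tsv", stringsAsFactors = FALSE)
calls <- read.delim("results/annotation_calls.tsv", stringsAsFactors = FALSE)

sel <- calls$category %in% c("non_annotated", "known_miRNA")
ctags <- tags[sel, , drop = FALSE]
chits <- hits[hits$seq %in% ctags$seq, , drop = FALSE]
cat(sprintf("%d candidate-source tags (non-annotated + known homologs)\n",
            nrow(ctags)))

report <- discover_mirnas(ctags, chits, genome, n_shuffles = 199)
write_mirna_report(report, "results", prefix = "mirna")
rej <- attr(report, "rejected")
write.table(rej, "results/mirna_rejected.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("accepted %d candidate miRNA(s); rejected %d (by stage: %s)\n",
            nrow(report), nrow(rej),
            paste(names(table(rej$stage)), table(rej$stage),
                  sep = "=", collapse = ", ")))
if (nrow(report)) {
  print(report[, c("seq", "location", "mfe", "len", "p_value",
                   "bulges", "mismatches", "PT1", "PT2", "PT3")])
  s <- precursor_summary(report)
  cat(sprintf("precursor length %d-%d nt (floor mean %d); MFE %.1f to %.1f kcal/mol (mean %.2f)\n",
              s$len_min, s$len_max, s$len_mean, s$mfe_min, s$mfe_max,
              s$mfe_mean))
}
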