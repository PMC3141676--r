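#!/usr/bin/env Rscript

# Stage 4: priority-rule annotation.
#
# Every tag receives exactly one category down the chain
# rRNA/tRNA/snRNA/snoRNA (genbank before rfam) > known miRNA > exon >
# intron > siRNA > non-annotated.  Writes the per-tag calls, the
# category summary table, the siRNA phasing statistic per hotspot locus,
# and the count of siRNA tags inside annotated repeats.

suppressMessages(library(srnapipe))

tags <- read.delim("results/tags.tsv", stringsAsFactors = FALSE)
hits <- read.delim("results/hits.tsv", stringsAsFactors = FALSE)
gene_models <- rtracklayer::import("results/sim/genes.gff3")
repeats <- rtracklayer::import("results/sim/repeats.bed")
nci <- index_ncrna(load_ncrna_refs())
known <- load_known_mirnas()

calls <- classify_tags(tags, hits, nci, known, gene_models)
write.table(calls, "results/annotation_calls.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
categories <- summarize_categories(calls, tags)
write.table(categories, "results/categories.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(categories[, 1:5])

# are the siRNA tags phased?
si_tags <- calls$seq[calls$category == "siRNA"]
si_hits <- hits[hits$seq %in% si_tags, ]
if (nrow(si_hits) >= 5) {
  ph <- phasing_statistic(si_hits, phase_len = 21, n_perm = 999)
  cat(sprintf("siRNA phasing: score %.3f, permutation p = %.3f (n = %d)\n",
              ph$score, ph$p_value, ph$n))
} else {
  cat("too few siRNA hits for a phasing test\n")
}
n_rep <- repeat_overlap(si_hits, repeats)
cat(sprintf("%d siRNA tag(s) fall inside annotated repeats\n", n_rep))
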