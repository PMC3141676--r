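#!/usr/bin/env Rscript

# Stage 6: miRNA target prediction.
#
# Scans the simulated transcript set (exonic sequence of the planted
# gene models, plus one transcript with an implanted complementary site
# as a positive control) for duplex sites of the discovered miRNAs
# (score >= 90, duplex energy <= -20 kcal/mol, seed scaling 2), then
# applies the strict position rules and the relaxed positions-2-21
# variant.  Under strict rules random transcripts rarely carry sites;
# the relaxed variant recovers near-complementary sites.

suppressMessages(library(srnapipe))

set.seed(as.integer(Sys.getenv("SRNA_SEED", "101")))
report <- read.delim("results/mirna_report.tsv", stringsAsFactors = FALSE)
if (!nrow(report)) {
  cat("no miRNAs discovered; nothing to scan\n")
  quit(status = 0)
}
mirnas <- setNames(report$seq, paste0("candidate_", seq_len(nrow(report))))

truth <- read.delim("results/sim/truth_features.tsv", stringsAsFactors = FALSE)
ex <- truth[truth$kind == "exon", ]
transcripts <- setNames(ex$payload, ex$name)
# positive control: a transcript carrying the exact complement of the
# first miRNA
transcripts <- c(transcripts, control_site = paste0(
  substr(transcripts[[1]], 1, 100), revcomp(mirnas[[1]]),
  substr(transcripts[[1]], 101, 200)))

strict <- predict_targets(mirnas, transcripts, rules = "strict")
relaxed <- predict_targets(mirnas, transcripts, rules = "relaxed")
write.table(strict, "results/targets_strict.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(relaxed, "results/targets_relaxed.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("candidate sites: %d; strict passes: %d; relaxed passes: %d\n",
            nrow(strict), sum(strict$pass), sum(relaxed$pass)))
ctrl <- strict[strict$transcript == "control_site" & strict$mirna == "candidate_1", ]
if (nrow(ctrl))
  cat(sprintf("positive control site: score %.0f, energy %.1f, ratio %.2f, strict pass %s\n",
              ctrl$score[1], ctrl$energy[1], ctrl$ratio[1], ctrl$pass[1]))
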