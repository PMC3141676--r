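#!/usr/bin/env Rscript

# Stage 1: simulate the study.
#
# Builds the toy genome with planted, truth-annotated features (hairpin
# miRNA loci, noncoding-RNA copies, two-exon genes, siRNA duplex loci, a
# repeat family, the organellar inverted repeat, a minus-strand read
# hotspot) and three small-RNA libraries -- a normal-growth analogue
# (PT1) and two nutrient-limited analogues (PT2, PT3) -- then writes
# everything in standard formats under results/sim/.

suppressMessages(library(srnapipe))

seed <- as.integer(Sys.getenv("SRNA_SEED", "101"))
cfg <- synthetic_config(seed = seed)
sim <- make_genome(cfg)
libs <- make_libraries(sim, cfg)

outdir <- "results/sim"
write_simulation(sim, libs, outdir)

cat(sprintf("seed %d: %d reference sequences, %d planted features\n",
            seed, length(sim$genome), nrow(sim$truth)))
print(table(sim$truth$kind))
for (lib in names(libs$reads))
  cat(sprintf("%s: %d raw reads\n", lib, length(libs$reads[[lib]])))
cat("written to", outdir, "\n")
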