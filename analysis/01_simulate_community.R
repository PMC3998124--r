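#!/usr/bin/env Rscript
# Stage 1: generate the synthetic gut-community stand-in.
#
# 40 contigs x 50 kb (one "species" each, phylum label per contig), genes
# laid out in operons, and 5 designated regulon COGs with 15 binding-site
# instances planted in promoter windows. Writes FASTA/TSV/JSON inputs for
# the downstream stages plus the ground-truth manifest.

suppressMessages(library(metaregulon))
seed <- as.integer(commandArgs(TRUE)[1]); if (is.na(seed)) seed <- 1L

dir.create("scratch/community", recursive = TRUE, showWarnings = FALSE)
cfg <- sim_config(seed = seed)
sim <- generate_metagenome(cfg)
write_metagenome(sim, "scratch/community")
print(sim)
cat(sprintf("planted site scores: mean %.2f bits, sd %.2f (model Rsequence %.2f)\n",
            mean(sim$truth$planted$score), sd(sim$truth$planted$score),
            rsequence(sim$model)))
cat("inputs written to scratch/community/\n")
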