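#!/usr/bin/env Rscript
# Stage 2: build the Ri scoring model from the aligned site collection.
#
# The collection is heterogeneous (as real multispecies collections of
# validated sites are), so the mu - 1.5*sigma threshold lands well below
# the mean — this is what makes the downstream 12-20 bit profiling range
# safe from truncation. Pseudocount 0.5 because a 60-site sample leaves
# some bases unseen in near-invariant columns.

suppressMessages(library(metaregulon))

sites <- read_site_collection("scratch/community/collection.fasta")
model <- build_scoring_model(sites, pseudocount = 0.5)
print(model)

dir.create("results", showWarnings = FALSE)
write_scoring_model(model, "results/scoring_model.tsv")
cat("model written to results/scoring_model.tsv (+ .json sidecar)\n")
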