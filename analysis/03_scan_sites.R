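#!/usr/bin/env Rscript
# Stage 3: scan every contig on both strands and keep windows whose Ri
# score beats the collection-derived threshold.

suppressMessages(library(metaregulon))

model <- read_scoring_model("results/scoring_model.tsv")
contigs <- Biostrings::readDNAStringSet("scratch/community/contigs.fasta")
hits <- scan_metagenome(model, contigs)

cat(sprintf("scanned %d windows (%d skipped for ambiguous bases): %d hits > %.2f bits\n",
            attr(hits, "windows_scanned"), attr(hits, "windows_skipped"),
            nrow(hits), model$threshold))
write_hits_tsv(hits, "scratch/community/hits.tsv")
write_hits_gff3(hits, "scratch/community/hits.gff3")
cat("hit tables written to scratch/community/hits.{tsv,gff3}\n")
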