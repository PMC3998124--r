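#!/usr/bin/env Rscript
# Stage 4: put hits in gene context and filter.
#
# Each site is associated with the gene whose translational start is
# closest, flagged if it lies wholly inside that gene's -300/+50 promoter
# window, then restricted to genes on Gram-positive (Firmicutes /
# Actinobacteria) contigs and decorated with COG identity.

suppressMessages(library(metaregulon))

model <- read_scoring_model("results/scoring_model.tsv")
contigs <- Biostrings::readDNAStringSet("scratch/community/contigs.fasta")
genes <- read_gene_table("scratch/community/genes.tsv")
ann <- read_annotation_table("scratch/community/annotations.tsv")
hits <- scan_metagenome(model, contigs)

links <- link_sites_to_genes(hits, genes,
                             contig_lens = setNames(Biostrings::width(contigs),
                                                    names(contigs)))
prom <- filter_promoter_sites(links)
phy <- filter_by_phylum(prom, ann)
filt <- attach_cogs(phy, ann)

ops <- infer_operons(genes)
cat(sprintf("%d raw sites -> %d in promoters -> %d on Gram-positive genes\n",
            nrow(links), nrow(prom), nrow(filt)))
cat(sprintf("(%d sites dropped for disallowed phylum, %d for unannotated genes)\n",
            attr(phy, "n_dropped"), attr(phy, "n_unannotated")))
cat(sprintf("promoter sites average %.2f bits vs %.2f outside promoters\n",
            mean(links$score[links$in_promoter]),
            mean(links$score[!links$in_promoter])))
cat(sprintf("gene map: %d genes in %d operons\n",
            nrow(genes), length(unique(ops$operon_id))))

out <- filt; out$start <- out$start + 1L
write.table(out, "scratch/community/filtered_links.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("filtered site-gene links written to scratch/community/filtered_links.tsv\n")
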