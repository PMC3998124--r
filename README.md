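# metaregulon

Inference of a transcription-factor regulon — the set of gene families a
regulator controls — directly from metagenomic assemblies. The motivating
case is the bacterial SOS response: its repressor, LexA, binds a
near-palindromic operator conserved across Gram-positive bacteria, so a
mixed-community assembly can be scanned for operator sites and the
community-level "meta-regulon" reconstructed without culturing anything.

The package is aimed at computational microbiologists who have (a) an
aligned collection of experimentally validated binding sites, (b) assembled
contigs, and (c) per-gene annotations (COG, functional category, phylum),
and want a tested, reproducible path from those inputs to a ranked list of
putative regulon COGs.

## Method

1. **Scoring model.** From the aligned collection, per-position base
   frequencies `f(b,l)` give individual-information weights
   `riw(b,l) = 2 + log2 f(b,l)` bits; a sequence's Ri score is the sum of
   its per-position weights. The scan threshold is `T = mu - 1.5 sigma`,
   computed from the collection members' own scores.
2. **Scan.** Every window of every contig, both strands, strict `> T`;
   near-palindromic double-strand hits at the same coordinates are
   deduplicated to the better strand.
3. **Gene context.** Each site is linked to the gene with the nearest
   translational start; sites wholly inside the gene's −300/+50 promoter
   window are kept. Operons are called as same-strand runs with intergenic
   gaps < 100 bp.
4. **Taxonomic filter.** Only sites linked to genes on Firmicutes or
   Actinobacteria contigs survive (the clades where the motif is valid).
5. **Classification.** For each COG, the cumulative count of site scores
   above each 1-bit threshold in the 12–20 bit range is fit by OLS. A COG
   is a *prototypical* regulon member when `R² > 0.85`, at least one site
   scores > 16 bits, and ≥ 10 sites fall in [12, 20] bits — the signature
   of the near-normal (mean ≈ 16 bits) score distribution that sites
   upstream of genuinely regulated genes display.

A synthetic-metagenome generator (`sim_config()` / `generate_metagenome()`)
produces contigs with operon-structured genes, phylum labels, a sampled
aligned site collection and motif instances planted in the promoters of
designated regulon COGs, plus a ground-truth manifest — so the whole chain
is validated end to end.

## Worked example

The `analysis/` directory holds the staged workflow. Running it end to end:

```sh
Rscript analysis/01_simulate_community.R   # 2-Mb community, 75 planted sites
Rscript analysis/02_build_model.R
Rscript analysis/03_scan_sites.R
Rscript analysis/04_link_filter_sites.R
Rscript analysis/05_regulon_profiles.R
```

prints, for the default seed:

```
Synthetic metagenome: 40 contigs (2.00 Mb), 1842 genes, 75 planted sites in 5 regulon COGs
planted site scores: mean 16.30 bits, sd 2.53 (model Rsequence 16.22)

Ri scoring model: width 16 bp, 60 sites, pseudocount 0.5
  mu = 13.927 bits, sigma = 4.934 (population), threshold mu - 1.5*sigma = 6.527 bits

scanned 3998800 windows (0 skipped for ambiguous bases): 1745 hits > 6.53 bits

1745 raw sites -> 540 in promoters -> 416 on Gram-positive genes
promoter sites average 9.44 bits vs 8.63 outside promoters

prototypical COGs: COG0556, COG0468, COG1974, COG2001, COG0389
recovered 5 of 5 planted regulon COGs, 0 false positives
   cog_id n_in_range max_score        r2 prototypical
1 COG0556         15  18.53128 0.9631579         TRUE
2 COG0468         15  18.28787 0.9404330         TRUE
3 COG1974         15  18.78654 0.9345200         TRUE
```

Reading the output: the collection-derived threshold (6.5 bits here) admits
~1 700 raw hits over 2 Mb, mostly chance matches near 7–10 bits; the
promoter and phylum filters cut these to 416, and the cumulative-score
linearity criterion then separates the five COGs whose promoters carry
planted operator sites (high `r2`, ≥ 10 in-range sites, max > 16 bits) from
background COGs, which typically hold one or two chance sites each. The
same run is available in one call as `run_regulon_analysis()` (in-memory)
or `run_regulon_pipeline()` (file/YAML-driven), and the per-COG tables land
under `results/`.

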