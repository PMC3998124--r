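Package: metaregulon
Title: Regulon Inference from Metagenomic Sequence with
    Information-Theoretic Binding-Site Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the composition of a transcription-factor regulon from
    metagenomic assemblies. Builds an individual-information (Ri) scoring
    model from an aligned collection of experimentally validated binding
    sites, scans contigs on both strands for above-threshold sites, assigns
    sites to genes through promoter windows and intergenic-distance operon
    prediction, filters by phylum-level taxonomy, and classifies gene
    clusters (COGs) as prototypical regulon members from the linearity of
    their cumulative site-score distribution. Ships a synthetic-metagenome
    generator with a ground-truth manifest for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
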