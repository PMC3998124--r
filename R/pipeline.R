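## End-to-end orchestration: model build -> both-strand scan -> site-gene
## linking -> promoter filter -> phylum filter -> COG profiling ->
## prototypical classification, with a stage-wise count report.

#' Run the regulon-inference pipeline on in-memory inputs
#'
#' @param sites Aligned binding-site collection (character vector), or an
#'   already-built `ri_model` (then `pseudocount` and
#'   `small_sample_correction` are ignored).
#' @param contigs Named character vector / `DNAStringSet` of contigs.
#' @param genes Gene table (internal 0-based half-open convention; see
#'   [read_gene_table()]).
#' @param annotations Annotation table (see [read_annotation_table()]).
#' @param pseudocount Pseudocount for model building (default 0).
#' @param small_sample_correction Apply the e(n) correction when building
#'   the model (default `FALSE`).
#' @param threshold `"auto"` (the model's `mu - 1.5 * sigma`) or explicit
#'   bits.
#' @param upstream,downstream Promoter window extent, bp (defaults
#'   300 / 50).
#' @param gap_max Operon-calling intergenic distance, bp (default 100;
#'   reported for the operon map, which is descriptive — sites are
#'   associated to single genes, not propagated along operons).
#' @param allowed_phyla Phyla kept by the taxonomic filter.
#' @param classifier A [classifier_config()].
#' @param reference_cog Optional COG id for normalised site counts
#'   (skipped when absent from the data).
#' @param category_thresholds Score thresholds for the category
#'   composition table.
#' @return A list of class `regulon_run`: `model`, `hits`, `links`,
#'   `promoter_links`, `filtered_links` (promoter + phylum + COG
#'   decorated), `operons`, `profiles`, `category_table`,
#'   `normalized_counts` (or `NULL`) and `report` (stage-wise counts and
#'   all effective parameters).
#' @export
run_regulon_analysis <- function(sites, contigs, genes, annotations,
                                 pseudocount = 0,
                                 small_sample_correction = FALSE,
                                 threshold = "auto",
                                 upstream = 300, downstream = 50,
                                 gap_max = 100,
                                 allowed_phyla = c("Firmicutes", "Actinobacteria"),
                                 classifier = classifier_config(),
                                 reference_cog = NULL,
                                 category_thresholds = 8:16) {
  model <- if (inherits(sites, "ri_model")) sites
           else build_scoring_model(sites, pseudocount = pseudocount,
                                    small_sample_correction = small_sample_correction)
  thr <- if (identical(threshold, "auto")) model$threshold else as.numeric(threshold)
  if (!is.finite(thr)) stop("stage scan: threshold is not finite")

  hits <- scan_metagenome(model, contigs, threshold = thr)

  if (methods::is(contigs, "DNAStringSet"))
    contigs <- stats::setNames(as.character(contigs), names(contigs))
  contig_lens <- vapply(contigs, nchar, 0L)

  links <- link_sites_to_genes(hits, genes, upstream = upstream,
                               downstream = downstream,
                               contig_lens = contig_lens)
  operons <- infer_operons(genes, gap_max = gap_max)
  promoter_links <- filter_promoter_sites(links)
  phylum_links <- filter_by_phylum(promoter_links, annotations,
                                   allowed = allowed_phyla)
  filtered <- attach_cogs(phylum_links, annotations)
  profiles <- cog_score_profiles(filtered, classifier)
  category_table <- category_distribution(filtered, category_thresholds)
  norm_counts <- if (!is.null(reference_cog) &&
                     reference_cog %in% filtered$cog_id)
    normalized_cog_counts(filtered, reference_cog) else NULL

  report <- list(
    n_raw_sites = nrow(hits),
    n_promoter_sites = nrow(promoter_links),
    n_phylum_filtered_sites = nrow(phylum_links),
    n_sites_dropped_phylum = attr(phylum_links, "n_dropped"),
    n_sites_unannotated_gene = attr(phylum_links, "n_unannotated"),
    n_genes = nrow(genes),
    n_genes_with_sites = length(unique(filtered$gene_id)),
    n_operons = length(unique(operons$operon_id)),
    n_cogs_profiled = nrow(profiles),
    n_prototypical_cogs = sum(profiles$prototypical),
    prototypical_cogs = profiles$cog_id[profiles$prototypical],
    windows_scanned = attr(hits, "windows_scanned"),
    windows_skipped = attr(hits, "windows_skipped"),
    parameters = list(pseudocount = model$pseudocount,
                      small_sample_correction = model$correction,
                      threshold = thr, threshold_mode =
                        if (identical(threshold, "auto")) "auto" else "explicit",
                      model_mu = model$mu, model_sigma = model$sigma,
                      upstream = upstream, downstream = downstream,
                      gap_max = gap_max, allowed_phyla = allowed_phyla,
                      classifier = unclass(classifier)))

  structure(list(model = model, hits = hits, links = links,
                 promoter_links = promoter_links, filtered_links = filtered,
                 operons = operons, profiles = profiles,
                 category_table = category_table,
                 normalized_counts = norm_counts, report = report),
            class = "regulon_run")
}

#' @export
print.regulon_run <- function(x, ...) {
  r <- x$report
  cat("Regulon inference run\n")
  cat(sprintf("  scan threshold     : %.3f bits (%s)\n",
              r$parameters$threshold, r$parameters$threshold_mode))
  cat(sprintf("  raw sites          : %d\n", r$n_raw_sites))
  cat(sprintf("  promoter sites     : %d\n", r$n_promoter_sites))
  cat(sprintf("  phylum-filtered    : %d\n", r$n_phylum_filtered_sites))
  cat(sprintf("  genes with sites   : %d\n", r$n_genes_with_sites))
  cat(sprintf("  COGs profiled      : %d\n", r$n_cogs_profiled))
  cat(sprintf("  prototypical COGs  : %d (%s)\n", r$n_prototypical_cogs,
              paste(r$prototypical_cogs, collapse = ", ")))
  invisible(x)
}

#' Run the pipeline from files described by a configuration
#'
#' The configuration is a list (or path to a YAML file) with elements:
#' `sites` (aligned collection, FASTA or one-per-line), `contigs` (FASTA),
#' `genes` (TSV, or GFF3 when the name ends in `.gff`/`.gff3`),
#' `annotations` (TSV), optional `out_dir` and any parameter accepted by
#' [run_regulon_analysis()] (`pseudocount`, `threshold`, `upstream`,
#' `downstream`, `gap_max`, `allowed_phyla`, `reference_cog`, and
#' classifier fields `r2_min`, `high_score_min`, `n_min`).
#'
#' When `out_dir` is set, writes `hits.tsv`, `hits.gff3`, `links.tsv`,
#' `profiles.tsv`, `category_distribution.tsv`, optionally
#' `normalized_counts.tsv`, and `report.json`.
#'
#' @param config List or YAML file path.
#' @return The `regulon_run` (invisibly when `out_dir` is written).
#' @export
run_regulon_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  for (f in c("sites", "contigs", "genes", "annotations")) {
    if (is.null(config[[f]])) stop("config lacks '", f, "'")
    if (!file.exists(config[[f]])) stop("stage input: file not found: ", config[[f]])
  }
  sites <- read_site_collection(config$sites)
  contigs <- Biostrings::readDNAStringSet(config$contigs)
  genes <- if (grepl("\\.gff3?$", config$genes, ignore.case = TRUE))
    read_genes_gff3(config$genes) else read_gene_table(config$genes)
  annotations <- read_annotation_table(config$annotations)

  cls <- classifier_config(
    r2_min = config$r2_min %||% 0.85,
    high_score_min = config$high_score_min %||% 16,
    n_min = config$n_min %||% 10)
  run <- run_regulon_analysis(
    sites, contigs, genes, annotations,
    pseudocount = config$pseudocount %||% 0,
    small_sample_correction = isTRUE(config$small_sample_correction),
    threshold = config$threshold %||% "auto",
    upstream = config$upstream %||% 300,
    downstream = config$downstream %||% 50,
    gap_max = config$gap_max %||% 100,
    allowed_phyla = config$allowed_phyla %||% c("Firmicutes", "Actinobacteria"),
    classifier = cls,
    reference_cog = config$reference_cog)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_hits_tsv(run$hits, file.path(config$out_dir, "hits.tsv"))
    write_hits_gff3(run$hits, file.path(config$out_dir, "hits.gff3"))
    lk <- run$filtered_links; lk$start <- lk$start + 1L
    utils::write.table(lk, file.path(config$out_dir, "links.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(run$profiles, file.path(config$out_dir, "profiles.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(run$category_table,
                       file.path(config$out_dir, "category_distribution.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(run$normalized_counts))
      utils::write.table(run$normalized_counts,
                         file.path(config$out_dir, "normalized_counts.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(run$report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(run))
  }
  run
}

`%||%` <- function(a, b) if (is.null(a)) b else a
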