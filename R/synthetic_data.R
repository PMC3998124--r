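## Synthetic metagenome generator: contigs carrying non-overlapping,
## strand-annotated genes grouped into operons, with COG / functional
## category / phylum labels, and motif instances planted in the promoter
## windows of designated "regulon" COGs. A ground-truth manifest records
## every planted site, so end-to-end recovery can be measured exactly.

#' Default binding-site frequency matrix
#'
#' A 16-column, near-palindromic motif qualitatively shaped like the
#' Gram-positive LexA operator: two strongly conserved GAAC / GTTC half
#' sites (consensus probability 0.995) separated and flanked by a weakly
#' constrained AT-rich spacer. Sites sampled position-wise from this
#' matrix score approximately normally with mean ~16.2 bits and standard
#' deviation ~2.3 bits under the matrix's own Ri model. It is a synthetic
#' fixture motif, not an estimate of any published matrix.
#'
#' @return 4 x 16 matrix of base probabilities (rows ACGT).
#' @export
lexa_motif_frequencies <- function() {
  consensus <- strsplit("AAGAACATATGTTCTT", "")[[1L]]
  p_cons <- c(0.35, 0.35, 0.995, 0.995, 0.995, 0.995, 0.40, 0.50,
              0.40, 0.45, 0.995, 0.995, 0.995, 0.995, 0.35, 0.35)
  freq <- matrix(0, 4L, 16L, dimnames = list(.BASES, NULL))
  for (l in seq_len(16L)) {
    freq[, l] <- (1 - p_cons[l]) / 3
    freq[consensus[l], l] <- p_cons[l]
  }
  freq
}

#' Sample binding sites position-wise from an Ri model
#'
#' Each position is drawn independently from the model's `f(., l)`, so the
#' expected score of a sampled site is `rsequence(model)` and a sampled
#' site never contains a zero-frequency (`-Inf` weight) base.
#'
#' @param model An `ri_model`.
#' @param n Number of sites to draw (uses the current RNG state).
#' @return Character vector of `n` sites of length `model$width`.
#' @export
sample_sites <- function(model, n) {
  stopifnot(inherits(model, "ri_model"), n >= 0)
  if (n == 0L) return(character())
  L <- model$width
  cols <- lapply(seq_len(L), function(l) sample(.BASES, n, replace = TRUE,
                                                prob = model$freq[, l]))
  do.call(paste0, cols)
}

#' Monte-Carlo estimate of the chance that a random window beats a threshold
#'
#' Scores `n` i.i.d. random windows of the model's width drawn with the
#' given GC content and returns the fraction strictly above `threshold` —
#' the per-window, per-strand false-positive rate of a scan over neutral
#' sequence.
#'
#' @param model An `ri_model`.
#' @param threshold Score threshold in bits.
#' @param n Number of Monte-Carlo windows (default 200000).
#' @param gc_content Background GC fraction (default 0.5).
#' @return Estimated probability (uses the current RNG state).
#' @export
background_hit_probability <- function(model, threshold, n = 200000L,
                                       gc_content = 0.5) {
  probs <- c((1 - gc_content) / 2, gc_content / 2,
             gc_content / 2, (1 - gc_content) / 2)
  L <- model$width
  s <- numeric(n)
  for (l in seq_len(L)) {
    idx <- sample.int(4L, n, replace = TRUE, prob = probs)
    s <- s + model$riw[cbind(idx, l)]
  }
  mean(s > threshold)
}

#' Configuration for the synthetic metagenome generator
#'
#' Defaults describe a ~2-Mb community: 40 contigs of 50 kb, each contig
#' one "species" with a single phylum label, genes of ~900 bp laid in
#' operons (within-operon gaps 5-80 bp, between-operon gaps 150-400 bp),
#' five designated regulon COGs with 15 promoter-planted motif instances
#' each, and 50 background COGs.
#'
#' @param seed Integer RNG seed; the single source of randomness.
#' @param n_contigs,contig_len Community shape.
#' @param mean_gene_len,sd_gene_len,min_gene_len Gene length distribution
#'   (normal, clipped below), bp.
#' @param operon_size_probs Probabilities for operon sizes 1, 2, 3, ...
#' @param gap_within,gap_between Integer ranges (min, max) for intergenic
#'   gaps inside and between operons, bp. `gap_within` must stay strictly
#'   below the operon-calling distance (100 bp by default);
#'   `gap_between[1]` must leave room for a planted site (>= 90 bp +
#'   motif width).
#' @param regulon_cogs COG ids designated as regulon members.
#' @param regulon_categories One-letter functional category per regulon
#'   COG.
#' @param sites_per_cog Motif instances planted per regulon COG (one per
#'   designated gene, inside its promoter window).
#' @param n_background_cogs Number of background COG ids.
#' @param frac_no_cog Fraction of background genes left without a COG.
#' @param frac_unannotated Fraction of background genes absent from the
#'   annotation table altogether.
#' @param phylum_mix Named proportions of contigs per phylum (must sum to
#'   1). Regulon genes are placed only on Firmicutes / Actinobacteria
#'   contigs so they survive the Gram-positive filter.
#' @param gc_content Background GC fraction.
#' @param collection_size Size of the sampled aligned site collection
#'   emitted alongside the metagenome (input for model building).
#' @param collection_noise_frac Fraction of the collection drawn from a
#'   degraded copy of the motif (frequencies mixed toward uniform). Real
#'   multispecies collections of validated sites are heterogeneous — they
#'   include weak species-specific variants — which makes the collection's
#'   score spread much wider than that of sites sampled from a single
#'   matrix, and puts the mu - 1.5*sigma threshold well below the 12-bit
#'   floor of the profiling range. Default 0.20.
#' @param collection_noise_mix Mixture weight toward uniform for the
#'   degraded subset. Default 0.25.
#' @param motif Optional `ri_model` to plant; default
#'   [lexa_motif_frequencies()] via [scoring_model_from_frequencies()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_contigs = 40L,
                       contig_len = 50000L,
                       mean_gene_len = 900L,
                       sd_gene_len = 200L,
                       min_gene_len = 300L,
                       operon_size_probs = c(0.5, 0.25, 0.15, 0.1),
                       gap_within = c(5L, 80L),
                       gap_between = c(150L, 400L),
                       regulon_cogs = c("COG1974", "COG0389", "COG0556",
                                        "COG2001", "COG0468"),
                       regulon_categories = c("K", "L", "L", "D", "L"),
                       sites_per_cog = 15L,
                       n_background_cogs = 50L,
                       frac_no_cog = 0.10,
                       frac_unannotated = 0.05,
                       phylum_mix = c(Firmicutes = 0.50, Actinobacteria = 0.20,
                                      Bacteroidetes = 0.25, Proteobacteria = 0.05),
                       gc_content = 0.5,
                       collection_size = 60L,
                       collection_noise_frac = 0.20,
                       collection_noise_mix = 0.25,
                       motif = NULL) {
  if (is.null(motif)) motif <- scoring_model_from_frequencies(lexa_motif_frequencies())
  stopifnot(inherits(motif, "ri_model"),
            abs(sum(phylum_mix) - 1) < 1e-9,
            sites_per_cog >= 0,
            length(regulon_categories) == length(regulon_cogs),
            gap_within[1] <= gap_within[2],
            gap_between[1] <= gap_between[2],
            gc_content > 0, gc_content < 1)
  if (gap_between[1] < 90 + motif$width)
    stop("gap_between[1] must be at least 90 + motif width so planted sites fit")
  if (contig_len < mean_gene_len + 2 * gap_between[2] + 200)
    stop("infeasible layout: contig_len too small for a single gene plus margins")
  structure(list(seed = as.integer(seed), n_contigs = as.integer(n_contigs),
                 contig_len = as.integer(contig_len),
                 mean_gene_len = mean_gene_len, sd_gene_len = sd_gene_len,
                 min_gene_len = min_gene_len,
                 operon_size_probs = operon_size_probs,
                 gap_within = as.integer(gap_within),
                 gap_between = as.integer(gap_between),
                 regulon_cogs = regulon_cogs,
                 regulon_categories = regulon_categories,
                 sites_per_cog = as.integer(sites_per_cog),
                 n_background_cogs = as.integer(n_background_cogs),
                 frac_no_cog = frac_no_cog,
                 frac_unannotated = frac_unannotated,
                 phylum_mix = phylum_mix, gc_content = gc_content,
                 collection_size = as.integer(collection_size),
                 collection_noise_frac = collection_noise_frac,
                 collection_noise_mix = collection_noise_mix,
                 motif = motif),
            class = "sim_config")
}

rint <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq.int(range[1], range[2]), n, replace = TRUE)
}

#' Generate a synthetic annotated metagenome with planted regulon sites
#'
#' Lays out genes operon-by-operon on each contig, assigns COG / category /
#' phylum labels (phylum per contig: one contig is one "species"), samples
#' background sequence at the configured GC content, and plants one motif
#' instance (sampled from the configured model, random orientation) in the
#' promoter of each gene designated to a regulon COG. Designated genes are
#' operon leads on Firmicutes / Actinobacteria contigs, with the site
#' placed wholly within 25-76 bp upstream of the translational start so it
#' is unambiguously closest to its gene.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `synthetic_metagenome`: `contigs` (named
#'   character), `genes` (full-truth gene table, internal 0-based
#'   half-open), `annotations` (the observable annotation table; a
#'   configured fraction of background genes is missing), `collection`
#'   (sampled aligned sites for model building), `truth` (list: `planted`
#'   site table with model-orientation sequences and true scores,
#'   `regulon_cogs`, `planted_per_cog`), `model` (the planting model) and
#'   `config`.
#' @export
generate_metagenome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  model <- cfg$motif
  L <- model$width
  allowed <- c("Firmicutes", "Actinobacteria")

  phyla <- sample(names(cfg$phylum_mix), cfg$n_contigs, replace = TRUE,
                  prob = cfg$phylum_mix)
  contig_ids <- sprintf("ctg%03d", seq_len(cfg$n_contigs))

  ## --- gene layout -------------------------------------------------------
  gene_rows <- vector("list", cfg$n_contigs)
  for (ci in seq_len(cfg$n_contigs)) {
    pos <- rint(1L, cfg$gap_between)
    rows <- list()
    gi <- 0L
    repeat {
      strand <- sample(c("+", "-"), 1L)
      size <- sample(seq_along(cfg$operon_size_probs), 1L,
                     prob = cfg$operon_size_probs)
      op_rows <- list()
      for (k in seq_len(size)) {
        len <- max(cfg$min_gene_len,
                   round(stats::rnorm(1L, cfg$mean_gene_len, cfg$sd_gene_len)))
        if (pos + len > cfg$contig_len - 100L) break
        gi <- gi + 1L
        op_rows[[k]] <- data.frame(
          gene_id = sprintf("%s_g%03d", contig_ids[ci], gi),
          contig_id = contig_ids[ci], start = pos, end = pos + len,
          strand = strand, stringsAsFactors = FALSE)
        pos <- pos + len +
          if (k < size) rint(1L, cfg$gap_within) else 0L
      }
      if (length(op_rows)) {
        op <- do.call(rbind, op_rows)
        ## operon lead = 5'-most member (first for +, last for -)
        op$is_lead <- FALSE
        op$is_lead[if (strand == "+") 1L else nrow(op)] <- TRUE
        rows[[length(rows) + 1L]] <- op
      }
      if (length(op_rows) < size) break   # ran out of contig
      pos <- pos + rint(1L, cfg$gap_between)
      if (pos + cfg$min_gene_len > cfg$contig_len - 100L) break
    }
    if (length(rows) == 0L)
      stop("infeasible layout: no gene fits on contig ", contig_ids[ci])
    gene_rows[[ci]] <- do.call(rbind, rows)
  }
  genes <- do.call(rbind, gene_rows)
  rownames(genes) <- NULL
  genes$phylum <- phyla[match(genes$contig_id, contig_ids)]

  ## --- COG assignment ----------------------------------------------------
  n_regulon_genes <- length(cfg$regulon_cogs) * cfg$sites_per_cog
  lead_candidates <- which(genes$is_lead & genes$phylum %in% allowed)
  if (n_regulon_genes > length(lead_candidates))
    stop("infeasible layout: need ", n_regulon_genes,
         " operon-lead genes on Gram-positive contigs, have ",
         length(lead_candidates))
  designated <- if (n_regulon_genes > 0L)
    sample(lead_candidates, n_regulon_genes) else integer()

  bg_cogs <- sprintf("COG9%03d", seq_len(cfg$n_background_cogs))
  bg_categories <- sample(strsplit("CDEFGHIJKLMNOPQRSTUV", "")[[1L]],
                          cfg$n_background_cogs, replace = TRUE)
  genes$cog_id <- ifelse(stats::runif(nrow(genes)) < cfg$frac_no_cog, "",
                         sample(bg_cogs, nrow(genes), replace = TRUE))
  genes$cog_category <- bg_categories[match(genes$cog_id, bg_cogs)]
  genes$cog_category[is.na(genes$cog_category)] <- ""
  if (n_regulon_genes > 0L) {
    reg_assign <- rep(seq_along(cfg$regulon_cogs), each = cfg$sites_per_cog)
    genes$cog_id[designated] <- cfg$regulon_cogs[reg_assign]
    genes$cog_category[designated] <- cfg$regulon_categories[reg_assign]
  }

  ## --- background sequence ----------------------------------------------
  probs <- c(A = (1 - cfg$gc_content) / 2, C = cfg$gc_content / 2,
             G = cfg$gc_content / 2, T = (1 - cfg$gc_content) / 2)
  seqs <- lapply(seq_len(cfg$n_contigs), function(i)
    sample(.BASES, cfg$contig_len, replace = TRUE, prob = probs))
  names(seqs) <- contig_ids

  ## --- plant motif instances in promoters of designated genes ------------
  planted <- list()
  occupied <- stats::setNames(vector("list", cfg$n_contigs), contig_ids)
  for (j in designated) {
    g <- genes[j, ]
    site <- sample_sites(model, 1L)
    placed <- FALSE
    for (try in seq_len(30L)) {
      u <- rint(1L, c(25L, 60L))   # bp from site's gene-proximal edge to TSS
      s0 <- if (g$strand == "+") g$start - u - L else g$end + u
      if (s0 < 0L || s0 + L > cfg$contig_len) next
      iv <- c(s0, s0 + L)
      clash <- any(vapply(occupied[[g$contig_id]],
                          function(o) iv[1] < o[2] && o[1] < iv[2], TRUE))
      if (clash) next
      orient <- sample(c("+", "-"), 1L)
      ins <- if (orient == "+") site else revcomp_string(site)
      seqs[[g$contig_id]][(s0 + 1L):(s0 + L)] <- strsplit(ins, "")[[1L]]
      occupied[[g$contig_id]] <- c(occupied[[g$contig_id]], list(iv))
      planted[[length(planted) + 1L]] <- data.frame(
        contig_id = g$contig_id, start = s0, end = s0 + L, strand = orient,
        gene_id = g$gene_id, cog_id = g$cog_id, site_seq = site,
        score = score_sequence(model, site), stringsAsFactors = FALSE)
      placed <- TRUE
      break
    }
    if (!placed) warning("could not place a site upstream of ", g$gene_id)
  }
  planted <- if (length(planted))
    do.call(rbind, c(planted, list(make.row.names = FALSE)))
  else data.frame(contig_id = character(), start = integer(), end = integer(),
                  strand = character(), gene_id = character(),
                  cog_id = character(), site_seq = character(),
                  score = numeric(), stringsAsFactors = FALSE)

  contigs <- vapply(seqs, paste, "", collapse = "")

  ## --- observable annotation table ---------------------------------------
  ann <- data.frame(gene_id = genes$gene_id,
                    best_hit_protein = sprintf("WP_%06d", seq_len(nrow(genes))),
                    cog_id = genes$cog_id, cog_category = genes$cog_category,
                    phylum = genes$phylum, stringsAsFactors = FALSE)
  droppable <- setdiff(seq_len(nrow(genes)), designated)
  drop <- droppable[stats::runif(length(droppable)) < cfg$frac_unannotated]
  if (length(drop)) ann <- ann[-drop, ]
  rownames(ann) <- NULL

  ## aligned collection for model building: mostly matrix-sampled sites
  ## plus a degraded minority emulating multispecies heterogeneity
  n_deg <- round(cfg$collection_noise_frac * cfg$collection_size)
  degraded_model <- scoring_model_from_frequencies(
    (1 - cfg$collection_noise_mix) * model$freq + cfg$collection_noise_mix * 0.25)
  collection <- c(sample_sites(model, cfg$collection_size - n_deg),
                  sample_sites(degraded_model, n_deg))

  planted_per_cog <- if (nrow(planted))
    as.list(table(planted$cog_id)) else list()
  genes$is_lead <- NULL

  structure(list(contigs = contigs, genes = genes, annotations = ann,
                 collection = collection,
                 truth = list(planted = planted,
                              regulon_cogs = cfg$regulon_cogs,
                              planted_per_cog = planted_per_cog),
                 model = model, config = cfg),
            class = "synthetic_metagenome")
}

#' @export
print.synthetic_metagenome <- function(x, ...) {
  cat(sprintf("Synthetic metagenome: %d contigs (%.2f Mb), %d genes, %d planted sites in %d regulon COGs\n",
              length(x$contigs), sum(nchar(x$contigs)) / 1e6, nrow(x$genes),
              nrow(x$truth$planted), length(x$truth$regulon_cogs)))
  invisible(x)
}

#' Write a synthetic metagenome to flat files
#'
#' Writes `contigs.fasta`, `genes.tsv` (1-based inclusive coordinates),
#' `annotations.tsv`, `collection.fasta` (the aligned site collection) and
#' `truth.json` (planted-site manifest, 1-based inclusive) into `dir`.
#'
#' @param sim A `synthetic_metagenome`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_metagenome <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_metagenome"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$contigs),
                              file.path(dir, "contigs.fasta"))
  write_gene_table(sim$genes, file.path(dir, "genes.tsv"))
  utils::write.table(sim$annotations, file.path(dir, "annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  coll <- Biostrings::DNAStringSet(sim$collection)
  names(coll) <- sprintf("site%03d", seq_along(sim$collection))
  Biostrings::writeXStringSet(coll, file.path(dir, "collection.fasta"))
  planted <- sim$truth$planted
  planted$start <- planted$start + 1L   # 1-based inclusive on disk
  jsonlite::write_json(list(coordinate_system = "1-based inclusive",
                            regulon_cogs = sim$truth$regulon_cogs,
                            planted_per_cog = sim$truth$planted_per_cog,
                            planted = planted),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a truth manifest written by [write_metagenome()]
#'
#' @param path Path to `truth.json`.
#' @return List with `planted` (internal 0-based half-open coordinates),
#'   `regulon_cogs`, `planted_per_cog`.
#' @export
read_truth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  planted <- as.data.frame(tr$planted, stringsAsFactors = FALSE)
  if (nrow(planted)) planted$start <- planted$start - 1L
  list(planted = planted, regulon_cogs = tr$regulon_cogs,
       planted_per_cog = tr$planted_per_cog)
}
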