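## Promoter windows, intergenic-distance operon inference and site-to-gene
## association. Gene coordinates are 0-based half-open internally (the
## translational start of a + gene is `start`; of a - gene, `end - 1`);
## TSV/GFF interchange is 1-based inclusive.

#' Read a gene-annotation table (TSV, 1-based inclusive coordinates)
#'
#' Expected columns: `gene_id`, `contig_id`, `start`, `end`, `strand`, and
#' optionally `cog_id`, `cog_category`, `phylum`. Coordinates are converted
#' to the internal 0-based half-open convention.
#'
#' @param path TSV path.
#' @return Gene `data.frame` with 0-based half-open `start`/`end`.
#' @export
read_gene_table <- function(path) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in c("cog_id", "cog_category", "phylum"))
    if (col %in% names(g)) g[[col]] <- ifelse(is.na(g[[col]]), "", as.character(g[[col]]))
  required <- c("gene_id", "contig_id", "start", "end", "strand")
  missing <- setdiff(required, names(g))
  if (length(missing)) stop("gene table lacks columns: ", paste(missing, collapse = ", "))
  g$start <- g$start - 1L   # to 0-based half-open
  validate_genes(g)
  g
}

#' Write a gene table (converts back to 1-based inclusive)
#' @param genes Gene `data.frame` (internal convention).
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_gene_table <- function(genes, path) {
  out <- genes
  out$start <- out$start + 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene annotations from GFF3
#'
#' Gene features are taken from the file's `gene` (or, failing that, `CDS`)
#' records; `cog_id`, `cog_category` and `phylum` are read from the
#' attribute column when present.
#'
#' @param path GFF3 path.
#' @return Gene `data.frame` in the internal 0-based half-open convention.
#' @export
read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  keep <- as.character(gr$type) %in% c("gene", "CDS")
  if (any(keep)) gr <- gr[keep]
  md <- as.data.frame(GenomicRanges::mcols(gr))
  pick <- function(col) if (col %in% names(md)) as.character(md[[col]]) else ""
  ids <- if ("ID" %in% names(md)) as.character(md$ID) else paste0("gene", seq_along(gr))
  g <- data.frame(gene_id = ids,
                  contig_id = as.character(GenomicRanges::seqnames(gr)),
                  start = GenomicRanges::start(gr) - 1L,
                  end = GenomicRanges::end(gr),
                  strand = as.character(GenomicRanges::strand(gr)),
                  cog_id = pick("cog_id"),
                  cog_category = pick("cog_category"),
                  phylum = pick("phylum"),
                  stringsAsFactors = FALSE)
  validate_genes(g)
  g
}

validate_genes <- function(genes) {
  stopifnot(all(c("gene_id", "contig_id", "start", "end", "strand") %in% names(genes)))
  if (nrow(genes) == 0L) return(invisible(genes))
  if (any(genes$start >= genes$end)) stop("gene with start >= end")
  if (!all(genes$strand %in% c("+", "-"))) stop("gene strand must be '+' or '-'")
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id")
  invisible(genes)
}

#' Group genes into operons by intergenic distance
#'
#' Consecutive genes (in coordinate order on a contig) that share a strand
#' and whose intergenic gap `next$start - prev$end` is strictly below
#' `gap_max` are chained into one operon; a strand switch or a gap of at
#' least `gap_max` starts a new operon. Singleton genes form singleton
#' operons.
#'
#' @param genes Gene `data.frame` (internal convention).
#' @param gap_max Maximum intergenic distance in bp (exclusive). Default
#'   100 bp.
#' @return A `data.frame` with one row per gene: `gene_id`, `operon_id`,
#'   `contig_id`, `strand`, `position_in_operon` (1 = operon lead, i.e.
#'   the 5'-most member on its strand).
#' @export
infer_operons <- function(genes, gap_max = 100) {
  if (nrow(genes) == 0L)
    return(data.frame(gene_id = character(), operon_id = character(),
                      contig_id = character(), strand = character(),
                      position_in_operon = integer(), stringsAsFactors = FALSE))
  ord <- order(genes$contig_id, genes$start)
  g <- genes[ord, ]
  n <- nrow(g)
  new_chain <- c(TRUE, g$contig_id[-1L] != g$contig_id[-n] |
                   g$strand[-1L] != g$strand[-n] |
                   (g$start[-1L] - g$end[-n]) >= gap_max)
  op_num <- cumsum(new_chain)
  out <- data.frame(gene_id = g$gene_id,
                    operon_id = sprintf("operon%05d", op_num),
                    contig_id = g$contig_id, strand = g$strand,
                    stringsAsFactors = FALSE)
  ## operon lead = 5'-most member: first in coordinate order for +, last for -
  pos <- stats::ave(seq_len(n), op_num, FUN = seq_along)
  len <- stats::ave(seq_len(n), op_num, FUN = length)
  out$position_in_operon <- ifelse(out$strand == "+", pos, len - pos + 1L)
  out
}

#' Promoter window around a gene's translational start
#'
#' Strand-aware interval covering `upstream` bp before and `downstream` bp
#' after (and including) the translational start, clipped to the contig.
#' For a + gene starting at `s` the window is `[s - upstream, s +
#' downstream)`; for a - gene ending at `e` it is `[e - downstream, e +
#' upstream)`.
#'
#' @param start,end Gene coordinates (0-based half-open); vectorised.
#' @param strand `"+"` or `"-"`; vectorised.
#' @param upstream,downstream Window extent in bp (defaults 300 and 50).
#' @param contig_len Contig length(s) for clipping.
#' @return A two-column matrix `win_start`, `win_end` (0-based half-open).
#' @export
promoter_window <- function(start, end, strand, upstream = 300,
                            downstream = 50, contig_len) {
  ws <- ifelse(strand == "+", start - upstream, end - downstream)
  we <- ifelse(strand == "+", start + downstream, end + upstream)
  ws <- pmax(ws, 0L)
  we <- pmin(we, contig_len)
  cbind(win_start = ws, win_end = we)
}

#' Associate each site with the gene whose translational start is closest
#'
#' Distance is measured from the site midpoint to the translational start,
#' on the same contig. Ties on distance are broken toward the gene whose
#' promoter window contains the whole site; if both or neither qualify,
#' toward the lower-coordinate gene. Sites on contigs without genes are
#' dropped and counted in the `n_dropped_no_gene` attribute.
#'
#' @param hits Hit table from [scan_metagenome()].
#' @param genes Gene `data.frame` (internal convention).
#' @param upstream,downstream Promoter window extent (defaults 300/50 bp).
#' @param contig_lens Named vector of contig lengths; when `NULL`, windows
#'   are clipped only at 0 (the right clip only matters within `downstream
#'   + upstream` bp of a contig end).
#' @return `hits` with added columns `gene_id`, `distance_to_start`
#'   (signed bp, negative = upstream of the start, strand-aware) and
#'   `in_promoter` (whole site inside the linked gene's promoter window).
#' @export
link_sites_to_genes <- function(hits, genes, upstream = 300, downstream = 50,
                                contig_lens = NULL) {
  validate_genes(genes)
  out_cols <- c(names(hits), "gene_id", "distance_to_start", "in_promoter")
  if (nrow(hits) == 0L) {
    out <- cbind(hits, data.frame(gene_id = character(0),
                                  distance_to_start = numeric(0),
                                  in_promoter = logical(0)))
    attr(out, "n_dropped_no_gene") <- 0L
    return(out)
  }
  res <- vector("list", 0L)
  dropped <- 0L
  for (cid in unique(hits$contig_id)) {
    h <- hits[hits$contig_id == cid, , drop = FALSE]
    g <- genes[genes$contig_id == cid, , drop = FALSE]
    if (nrow(g) == 0L) { dropped <- dropped + nrow(h); next }
    clen <- if (!is.null(contig_lens)) contig_lens[[cid]] else
      max(g$end, h$end) + upstream + downstream
    win <- promoter_window(g$start, g$end, g$strand, upstream, downstream, clen)
    tss <- ifelse(g$strand == "+", g$start, g$end - 1L)
    mid <- (h$start + h$end) / 2
    pick <- integer(nrow(h))
    for (i in seq_len(nrow(h))) {
      d <- abs(mid[i] - tss)
      cand <- which(d == min(d))
      if (length(cand) > 1L) {
        inw <- h$start[i] >= win[cand, 1L] & h$end[i] <= win[cand, 2L]
        if (sum(inw) == 1L) cand <- cand[inw]
        else cand <- cand[order(g$start[cand], g$gene_id[cand])][1L]
      }
      pick[i] <- cand[1L]
    }
    h$gene_id <- g$gene_id[pick]
    h$distance_to_start <- ifelse(g$strand[pick] == "+",
                                  mid - tss[pick], tss[pick] - mid)
    h$in_promoter <- h$start >= win[pick, 1L] & h$end <= win[pick, 2L]
    res[[length(res) + 1L]] <- h
  }
  out <- if (length(res)) do.call(rbind, c(res, list(make.row.names = FALSE)))
         else cbind(hits[0, ], data.frame(gene_id = character(0),
                                          distance_to_start = numeric(0),
                                          in_promoter = logical(0)))
  out <- out[order(out$contig_id, out$start), out_cols]
  rownames(out) <- NULL
  attr(out, "n_dropped_no_gene") <- dropped
  out
}

#' Keep only sites lying wholly inside their gene's promoter window
#'
#' @param links Output of [link_sites_to_genes()].
#' @return The subset with `in_promoter == TRUE`.
#' @export
filter_promoter_sites <- function(links) {
  stopifnot("in_promoter" %in% names(links))
  out <- links[links$in_promoter, , drop = FALSE]
  rownames(out) <- NULL
  out
}
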