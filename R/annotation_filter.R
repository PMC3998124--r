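## Declarative stand-in for alignment-based taxonomic typing: a per-gene
## annotation table (best-hit protein, COG id, COG functional category,
## phylum) drives phylum filtering and COG decoration of site-gene links.

#' Controlled phylum vocabulary used by the synthetic generator and the
#' default filter.
#' @export
PHYLA <- c("Firmicutes", "Actinobacteria", "Bacteroidetes", "Proteobacteria",
           "Verrucomicrobia", "Fusobacteria")

#' Read a gene annotation table
#'
#' TSV with header `gene_id`, `best_hit_protein`, `cog_id`,
#' `cog_category`, `phylum`. `gene_id` must be unique; empty strings mark
#' missing annotations.
#'
#' @param path TSV path.
#' @return Annotation `data.frame`.
#' @export
read_annotation_table <- function(path) {
  a <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("gene_id", "cog_id", "cog_category", "phylum")
  missing <- setdiff(required, names(a))
  if (length(missing)) stop("annotation table lacks columns: ",
                            paste(missing, collapse = ", "))
  if (anyDuplicated(a$gene_id)) stop("duplicate gene_id in annotation table")
  for (col in setdiff(names(a), "gene_id"))
    a[[col]] <- ifelse(is.na(a[[col]]), "", as.character(a[[col]]))
  a
}

#' Filter site-gene links by the phylum of the linked gene
#'
#' Keeps links whose gene is annotated to an allowed phylum. Genes absent
#' from the table, or present without a phylum, count as unannotated and
#' are excluded. The attributes `n_kept`, `n_dropped` (disallowed phylum)
#' and `n_unannotated` always satisfy `n_kept + n_dropped + n_unannotated
#' == nrow(links)`.
#'
#' @param links Output of [link_sites_to_genes()] (any table with a
#'   `gene_id` column).
#' @param table Annotation table (see [read_annotation_table()]).
#' @param allowed Character vector of allowed phyla. Default: the
#'   Gram-positive phyla Firmicutes and Actinobacteria.
#' @return Filtered links with counting attributes.
#' @export
filter_by_phylum <- function(links, table,
                             allowed = c("Firmicutes", "Actinobacteria")) {
  phylum <- table$phylum[match(links$gene_id, table$gene_id)]
  unannot <- is.na(phylum) | !nzchar(phylum)
  keep <- !unannot & phylum %in% allowed
  out <- links[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_dropped") <- sum(!keep & !unannot)
  attr(out, "n_unannotated") <- sum(unannot)
  out
}

#' Decorate links with COG identity and functional category
#'
#' Genes without a COG assignment (or absent from the table) get
#' `cog_id = ""` and are thereby excluded from COG-level statistics
#' downstream; their number is recorded in the `n_no_cog` attribute.
#'
#' @param links Links table with a `gene_id` column.
#' @param table Annotation table.
#' @return `links` with `cog_id` and `cog_category` columns added.
#' @export
attach_cogs <- function(links, table) {
  i <- match(links$gene_id, table$gene_id)
  cog <- table$cog_id[i]
  cat <- table$cog_category[i]
  links$cog_id <- ifelse(is.na(cog), "", cog)
  links$cog_category <- ifelse(is.na(cat), "", cat)
  attr(links, "n_no_cog") <- sum(!nzchar(links$cog_id))
  links
}
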