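## Both-strand sliding-window scan of contigs with an Ri model. Coordinates
## are 0-based half-open internally; exports (TSV/GFF3) are 1-based
## inclusive. Windows containing non-ACGT bases are skipped and counted.

revcomp_string <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Score every width-L window of an integer-encoded sequence against a
## 4 x L weight matrix. Returns a numeric vector of length n - L + 1 with
## NA where the window contains a non-ACGT base.
slide_scores <- function(idx, W) {
  L <- ncol(W)
  n <- length(idx)
  nw <- n - L + 1L
  s <- numeric(nw)
  for (l in seq_len(L)) {
    s <- s + W[, l][idx[l:(nw + l - 1L)]]
  }
  s
}

#' Scan one contig on both strands for above-threshold sites
#'
#' Every window of the model's width is scored on the forward strand and,
#' through the complemented and column-reversed weight matrix, on the
#' reverse strand. A window is reported when its Ri score strictly exceeds
#' `threshold`. When both strands of the same window pass, only the
#' higher-scoring strand is kept (ties go to `+`) — the motif may be
#' near-palindromic and double counting would inflate every downstream
#' statistic. Windows containing non-ACGT characters are skipped.
#'
#' @param model An `ri_model`.
#' @param seq A single DNA string (ACGTN alphabet tolerated).
#' @param contig_id Contig identifier for the output table.
#' @param threshold Scan threshold in bits (default: the model's
#'   `mu - 1.5 * sigma`). Must be finite.
#' @return A `data.frame` with columns `contig_id`, `start` (0-based),
#'   `end` (exclusive, `start + width`), `strand`, `score` (bits) and
#'   `site_seq` (the matched sequence, reverse-complemented for `-`
#'   hits), sorted by `start`. Attributes `windows_scanned`,
#'   `windows_skipped` and `n_hits` summarise the scan.
#' @export
scan_contig <- function(model, seq, contig_id = "contig",
                        threshold = model$threshold) {
  stopifnot(inherits(model, "ri_model"))
  if (!is.numeric(threshold) || length(threshold) != 1L || !is.finite(threshold))
    stop("threshold must be a single finite number of bits")
  L <- model$width
  idx <- seq_to_idx(seq)
  n <- length(idx)
  if (n < L) return(empty_hits(windows_scanned = 0L, windows_skipped = 0L))

  W <- model$riw
  ## reverse-strand weights: Wrc[b, m] = W[complement(b), L + 1 - m], so
  ## sliding Wrc over the forward sequence scores the reverse complement
  ## of each window.
  Wrc <- W[4:1, L:1, drop = FALSE]

  s_fwd <- slide_scores(idx, W)
  s_rev <- slide_scores(idx, Wrc)

  nw <- n - L + 1L
  skipped <- sum(is.na(s_fwd))
  pass_f <- !is.na(s_fwd) & s_fwd > threshold
  pass_r <- !is.na(s_rev) & s_rev > threshold

  ## dedupe same-window double-strand hits: keep the better strand. Scores
  ## within 1e-9 bits count as a tie and go to + (palindromic windows score
  ## identically up to summation order).
  both <- pass_f & pass_r
  pass_r[both & s_fwd >= s_rev - 1e-9] <- FALSE
  pass_f[both & s_rev > s_fwd + 1e-9] <- FALSE

  starts <- c(which(pass_f), which(pass_r)) - 1L
  strands <- rep(c("+", "-"), c(sum(pass_f), sum(pass_r)))
  scores <- c(s_fwd[pass_f], s_rev[pass_r])
  ord <- order(starts)
  starts <- starts[ord]; strands <- strands[ord]; scores <- scores[ord]

  if (length(starts) == 0L)
    return(empty_hits(windows_scanned = 2L * nw, windows_skipped = 2L * skipped))
  site_seq <- substring(toupper(seq), starts + 1L, starts + L)
  minus <- strands == "-"
  if (any(minus)) site_seq[minus] <- revcomp_string(site_seq[minus])

  hits <- data.frame(contig_id = rep(contig_id, length(starts)),
                     start = starts, end = starts + L,
                     strand = strands, score = scores, site_seq = site_seq,
                     stringsAsFactors = FALSE)
  attr(hits, "windows_scanned") <- 2L * nw
  attr(hits, "windows_skipped") <- 2L * skipped
  attr(hits, "n_hits") <- nrow(hits)
  hits
}

empty_hits <- function(windows_scanned = 0L, windows_skipped = 0L) {
  hits <- data.frame(contig_id = character(), start = integer(),
                     end = integer(), strand = character(),
                     score = numeric(), site_seq = character(),
                     stringsAsFactors = FALSE)
  attr(hits, "windows_scanned") <- windows_scanned
  attr(hits, "windows_skipped") <- windows_skipped
  attr(hits, "n_hits") <- 0L
  hits
}

#' Scan a set of contigs
#'
#' @param model An `ri_model`.
#' @param contigs Named character vector of contig sequences, or a
#'   [Biostrings::DNAStringSet]. Names must be unique.
#' @param threshold Scan threshold in bits (default `model$threshold`).
#' @return Concatenated per-contig hit tables (see [scan_contig()]),
#'   ordered by (`contig_id`, `start`), with summary attributes
#'   `windows_scanned`, `windows_skipped`, `n_hits`.
#' @export
scan_metagenome <- function(model, contigs, threshold = model$threshold) {
  if (methods::is(contigs, "DNAStringSet")) {
    contigs <- stats::setNames(as.character(contigs), names(contigs))
  }
  ids <- names(contigs)
  if (is.null(ids) || any(!nzchar(ids))) stop("contigs must be named")
  if (anyDuplicated(ids)) stop("duplicate contig ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  per <- lapply(ids[order(ids)], function(id)
    scan_contig(model, contigs[[id]], contig_id = id, threshold = threshold))
  hits <- if (length(per)) do.call(rbind, c(per, list(make.row.names = FALSE)))
          else empty_hits()
  attr(hits, "windows_scanned") <- sum(vapply(per, attr, 0L, "windows_scanned"))
  attr(hits, "windows_skipped") <- sum(vapply(per, attr, 0L, "windows_skipped"))
  attr(hits, "n_hits") <- nrow(hits)
  hits
}

#' Write a hit table as TSV (1-based inclusive coordinates)
#'
#' @param hits Hit table from [scan_metagenome()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hits_tsv <- function(hits, path) {
  out <- hits
  out$start <- out$start + 1L   # 1-based inclusive
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a hit table as GFF3 (`TF_binding_site` features, score in bits)
#'
#' @param hits Hit table from [scan_metagenome()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hits_gff3 <- function(hits, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = hits$contig_id,
    ranges = IRanges::IRanges(start = hits$start + 1L, end = hits$end),
    strand = hits$strand)
  gr$score <- hits$score
  gr$type <- "TF_binding_site"
  gr$site_seq <- hits$site_seq
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}
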