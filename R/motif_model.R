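## Individual-information (Ri) scoring model built from an aligned collection
## of validated binding sites. Weights are riw(b,l) = 2 + log2 f(b,l) bits
## (uniform genomic background); a site's score is the sum of its per-position
## weights. The model also carries the score statistics of the collection
## itself, from which the scan threshold mu - 1.5*sigma is derived.

.BASES <- c("A", "C", "G", "T")

#' Read an aligned binding-site collection
#'
#' Accepts either FASTA or plain text with one site per line. All sites must
#' have identical length and be over the strict ACGT alphabet; ambiguity
#' codes are rejected at this stage because the Ri score of an ambiguous
#' base is undefined.
#'
#' @param path Path to a FASTA file or a one-sequence-per-line text file.
#' @return Character vector of upper-case, equal-length site sequences,
#'   named when the input was FASTA.
#' @export
read_site_collection <- function(path) {
  stopifnot(file.exists(path))
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) && startsWith(trimws(first), ">")) {
    sites <- as.character(Biostrings::readDNAStringSet(path))
  } else {
    sites <- readLines(path, warn = FALSE)
    sites <- trimws(sites)
    sites <- sites[nzchar(sites) & !startsWith(sites, "#")]
  }
  sites <- toupper(sites)
  validate_site_collection(sites)
  sites
}

#' Validate a binding-site collection
#'
#' @param sites Character vector of aligned site sequences.
#' @return Invisibly, `sites`; errors on an empty collection, unequal
#'   lengths, width < 4 or non-ACGT characters.
#' @export
validate_site_collection <- function(sites) {
  if (length(sites) == 0L) stop("site collection is empty")
  widths <- nchar(sites)
  if (length(unique(widths)) != 1L)
    stop("sites are not aligned: lengths ", paste(sort(unique(widths)), collapse = ", "))
  if (widths[1L] < 4L) stop("site width must be at least 4 bp, got ", widths[1L])
  if (any(grepl("[^ACGT]", sites)))
    stop("site collection contains non-ACGT characters (ambiguity codes are not accepted)")
  invisible(sites)
}

## Integer-encode a DNA string: A=1 C=2 G=3 T=4, anything else NA.
seq_to_idx <- function(seq) {
  idx <- match(strsplit(toupper(seq), "")[[1L]], .BASES)
  idx
}

#' Build an Ri scoring model from aligned binding sites
#'
#' Computes per-position base frequencies `f(b,l) = (n(b,l) + pseudocount) /
#' (N + 4 * pseudocount)` and Ri weights `riw(b,l) = 2 + log2 f(b,l)` bits.
#' With `pseudocount = 0` a base absent from a column gets weight `-Inf`,
#' which is the documented sentinel for an impossible base. The collection's
#' own scores give the mean `mu`, standard deviation `sigma`, and the scan
#' threshold `mu - 1.5 * sigma`.
#'
#' @param sites Character vector of aligned ACGT sites (see
#'   [validate_site_collection()]).
#' @param pseudocount Non-negative count added to every cell before
#'   normalisation. Default 0, i.e. the literal frequency matrix.
#' @param sd_type `"population"` (divide by N; default) or `"sample"`
#'   (divide by N - 1) for `sigma`.
#' @param small_sample_correction If `TRUE`, subtract the small-sample
#'   entropy correction `e(N) = 3 / (2 * ln(2) * N)` bits from every weight
#'   (Schneider's approximation for a 4-letter alphabet). Default `FALSE`.
#' @return An object of class `ri_model`: a list with elements `width`,
#'   `freq` (4 x L matrix, rows ACGT), `riw` (4 x L weight matrix, bits),
#'   `pseudocount`, `n_sites`, `mu`, `sigma`, `sd_type`, `threshold`
#'   (`mu - 1.5 * sigma`), `correction` and `e_n`.
#' @export
build_scoring_model <- function(sites, pseudocount = 0,
                                sd_type = c("population", "sample"),
                                small_sample_correction = FALSE) {
  sd_type <- match.arg(sd_type)
  validate_site_collection(sites)
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount < 0)
    stop("pseudocount must be a single non-negative number")
  n_sites <- length(sites)
  width <- nchar(sites[1L])

  mat <- matrix(unlist(lapply(sites, seq_to_idx), use.names = FALSE),
                nrow = n_sites, ncol = width, byrow = TRUE)
  counts <- vapply(seq_len(width),
                   function(l) tabulate(mat[, l], nbins = 4L),
                   integer(4L))
  freq <- (counts + pseudocount) / (n_sites + 4 * pseudocount)
  dimnames(freq) <- list(.BASES, NULL)

  riw <- 2 + log2(freq)  # -Inf where freq == 0
  e_n <- if (small_sample_correction) 3 / (2 * log(2) * n_sites) else 0
  riw <- riw - e_n

  model <- structure(list(width = width, freq = freq, riw = riw,
                          pseudocount = pseudocount, n_sites = n_sites,
                          sd_type = sd_type,
                          correction = small_sample_correction, e_n = e_n),
                     class = "ri_model")

  scores <- vapply(sites, function(s) score_sequence(model, s), 0,
                   USE.NAMES = FALSE)
  model$mu <- mean(scores)
  model$sigma <- if (sd_type == "population") {
    sqrt(mean((scores - model$mu)^2))
  } else {
    stats::sd(scores)
  }
  model$threshold <- model$mu - 1.5 * model$sigma
  model$site_scores <- scores
  model
}

#' Build an Ri model directly from a frequency matrix
#'
#' Used when the motif is specified as per-position base probabilities
#' rather than an aligned collection (e.g. the synthetic-data generator's
#' default motif). The collection statistics `mu` and `sigma` are then the
#' analytic moments of the score of a site sampled position-wise from the
#' matrix: `mu = rsequence` and `sigma^2 = sum_l Var_l(riw)`.
#'
#' @param freq 4 x L numeric matrix of per-position base probabilities;
#'   rows in ACGT order (row names, if present, must be ACGT). Columns must
#'   each sum to 1.
#' @return An `ri_model` (see [build_scoring_model()]); `n_sites` is `NA`.
#' @export
scoring_model_from_frequencies <- function(freq) {
  freq <- as.matrix(freq)
  if (nrow(freq) != 4L) stop("frequency matrix must have 4 rows (A, C, G, T)")
  if (!is.null(rownames(freq)) && !identical(rownames(freq), .BASES))
    stop("frequency matrix rows must be in A, C, G, T order")
  if (any(freq < 0)) stop("negative frequencies")
  if (any(abs(colSums(freq) - 1) > 1e-9)) stop("frequency columns must sum to 1")
  rownames(freq) <- .BASES
  riw <- 2 + log2(freq)
  riw_f <- ifelse(freq > 0, riw, 0)           # 0 * -Inf convention for moments
  info_l <- colSums(freq * riw_f)
  var_l <- colSums(freq * riw_f^2) - info_l^2
  mu <- sum(info_l)
  sigma <- sqrt(sum(var_l))
  structure(list(width = ncol(freq), freq = freq, riw = riw,
                 pseudocount = NA_real_, n_sites = NA_integer_,
                 sd_type = "analytic", correction = FALSE, e_n = 0,
                 mu = mu, sigma = sigma, threshold = mu - 1.5 * sigma,
                 site_scores = NULL),
            class = "ri_model")
}

#' @export
print.ri_model <- function(x, ...) {
  cat(sprintf("Ri scoring model: width %d bp, %s sites, pseudocount %s\n",
              x$width,
              if (is.na(x$n_sites)) "matrix-specified" else x$n_sites,
              format(x$pseudocount)))
  cat(sprintf("  mu = %.3f bits, sigma = %.3f (%s), threshold mu - 1.5*sigma = %.3f bits\n",
              x$mu, x$sigma, x$sd_type, x$threshold))
  cat(sprintf("  Rsequence = %.3f bits%s\n", rsequence(x),
              if (x$correction) sprintf(" (e(n) = %.4f subtracted)", x$e_n) else ""))
  invisible(x)
}

#' Score one sequence under an Ri model
#'
#' `Ri(seq) = sum_l riw(seq[l], l)` bits. A position whose base has zero
#' frequency (possible only with `pseudocount = 0`) contributes `-Inf`, so
#' the score of a sequence containing any impossible base is `-Inf`.
#'
#' @param model An `ri_model`.
#' @param seq A single DNA string of exactly `model$width` ACGT characters.
#' @return The Ri score in bits (possibly `-Inf`).
#' @export
score_sequence <- function(model, seq) {
  stopifnot(inherits(model, "ri_model"), is.character(seq), length(seq) == 1L)
  idx <- seq_to_idx(seq)
  if (length(idx) != model$width)
    stop("sequence length ", length(idx), " != model width ", model$width)
  if (anyNA(idx)) stop("sequence contains non-ACGT characters")
  sum(model$riw[cbind(idx, seq_len(model$width))])
}

#' Expected information content of the model
#'
#' `Rsequence = sum_l sum_b f(b,l) * riw(b,l)` bits — the expected Ri score
#' of a site sampled position-wise from the model's own frequencies. Terms
#' with `f = 0` contribute 0 (so `-Inf` weights never propagate).
#'
#' @param model An `ri_model`.
#' @return Expected per-site information in bits.
#' @export
rsequence <- function(model) {
  stopifnot(inherits(model, "ri_model"))
  w <- ifelse(model$freq > 0, model$riw, 0)
  sum(model$freq * w)
}

#' Write a scoring model to plain-text files
#'
#' The matrix file has one row per motif position with the ACGT frequencies
#' and the ACGT Ri weights; the JSON sidecar records width, pseudocount,
#' mu, sigma, the sd convention and the threshold.
#'
#' @param model An `ri_model`.
#' @param matrix_path Output TSV path for the frequency/weight matrix.
#' @param json_path Optional output path for the JSON sidecar (default:
#'   `matrix_path` with a `.json` extension).
#' @return Invisibly, the matrix path.
#' @export
write_scoring_model <- function(model, matrix_path,
                                json_path = sub("\\.[^.]*$", ".json", matrix_path)) {
  stopifnot(inherits(model, "ri_model"))
  tab <- data.frame(position = seq_len(model$width),
                    t(model$freq), t(model$riw), check.names = FALSE)
  names(tab) <- c("position", paste0("f_", .BASES), paste0("riw_", .BASES))
  utils::write.table(tab, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(width = model$width, pseudocount = model$pseudocount,
               n_sites = model$n_sites, mu = model$mu, sigma = model$sigma,
               sd_type = model$sd_type, threshold = model$threshold,
               small_sample_correction = model$correction, e_n = model$e_n)
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  invisible(matrix_path)
}

#' Read a scoring model written by [write_scoring_model()]
#'
#' @param matrix_path TSV matrix path.
#' @param json_path JSON sidecar path.
#' @return An `ri_model`.
#' @export
read_scoring_model <- function(matrix_path,
                               json_path = sub("\\.[^.]*$", ".json", matrix_path)) {
  tab <- utils::read.delim(matrix_path, check.names = FALSE)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  freq <- t(as.matrix(tab[, paste0("f_", .BASES)]))
  riw <- t(as.matrix(tab[, paste0("riw_", .BASES)]))
  dimnames(freq) <- dimnames(riw) <- list(.BASES, NULL)
  structure(list(width = meta$width, freq = freq, riw = riw,
                 pseudocount = meta$pseudocount, n_sites = meta$n_sites,
                 sd_type = meta$sd_type, correction = meta$small_sample_correction,
                 e_n = meta$e_n, mu = meta$mu, sigma = meta$sigma,
                 threshold = meta$threshold, site_scores = NULL),
            class = "ri_model")
}
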