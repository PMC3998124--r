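## Per-COG cumulative site-score distributions and the prototypical-regulon
## classifier: a COG belongs to the prototypical regulon when the cumulative
## count of its promoter-site scores, taken in 1-bit steps over 12-20 bits,
## is well fit by a straight line (R^2 > 0.85), it has at least one site
## above 16 bits, and at least 10 sites inside the 12-20 bit range.

#' Classifier configuration for prototypical regulon COGs
#'
#' @param r2_min Minimum coefficient of determination of the linear fit to
#'   the cumulative score distribution (strict >). Default 0.85.
#' @param high_score_min A COG must have at least one site scoring strictly
#'   above this (bits). Default 16.
#' @param n_min Minimum number of sites with scores inside `bin_range`
#'   (closed interval). Default 10.
#' @param bin_range Score range for the cumulative distribution, bits.
#'   Default `c(12, 20)`.
#' @param bin_step Bin width in bits. Default 1.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(r2_min = 0.85, high_score_min = 16, n_min = 10,
                              bin_range = c(12, 20), bin_step = 1) {
  stopifnot(length(bin_range) == 2L, bin_range[1] < bin_range[2],
            bin_step > 0, is.finite(r2_min), is.finite(high_score_min),
            is.finite(n_min))
  structure(list(r2_min = r2_min, high_score_min = high_score_min,
                 n_min = n_min, bin_range = bin_range, bin_step = bin_step),
            class = "classifier_config")
}

#' Cumulative site counts over score thresholds
#'
#' `C(t) = #{s : s > t}` for each threshold `t` on the 1-bit grid over
#' `bin_range` (strict >, i.e. sites *above* each threshold).
#'
#' @param scores Numeric vector of site scores in bits.
#' @param cfg A [classifier_config()].
#' @return Named integer vector of counts, one per threshold.
#' @export
cumulative_counts <- function(scores, cfg = classifier_config()) {
  bins <- seq(cfg$bin_range[1], cfg$bin_range[2], by = cfg$bin_step)
  counts <- vapply(bins, function(t) sum(scores > t), integer(1L))
  names(counts) <- bins
  counts
}

#' Linear fit to a cumulative score distribution
#'
#' Ordinary least squares of `C(t)` on `t`. When the counts are constant
#' (zero total sum of squares) `r2` is defined as 0, never `NaN`.
#'
#' @param counts Cumulative counts (e.g. from [cumulative_counts()]).
#' @param bins Thresholds; default taken from `names(counts)`.
#' @return List with `slope`, `intercept`, `r2`.
#' @export
fit_cumulative <- function(counts, bins = as.numeric(names(counts))) {
  if (length(counts) < 2L) stop("need at least 2 bins to fit")
  fit <- stats::lm(counts ~ bins)
  sstot <- sum((counts - mean(counts))^2)
  r2 <- if (sstot == 0) 0 else 1 - sum(stats::residuals(fit)^2) / sstot
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r2 = r2)
}

#' Prototypical-regulon decision rule
#'
#' True iff `r2 > r2_min` AND `max_score > high_score_min` AND
#' `n_in_range >= n_min`. All three comparisons follow the documented
#' conventions: strict `>` for the fit quality and the high-score clause,
#' `>=` for the site-abundance clause; `n_in_range` counts scores in the
#' closed interval `bin_range`.
#'
#' @param r2,max_score,n_in_range Profile statistics (vectorised).
#' @param cfg A [classifier_config()].
#' @return Logical vector.
#' @export
classify_prototypical <- function(r2, max_score, n_in_range,
                                  cfg = classifier_config()) {
  r2 > cfg$r2_min & max_score > cfg$high_score_min & n_in_range >= cfg$n_min
}

#' Per-COG score profiles and prototypical classification
#'
#' Groups (typically promoter- and phylum-filtered) site-gene links by
#' `cog_id`, computes each COG's cumulative score distribution over the
#' configured range, fits it by OLS and applies the prototypical decision
#' rule. Links with an empty `cog_id` are excluded.
#'
#' @param links Links carrying `score` and `cog_id` columns.
#' @param cfg A [classifier_config()].
#' @return `data.frame` with one row per COG: `cog_id`, `n_sites`,
#'   `n_in_range`, `max_score`, `slope`, `intercept`, `r2`,
#'   `prototypical`; ordered by decreasing `r2` then `n_in_range`.
#' @export
cog_score_profiles <- function(links, cfg = classifier_config()) {
  stopifnot(all(c("score", "cog_id") %in% names(links)))
  links <- links[nzchar(links$cog_id), , drop = FALSE]
  if (nrow(links) == 0L)
    return(data.frame(cog_id = character(), n_sites = integer(),
                      n_in_range = integer(), max_score = numeric(),
                      slope = numeric(), intercept = numeric(),
                      r2 = numeric(), prototypical = logical(),
                      stringsAsFactors = FALSE))
  by_cog <- split(links$score, links$cog_id)
  rows <- lapply(names(by_cog), function(cog) {
    s <- by_cog[[cog]]
    counts <- cumulative_counts(s, cfg)
    fit <- fit_cumulative(counts)
    n_in <- sum(s >= cfg$bin_range[1] & s <= cfg$bin_range[2])
    data.frame(cog_id = cog, n_sites = length(s), n_in_range = n_in,
               max_score = max(s), slope = fit$slope,
               intercept = fit$intercept, r2 = fit$r2,
               stringsAsFactors = FALSE)
  })
  prof <- do.call(rbind, rows)
  prof$prototypical <- classify_prototypical(prof$r2, prof$max_score,
                                             prof$n_in_range, cfg)
  prof <- prof[order(-prof$r2, -prof$n_in_range, prof$cog_id), ]
  rownames(prof) <- NULL
  prof
}

#' COG-category composition as a function of score threshold
#'
#' For each threshold, the fraction of surviving links per single-letter
#' functional category (over links that carry a category; fractions sum to
#' 1 at each threshold). Optionally joined against a reference category
#' distribution, e.g. one derived from an ensemble of experimentally
#' characterised regulons.
#'
#' @param links Links carrying `score` and `cog_category` columns.
#' @param thresholds Numeric vector of score thresholds (bits); links with
#'   `score > t` survive at threshold `t`.
#' @param reference Optional `data.frame` with columns `cog_category` and
#'   `proportion` (the reference ensemble's composition); joined as a
#'   `ref_proportion` column.
#' @return Long `data.frame`: `threshold`, `cog_category`, `n`,
#'   `proportion` (+ `ref_proportion` when a reference is given).
#' @export
category_distribution <- function(links, thresholds, reference = NULL) {
  stopifnot(all(c("score", "cog_category") %in% names(links)))
  links <- links[nzchar(links$cog_category), , drop = FALSE]
  rows <- lapply(thresholds, function(t) {
    surv <- links$cog_category[links$score > t]
    if (length(surv) == 0L) return(NULL)
    tab <- table(surv)
    data.frame(threshold = t, cog_category = names(tab),
               n = as.integer(tab),
               proportion = as.numeric(tab) / length(surv),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(threshold = numeric(), cog_category = character(),
                      n = integer(), proportion = numeric(),
                      stringsAsFactors = FALSE)
  if (!is.null(reference)) {
    stopifnot(all(c("cog_category", "proportion") %in% names(reference)))
    out$ref_proportion <- reference$proportion[
      match(out$cog_category, reference$cog_category)]
    out$ref_proportion[is.na(out$ref_proportion)] <- 0
  }
  rownames(out) <- NULL
  out
}

#' Per-COG site counts normalised to a reference COG
#'
#' @param links Links carrying a `cog_id` column.
#' @param reference_cog COG id to normalise against (default `"COG1974"`,
#'   the LexA repressor's own cluster).
#' @return `data.frame` `cog_id`, `n_sites`, `ratio` (count divided by the
#'   reference COG's count), ordered by decreasing ratio.
#' @export
normalized_cog_counts <- function(links, reference_cog = "COG1974") {
  stopifnot("cog_id" %in% names(links))
  links <- links[nzchar(links$cog_id), , drop = FALSE]
  tab <- table(links$cog_id)
  ref <- tab[reference_cog]
  if (is.na(ref) || ref == 0)
    stop("reference COG '", reference_cog, "' has no sites")
  out <- data.frame(cog_id = names(tab), n_sites = as.integer(tab),
                    ratio = as.numeric(tab) / as.numeric(ref),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$ratio, out$cog_id), ]
  rownames(out) <- NULL
  out
}
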