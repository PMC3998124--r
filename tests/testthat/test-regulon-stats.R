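test_that("cumulative counts use strict > on the 12-20 bit grid", {
  scores <- seq(12.5, 19.5, by = 1)     # one score per bin
  C <- cumulative_counts(scores)
  expect_equal(unname(C), 8:0)
  expect_equal(names(C), as.character(12:20))
  expect_equal(unname(cumulative_counts(numeric())), rep(0L, 9))
  # a score exactly on a bin edge does not count at that edge (strict >)
  expect_equal(unname(cumulative_counts(16)[["16"]]), 0L)
  expect_equal(unname(cumulative_counts(16)[["15"]]), 1L)
})

test_that("cumulative counts match a direct recount for sampled scores", {
  set.seed(20)
  scores <- rnorm(200, 16, 3)
  C <- cumulative_counts(scores)
  for (t in 12:20) {
    manual <- 0L
    for (s in scores) if (s > t) manual <- manual + 1L
    expect_equal(unname(C[[as.character(t)]]), manual)
  }
  expect_true(all(diff(C) <= 0))   # monotone non-increasing
})

test_that("the linear fit is exact on an exactly linear distribution", {
  C <- cumulative_counts(seq(12.5, 19.5, by = 1))
  fit <- fit_cumulative(C)
  expect_equal(fit$slope, -1)
  expect_equal(fit$r2, 1.0)
  # constant counts: r2 is 0 by convention, never NaN
  const <- fit_cumulative(setNames(rep(5L, 9), 12:20))
  expect_equal(const$r2, 0)
  expect_false(is.nan(const$r2))
})

test_that("OLS agrees with the closed-form normal equations", {
  set.seed(21)
  scores <- rnorm(200, 16, 3)
  C <- cumulative_counts(scores)
  fit <- fit_cumulative(C)
  orc <- oracle_ols(12:20, unname(C))
  expect_equal(fit$slope, orc$slope, tolerance = 1e-12)
  expect_equal(fit$intercept, orc$intercept, tolerance = 1e-12)
  expect_equal(fit$r2, orc$r2, tolerance = 1e-12)
})

test_that("the prototypical rule is a strict conjunction of three clauses", {
  cfg <- classifier_config()
  # perfectly linear but only 8 sites in range -> fails the abundance clause
  scores <- seq(12.5, 19.5, by = 1)
  fit <- fit_cumulative(cumulative_counts(scores))
  expect_false(classify_prototypical(fit$r2, max(scores),
                                     sum(scores >= 12 & scores <= 20), cfg))
  # all scores above the range -> n_in_range = 0 -> fails
  expect_false(classify_prototypical(1, 21, 0, cfg))
  # 12 evenly spread scores, max 17: all three clauses evaluated by hand
  sc <- c(seq(12.4, 16.9, length.out = 11), 17)
  C <- cumulative_counts(sc)
  f <- fit_cumulative(C)
  n_in <- sum(sc >= 12 & sc <= 20)
  expect_equal(n_in, 12L)
  expect_true(max(sc) > 16)
  want <- f$r2 > 0.85 && max(sc) > 16 && n_in >= 10
  expect_equal(unname(classify_prototypical(f$r2, max(sc), n_in, cfg)), want)
  # boundary behaviour: r2 and high-score clauses are strict
  expect_false(classify_prototypical(0.85, 17, 12, cfg))
  expect_false(classify_prototypical(0.9, 16, 12, cfg))
  expect_true(classify_prototypical(0.9, 16.01, 10, cfg))
})

test_that("classification is invariant to score order and keeps duplicates", {
  set.seed(22)
  sc <- c(rnorm(30, 16, 2), 16.5, 16.5)
  prof1 <- cog_score_profiles(data.frame(score = sc, cog_id = "COGX"))
  prof2 <- cog_score_profiles(data.frame(score = rev(sc), cog_id = "COGX"))
  expect_equal(prof1, prof2)
  expect_equal(prof1$n_sites, length(sc))
})

test_that("category proportions sum to 1 and enrich with threshold", {
  lk <- data.frame(score = 15, cog_category = "L")
  out <- category_distribution(lk, thresholds = c(8, 10, 12))
  expect_equal(out$proportion, rep(1, 3))
  # planted high-scoring L/T/K over low-scoring background
  set.seed(23)
  lk2 <- data.frame(
    score = c(runif(60, 9, 13), runif(40, 14, 20)),
    cog_category = c(sample(c("C", "E", "G", "J"), 60, TRUE),
                     sample(c("L", "T", "K"), 40, TRUE)),
    stringsAsFactors = FALSE)
  out2 <- category_distribution(lk2, thresholds = c(8, 10, 12, 14))
  share <- vapply(c(8, 10, 12, 14), function(t) {
    sub <- out2[out2$threshold == t & out2$cog_category %in% c("L", "T", "K"), ]
    sum(sub$proportion)
  }, 0)
  expect_true(all(diff(share) >= 0))
  for (t in c(8, 10, 12, 14))
    expect_equal(sum(out2$proportion[out2$threshold == t]), 1)
  # reference ensemble join
  ref <- data.frame(cog_category = c("L", "T"), proportion = c(0.5, 0.2))
  out3 <- category_distribution(lk2, 14, reference = ref)
  expect_equal(out3$ref_proportion[out3$cog_category == "L"], 0.5)
  expect_equal(out3$ref_proportion[out3$cog_category == "K"], 0)
  # empty links -> empty table
  expect_equal(nrow(category_distribution(lk2[0, ], c(8, 10))), 0L)
})

test_that("normalised COG counts divide by the reference COG", {
  lk <- data.frame(cog_id = c(rep("COG1974", 10), rep("COG0389", 5),
                              rep("COG0556", 20)))
  out <- normalized_cog_counts(lk)
  expect_equal(out$ratio[out$cog_id == "COG1974"], 1.0)
  expect_equal(out$ratio[out$cog_id == "COG0389"], 0.5)
  expect_equal(out$ratio[out$cog_id == "COG0556"], 2.0)
  expect_error(normalized_cog_counts(lk, "COG9999"), "COG9999")
})

test_that("normal site scores give a near-linear central cumulative range", {
  set.seed(24)
  scores <- rnorm(500, 16, 3)
  fit <- fit_cumulative(cumulative_counts(scores))
  expect_gt(fit$r2, 0.95)
})
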