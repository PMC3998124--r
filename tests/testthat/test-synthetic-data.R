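test_that("sites sampled from degenerate models are fully determined", {
  cons <- build_scoring_model(IDENT_SITES, pseudocount = 0)
  set.seed(30)
  draws <- sample_sites(cons, 20)
  expect_true(all(draws == IDENT_SITES[1]))
  expect_equal(score_sequence(cons, draws[1]), 16)

  unif <- build_scoring_model(UNIFORM_SITES, pseudocount = 0)
  expect_equal(score_sequence(unif, sample_sites(unif, 1)), 0)
})

test_that("the default motif has the designed information content", {
  m <- scoring_model_from_frequencies(lexa_motif_frequencies())
  expect_equal(m$width, 16L)
  expect_equal(rsequence(m), 16.2153, tolerance = 1e-4)
  expect_equal(m$mu, rsequence(m))
  expect_equal(m$sigma, 2.3116, tolerance = 1e-3)
  # near-palindromic: revcomp of a high-probability site still scores high
  site <- "AAGAACATATGTTCTT"
  expect_gt(score_sequence(m, oracle_revcomp(site)), 14)
})

test_that("sampled-site mean score converges to Rsequence", {
  m <- scoring_model_from_frequencies(lexa_motif_frequencies())
  set.seed(31)
  sc <- vapply(sample_sites(m, 10000), function(s) score_sequence(m, s), 0,
               USE.NAMES = FALSE)
  se <- sd(sc) / sqrt(length(sc))
  expect_lt(abs(mean(sc) - rsequence(m)), 3 * se)
})

test_that("generation is deterministic for a fixed seed", {
  cfg <- sim_config(seed = 77, n_contigs = 3, contig_len = 20000,
                    sites_per_cog = 2)
  a <- generate_metagenome(cfg)
  b <- generate_metagenome(cfg)
  expect_identical(a$contigs, b$contigs)
  expect_identical(a$genes, b$genes)
  expect_identical(a$annotations, b$annotations)
  expect_identical(a$truth$planted, b$truth$planted)
  expect_identical(a$collection, b$collection)
  d <- generate_metagenome(sim_config(seed = 78, n_contigs = 3,
                                      contig_len = 20000, sites_per_cog = 2))
  expect_false(identical(a$contigs, d$contigs))
})

test_that("the truth manifest is consistent with the generated sequence", {
  sim <- recovery_fixture()$sim
  pl <- sim$truth$planted
  expect_equal(nrow(pl), length(sim$truth$regulon_cogs) *
                 sim$config$sites_per_cog)
  for (i in seq_len(nrow(pl))) {
    frag <- substr(sim$contigs[[pl$contig_id[i]]], pl$start[i] + 1, pl$end[i])
    if (pl$strand[i] == "-") frag <- oracle_revcomp(frag)
    expect_equal(frag, pl$site_seq[i])
    expect_equal(score_sequence(sim$model, frag), pl$score[i])
  }
  # planted sites sit inside their gene's promoter window
  g <- sim$genes[match(pl$gene_id, sim$genes$gene_id), ]
  win <- promoter_window(g$start, g$end, g$strand, 300, 50,
                         sim$config$contig_len)
  expect_true(all(pl$start >= win[, 1] & pl$end <= win[, 2]))
  # designated genes carry regulon COGs on Gram-positive contigs
  expect_true(all(g$cog_id %in% sim$truth$regulon_cogs))
  expect_true(all(g$phylum %in% c("Firmicutes", "Actinobacteria")))
})

test_that("gene layout is non-overlapping with operon-structured gaps", {
  sim <- recovery_fixture()$sim
  for (cid in unique(sim$genes$contig_id)[1:5]) {
    g <- sim$genes[sim$genes$contig_id == cid, ]
    g <- g[order(g$start), ]
    gaps <- g$start[-1] - g$end[-nrow(g)]
    expect_true(all(gaps >= sim$config$gap_within[1]))
    expect_true(all(g$end <= sim$config$contig_len))
    # gaps are either within-operon (< 100) or between-operon (>= 150)
    expect_true(all(gaps < 100 | gaps >= sim$config$gap_between[1]))
  }
})

test_that("a site-free genome yields chance hits at the analytic rate", {
  cfg <- sim_config(seed = 55, n_contigs = 10, contig_len = 50000,
                    sites_per_cog = 0)
  sim <- generate_metagenome(cfg)
  expect_equal(nrow(sim$truth$planted), 0L)
  model <- sim$model
  hits <- scan_metagenome(model, sim$contigs, threshold = 12)
  # per-window probability that the better strand beats 12 bits, by MC
  set.seed(56)
  L <- model$width
  nmc <- 400000L
  Wrc <- model$riw[4:1, L:1]
  sf <- sr <- numeric(nmc)
  for (l in seq_len(L)) {
    idx <- sample.int(4L, nmc, replace = TRUE)
    sf <- sf + model$riw[cbind(idx, l)]
    sr <- sr + Wrc[cbind(idx, l)]
  }
  p <- mean(pmax(sf, sr) > 12)
  expected <- sum(nchar(sim$contigs) - L + 1) * p
  # Poisson dispersion plus MC error on p: accept a generous band
  expect_gt(expected, 1)
  expect_gt(nrow(hits), expected / 4)
  expect_lt(nrow(hits), expected * 4 + 10)
})

test_that("infeasible layouts are rejected with an error", {
  expect_error(sim_config(contig_len = 1500), "infeasible")
  cfg <- sim_config(seed = 9, n_contigs = 2, contig_len = 20000,
                    sites_per_cog = 500)
  expect_error(generate_metagenome(cfg), "operon-lead")
})

test_that("written outputs round-trip and match the in-memory objects", {
  cfg <- sim_config(seed = 12, n_contigs = 2, contig_len = 20000,
                    sites_per_cog = 2)
  sim <- generate_metagenome(cfg)
  dir <- tempfile("simout")
  write_metagenome(sim, dir)
  contigs <- Biostrings::readDNAStringSet(file.path(dir, "contigs.fasta"))
  expect_equal(unname(as.character(contigs)), unname(sim$contigs))
  genes <- read_gene_table(file.path(dir, "genes.tsv"))
  expect_equal(genes$start, sim$genes$start)
  tr <- read_truth(file.path(dir, "truth.json"))
  expect_equal(tr$planted$start, sim$truth$planted$start)
  expect_equal(tr$planted$score, sim$truth$planted$score)
  expect_equal(tr$regulon_cogs, sim$truth$regulon_cogs)
  coll <- read_site_collection(file.path(dir, "collection.fasta"))
  expect_equal(unname(coll), sim$collection)
})
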