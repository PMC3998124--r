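# Shared fixtures. Frozen expected values for the 6-site fixture were
# computed once with the naive counting oracle (scratch script, same
# formulas as oracle_build_model) and are asserted against it in tests.

SIX_SITES <- c("GAACGTTC", "GATCGTTC", "GAACGTAC",
               "CAACGTTG", "GAACGATC", "GATCGAAC")
SIX_PC <- 0.25
SIX_FROZEN <- list(
  mu = 10.9120849464,
  sigma_pop = 1.3988677057,
  sigma_samp = 1.5323827948,
  threshold = 8.8137833878,
  rsequence = 7.8995322979,
  probes = c(GAACGTTC = 12.5197525622,
             CATCGATG = 6.5438982268,
             GTACGTTC = 7.8758963724))

# Four identical sites: consensus-only model, 2 bits/position.
IDENT_SITES <- rep("GAACGTTG", 4)   # deliberately non-palindromic

# Every position has exactly one of each base: uniform model, 0 bits.
UNIFORM_SITES <- c("AAAAAAAA", "CCCCCCCC", "GGGGGGGG", "TTTTTTTT")

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# The end-to-end recovery fixture (5 regulon COGs x 15 planted sites,
# ~2-Mb community) and its pipeline run, generated once per test session.
recovery_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- generate_metagenome(sim_config(seed = 2014L))
      run <- run_regulon_analysis(sim$collection, sim$contigs, sim$genes,
                                  sim$annotations, pseudocount = 0.5,
                                  reference_cog = "COG1974")
      cache <<- list(sim = sim, run = run)
    }
    cache
  }
})
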