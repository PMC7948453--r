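# The reference washout simulation (default kinetics, seed 1) is shared by
# several tests; build it once per test run.
.fixture_env <- new.env(parent = emptyenv())

reference_washout <- function() {
  if (is.null(.fixture_env$washout)) {
    cfg <- sim_config(seed = 1)
    genome <- build_genome(cfg)
    .fixture_env$washout <- list(
      cfg = cfg, genome = genome,
      sim = simulate_fp_washout(genome, cfg, conditions = "wt"))
  }
  .fixture_env$washout
}

reference_fronts <- function() {
  if (is.null(.fixture_env$fronts)) {
    fx <- reference_washout()
    g5 <- filter_genes_by_length(fx$genome$genes, 15000)
    g10 <- filter_genes_by_length(fx$genome$genes, 30000)
    p5 <- build_metagene(fx$sim$tracks$wt_5, g5, "tss", c(-2000, 18000))
    p10 <- build_metagene(fx$sim$tracks$wt_10, g10, "tss", c(-2000, 34000))
    f5 <- detect_wavefront(p5, estimate_background(p5))
    f10 <- detect_wavefront(p10, estimate_background(p10))
    .fixture_env$fronts <- list(f5 = f5, f10 = f10,
                                rate = estimate_rate(f5, 5, f10, 10))
  }
  .fixture_env$fronts
}
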