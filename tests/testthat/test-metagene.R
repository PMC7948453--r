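test_that("length filter keeps genes strictly longer than the cutoff", {
  genes <- dplyr::bind_rows(
    toy_gene(id = "a", start = 0, end = 10000),
    toy_gene(id = "b", start = 20000, end = 36000),
    toy_gene(id = "c", start = 40000, end = 71000))
  expect_equal(filter_genes_by_length(genes, 15000)$gene_id, c("b", "c"))
  expect_equal(filter_genes_by_length(genes, 30000)$gene_id, "c")
  expect_equal(nrow(filter_genes_by_length(genes, 0)), 3)
  expect_warning(filter_genes_by_length(genes, 1e9), "no genes")
})

test_that("metagene of a uniform gene is flat at the RPM-scaled density", {
  cov <- toy_coverage(20000, 50)
  cov <- set_bins(cov, "chrT", "+", rep(4, 400))
  gene <- toy_gene(strand = "+", start = 5000, end = 15000)
  prof <- build_metagene(cov, gene, "tss", c(-1000, 5000))
  expect_equal(length(prof$values), 120)
  expect_true(all(abs(prof$values - 4e6 / cov$total_reads) < 1e-9))
  expect_equal(prof$n_genes, 1)
})

test_that("profiles are strand-flip invariant", {
  set.seed(21)
  dens <- stats::rpois(120, 5)
  cov_p <- toy_coverage(20000, 50)
  # plus gene at TSS 5000: window [-1000, 5000) covers bins 80..199
  cov_p <- set_bins(cov_p, "chrT", "+",
                    c(rep(0, 80), dens, rep(0, 200)))
  g_p <- toy_gene(strand = "+", start = 5000, end = 15000)
  # minus gene mirrored at TSS 15000 on the minus strand
  cov_m <- toy_coverage(20000, 50)
  cov_m <- set_bins(cov_m, "chrT", "-",
                    c(rep(0, 200), rev(dens), rep(0, 80)))
  g_m <- toy_gene(strand = "-", start = 5000, end = 15000)
  p1 <- build_metagene(cov_p, g_p, "tss", c(-1000, 5000))
  p2 <- build_metagene(cov_m, g_m, "tss", c(-1000, 5000))
  expect_equal(p1$values, p2$values, tolerance = 1e-12)
})

test_that("multi-gene profiles are the unweighted per-gene mean", {
  cov <- toy_coverage(40000, 50)
  v <- numeric(800)
  v[101:200] <- 2   # gene A body
  v[501:600] <- 6   # gene B body, 3x denser
  cov <- set_bins(cov, "chrT", "+", v)
  genes <- dplyr::bind_rows(
    toy_gene(id = "A", start = 5000, end = 10000),
    toy_gene(id = "B", start = 25000, end = 30000))
  prof <- build_metagene(cov, genes, "tss", c(0, 5000))
  scale <- 1e6 / cov$total_reads
  expect_true(all(abs(prof$values - 4 * scale) < 1e-9))

  # genes running off the chromosome edge are dropped
  edge <- toy_gene(id = "E", start = 100, end = 5100)
  prof2 <- build_metagene(cov, dplyr::bind_rows(genes, edge), "tss",
                          c(-1000, 5000))
  expect_equal(prof2$n_genes, 2)
})

test_that("replicate averaging is bin-wise with matched geometry", {
  cov <- toy_coverage(20000, 50)
  cov <- set_bins(cov, "chrT", "+", rep(2, 400))
  gene <- toy_gene(start = 5000, end = 15000)
  p <- build_metagene(cov, gene, "tss", c(0, 4000))
  p3 <- p; p3$values <- 3 * p$values
  avg <- average_replicates(list(p, p3))
  expect_equal(avg$values, 2 * p$values)
  expect_equal(average_replicates(list(p))$values, p$values)
  bad <- build_metagene(cov, gene, "tss", c(0, 2000))
  expect_error(average_replicates(list(p, bad)), "geometry")
})

test_that("background is the distal-window median, robust to spikes", {
  prof <- structure(list(anchor = "tss", bin_size = 50,
                         window = c(0, 600),
                         positions = seq(25, 575, by = 50),
                         values = c(9, 9, 9, 9, 9, 9, 9, 9, 9, 1, 1, 9),
                         n_genes = 1),
                    class = "metagene_profile")
  # distal quarter = last 3 bins {1, 1, 9}: median 1 despite the spike
  expect_equal(estimate_background(prof), 1)
  flat <- prof; flat$values <- rep(3, 12)
  expect_equal(estimate_background(flat), 3)
  expect_error(estimate_background(prof, distal_frac = 0.01), "no bins")
})

test_that("wave front lands on an analytic step and interpolates a ramp", {
  bin <- 50
  n <- 400  # 20 kb window
  pos <- (seq_len(n) - 0.5) * bin
  step <- ifelse(pos < 11000, 100, 1)
  prof <- structure(list(anchor = "tss", bin_size = bin, window = c(0, n * bin),
                         positions = pos, values = step, n_genes = 10),
                    class = "metagene_profile")
  wf <- detect_wavefront(prof, background = 1, smooth_bins = 1)
  expect_lt(abs(wf$position - 11000), bin + 1e-9)

  # linear ramp from 100 to 0 over the window: threshold crossing has a
  # closed form and interpolation should recover it almost exactly
  ramp <- 100 * (1 - pos / 20000)
  prof$values <- ramp
  bg <- 0
  thr <- 0.05 * 100
  x_star <- 20000 * (1 - thr / 100)
  wf2 <- detect_wavefront(prof, bg, smooth_bins = 1)
  expect_lt(abs(wf2$position - x_star), bin / 2)

  # all-high profile never crosses: explicit failure
  prof$values <- rep(100, n)
  expect_error(detect_wavefront(prof, 1), "front beyond window")
})

test_that("rate arithmetic and failure modes", {
  r <- estimate_rate(11000, 5, 22000, 10)
  expect_equal(r$rate, 2.2)
  expect_equal(r$method, "two-timepoint")
  expect_equal(estimate_rate(10000, 5, 20000, 10)$rate, 2.0)
  single <- estimate_rate(40, 0, 11040, 5)
  expect_equal(single$method, "single-timepoint")
  expect_equal(single$rate, 2.2)
  expect_error(estimate_rate(12000, 5, 11000, 10), "non-increasing")
})

test_that("front and rate are invariant to global coverage rescaling", {
  cfg <- sim_config(n_genes = 80, chrom_lengths = c(chrA = 3e6),
                    n_enhancers = 0, n_se_clusters = 0, n_up_enhancers = 0,
                    frac_intragenic_enh = 0, label_minutes = c(5, 10),
                    seed = 13)
  g <- build_genome(cfg)
  w <- simulate_fp_washout(g, cfg, conditions = "wt")
  g5 <- filter_genes_by_length(g$genes, 15000)
  p1 <- build_metagene(w$tracks$wt_5, g5, "tss", c(-2000, 18000))
  f1 <- detect_wavefront(p1, estimate_background(p1))
  scaled <- coverage_scale(w$tracks$wt_5, 7.3)
  p2 <- build_metagene(scaled, g5, "tss", c(-2000, 18000))
  f2 <- detect_wavefront(p2, estimate_background(p2))
  expect_equal(f1$position, f2$position, tolerance = 1e-9)
})

test_that("the front advances with labelling time on one simulation", {
  cfg <- sim_config(n_genes = 150, chrom_lengths = c(chrA = 4e6),
                    n_enhancers = 0, n_se_clusters = 0, n_up_enhancers = 0,
                    frac_intragenic_enh = 0, seed = 17)
  g <- build_genome(cfg)
  w <- simulate_fp_washout(g, cfg, conditions = "wt")
  p5 <- build_metagene(w$tracks$wt_5,
                       filter_genes_by_length(g$genes, 15000),
                       "tss", c(-2000, 18000))
  p10 <- build_metagene(w$tracks$wt_10,
                        filter_genes_by_length(g$genes, 30000),
                        "tss", c(-2000, 34000))
  f5 <- detect_wavefront(p5, estimate_background(p5))
  f10 <- detect_wavefront(p10, estimate_background(p10))
  expect_gte(f10$position, f5$position)
})

test_that("bootstrap CI brackets the point estimate and rejects tiny n_boot", {
  cfg <- sim_config(n_genes = 150, chrom_lengths = c(chrA = 4e6),
                    n_enhancers = 0, n_se_clusters = 0, n_up_enhancers = 0,
                    frac_intragenic_enh = 0, seed = 19)
  g <- build_genome(cfg)
  w <- simulate_fp_washout(g, cfg, conditions = "wt")
  g5 <- filter_genes_by_length(g$genes, 15000)
  g10 <- filter_genes_by_length(g$genes, 30000)
  r <- bootstrap_rate(w$tracks$wt_5, w$tracks$wt_10, g5, g10, 5, 10,
                      n_boot = 100, seed = 19)
  expect_true(r$ci[1] <= r$rate && r$rate <= r$ci[2])
  # resampling genes quantifies sampling spread: a sane, narrow interval
  # around the point estimate (detector quantization bias is not covered)
  expect_lt(r$ci[2] - r$ci[1], 0.5)
  expect_lt(abs(r$rate - cfg$v) / cfg$v, 0.1)
  expect_error(bootstrap_rate(w$tracks$wt_5, w$tracks$wt_10, g5, g10,
                              5, 10, n_boot = 1), "at least 100")
})

test_that("tidiers return the documented shapes", {
  cov <- toy_coverage(20000, 50)
  cov <- set_bins(cov, "chrT", "+", rep(2, 400))
  p <- build_metagene(cov, toy_gene(start = 5000, end = 15000), "tss",
                      c(0, 4000))
  td <- tidy(p)
  expect_named(td, c("position", "density"))
  expect_equal(nrow(td), 80)
  expect_equal(glance(p)$n_genes, 1)
  r <- estimate_rate(11000, 5, 22000, 10)
  expect_equal(tidy(r)$rate, 2.2)
  expect_true(is.na(tidy(r)$ci_low))
})
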