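test_that("window counts equal the per-base brute force on random tracks", {
  set.seed(41)
  for (rep in 1:30) {
    cov <- random_coverage(10000, 50)
    s <- sample(0:9000, 1)
    e <- s + sample(100:900, 1)
    w <- tibble::tibble(chrom = "chrT", start = s, end = e,
                        strand = sample(c("+", "-"), 1))
    for (mode in c("both", "sense", "antisense")) {
      strands <- switch(mode, both = c("+", "-"), sense = w$strand,
                        antisense = setdiff(c("+", "-"), w$strand))
      expect_equal(count_windows(w, cov, mode)$raw,
                   oracle_count(cov, "chrT", strands, s, e, 10000),
                   tolerance = 1e-9)
    }
  }
})

test_that("uniform and empty tracks count as expected, clipping warns", {
  cov <- toy_coverage(10000, 50)
  cov <- set_bins(cov, "chrT", "+", rep(2, 200))
  w <- tibble::tibble(chrom = "chrT", start = 1000, end = 1500)
  expect_equal(count_windows(w, cov, "both")$raw, 20)
  empty <- toy_coverage(10000, 50)
  expect_equal(count_windows(w, empty, "both")$raw, 0)
  # clipped to [9500, 10000): 10 bins of 2 remain countable
  off <- tibble::tibble(chrom = "chrT", start = 9500, end = 12000)
  expect_warning(res <- count_windows(off, cov, "both"), "clipped")
  expect_equal(res$raw, 20)
})

test_that("eRNA windows apply the +/- 1 kb rule and clip at chrom start", {
  asm <- genome_assembly("chrT", 10000)
  pk <- tibble::tibble(chrom = "chrT", start = 5000, end = 5200,
                       name = "p1")
  expect_equal(erna_windows(pk, asm)[, c("start", "end")],
               tibble::tibble(start = 4000, end = 6200))
  expect_equal(erna_windows(pk, asm, pad = 0)$start, 5000)
  edge <- tibble::tibble(chrom = "chrT", start = 100, end = 300,
                         name = "p2")
  expect_equal(erna_windows(edge, asm)$start, 0)
})

test_that("spike normalisation inverts a known efficiency", {
  # spikes observed at half the WT efficiency in null: null counts double
  spikes <- tibble::tibble(
    species = rep(c("a", "b", "c"), 2),
    abundance = rep(c(100, 200, 400), 2),
    condition = rep(c("wt", "null"), each = 3),
    count = c(100, 200, 400, 50, 100, 200))
  counts <- tibble::tibble(id = c("x", "x"), condition = c("wt", "null"),
                           raw = c(10, 10))
  norm <- normalize_counts(counts, spikes = spikes, mode = "spike")
  expect_equal(norm$normalized[norm$condition == "null"] /
                 norm$normalized[norm$condition == "wt"], 2)

  # equal efficiencies give equal factors
  eq <- spikes; eq$count <- rep(c(100, 200, 400), 2)
  neq <- normalize_counts(counts, spikes = eq, mode = "spike")
  expect_equal(length(unique(neq$factor)), 1)

  zero <- spikes; zero$count <- 0
  expect_error(normalize_counts(counts, spikes = zero, mode = "spike"),
               "zero")
  expect_error(normalize_counts(counts, mode = "library"), "totals")
  lib <- normalize_counts(counts, library_totals = c(wt = 2e6, null = 1e6),
                          mode = "library")
  expect_equal(lib$normalized, c(5, 10))
})

test_that("a simulated 0.7 efficiency is recovered within 5%", {
  set.seed(5)
  abundance <- c(500, 1000, 2000, 4000, 8000, 16000, 32000, 64000)
  eff <- 0.7
  spikes <- tibble::tibble(
    species = rep(paste0("s", 1:8), 2),
    abundance = rep(abundance, 2),
    condition = rep(c("wt", "null"), each = 8),
    count = c(stats::rpois(8, abundance), stats::rpois(8, abundance * eff)))
  counts <- tibble::tibble(id = "x", condition = c("wt", "null"),
                           raw = c(1, 1))
  norm <- normalize_counts(counts, spikes = spikes, mode = "spike")
  ratio <- norm$factor[norm$condition == "null"] /
    norm$factor[norm$condition == "wt"]
  expect_lt(abs(ratio - 1 / eff) / (1 / eff), 0.05)
})

test_that("expression filter applies the RPKM cutoff", {
  cov <- toy_coverage(100000, 50)
  v <- numeric(2000)
  v[201:400] <- 5    # gene hi: 10 kb at 5/bin = 1000 reads
  v[1001:1200] <- 0.05  # gene lo: 10 reads over 10 kb
  cov <- set_bins(cov, "chrT", "+", v)
  # pin the library size so RPKM values are on a realistic scale:
  # hi = 1000/(10 kb x 2 M) = 50, lo = 10/(10 kb x 2 M) = 0.5 exactly
  cov$total_reads <- 2e6
  genes <- dplyr::bind_rows(
    toy_gene(id = "hi", start = 10000, end = 20000),
    toy_gene(id = "lo", start = 50000, end = 60000))
  kept <- classify_expressed(genes, cov, 0.5)
  # the cutoff is strict: RPKM exactly 0.5 is excluded
  expect_equal(kept$gene_id, "hi")
  all_sig <- classify_expressed(genes, cov, 0)
  expect_equal(all_sig$gene_id, c("hi", "lo"))
})

test_that("fold-change classifier follows the 1.5 rule with pseudocount", {
  d <- tibble::tibble(id = c("a", "b", "c"),
                      count_wt = c(10, 7, 0),
                      count_null = c(20, 7, 0))
  fc <- fold_change(d)
  expect_equal(fc$fc[1], 21 / 11, tolerance = 1e-12)
  expect_equal(fc$class, c("up", "unchanged", "unchanged"))
  down <- fold_change(tibble::tibble(id = "d", count_wt = 20,
                                     count_null = 10))
  expect_equal(down$class, "down")
  # long input from normalize_counts pivots automatically
  long <- tibble::tibble(id = c("a", "a"), condition = c("wt", "null"),
                         raw = c(10, 20), factor = 1, normalized = c(10, 20))
  expect_equal(fold_change(long)$class, "up")
})

test_that("processivity ratio: flat gene gives 1, termination gives exp decay", {
  cov <- toy_coverage(60000, 50)
  cov <- set_bins(cov, "chrT", "+", rep(3, 1200))
  gene <- toy_gene(start = 5000, end = 45000)
  pr <- processivity_ratio(gene, cov)
  expect_equal(pr$ratio, 1)

  # density exp(-pi*x_kb) along a 40 kb body: ratio has a closed form
  pi_kb <- 0.03
  x_kb <- ((1:800) - 0.5) * 50 / 1000
  v <- numeric(1200)
  v[101:900] <- 100 * exp(-pi_kb * x_kb)
  cov2 <- set_bins(toy_coverage(60000, 50), "chrT", "+", v)
  pr2 <- processivity_ratio(gene, cov2)
  # window separation: proximal centre 3 kb, distal centre L-3 kb
  expect_lt(abs(pr2$ratio - exp(-pi_kb * (40 - 6))) / pr2$ratio, 0.01)

  short <- toy_gene(id = "s", start = 0, end = 8000)
  expect_warning(out <- processivity_ratio(short, cov), "too short")
  expect_equal(nrow(out), 0)
})

test_that("simulated termination rate is recovered by the processivity ratio", {
  cfg <- sim_config(n_genes = 60, chrom_lengths = c(chrA = 4e6),
                    gene_length_meanlog = log(50000),
                    gene_length_sdlog = 0.1, gene_length_min = 40000,
                    gene_length_max = 60000, pi_term = 0.02, bg = 0,
                    frac_silent = 0, alpha_sdlog = 0, depth = 100,
                    n_enhancers = 0, n_se_clusters = 0, n_up_enhancers = 0,
                    frac_intragenic_enh = 0, seed = 23)
  g <- build_genome(cfg)
  ss <- simulate_steady_state(g, cfg, "wt")
  pr <- processivity_ratio(g$genes, ss$cov)
  joined <- dplyr::left_join(pr, g$genes[, c("gene_id", "length")],
                             by = "gene_id")
  pred <- exp(-cfg$pi_term * (joined$length / 1000 - 6))
  expect_lt(stats::median(abs(joined$ratio / pred - 1)), 0.1)
})

test_that("readthrough density reflects the termination decay settings", {
  cov <- toy_coverage(60000, 50)
  v <- numeric(1200)
  v[101:800] <- 10
  v[801:1000] <- 4   # uniform readthrough block past TES at 40 kb
  cov <- set_bins(cov, "chrT", "+", v)
  gene <- toy_gene(start = 5000, end = 40000)
  rt <- tes_readthrough(gene, cov, 10000)
  expect_equal(rt$readthrough_density, 4 / 50)
})

test_that("distance strata follow the documented boundary rule", {
  enh <- tibble::tibble(chrom = "chrT", start = 100000, end = 100300,
                        name = "e1")
  mk <- function(tss, id) toy_gene(id = id, start = tss, end = tss + 5000)
  genes <- dplyr::bind_rows(
    mk(115000, "near"),    # 14.7 kb from enhancer edge
    mk(120300, "exact20"), # exactly 20 kb
    mk(145300, "mid45"),   # exactly 45 kb
    mk(170000, "far"))     # past 60 kb: excluded
  out <- stratify_by_distance(genes, enh)
  expect_equal(out$gene_id, c("near", "exact20", "mid45"))
  expect_equal(as.character(out$stratum),
               c("0-20 kb", "20-40 kb", "40-60 kb"))
  none <- stratify_by_distance(
    dplyr::mutate(genes, chrom = "chrX"), enh)
  expect_equal(nrow(none), 0)
})

test_that("rank-sum test matches exact enumeration and behaves monotonically", {
  res <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p_value, 0.1, tolerance = 1e-12)
  expect_equal(res$method, "exact")

  same <- rank_sum_test(c(1, 2, 3, 4), c(1.001, 2.001, 3.001, 4.001))
  expect_gte(same$p_value, 0.68)

  set.seed(31)
  a <- stats::rnorm(30)
  p_small <- rank_sum_test(a, stats::rnorm(30, 0.5))$p_value
  p_large <- rank_sum_test(a, stats::rnorm(30, 3))$p_value
  expect_lt(p_large, p_small)
  expect_error(rank_sum_test(c(1, 2), c(3, 4, 5)), "at least 3")
})
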