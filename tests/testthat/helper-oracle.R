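# Independent per-base brute-force oracles. These deliberately share no
# code with the package internals: coverage is expanded to one value per
# base and every quantity is a plain sum over bases.

# per-base density vector of one chrom/strand (length = chrom length)
oracle_per_base <- function(cov, chrom, strand, chrom_len) {
  v <- cov$values[[strand]][[chrom]]
  rep(v / cov$bin_size, each = cov$bin_size)[seq_len(chrom_len)]
}

# brute-force window count: sum of per-base density over [s, e)
oracle_count <- function(cov, chrom, strands, s, e, chrom_len) {
  sum(vapply(strands, function(st) {
    pb <- oracle_per_base(cov, chrom, st, chrom_len)
    sum(pb[(s + 1):e])
  }, 0))
}

# brute-force pro-rata binning of bedGraph intervals (value = per-bin
# units): per-base mass is value / bin_size, then summed within bins
oracle_bin <- function(start, end, value, bin_size, n_bins) {
  base <- numeric(n_bins * bin_size)
  for (j in seq_along(start)) {
    idx <- (start[j] + 1):end[j]
    base[idx] <- base[idx] + value[j] / bin_size
  }
  vapply(seq_len(n_bins), function(b) {
    sum(base[((b - 1) * bin_size + 1):(b * bin_size)])
  }, 0)
}

# brute-force interval overlap via per-base occupancy (coordinates are
# clamped to [0, len])
oracle_overlaps <- function(qs, qe, ss, se, len) {
  occupied <- logical(len)
  ss <- pmax(ss, 0); se <- pmin(se, len)
  for (j in seq_along(ss)) {
    if (se[j] > ss[j]) occupied[(ss[j] + 1):se[j]] <- TRUE
  }
  qs <- pmax(qs, 0); qe <- pmin(qe, len)
  vapply(seq_along(qs), function(i) any(occupied[(qs[i] + 1):qe[i]]), TRUE)
}

# tiny assembly + manually filled coverage for unit tests
toy_coverage <- function(chrom_len = 10000, bin_size = 50,
                         chrom = "chrT") {
  stranded_coverage(genome_assembly(chrom, chrom_len), bin_size)
}

set_bins <- function(cov, chrom, strand, values) {
  stopifnot(length(values) == length(cov$values[[strand]][[chrom]]))
  cov$values[[strand]][[chrom]] <- values
  cov$total_reads <- coverage_total(cov)
  cov
}

random_coverage <- function(chrom_len = 10000, bin_size = 50) {
  cov <- toy_coverage(chrom_len, bin_size)
  for (s in c("+", "-")) {
    cov <- set_bins(cov, "chrT", s,
                    stats::rpois(chrom_len / bin_size, 2) *
                      stats::runif(chrom_len / bin_size, 0.5, 1.5))
  }
  cov
}

# minimal single-gene tibble in the package's gene-model schema
toy_gene <- function(chrom = "chrT", strand = "+", start = 2000,
                     end = 8000, id = "g1") {
  tss <- if (strand == "+") start else end
  tes <- if (strand == "+") end else start
  tibble::tibble(gene_id = id, chrom = chrom, strand = strand,
                 start = start, end = end, tss = tss, tes = tes,
                 length = end - start)
}
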