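#' Simulation configuration
#'
#' Bundles every tunable of the stochastic Pol II kinetics simulator. The
#' defaults emulate a CDK9-inhibitor (flavopiridol) washout experiment in
#' mouse embryonic stem cells: productive elongation is blocked for 60 min
#' so polymerases accumulate at the promoter-proximal pause site (20-60 bp
#' downstream of the TSS), then released; nascent RNA is metabolically
#' labelled for 5 or 10 min and sequenced, so the labelled-read density
#' forms a wave whose front advances at the elongation rate.
#'
#' @param n_genes Number of genes to place (default 500).
#' @param chrom_lengths Named vector of chromosome lengths in bp
#'   (default two 6 Mb chromosomes: desk-scale, minutes not hours, with
#'   enough intergenic room for enhancer deserts).
#' @param gene_length_meanlog,gene_length_sdlog Log-normal gene-length law
#'   (bp); default median 10 kb, sdlog 0.8, truncated to
#'   `[gene_length_min, gene_length_max]`.
#' @param gene_length_min,gene_length_max Truncation bounds in bp.
#' @param flank Minimum gap between gene spans in bp (default 3000).
#' @param v Elongation rate in kb/min (default 2.2).
#' @param beta Pause-release rate in min^-1; default `log(2)/0.5`
#'   (half-time 30 s), so the pioneer front sits close to `v * T`.
#' @param alpha Initiation rate in events/min/gene (default 0.5); per-gene
#'   rates are log-normally dispersed around it and a fraction of genes is
#'   silent.
#' @param alpha_sdlog Dispersion (sdlog) of per-gene initiation rates.
#' @param frac_silent Fraction of genes with no initiation (default 0.1),
#'   giving the expression filter something to remove.
#' @param pause_min,pause_max Uniform pause-offset law in bp downstream of
#'   the TSS (default 20-60).
#' @param pause_capacity Polymerases the pause site can hold at washout
#'   (default 1: steric occlusion).
#' @param block_minutes Duration of release inhibition (default 60).
#' @param label_minutes Labelling windows in minutes for washout mode
#'   (default `c(5, 10)`).
#' @param ss_label_minutes Labelling window for steady-state mode (default 10).
#' @param pi_term Premature-termination probability per kb of gene body
#'   (default 0.02); body density decays as `exp(-pi_term * x_kb)`.
#' @param term_distance Decay length in bp of post-TES readthrough signal
#'   (default 3000); readthrough is simulated out to 15 kb or the value's
#'   practical extinction.
#' @param depth Expected reads per kb of labelled RNA (default 50).
#' @param bg Uniform background in reads per kb per strand genome-wide
#'   (default 0.05; nascent-RNA enrichment leaves little intergenic
#'   signal, and at desk-scale library depth the background RPKM must sit
#'   clearly below the 0.5 expression cutoff).
#' @param n_enhancers Number of enhancers (default 150).
#' @param enhancer_width Enhancer interval width in bp (default 300).
#' @param frac_intragenic_enh Fraction of enhancers placed inside gene
#'   spans (default 0.25); the rest are intergenic, at least 500 bp from
#'   any gene span.
#' @param n_se_clusters Number of enhancer clusters seeded as
#'   superenhancers (default 12), each of `se_cluster_size` enhancers
#'   within `se_cluster_span` bp.
#' @param se_cluster_size Enhancers per seeded cluster (default 3).
#' @param se_cluster_span Maximum span of a cluster in bp (default 12500);
#'   also the gap rule used when calling superenhancers from intervals.
#' @param erna_meanlog,erna_sdlog Log-normal eRNA transcript-length law in
#'   bp (default median 1 kb).
#' @param erna_depth Expected reads per enhancer per strand per labelling,
#'   at multiplier 1 (default 60, deep enough that the fold-change
#'   classifier is a calibrated detector). eRNAs are bidirectional: both strands
#'   fire.
#' @param n_up_enhancers Number of intergenic enhancers whose
#'   null-condition output is multiplied by `up_multiplier` (default 50,
#'   emulating the subset of enhancers that gain activity when the
#'   elongation factor is deleted; intergenic because that is where eRNA
#'   is quantified free of host-gene signal).
#' @param up_multiplier Null-condition eRNA multiplier for that subset
#'   (default 2).
#' @param enh_gene_coupling Strength of the enhancer-to-gene rate coupling
#'   (default 0.5): genes with a TSS within `coupling_max_kb` of an
#'   enhancer get initiation boosted by
#'   `1 + coupling * exp(-d_kb / coupling_decay_kb) * multiplier`.
#' @param coupling_decay_kb Distance decay constant of the coupling (kb).
#' @param coupling_max_kb Maximum TSS-enhancer distance for coupling (kb).
#' @param null_release_factor Multiplier on `beta` in the null condition
#'   (default 0.9: a 10% slower effective pause release, leaving the
#'   elongation rate itself untouched, so the rate estimator should find
#'   no rate difference).
#' @param null_v_factor Multiplier on `v` in the null condition (default 1).
#' @param spike_abundance Named numeric vector of spike-in species
#'   abundances (known input amounts, arbitrary units).
#' @param spike_efficiency Named per-condition capture efficiencies; the
#'   efficiency scales the whole library including the spikes, which is the
#'   confound spike-in normalisation exists to remove (default wt 1,
#'   null 0.7).
#' @param bin_size Coverage bin width in bp (default 50).
#' @param seed Integer seed; all stage seeds are derived from it by fixed
#'   offsets.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 500,
                       chrom_lengths = c(chrS1 = 6e6, chrS2 = 6e6),
                       gene_length_meanlog = log(10000),
                       gene_length_sdlog = 0.8,
                       gene_length_min = 2000,
                       gene_length_max = 120000,
                       flank = 3000,
                       v = 2.2,
                       beta = log(2) / 0.5,
                       alpha = 0.5,
                       alpha_sdlog = 0.5,
                       frac_silent = 0.1,
                       pause_min = 20, pause_max = 60,
                       pause_capacity = 1,
                       block_minutes = 60,
                       label_minutes = c(5, 10),
                       ss_label_minutes = 10,
                       pi_term = 0.02,
                       term_distance = 3000,
                       depth = 50,
                       bg = 0.05,
                       n_enhancers = 150,
                       enhancer_width = 300,
                       frac_intragenic_enh = 0.25,
                       n_se_clusters = 12,
                       se_cluster_size = 3,
                       se_cluster_span = 12500,
                       erna_meanlog = log(1000),
                       erna_sdlog = 0.4,
                       erna_depth = 60,
                       n_up_enhancers = 50,
                       up_multiplier = 2,
                       enh_gene_coupling = 0.5,
                       coupling_decay_kb = 10,
                       coupling_max_kb = 20,
                       null_release_factor = 0.9,
                       null_v_factor = 1,
                       spike_abundance = c(spk01 = 500, spk02 = 1000,
                                           spk03 = 2000, spk04 = 4000,
                                           spk05 = 8000, spk06 = 16000,
                                           spk07 = 32000, spk08 = 64000),
                       spike_efficiency = c(wt = 1, null = 0.7),
                       bin_size = 50,
                       seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

## Derive a child seed from the master seed; keeps every stage independently
## reproducible and all seeds inside 32-bit integer range.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset) %% 2147483647)
}

#' Build a synthetic genome, gene and enhancer annotation
#'
#' Places non-overlapping genes with minimum flanks and Bernoulli(0.5)
#' strands, draws per-gene kinetic parameters, and places enhancers:
#' intergenic ones at least 500 bp from any gene span (a subset seeded as
#' clusters that satisfy the superenhancer rule), intragenic ones inside
#' gene spans. Also derives a peak set emulating a chromatin-profiling
#' experiment for an elongation factor that binds promoters, gene ends and
#' active enhancers. Deterministic under a fixed seed.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed override (defaults to `config$seed`).
#' @return A list with elements `assembly`, `genes` (gene models plus
#'   per-gene `alpha` and `pause_offset`), `enhancers` (peak tibble with
#'   `class`, `superenhancer`, `mult_wt`, `mult_null`), `peaks`, and
#'   `truth` (ground-truth ledger: `genes`, `enhancers`, `spikes`).
#' @export
build_genome <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(seed, 1))
  assembly <- genome_assembly(names(config$chrom_lengths),
                              config$chrom_lengths)

  genes <- place_genes(config, assembly)
  enh <- place_enhancers(config, assembly, genes)

  ## Peak set: promoters of active genes (strong), gene ends (weaker),
  ## enhancers, plus uniform intergenic noise peaks.
  peaks <- synth_peaks(config, assembly, genes, enh)

  truth <- list(
    genes = dplyr::select(genes, "gene_id", "chrom", "strand", "tss", "tes",
                          "length", "alpha", "pause_offset") |>
      dplyr::mutate(v = config$v, beta_wt = config$beta,
                    beta_null = config$beta * config$null_release_factor,
                    v_null = config$v * config$null_v_factor),
    enhancers = dplyr::select(enh, "name", "chrom", "start", "end", "class",
                              "superenhancer", "mult_wt", "mult_null"),
    spikes = tibble::tibble(
      species = names(config$spike_abundance),
      abundance = unname(config$spike_abundance)) |>
      tidyr::crossing(tibble::tibble(
        condition = names(config$spike_efficiency),
        efficiency = unname(config$spike_efficiency))) |>
      dplyr::mutate(scale_truth = 1 / .data$efficiency)
  )
  list(assembly = assembly, genes = genes, enhancers = enh, peaks = peaks,
       truth = truth)
}

place_genes <- function(config, assembly) {
  for (attempt in 1:20) {
    len <- stats::rlnorm(config$n_genes, config$gene_length_meanlog,
                         config$gene_length_sdlog)
    len <- round(pmin(pmax(len, config$gene_length_min),
                      config$gene_length_max))
    total <- sum(len) + (config$n_genes + 1) * config$flank
    if (total <= 0.95 * sum(assembly$length)) break
    if (attempt == 20) stop("gene packing failed: total gene length + ",
                            "flanks exceeds genome size")
  }
  ## Assign genes to chromosomes proportionally to length, then lay each
  ## chromosome's genes left to right with random extra gaps.
  ord <- sample.int(config$n_genes)
  len <- len[ord]
  chrom_of <- rep(NA_character_, config$n_genes)
  starts <- numeric(config$n_genes)
  i <- 1
  for (ci in seq_len(nrow(assembly))) {
    clen <- assembly$length[ci]
    pos <- config$flank
    while (i <= config$n_genes && pos + len[i] + config$flank <= clen) {
      chrom_of[i] <- assembly$chrom[ci]
      starts[i] <- pos
      gap <- config$flank + round(stats::rexp(1, 1 / (config$flank / 2)))
      ## occasional gene deserts: the intergenic space real enhancer
      ## clusters live in
      if (stats::runif(1) < 0.15) gap <- gap + round(stats::rexp(1, 1 / 25000))
      pos <- pos + len[i] + gap
      i <- i + 1
    }
  }
  if (any(is.na(chrom_of))) stop("gene packing failed: ran out of genome")
  alpha <- config$alpha *
    stats::rlnorm(config$n_genes, -config$alpha_sdlog^2 / 2,
                  config$alpha_sdlog)
  alpha[stats::runif(config$n_genes) < config$frac_silent] <- 0
  g <- tibble::tibble(
    gene_id = sprintf("g%04d", seq_len(config$n_genes)),
    chrom = chrom_of,
    strand = ifelse(stats::runif(config$n_genes) < 0.5, "+", "-"),
    start = starts,
    end = starts + len,
    alpha = alpha,
    pause_offset = round(stats::runif(config$n_genes, config$pause_min,
                                      config$pause_max))
  )
  finish_gene_models(g) |>
    dplyr::relocate("tss", "tes", "length", .after = "end")
}

empty_enhancers <- function() {
  tibble::tibble(chrom = character(), start = numeric(), end = numeric(),
                 name = character(), class = character(),
                 seeded_se = logical(), score = numeric(),
                 superenhancer = logical(), mult_wt = numeric(),
                 mult_null = numeric(), erna_len_plus = numeric(),
                 erna_len_minus = numeric())
}

place_enhancers <- function(config, assembly, genes) {
  if (config$n_enhancers == 0) return(empty_enhancers())
  w <- config$enhancer_width
  n_clustered <- config$n_se_clusters * config$se_cluster_size
  n_intra <- round(config$n_enhancers * config$frac_intragenic_enh)
  n_single <- config$n_enhancers - n_clustered - n_intra
  if (n_single < 0) stop("enhancer counts inconsistent: clusters + ",
                         "intragenic exceed n_enhancers")

  ## A position is intergenic-safe if its enhancer span keeps >= 500 bp
  ## clearance from every gene span and stays out of the termination
  ## readthrough zone downstream of each TES (where nascent signal from
  ## terminating polymerases, not eRNA, would dominate a +/-1 kb window).
  rt_clear <- 1000 + 3 * config$term_distance
  safe <- function(chrom, start, end, pad = 500) {
    g <- genes[genes$chrom == chrom, ]
    lo <- g$start - ifelse(g$strand == "+", pad, rt_clear)
    hi <- g$end + ifelse(g$strand == "+", rt_clear, pad)
    all(end <= lo | start >= hi)
  }
  draw_intergenic <- function(span_bp) {
    for (k in 1:5000) {
      ci <- sample.int(nrow(assembly), 1)
      s <- round(stats::runif(1, 1000, assembly$length[ci] - span_bp - 1000))
      if (safe(assembly$chrom[ci], s, s + span_bp)) {
        return(list(chrom = assembly$chrom[ci], start = s))
      }
    }
    stop("enhancer placement failed: no intergenic room")
  }

  rows <- list()
  ## seeded superenhancer clusters
  for (cl in seq_len(config$n_se_clusters)) {
    span <- config$se_cluster_span - w
    at <- draw_intergenic(config$se_cluster_span)
    offs <- sort(round(stats::runif(config$se_cluster_size, 0, span - w)))
    ## enforce pairwise gaps so members do not merge into one interval
    offs <- offs + (seq_along(offs) - 1) * 1  # keep order; widths separate
    for (j in seq_along(offs)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        chrom = at$chrom, start = at$start + offs[j],
        end = at$start + offs[j] + w, class = "intergenic", seeded_se = TRUE)
    }
  }
  ## singleton intergenic enhancers
  for (k in seq_len(n_single)) {
    at <- draw_intergenic(w)
    rows[[length(rows) + 1]] <- tibble::tibble(
      chrom = at$chrom, start = at$start, end = at$start + w,
      class = "intergenic", seeded_se = FALSE)
  }
  ## intragenic enhancers, inside gene spans away from the TSS
  host <- genes[genes$length > 4 * w + 2000, ]
  hosts <- host[sample.int(nrow(host), n_intra, replace = TRUE), ]
  for (k in seq_len(n_intra)) {
    s <- round(stats::runif(1, hosts$start[k] + 1000,
                            hosts$end[k] - 1000 - w))
    rows[[length(rows) + 1]] <- tibble::tibble(
      chrom = hosts$chrom[k], start = s, end = s + w,
      class = "intragenic", seeded_se = FALSE)
  }
  enh <- dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::mutate(name = sprintf("enh%04d", dplyr::row_number()),
                  score = stats::rlnorm(dplyr::n(), log(10), 0.6))

  ## superenhancer call from the intervals themselves (the generative
  ## seeding must be recoverable by the clustering rule)
  enh$superenhancer <- call_superenhancers(enh, config$se_cluster_span,
                                           config$se_cluster_size)

  ## null-condition multipliers: a fixed-size subset of intergenic
  ## enhancers doubles (eRNA is quantified at intergenic peaks, where the
  ## signal is not confounded by host-gene transcription). Regulation is
  ## cluster-coherent: a superenhancer gains or keeps activity as a unit,
  ## so closely spaced members never mix multipliers within one cluster.
  mult_null <- rep(1, nrow(enh))
  n_up <- min(config$n_up_enhancers, sum(enh$class == "intergenic"))
  if (n_up > 0) {
    units <- regulation_units(enh, config$se_cluster_span)
    units <- units[sample.int(length(units))]
    chosen <- integer(0)
    for (u in units) {
      if (length(chosen) + length(u) <= n_up) chosen <- c(chosen, u)
      if (length(chosen) == n_up) break
    }
    mult_null[chosen] <- config$up_multiplier
  }
  enh$mult_wt <- 1
  enh$mult_null <- mult_null
  ## the eRNA transcript unit is a fixed property of the enhancer: its
  ## per-strand length is drawn once here, not per simulated library
  enh$erna_len_plus <- stats::rlnorm(nrow(enh), config$erna_meanlog,
                                     config$erna_sdlog)
  enh$erna_len_minus <- stats::rlnorm(nrow(enh), config$erna_meanlog,
                                      config$erna_sdlog)
  dplyr::relocate(enh, "name", .after = "end")
}

## Intergenic enhancers grouped into co-regulated units: each chain
## cluster (same single-linkage rule as the superenhancer call) is one
## unit, singletons are their own unit.
regulation_units <- function(enh, span) {
  inter <- which(enh$class == "intergenic")
  if (length(inter) == 0) return(list())
  units <- list()
  for (cm in unique(enh$chrom[inter])) {
    i <- inter[enh$chrom[inter] == cm]
    i <- i[order(enh$start[i])]
    cluster_start <- enh$start[i[1]]
    members <- i[1]
    for (j in i[-1]) {
      if (enh$end[j] - cluster_start <= span) {
        members <- c(members, j)
      } else {
        units[[length(units) + 1]] <- members
        cluster_start <- enh$start[j]
        members <- j
      }
    }
    units[[length(units) + 1]] <- members
  }
  units
}

#' Call superenhancers from enhancer intervals
#'
#' Single-linkage chaining: enhancers on the same chromosome whose spans lie
#' within `span` bp of the chain are one cluster; clusters of at least
#' `min_size` members are superenhancers.
#'
#' @param enhancers Peak tibble (`chrom`, `start`, `end`).
#' @param span Maximum chain span in bp (default 12500).
#' @param min_size Minimum cluster size (default 3).
#' @return Logical vector: superenhancer membership per input row.
#' @export
call_superenhancers <- function(enhancers, span = 12500, min_size = 3) {
  out <- logical(nrow(enhancers))
  for (cm in unique(enhancers$chrom)) {
    i <- which(enhancers$chrom == cm)
    i <- i[order(enhancers$start[i])]
    cluster_start <- enhancers$start[i[1]]
    members <- i[1]
    flush <- function(members) {
      if (length(members) >= min_size) out[members] <<- TRUE
    }
    for (j in i[-1]) {
      if (enhancers$end[j] - cluster_start <= span) {
        members <- c(members, j)
      } else {
        flush(members)
        cluster_start <- enhancers$start[j]
        members <- j
      }
    }
    flush(members)
  }
  out
}

synth_peaks <- function(config, assembly, genes, enh) {
  active <- genes[genes$alpha > 0, ]
  prom <- tibble::tibble(
    chrom = active$chrom,
    start = pmax(active$tss - 400, 0),
    end = active$tss + 400,
    score = active$alpha / config$alpha *
      stats::rlnorm(nrow(active), log(20), 0.5),
    origin = "promoter")
  tes_sub <- active[stats::runif(nrow(active)) < 0.4, ]
  tts <- tibble::tibble(
    chrom = tes_sub$chrom,
    start = pmax(tes_sub$tes - 300, 0),
    end = tes_sub$tes + 300,
    score = stats::rlnorm(nrow(tes_sub), log(8), 0.5),
    origin = "tes")
  enhp <- tibble::tibble(
    chrom = enh$chrom, start = enh$start, end = enh$end,
    score = enh$score, origin = "enhancer")
  n_noise <- round(0.05 * (nrow(prom) + nrow(tts) + nrow(enhp)))
  ci <- sample.int(nrow(assembly), n_noise, replace = TRUE)
  s <- round(stats::runif(n_noise, 1000, assembly$length[ci] - 1300))
  noise <- tibble::tibble(chrom = assembly$chrom[ci], start = s,
                          end = s + 300,
                          score = stats::rlnorm(n_noise, log(4), 0.4),
                          origin = "noise")
  dplyr::bind_rows(prom, tts, enhp, noise) |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::mutate(name = sprintf("pk%05d", dplyr::row_number()),
                  strand = ".") |>
    dplyr::relocate("name", "score", .after = "end")
}

#' Simulate the drug-washout labelling experiment
#'
#' At washout (t = 0) every gene carries a paused cohort
#' (Poisson(`alpha * block_minutes`) capped at `pause_capacity`); each
#' polymerase releases after an Exponential(`beta`) wait and then elongates
#' at `v`, terminating prematurely with probability `pi_term` per kb. New
#' initiations continue at `alpha` during labelling. The labelled RNA of a
#' polymerase spans from the pause site to its current position (capped at
#' the gene end and its termination point); reads are Poisson with mean
#' `depth` per labelled kb, placed uniformly on the labelled span, sense
#' strand only, plus uniform background on both strands.
#'
#' @param genome Output of [build_genome()].
#' @param config A [sim_config()]; `label_minutes` must be non-empty and
#'   positive, and the block must be long enough to clear gene bodies
#'   (`block_minutes * v >=` longest gene).
#' @param seed Optional seed override.
#' @param conditions Conditions to simulate (default `c("wt", "null")`;
#'   the null condition applies `null_release_factor` to `beta` and
#'   `null_v_factor` to `v`).
#' @return A list: `tracks`, a named list of `stranded_coverage` keyed
#'   `<condition>_<minutes>`; `truth`, a tibble of per-gene polymerase
#'   counts and first-release times per track.
#' @export
simulate_fp_washout <- function(genome, config, seed = config$seed,
                                conditions = c("wt", "null")) {
  stopifnot(inherits(config, "sim_config"))
  if (length(config$label_minutes) == 0 || any(config$label_minutes <= 0)) {
    stop("label_minutes must be positive in washout mode")
  }
  if (config$block_minutes * config$v * 1000 < max(genome$genes$length)) {
    stop("block too short to clear the longest gene body")
  }
  tracks <- list()
  truth <- list()
  off <- 100
  for (cond in conditions) {
    beta <- config$beta *
      if (cond == "null") config$null_release_factor else 1
    v_bp <- config$v * 1000 *
      if (cond == "null") config$null_v_factor else 1
    for (T in config$label_minutes) {
      off <- off + 1
      set.seed(child_seed(seed, off))
      sim <- washout_track(genome, config, beta, v_bp, T)
      key <- paste0(cond, "_", T)
      tracks[[key]] <- sim$cov
      truth[[key]] <- dplyr::mutate(sim$genes, condition = cond,
                                    label_minutes = T)
    }
  }
  list(tracks = tracks, truth = dplyr::bind_rows(truth))
}

washout_track <- function(genome, config, beta, v_bp, T) {
  cov <- stranded_coverage(genome$assembly, config$bin_size)
  g <- genome$genes
  n_pols <- integer(nrow(g))
  first_rel <- rep(NA_real_, nrow(g))
  for (i in seq_len(nrow(g))) {
    if (g$alpha[i] <= 0) next
    n0 <- min(stats::rpois(1, g$alpha[i] * config$block_minutes),
              config$pause_capacity)
    t_start <- c(rep(0, n0),  # paused cohort, ready at washout
                 sort(stats::runif(stats::rpois(1, g$alpha[i] * T), 0, T)))
    if (length(t_start) == 0) next
    t_rel <- t_start + stats::rexp(length(t_start), beta)
    t_rel <- t_rel[t_rel < T]
    if (length(t_rel) == 0) next
    n_pols[i] <- length(t_rel)
    first_rel[i] <- min(t_rel)
    span <- v_bp * (T - t_rel)
    if (config$pi_term > 0) {
      span <- pmin(span, 1000 * stats::rexp(length(span), config$pi_term))
    }
    span <- pmin(span, g$length[i] - g$pause_offset[i])
    span <- span[span > 0]
    if (length(span) == 0) next
    n_reads <- stats::rpois(length(span), config$depth * span / 1000)
    pos_rel <- g$pause_offset[i] +
      stats::runif(sum(n_reads)) * rep(span, n_reads)
    pos <- if (g$strand[i] == "+") g$tss[i] + pos_rel else g$tss[i] - pos_rel
    cov <- add_point_reads(cov, g$chrom[i], g$strand[i], pos)
  }
  cov <- add_background(cov, config)
  list(cov = refresh_total(cov),
       genes = tibble::tibble(gene_id = g$gene_id, n_pols = n_pols,
                              first_release = first_rel))
}

add_background <- function(cov, config) {
  if (config$bg <= 0) return(cov)
  for (s in c("+", "-")) {
    for (ci in seq_len(nrow(cov$assembly))) {
      clen <- cov$assembly$length[ci]
      n <- stats::rpois(1, config$bg * clen / 1000)
      cov <- add_point_reads(cov, cov$assembly$chrom[ci], s,
                             stats::runif(n, 0, clen))
    }
  }
  cov
}

#' Simulate steady-state nascent transcription
#'
#' Expected sense-strand read density per gene: a pause-site peak with mass
#' proportional to the pause occupancy (`alpha / beta`, expressed as
#' `v / beta` bp of body-equivalent signal), a gene body decaying as
#' `exp(-pi_term * x_kb)` (premature termination), and post-TES readthrough
#' decaying over `term_distance`. Enhancers emit bidirectional transcripts
#' of log-normal length centred on the enhancer with output proportional to
#' their condition multiplier; genes with a TSS within `coupling_max_kb` of
#' an enhancer have initiation boosted by a distance-decaying coupling times
#' that multiplier. Reads are Poisson per bin; spike-in counts are Poisson
#' in `abundance * efficiency`. The condition's capture efficiency scales
#' the whole library, which is the confound spike-in normalisation removes.
#'
#' @param genome Output of [build_genome()].
#' @param config A [sim_config()].
#' @param condition `"wt"` or `"null"`.
#' @param seed Optional seed override.
#' @return A list: `cov` (a `stranded_coverage`), `spikes` (tibble
#'   `species`, `abundance`, `condition`, `count`), `gene_rates` (per-gene
#'   effective initiation rates after enhancer coupling).
#' @export
simulate_steady_state <- function(genome, config, condition = "wt",
                                  seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(seed, 300 + match(condition, c("wt", "null", "x"))))
  eff <- config$spike_efficiency[[condition]]
  if (is.null(eff)) eff <- 1
  mult <- if (condition == "null") genome$enhancers$mult_null else
    genome$enhancers$mult_wt
  T <- config$ss_label_minutes
  bin <- config$bin_size
  cov <- stranded_coverage(genome$assembly, bin)
  g <- genome$genes

  rates <- gene_effective_rates(g, genome$enhancers, mult, config)
  for (i in seq_len(nrow(g))) {
    rel <- rates[i] / config$alpha
    if (rel <= 0) next
    dir <- if (g$strand[i] == "+") 1 else -1
    L_bp <- g$length[i] - g$pause_offset[i]
    nb <- ceiling(L_bp / bin)
    x_kb <- (seq_len(nb) - 0.5) * bin / 1000
    lam <- eff * config$depth * (T / 10) * rel * (bin / 1000) *
      exp(-config$pi_term * x_kb)
    ## trailing partial bin carries proportionally less mass
    lam[nb] <- lam[nb] * (L_bp - (nb - 1) * bin) / bin
    ## pause peak: occupancy alpha/beta as v/beta bp of body density
    pk <- eff * config$depth * (T / 10) * rel *
      (config$v * 1000 / config$beta) / 1000
    start_bp <- g$tss[i] + dir * g$pause_offset[i]
    cov <- deposit_run(cov, g$chrom[i], g$strand[i], start_bp, dir,
                       c(lam[1] + pk, lam[-1]))
    ## readthrough past the TES
    if (config$term_distance > 0) {
      rt_bp <- min(15000, 10 * config$term_distance)
      nrt <- ceiling(rt_bp / bin)
      xr <- (seq_len(nrt) - 0.5) * bin
      lam_rt <- eff * config$depth * (T / 10) * rel * (bin / 1000) *
        exp(-config$pi_term * L_bp / 1000) *
        exp(-xr / config$term_distance)
      cov <- deposit_run(cov, g$chrom[i], g$strand[i], g$tes[i], dir, lam_rt)
    }
  }
  ## bidirectional eRNA
  e <- genome$enhancers
  mid <- (e$start + e$end) / 2
  for (j in seq_len(nrow(e))) {
    len <- c(e$erna_len_plus[j], e$erna_len_minus[j])
    lam_tot <- eff * config$erna_depth * mult[j]
    for (k in 1:2) {
      strand <- c("+", "-")[k]
      dir <- c(1, -1)[k]
      nb2 <- max(1, ceiling(len[k] / bin))
      lam2 <- rep(lam_tot / nb2, nb2)
      cov <- deposit_run(cov, e$chrom[j], strand, mid[j], dir, lam2)
    }
  }
  cov <- add_background(cov, config)
  spikes <- tibble::tibble(
    species = names(config$spike_abundance),
    abundance = unname(config$spike_abundance),
    condition = condition,
    count = stats::rpois(length(config$spike_abundance),
                         unname(config$spike_abundance) * eff))
  list(cov = refresh_total(cov), spikes = spikes,
       gene_rates = tibble::tibble(gene_id = g$gene_id, rate = rates,
                                   condition = condition))
}

## Effective initiation after enhancer->gene coupling: nearest enhancer
## within coupling_max_kb (edge-to-TSS) boosts the gene's rate.
gene_effective_rates <- function(genes, enhancers, mult, config) {
  d <- nearest_enhancer_distance(genes, enhancers)
  boost <- rep(1, nrow(genes))
  ok <- !is.na(d$dist_kb) & d$dist_kb <= config$coupling_max_kb
  boost[ok] <- 1 + config$enh_gene_coupling *
    exp(-d$dist_kb[ok] / config$coupling_decay_kb) * mult[d$which[ok]]
  genes$alpha * boost
}

## For each gene: distance (kb, enhancer edge to TSS) and index of the
## nearest enhancer on the same chromosome. 0 if the TSS lies inside one.
nearest_enhancer_distance <- function(genes, enhancers) {
  dist_kb <- rep(NA_real_, nrow(genes))
  which_e <- rep(NA_integer_, nrow(genes))
  for (cm in unique(genes$chrom)) {
    gi <- which(genes$chrom == cm)
    ei <- which(enhancers$chrom == cm)
    if (length(ei) == 0) next
    for (i in gi) {
      tss <- genes$tss[i]
      d <- pmax(enhancers$start[ei] - tss, tss - enhancers$end[ei], 0)
      j <- which.min(d)
      dist_kb[i] <- d[j] / 1000
      which_e[i] <- ei[j]
    }
  }
  list(dist_kb = dist_kb, which = which_e)
}

## Deposit a run of per-bin Poisson means starting at genomic position
## start_bp, walking in direction dir (+1/-1), into the given strand.
deposit_run <- function(cov, chrom, strand, start_bp, dir, lambda) {
  b0 <- floor(start_bp / cov$bin_size)
  bins <- if (dir > 0) b0 + seq_along(lambda) - 1 else
    b0 - seq_along(lambda) + 1
  add_poisson_bins_at(cov, chrom, strand, bins, lambda)
}

add_poisson_bins_at <- function(cov, chrom, strand, bins, lambda) {
  v <- cov_values(cov, chrom, strand)
  ok <- bins >= 0 & bins < length(v)
  if (!any(ok)) return(cov)
  v[bins[ok] + 1] <- v[bins[ok] + 1] + stats::rpois(sum(ok), lambda[ok])
  cov$values[[strand]][[chrom]] <- v
  cov
}

#' Write a ground-truth ledger to TSV files
#'
#' Lossless, schema-stable dump of the simulator's truth tables; one TSV
#' per table (`<prefix>_genes.tsv`, `<prefix>_enhancers.tsv`,
#' `<prefix>_spikes.tsv`).
#'
#' @param truth The `truth` element of [build_genome()].
#' @param prefix Output path prefix.
#' @return The written paths, invisibly.
#' @export
write_truth <- function(truth, prefix) {
  paths <- character(0)
  for (nm in names(truth)) {
    p <- paste0(prefix, "_", nm, ".tsv")
    readr::write_tsv(truth[[nm]], p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
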