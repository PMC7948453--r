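#' Full-run configuration
#'
#' One home for every tunable of the end-to-end pipeline: the simulator
#' block plus the analysis parameters of each stage. A serialised copy is
#' written into every output directory so runs are self-describing.
#'
#' @param sim A [sim_config()].
#' @param min_gene_length Named vector: minimum gene length (bp) per
#'   labelling time; default `c("5" = 15000, "10" = 30000)`, pairing the
#'   5-min labelling with genes > 15 kb and the 10-min with > 30 kb.
#' @param windows Named list of metagene windows (bp around the TSS) per
#'   labelling time; defaults `[-2, 18]` kb and `[-2, 34]` kb leave distal
#'   background room beyond the expected fronts.
#' @param distal_frac,smooth_bins,threshold_frac,run_k Wave-front
#'   parameters (see [estimate_background()] and [detect_wavefront()]).
#' @param n_boot Bootstrap resamples for the rate CI (default 200).
#' @param erna_pad eRNA window pad in bp (default 1000).
#' @param pseudocount,fc_cut Fold-change classifier parameters.
#' @param norm_mode `"spike"` or `"library"`.
#' @param threshold_rpkm Expression filter (default 0.5).
#' @param strata_breaks Distance strata in kb (default `c(0, 20, 40, 60)`).
#' @param seed Master seed; stage seeds derive from it by fixed offsets.
#' @param outdir Output directory for artifacts, or NULL for none.
#' @param verbose Log stage progress to stderr (default TRUE).
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       min_gene_length = c("5" = 15000, "10" = 30000),
                       windows = list("5" = c(-2000, 18000),
                                      "10" = c(-2000, 34000)),
                       distal_frac = 0.25,
                       smooth_bins = 5,
                       threshold_frac = 0.05,
                       run_k = 3,
                       n_boot = 200,
                       erna_pad = 1000,
                       pseudocount = 1,
                       fc_cut = 1.5,
                       norm_mode = c("spike", "library"),
                       threshold_rpkm = 0.5,
                       strata_breaks = c(0, 20, 40, 60),
                       seed = sim$seed,
                       outdir = NULL,
                       verbose = TRUE) {
  norm_mode <- match.arg(norm_mode)
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Validate a run configuration
#'
#' Checks every cross-field constraint and reports all violations, not
#' just the first. Hard violations (non-positive rates, missing labelling
#' times, metagene windows that cannot contain the expected front) are
#' errors; questionable pairings (a gene-length filter shorter than the
#' distance the wave travels) are warnings.
#'
#' @param config A [run_config()].
#' @return A list `ok` (no errors), `errors`, `warnings` (character
#'   vectors).
#' @export
validate_config <- function(config) {
  errors <- character(0)
  warnings <- character(0)
  s <- config$sim
  if (!inherits(s, "sim_config")) errors <- c(errors, "sim block missing")
  if (s$v <= 0) errors <- c(errors, "elongation rate v must be > 0")
  if (s$beta <= 0) errors <- c(errors, "release rate beta must be > 0")
  if (s$alpha < 0) errors <- c(errors, "initiation rate alpha must be >= 0")
  if (s$pi_term < 0) errors <- c(errors, "pi_term must be >= 0")
  if (length(s$label_minutes) == 0 || any(s$label_minutes <= 0)) {
    errors <- c(errors, "label_minutes must be positive and non-empty")
  }
  for (T in s$label_minutes) {
    key <- as.character(T)
    front <- s$pause_max + s$v * 1000 * T
    w <- config$windows[[key]]
    if (is.null(w)) {
      errors <- c(errors, paste0("no metagene window for ", T, "-min labelling"))
    } else if (w[2] < front * 1.2) {
      errors <- c(errors, sprintf(
        "window for %g-min labelling ends at %d bp but the expected front is %.0f bp: no room to estimate background",
        T, w[2], front))
    }
    ml <- config$min_gene_length[[key]]
    if (is.null(ml) || is.na(ml)) {
      errors <- c(errors, paste0("no gene-length filter for ", T,
                                 "-min labelling"))
    } else if (ml < front) {
      warnings <- c(warnings, sprintf(
        "gene filter %g kb for %g-min labelling is shorter than the expected front (%.1f kb): the front may run past short genes",
        ml / 1000, T, front / 1000))
    }
  }
  if (config$threshold_frac <= 0 || config$threshold_frac >= 1) {
    errors <- c(errors, "threshold_frac must be in (0, 1)")
  }
  if (config$pseudocount <= 0) errors <- c(errors, "pseudocount must be > 0")
  list(ok = length(errors) == 0, errors = errors, warnings = warnings)
}

#' Run the full pipeline on synthetic data
#'
#' Executes simulate, metagene/wave-front, rate, quantification and
#' annotation and returns a machine-readable report: wave-front positions,
#' rate estimates with bootstrap CI, WT-vs-null rate ratio, eRNA
#' up/down/unchanged counts, neighbour-gene distance strata, processivity
#' and readthrough ratios, and the peak annotation summary. Byte-identical
#' under identical config and seed (see [report_json()]).
#'
#' @param config A [run_config()].
#' @return A list of class `bruwave_report`.
#' @export
run_all <- function(config = run_config()) {
  val <- validate_config(config)
  for (w in val$warnings) warning(w, call. = FALSE)
  if (!val$ok) {
    stop("invalid configuration:\n  ", paste(val$errors, collapse = "\n  "))
  }
  s <- config$sim
  seed <- config$seed
  say <- function(...) if (isTRUE(config$verbose)) {
    message("[bruwave] ", sprintf(...))
  }

  say("stage simulate: building genome (%d genes)", s$n_genes)
  genome <- build_genome(s, seed = seed)
  say("stage simulate: washout labelling (%s min x wt/null)",
      paste(s$label_minutes, collapse = "/"))
  washout <- simulate_fp_washout(genome, s, seed = seed)

  say("stage metagene/rate")
  fronts <- list()
  rates <- list()
  for (cond in c("wt", "null")) {
    for (T in s$label_minutes) {
      key <- as.character(T)
      genes_f <- filter_genes_by_length(genome$genes,
                                        config$min_gene_length[[key]])
      prof <- build_metagene(washout$tracks[[paste0(cond, "_", T)]], genes_f,
                             "tss", config$windows[[key]])
      bg <- estimate_background(prof, config$distal_frac)
      wf <- detect_wavefront(prof, bg, config$smooth_bins,
                             config$threshold_frac, config$run_k)
      fronts[[paste0(cond, "_", T)]] <- wf
      say("  %s %g-min front: %.2f kb (n=%d genes)", cond, T,
          wf$position / 1000, prof$n_genes)
    }
    Ts <- sort(s$label_minutes)
    t_a <- Ts[1]; t_b <- Ts[length(Ts)]
    rates[[cond]] <- estimate_rate(
      fronts[[paste0(cond, "_", t_a)]], t_a,
      fronts[[paste0(cond, "_", t_b)]], t_b)
    say("  %s rate: %.3f kb/min", cond, rates[[cond]]$rate)
  }
  Ts <- sort(s$label_minutes)
  ka <- as.character(Ts[1]); kb <- as.character(Ts[length(Ts)])
  rate_ci <- bootstrap_rate(
    washout$tracks[[paste0("wt_", ka)]], washout$tracks[[paste0("wt_", kb)]],
    filter_genes_by_length(genome$genes, config$min_gene_length[[ka]]),
    filter_genes_by_length(genome$genes, config$min_gene_length[[kb]]),
    Ts[1], Ts[length(Ts)],
    window_a = config$windows[[ka]], window_b = config$windows[[kb]],
    n_boot = config$n_boot, seed = seed,
    smooth_bins = config$smooth_bins, frac = config$threshold_frac,
    k = config$run_k)

  say("stage quantify: steady-state synthesis and eRNA classification")
  ss_wt <- simulate_steady_state(genome, s, "wt", seed = seed)
  ss_null <- simulate_steady_state(genome, s, "null", seed = seed)
  spikes <- dplyr::bind_rows(ss_wt$spikes, ss_null$spikes)
  lib_totals <- c(wt = ss_wt$cov$total_reads, null = ss_null$cov$total_reads)

  ## eRNA is quantified at intergenic enhancers, away from host-gene signal
  erna_enh <- genome$enhancers[genome$enhancers$class == "intergenic", ]
  wins <- erna_windows(erna_enh, genome$assembly, config$erna_pad)
  raw <- dplyr::bind_rows(
    dplyr::mutate(count_windows(wins, ss_wt$cov, "both"), condition = "wt"),
    dplyr::mutate(count_windows(wins, ss_null$cov, "both"),
                  condition = "null"))
  norm <- normalize_counts(dplyr::select(raw, "id", "condition", "raw"),
                           spikes = spikes, library_totals = lib_totals,
                           mode = config$norm_mode)
  diff <- fold_change(norm, config$pseudocount, config$fc_cut)
  class_counts <- table(factor(diff$class,
                               levels = c("up", "down", "unchanged")))

  say("stage quantify: expression filter, strata, processivity, readthrough")
  expressed <- classify_expressed(genome$genes, ss_wt$cov,
                                  config$threshold_rpkm)
  changed_enh <- genome$enhancers[diff$class[match(genome$enhancers$name,
                                                   diff$id)] == "up", ]
  strata <- gene_strata_fc(expressed, changed_enh, ss_wt$cov, ss_null$cov,
                           spikes, lib_totals, config)
  proc <- list(
    wt = processivity_summary(expressed, ss_wt$cov),
    null = processivity_summary(expressed, ss_null$cov))
  rt <- list(
    wt = stats::median(tes_readthrough(expressed, ss_wt$cov,
                                       neighbors = genome$genes)$readthrough_density /
                  (ss_wt$cov$total_reads / 1e6)),
    null = stats::median(tes_readthrough(expressed, ss_null$cov,
                                         neighbors = genome$genes)$readthrough_density /
                    (ss_null$cov$total_reads / 1e6)))

  say("stage annotate: %d peaks", nrow(genome$peaks))
  ann <- feature_distribution(genome$peaks, genome$genes, genome$assembly)
  inter <- genome$peaks[classify_intergenic(genome$peaks, genome$genes), ]
  se <- genome$enhancers[genome$enhancers$superenhancer, ]
  enh_classes <- table(factor(
    overlap_enhancers(inter, genome$enhancers, se)$enhancer_class,
    levels = c("superenhancer", "enhancer", "none")))
  bound <- bind_genes(expressed, genome$peaks)

  report <- list(
    config = config_fingerprint(config),
    n_genes = nrow(genome$genes),
    fronts_kb = lapply(fronts, function(f) round(f$position / 1000, 4)),
    rate_wt = round(rates$wt$rate, 4),
    rate_null = round(rates$null$rate, 4),
    rate_ratio_null_wt = round(rates$null$rate / rates$wt$rate, 4),
    rate_ci = round(rate_ci$ci, 4),
    erna = list(n_up = unname(class_counts[["up"]]),
                n_down = unname(class_counts[["down"]]),
                n_unchanged = unname(class_counts[["unchanged"]]),
                up_fraction = round(unname(class_counts[["up"]]) /
                                      nrow(wins), 4)),
    strata = strata,
    processivity = lapply(proc, round, 4),
    processivity_ratio_null_wt = round(proc$null / proc$wt, 4),
    readthrough = lapply(rt, signif, 6),
    readthrough_ratio_null_wt = round(rt$null / rt$wt, 4),
    n_expressed = nrow(expressed),
    n_bound_expressed = sum(bound$bound),
    annotation = list(category = ann$category,
                      peak_fraction = round(ann$peak_fraction, 4),
                      genome_fraction = round(ann$genome_fraction, 4)),
    intergenic_peak_classes = as.list(enh_classes)
  )
  class(report) <- "bruwave_report"

  if (!is.null(config$outdir)) write_artifacts(config, genome, washout,
                                               report)
  report
}

## medians of the per-gene distal/proximal ratio distribution
processivity_summary <- function(genes, cov) {
  suppressWarnings(stats::median(processivity_ratio(genes, cov)$ratio))
}

## per-stratum median gene fold change (null/wt) by distance to the given
## enhancers, plus a rank-sum p-value of the nearest vs farthest stratum
gene_strata_fc <- function(genes, enhancers, cov_wt, cov_null, spikes,
                           lib_totals, config) {
  if (nrow(enhancers) == 0 || nrow(genes) == 0) {
    return(list(note = "no changed enhancers or no expressed genes"))
  }
  strat <- stratify_by_distance(genes, enhancers, config$strata_breaks)
  if (nrow(strat) == 0) return(list(note = "no genes within strata"))
  raw <- dplyr::bind_rows(
    dplyr::mutate(count_windows(strat, cov_wt, "sense"), condition = "wt"),
    dplyr::mutate(count_windows(strat, cov_null, "sense"),
                  condition = "null")) |>
    dplyr::mutate(id = .data$gene_id)
  norm <- normalize_counts(dplyr::select(raw, "id", "condition", "raw"),
                           spikes = spikes, library_totals = lib_totals,
                           mode = config$norm_mode)
  fc <- fold_change(norm, config$pseudocount, config$fc_cut)
  strat <- dplyr::left_join(strat, dplyr::select(fc, "id", "fc"),
                            by = c("gene_id" = "id"))
  med <- strat |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(n = dplyr::n(),
                     median_fc = round(stats::median(.data$fc), 4),
                     .groups = "drop")
  levs <- levels(strat$stratum)
  near <- strat$fc[strat$stratum == levs[1]]
  far <- strat$fc[strat$stratum == levs[length(levs)]]
  p <- if (length(near) >= 3 && length(far) >= 3) {
    rank_sum_test(near, far)$p_value
  } else NA_real_
  list(stratum = as.character(med$stratum), n = med$n,
       median_fc = med$median_fc,
       p_near_vs_far = if (is.na(p)) NULL else signif(p, 4))
}

## stable fingerprint of the tunables (drops outdir/verbose, which do not
## affect results)
config_fingerprint <- function(config) {
  cfg <- unclass(config)
  cfg$outdir <- NULL
  cfg$verbose <- NULL
  cfg$sim <- unclass(cfg$sim)
  cfg
}

#' Canonical JSON for a pipeline report
#'
#' Deterministic serialisation: two runs under the same config and seed
#' produce byte-identical strings.
#'
#' @param report A `bruwave_report` from [run_all()].
#' @return A JSON string.
#' @export
report_json <- function(report) {
  jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                   pretty = TRUE)
}

#' @export
print.bruwave_report <- function(x, ...) {
  cat("<bruwave_report>\n")
  cat(sprintf("  fronts (kb): %s\n",
              paste(names(x$fronts_kb), unlist(x$fronts_kb), sep = "=",
                    collapse = ", ")))
  cat(sprintf("  rate wt %.3f, null %.3f kb/min (ratio %.3f), CI [%.3f, %.3f]\n",
              x$rate_wt, x$rate_null, x$rate_ratio_null_wt,
              x$rate_ci[1], x$rate_ci[2]))
  cat(sprintf("  eRNA: %d up / %d down / %d unchanged\n",
              x$erna$n_up, x$erna$n_down, x$erna$n_unchanged))
  cat(sprintf("  processivity ratio null/wt: %.3f; readthrough ratio: %.3f\n",
              x$processivity_ratio_null_wt, x$readthrough_ratio_null_wt))
  cat(sprintf("  expressed genes: %d (bound: %d)\n",
              x$n_expressed, x$n_bound_expressed))
  invisible(x)
}

write_artifacts <- function(config, genome, washout, report) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(config$outdir, ...)
  write_gene_models_bed12(genome$genes, p("genes.bed12"))
  enh <- dplyr::mutate(genome$enhancers, name = ifelse(
    .data$superenhancer, paste0(.data$name, "_SE"), .data$name))
  write_bed(enh, p("enhancers.bed"))
  write_bed(genome$peaks, p("peaks.bed"))
  write_truth(genome$truth, p("truth"))
  for (key in names(washout$tracks)) {
    write_bedgraph(washout$tracks[[key]], p(paste0(key, "_plus.bedgraph")), "+")
    write_bedgraph(washout$tracks[[key]], p(paste0(key, "_minus.bedgraph")), "-")
  }
  writeLines(report_json(report), p("report.json"))
  writeLines(jsonlite::toJSON(config_fingerprint(config), auto_unbox = TRUE,
                              digits = NA, pretty = TRUE),
             p("config.json"))
  invisible(config$outdir)
}
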