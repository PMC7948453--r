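#' Filter genes by length
#'
#' Keeps genes strictly longer than `min_length` bp, preserving order. The
#' washout analysis pairs the 5-min labelling with a 15 kb filter and the
#' 10-min labelling with a 30 kb filter so the wave front stays inside the
#' gene body.
#'
#' @param genes Gene-model tibble.
#' @param min_length Minimum length in bp (> 0; use 0 to keep all).
#' @return The filtered tibble.
#' @export
filter_genes_by_length <- function(genes, min_length) {
  stopifnot(min_length >= 0)
  out <- dplyr::filter(genes, .data$length > min_length)
  if (nrow(out) == 0) warning("no genes pass the length filter")
  out
}

#' Build a TSS- or TES-anchored metagene profile
#'
#' Per gene, the sense-strand binned density is extracted in anchor-relative
#' coordinates (minus-strand genes are reversed so downstream is positive),
#' scaled to reads per million using the track's library total, and the
#' profile is the unweighted mean over genes. Genes whose window would run
#' off a chromosome edge are dropped.
#'
#' @param cov A `stranded_coverage`.
#' @param genes Gene-model tibble (all on `cov`'s assembly).
#' @param anchor `"tss"` or `"tes"`.
#' @param window `c(upstream, downstream)` in bp relative to the anchor
#'   (upstream negative).
#' @param bin_size Must equal the coverage bin size.
#' @return A `metagene_profile`: positions (bin centres, bp relative to the
#'   anchor), values (reads per million per bin), `n_genes`.
#' @export
build_metagene <- function(cov, genes, anchor = c("tss", "tes"),
                           window = c(-2000, 18000),
                           bin_size = cov$bin_size) {
  anchor <- match.arg(anchor)
  stopifnot(bin_size == cov$bin_size, window[1] < window[2],
            window[1] %% bin_size == 0, window[2] %% bin_size == 0)
  if (cov$total_reads <= 0) stop("coverage track is empty")
  scale <- 1e6 / cov$total_reads
  k0 <- window[1] / bin_size
  k1 <- window[2] / bin_size - 1
  offs <- k0:k1
  acc <- numeric(length(offs))
  used <- 0L
  for (i in seq_len(nrow(genes))) {
    v <- cov_values(cov, genes$chrom[i], genes$strand[i])
    apos <- genes[[anchor]][i]
    ## on '-', offset +k mirrors to the bin holding base (apos - 1) - k*bin,
    ## so a minus gene is the exact reflection of its plus counterpart
    bins <- if (genes$strand[i] == "+") floor(apos / bin_size) + offs
            else floor((apos - 1) / bin_size) - offs
    if (min(bins) < 0 || max(bins) >= length(v)) next
    acc <- acc + v[bins + 1]
    used <- used + 1L
  }
  if (used == 0L) stop("no usable genes inside the window")
  structure(
    list(anchor = anchor, bin_size = bin_size, window = window,
         positions = window[1] + (seq_along(offs) - 0.5) * bin_size,
         values = acc / used * scale, n_genes = used),
    class = "metagene_profile"
  )
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat("<metagene_profile> anchor=", x$anchor, ", window=[", x$window[1], ",",
      x$window[2], ") bp, bin=", x$bin_size, " bp, n_genes=", x$n_genes,
      "\n", sep = "")
  invisible(x)
}

#' Average replicate metagene profiles
#'
#' Bin-wise arithmetic mean of profiles with identical geometry;
#' `n_genes` is the minimum over replicates.
#'
#' @param profiles List of `metagene_profile` objects.
#' @return A `metagene_profile`.
#' @export
average_replicates <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  p1 <- profiles[[1]]
  for (p in profiles[-1]) {
    if (!identical(p$anchor, p1$anchor) || !identical(p$window, p1$window) ||
        !identical(p$bin_size, p1$bin_size)) {
      stop("replicate profiles have mismatched geometry")
    }
  }
  p1$values <- Reduce(`+`, lapply(profiles, `[[`, "values")) /
    length(profiles)
  p1$n_genes <- min(vapply(profiles, `[[`, 0L, "n_genes"))
  p1
}

#' Estimate the background density of a profile
#'
#' Median of the most distal fraction of the profile window. The washout
#' wave front is called where signal "approaches background"; a robust
#' distal statistic operationalises that, provided the window extends well
#' past any plausible front.
#'
#' @param profile A `metagene_profile`.
#' @param distal_frac Fraction of the window, from the distal end, used for
#'   the median (default 0.25).
#' @return Background density (reads per million per bin).
#' @export
estimate_background <- function(profile, distal_frac = 0.25) {
  n <- length(profile$values)
  k <- floor(n * distal_frac)
  if (k < 1) stop("distal fraction selects no bins")
  stats::median(profile$values[(n - k + 1):n])
}

#' Detect the nascent-transcription wave front
#'
#' The profile is smoothed with a centred moving mean, a threshold is set a
#' small fraction of the dynamic range above background, and scanning
#' downstream from the profile maximum (so the pause peak cannot trigger a
#' spurious crossing), the front is the start of the first run of at least
#' `k` consecutive sub-threshold bins, linearly interpolated inside the
#' crossing bin.
#'
#' @param profile A `metagene_profile`.
#' @param background Background density from [estimate_background()].
#' @param smooth_bins Moving-mean width in bins (default 5; 1 disables).
#' @param frac Threshold fraction of (max - background) above background
#'   (default 0.05).
#' @param k Consecutive sub-threshold bins required (default 3, suppressing
#'   single-bin noise crossings).
#' @return A `wavefront`: `position` (bp downstream of the anchor),
#'   `background`, `threshold`, `ci` (NULL unless bootstrapped).
#' @export
detect_wavefront <- function(profile, background, smooth_bins = 5,
                             frac = 0.05, k = 3) {
  v <- smooth_profile(profile$values, smooth_bins)
  peak <- max(v)
  if (peak <= background) stop("profile peak does not exceed background")
  thr <- background + frac * (peak - background)
  m <- which.max(v)
  below <- v < thr
  run <- 0L
  cross <- NA_integer_
  for (i in seq(m, length(v))) {
    if (below[i]) {
      run <- run + 1L
      if (run >= k) { cross <- i - run + 1L; break }
    } else run <- 0L
  }
  if (is.na(cross) || cross == 1L) {
    stop("front beyond window: no background crossing detected")
  }
  ## interpolate between the last >= thr bin and the crossing bin
  p_hi <- profile$positions[cross - 1L]
  v_hi <- v[cross - 1L]
  v_lo <- v[cross]
  pos <- if (v_hi > v_lo) {
    p_hi + (v_hi - thr) / (v_hi - v_lo) * profile$bin_size
  } else p_hi + profile$bin_size / 2
  structure(list(position = pos, background = background, threshold = thr,
                 ci = NULL),
            class = "wavefront")
}

smooth_profile <- function(v, smooth_bins) {
  if (smooth_bins <= 1) return(v)
  half <- floor(smooth_bins / 2)
  n <- length(v)
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' @export
print.wavefront <- function(x, ...) {
  cat(sprintf("<wavefront> position = %.0f bp (background %.3g, threshold %.3g)\n",
              x$position, x$background, x$threshold))
  if (!is.null(x$ci)) cat(sprintf("  95%% CI [%.0f, %.0f] bp\n",
                                  x$ci[1], x$ci[2]))
  invisible(x)
}

#' Estimate the elongation rate from wave fronts
#'
#' Two-timepoint: `(front_b - front_a) / (t_b - t_a)`, in kb/min.
#' Single-timepoint: pass `t_a = 0` with `front_a` at the pause offset.
#'
#' @param front_a,front_b Front positions in bp (numbers or `wavefront`
#'   objects) at times `t_a < t_b`.
#' @param t_a,t_b Labelling times in minutes.
#' @return A `rate_estimate`: `rate` (kb/min), `method`, `ci`.
#' @export
estimate_rate <- function(front_a, t_a, front_b, t_b) {
  fa <- if (inherits(front_a, "wavefront")) front_a$position else front_a
  fb <- if (inherits(front_b, "wavefront")) front_b$position else front_b
  stopifnot(t_b > t_a, t_a >= 0)
  if (fb <= fa) {
    stop("non-increasing front: front at the later time must be larger ",
         "(front detection likely failed)")
  }
  structure(
    list(rate = (fb - fa) / (t_b - t_a) / 1000,
         method = if (t_a == 0) "single-timepoint" else "two-timepoint",
         ci = NULL, fronts = c(fa, fb), times = c(t_a, t_b)),
    class = "rate_estimate"
  )
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("<rate_estimate> %.3g kb/min (%s)\n", x$rate, x$method))
  if (!is.null(x$ci)) cat(sprintf("  95%% CI [%.3g, %.3g] kb/min\n",
                                  x$ci[1], x$ci[2]))
  invisible(x)
}

#' Bootstrap confidence interval for the elongation rate
#'
#' Resamples genes with replacement, rebuilds both metagenes, re-detects
#' both fronts and re-estimates the rate; the CI is the percentile
#' interval of the bootstrap distribution.
#'
#' @param cov_a,cov_b Coverage tracks for the two labelling times.
#' @param genes_a,genes_b Length-filtered gene sets for each track.
#' @param t_a,t_b Labelling times in minutes.
#' @param window_a,window_b Metagene windows.
#' @param n_boot Number of resamples (>= 100).
#' @param seed Integer seed.
#' @param ... Passed to [detect_wavefront()].
#' @return A `rate_estimate` with a percentile `ci`; errors if more than
#'   20% of resamples fail front detection.
#' @export
bootstrap_rate <- function(cov_a, cov_b, genes_a, genes_b, t_a, t_b,
                           window_a = c(-2000, 18000),
                           window_b = c(-2000, 34000),
                           n_boot = 200, seed = 1, ...) {
  if (n_boot < 100) stop("n_boot must be at least 100")
  point <- rate_from_tracks(cov_a, cov_b, genes_a, genes_b, t_a, t_b,
                            window_a, window_b, ...)
  set.seed(child_seed(seed, 77))
  rates <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    ga <- genes_a[sample.int(nrow(genes_a), replace = TRUE), ]
    gb <- genes_b[sample.int(nrow(genes_b), replace = TRUE), ]
    r <- tryCatch(
      rate_from_tracks(cov_a, cov_b, ga, gb, t_a, t_b,
                       window_a, window_b, ...)$rate,
      error = function(e) NA_real_)
    rates[b] <- r
  }
  fail <- mean(is.na(rates))
  if (fail > 0.2) {
    stop(sprintf("front detection failed in %.0f%% of resamples", 100 * fail))
  }
  point$ci <- unname(stats::quantile(rates, c(0.025, 0.975), na.rm = TRUE))
  point$n_boot <- n_boot
  point
}

rate_from_tracks <- function(cov_a, cov_b, genes_a, genes_b, t_a, t_b,
                             window_a, window_b, ...) {
  pa <- build_metagene(cov_a, genes_a, "tss", window_a)
  pb <- build_metagene(cov_b, genes_b, "tss", window_b)
  fa <- detect_wavefront(pa, estimate_background(pa), ...)
  fb <- detect_wavefront(pb, estimate_background(pb), ...)
  estimate_rate(fa, t_a, fb, t_b)
}
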