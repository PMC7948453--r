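#' Count coverage in windows
#'
#' Sum of bin densities overlapping each interval, pro-rata at the edges
#' (a bin half inside the window contributes half its value), equal to the
#' per-base density integral. Out-of-bounds intervals are clipped with a
#' warning.
#'
#' @param windows Tibble with `chrom`, `start`, `end` and (for stranded
#'   modes) `strand`; an `id`/`name` column is carried through.
#' @param cov A `stranded_coverage`.
#' @param strand_mode `"both"` (sum of strands), `"sense"` or
#'   `"antisense"` (relative to the window's strand).
#' @return The input tibble with a `raw` count column, plus `rpkm`
#'   (reads per kb of window per million library reads).
#' @export
count_windows <- function(windows, cov, strand_mode = c("both", "sense",
                                                        "antisense")) {
  strand_mode <- match.arg(strand_mode)
  raw <- numeric(nrow(windows))
  clen <- assembly_length(cov$assembly, windows$chrom)
  s <- pmax(windows$start, 0)
  e <- pmin(windows$end, clen)
  if (any(s != windows$start | e != windows$end)) {
    warning("some windows extend beyond chromosome bounds; clipped")
  }
  for (i in seq_len(nrow(windows))) {
    if (s[i] >= e[i]) { raw[i] <- 0; next }
    strands <- switch(strand_mode,
      both = c("+", "-"),
      sense = windows$strand[i],
      antisense = setdiff(c("+", "-"), windows$strand[i]))
    raw[i] <- sum(vapply(strands, function(st) {
      window_sum(cov_values(cov, windows$chrom[i], st), s[i], e[i],
                 cov$bin_size)
    }, 0))
  }
  out <- windows
  out$raw <- raw
  out$rpkm <- raw / ((e - s) / 1000) / (cov$total_reads / 1e6)
  out
}

## Pro-rata sum of bin values over [s, e): integral of the per-base density.
window_sum <- function(v, s, e, bin_size) {
  b0 <- floor(s / bin_size)
  b1 <- min(ceiling(e / bin_size) - 1, length(v) - 1)
  bins <- b0:b1
  ov <- pmin(e, (bins + 1) * bin_size) - pmax(s, bins * bin_size)
  sum(v[bins + 1] * ov / bin_size)
}

#' Build eRNA quantification windows around peaks
#'
#' Each peak expanded by `pad` bp on both sides (the +/- 1 kb convention for
#' enhancer RNA), clipped to chromosome bounds. eRNAs are bidirectional, so
#' these windows are counted with `strand_mode = "both"`.
#'
#' @param peaks Peak tibble (`chrom`, `start`, `end`, `name`).
#' @param assembly A [genome_assembly()] for clipping.
#' @param pad Expansion in bp (default 1000).
#' @return A tibble of windows with the peak `name` as `id`.
#' @export
erna_windows <- function(peaks, assembly, pad = 1000) {
  stopifnot(pad >= 0)
  tibble::tibble(
    id = if ("name" %in% names(peaks)) peaks$name else
      sprintf("w%05d", seq_len(nrow(peaks))),
    chrom = peaks$chrom,
    start = pmax(peaks$start - pad, 0),
    end = pmin(peaks$end + pad, assembly_length(assembly, peaks$chrom))
  )
}

#' Normalise counts across conditions
#'
#' Spike mode anchors each condition to exogenous RNA of known abundance:
#' the per-condition factor is `median(abundance / observed spike count)`,
#' applied multiplicatively, which cancels any global capture-efficiency
#' difference between libraries. Library mode scales to reads per million.
#'
#' @param counts Long tibble with `id`, `condition`, `raw`.
#' @param spikes Spike table (`species`, `abundance`, `condition`, `count`);
#'   required for `mode = "spike"`.
#' @param library_totals Named vector of per-condition library totals;
#'   required for `mode = "library"`.
#' @param mode `"spike"` or `"library"`.
#' @return `counts` with a `normalized` column (and the `factor` used).
#' @export
normalize_counts <- function(counts, spikes = NULL, library_totals = NULL,
                             mode = c("spike", "library")) {
  mode <- match.arg(mode)
  if (mode == "spike") {
    if (is.null(spikes)) stop("spike table required for spike mode")
    if (all(spikes$count == 0)) stop("all spike counts are zero")
    factors <- spikes |>
      dplyr::filter(.data$count > 0) |>
      dplyr::group_by(.data$condition) |>
      dplyr::summarise(factor = stats::median(.data$abundance / .data$count),
                       .groups = "drop")
  } else {
    if (is.null(library_totals)) stop("library totals required")
    factors <- tibble::tibble(condition = names(library_totals),
                              factor = 1e6 / unname(library_totals))
  }
  missing <- setdiff(unique(counts$condition), factors$condition)
  if (length(missing) > 0) {
    stop("no normalisation factor for condition: ",
         paste(missing, collapse = ", "))
  }
  counts |>
    dplyr::left_join(factors, by = "condition") |>
    dplyr::mutate(normalized = .data$raw * .data$factor)
}

#' Filter genes by expression
#'
#' Keeps genes whose sense-strand gene-body RPKM exceeds the threshold
#' (default 0.5, the conventional cutoff for calling a gene transcribed in
#' nascent-RNA data).
#'
#' @param genes Gene-model tibble.
#' @param cov A `stranded_coverage`.
#' @param threshold_rpkm RPKM cutoff (>= 0).
#' @return The expressed subset, with an `rpkm` column.
#' @export
classify_expressed <- function(genes, cov, threshold_rpkm = 0.5) {
  stopifnot(threshold_rpkm >= 0)
  counted <- count_windows(genes, cov, strand_mode = "sense")
  dplyr::filter(counted, .data$rpkm > threshold_rpkm)
}

#' Fold-change classification of normalised counts
#'
#' `fc = (null + p) / (wt + p)` with pseudocount `p`; windows with
#' `fc > 1.5` are `up`, `fc < 1/1.5` are `down`, the rest `unchanged` —
#' the operative differential-synthesis classifier for eRNA windows and
#' genes alike.
#'
#' @param diff Tibble with `id`, `count_wt`, `count_null` (normalised), or
#'   a long tibble from [normalize_counts()] with conditions `wt`/`null`.
#' @param pseudocount Positive pseudocount in normalised units (default 1).
#' @param fc_cut Fold-change cutoff (default 1.5).
#' @return A tibble `id`, `count_wt`, `count_null`, `fc`, `class`.
#' @export
fold_change <- function(diff, pseudocount = 1, fc_cut = 1.5) {
  stopifnot(pseudocount > 0, fc_cut > 1)
  if (!all(c("count_wt", "count_null") %in% names(diff)) &&
      all(c("condition", "normalized") %in% names(diff))) {
    diff <- diff |>
      dplyr::select("id", "condition", "normalized") |>
      tidyr::pivot_wider(names_from = "condition",
                         values_from = "normalized",
                         names_prefix = "count_")
  }
  diff |>
    dplyr::mutate(
      fc = (.data$count_null + pseudocount) / (.data$count_wt + pseudocount),
      class = dplyr::case_when(
        .data$fc > fc_cut ~ "up",
        .data$fc < 1 / fc_cut ~ "down",
        TRUE ~ "unchanged")) |>
    dplyr::select("id", "count_wt", "count_null", "fc", "class")
}

#' Processivity ratio of a gene
#'
#' Distal over proximal mean sense-strand density during steady-state
#' transcription. With premature termination at `pi` per kb the ratio is
#' approximately `exp(-pi * d_kb)` for window separation `d_kb`; a
#' processivity defect depresses it. Invariant to global track rescaling.
#'
#' @param genes Gene-model tibble; genes too short to host both windows are
#'   dropped with a warning, as are genes with zero proximal signal.
#' @param cov A `stranded_coverage`.
#' @param proximal Offsets from the TSS in bp, default `c(1000, 5000)`.
#' @param distal Offsets from the TES in bp (upstream), default
#'   `c(-5000, -1000)`.
#' @return Tibble `gene_id`, `proximal_density`, `distal_density`, `ratio`.
#' @export
processivity_ratio <- function(genes, cov, proximal = c(1000, 5000),
                               distal = c(-5000, -1000)) {
  min_len <- proximal[2] - distal[1]
  ok <- genes$length >= min_len
  if (any(!ok)) warning(sum(!ok), " gene(s) too short for both windows; dropped")
  g <- genes[ok, ]
  dir <- ifelse(g$strand == "+", 1, -1)
  prox <- stranded_window(g, g$tss + dir * proximal[1],
                          g$tss + dir * proximal[2])
  dist <- stranded_window(g, g$tes + dir * distal[1], g$tes + dir * distal[2])
  pd <- count_windows(prox, cov, "sense")$raw / (proximal[2] - proximal[1])
  dd <- count_windows(dist, cov, "sense")$raw / (distal[2] - distal[1])
  zero <- pd <= 0
  if (any(zero)) warning(sum(zero), " gene(s) with zero proximal signal; dropped")
  tibble::tibble(gene_id = g$gene_id[!zero],
                 proximal_density = pd[!zero],
                 distal_density = dd[!zero],
                 ratio = dd[!zero] / pd[!zero])
}

stranded_window <- function(g, a, b) {
  tibble::tibble(chrom = g$chrom, start = pmin(a, b), end = pmax(a, b),
                 strand = g$strand)
}

#' Mean readthrough density downstream of the TES
#'
#' Mean sense-strand density over `(TES, TES + downstream_bp]`, the region
#' where terminating polymerases still produce nascent signal. The region
#' is clipped at chromosome edges and at the nearest downstream neighbour
#' gene on the same strand, so a neighbour's transcription is not mistaken
#' for readthrough; genes whose region clips away entirely are dropped.
#'
#' @param genes Gene-model tibble to measure.
#' @param cov A `stranded_coverage`.
#' @param downstream_bp Extent in bp (default 10000).
#' @param neighbors Gene-model tibble used for clipping (defaults to
#'   `genes`; pass the full annotation when measuring a subset).
#' @return Tibble `gene_id`, `readthrough_density` (reads per bp).
#' @export
tes_readthrough <- function(genes, cov, downstream_bp = 10000,
                            neighbors = genes) {
  dir <- ifelse(genes$strand == "+", 1, -1)
  clen <- assembly_length(cov$assembly, genes$chrom)
  lim <- numeric(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    nb <- neighbors[neighbors$chrom == genes$chrom[i] &
                      neighbors$strand == genes$strand[i] &
                      neighbors$gene_id != genes$gene_id[i], ]
    if (dir[i] > 0) {
      edge <- nb$start[nb$start >= genes$tes[i]]
      lim[i] <- min(genes$tes[i] + downstream_bp, clen[i],
                    if (length(edge)) min(edge) else Inf)
    } else {
      edge <- nb$end[nb$end <= genes$tes[i]]
      lim[i] <- max(genes$tes[i] - downstream_bp, 0,
                    if (length(edge)) max(edge) else -Inf)
    }
  }
  w <- stranded_window(genes, genes$tes, lim)
  keep <- w$end - w$start >= cov$bin_size
  w <- w[keep, ]
  d <- suppressWarnings(count_windows(w, cov, "sense"))
  tibble::tibble(gene_id = genes$gene_id[keep],
                 readthrough_density = d$raw / (w$end - w$start))
}

#' Stratify genes by distance to the nearest selected enhancer
#'
#' Distance is nearest enhancer-edge to gene-TSS. Bins follow the
#' `breaks` vector as right-open intervals (a gene exactly 20 kb away falls
#' in the 20-40 kb stratum); genes at or beyond the last break, or with no
#' enhancer on their chromosome, are excluded.
#'
#' @param genes Gene-model tibble.
#' @param enhancers Peak tibble of the selected enhancers.
#' @param breaks Distance breaks in kb (default `c(0, 20, 40, 60)`).
#' @return `genes` with `dist_kb` and `stratum` columns, excluded genes
#'   dropped.
#' @export
stratify_by_distance <- function(genes, enhancers, breaks = c(0, 20, 40, 60)) {
  d <- nearest_enhancer_distance(genes, enhancers)
  labs <- paste0(utils::head(breaks, -1), "-", breaks[-1], " kb")
  stratum <- cut(d$dist_kb, breaks = breaks, labels = labs, right = FALSE,
                 include.lowest = FALSE)
  out <- genes
  out$dist_kb <- d$dist_kb
  out$stratum <- stratum
  dplyr::filter(out, !is.na(.data$stratum))
}

#' Wilcoxon rank-sum comparison of two groups
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test: exact enumeration for
#' small tie-free samples (both n <= 20), normal approximation with tie and
#' continuity correction otherwise.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 3.
#' @return Tibble `statistic` (rank-sum W), `p_value`, `n_a`, `n_b`,
#'   `method`.
#' @export
rank_sum_test <- function(values_a, values_b) {
  if (length(values_a) < 3 || length(values_b) < 3) {
    stop("each group needs at least 3 values")
  }
  ties <- anyDuplicated(c(values_a, values_b)) > 0
  exact <- !ties && length(values_a) <= 20 && length(values_b) <= 20
  ht <- stats::wilcox.test(values_a, values_b, alternative = "two.sided",
                           exact = exact, correct = TRUE)
  tibble::tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
                 n_a = length(values_a), n_b = length(values_b),
                 method = if (exact) "exact" else "normal approximation")
}
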