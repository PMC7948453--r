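## Strand-aware regulatory span of a gene: [TSS - pad, TES] on '+',
## [TES, TSS + pad] on '-' (0-based half-open, pad default 500 bp). Used
## both for calling peaks intergenic and for calling genes bound, so the
## two are logical complements by construction.
gene_spans <- function(genes, pad = 500) {
  tibble::tibble(
    chrom = genes$chrom,
    start = pmax(ifelse(genes$strand == "+", genes$tss - pad, genes$tes), 0),
    end = ifelse(genes$strand == "+", genes$tes, genes$tss + pad),
    gene_id = genes$gene_id
  )
}

overlaps_any <- function(chrom, start, end, spans) {
  vapply(seq_along(chrom), function(i) {
    s <- spans[spans$chrom == chrom[i], ]
    any(start[i] < s$end & end[i] > s$start)
  }, TRUE)
}

#' Classify peaks as intergenic
#'
#' A peak is intergenic iff it has zero overlap with every gene's
#' strand-aware span from 500 bp upstream of the TSS to the TES.
#'
#' @param peaks Peak tibble.
#' @param genes Gene-model tibble.
#' @param pad Upstream pad in bp (default 500).
#' @return Logical vector per peak.
#' @export
classify_intergenic <- function(peaks, genes, pad = 500) {
  !overlaps_any(peaks$chrom, peaks$start, peaks$end, gene_spans(genes, pad))
}

#' Genes bound by at least one peak
#'
#' A gene is bound iff at least one peak overlaps its span from 500 bp
#' upstream of the TSS to the TES — the complement, over the same span
#' definition, of [classify_intergenic()].
#'
#' @param genes Gene-model tibble.
#' @param peaks Peak tibble.
#' @param pad Upstream pad in bp (default 500).
#' @return `genes` with a logical `bound` column.
#' @export
bind_genes <- function(genes, peaks, pad = 500) {
  spans <- gene_spans(genes, pad)
  out <- genes
  out$bound <- vapply(seq_len(nrow(spans)), function(i) {
    p <- peaks[peaks$chrom == spans$chrom[i], ]
    any(p$start < spans$end[i] & p$end > spans$start[i])
  }, TRUE)
  out
}

#' Assign each peak to a genomic feature category
#'
#' Categories are assigned by peak midpoint with priority
#' promoter (TSS-1000..TSS+100, strand-aware) > tts (TES-100..TES+1000) >
#' gene body > intergenic, following the usual peak-annotation convention.
#' Ties across genes are broken by smallest absolute distance to a TSS,
#' then by gene order (lower coordinate first).
#'
#' @param peaks Peak tibble.
#' @param genes Gene-model tibble.
#' @param promoter Window around the TSS in bp, default `c(-1000, 100)`
#'   (upstream negative, in the gene's reading direction).
#' @param tts Window around the TES in bp, default `c(-100, 1000)`.
#' @return Tibble `name`, `category`, `nearest_gene`, `dist_to_tss`
#'   (signed bp, positive downstream of the nearest TSS).
#' @export
assign_feature <- function(peaks, genes, promoter = c(-1000, 100),
                           tts = c(-100, 1000)) {
  n <- nrow(peaks)
  category <- character(n)
  nearest <- character(n)
  dist_tss <- numeric(n)
  mid <- (peaks$start + peaks$end) / 2
  for (i in seq_len(n)) {
    g <- genes[genes$chrom == peaks$chrom[i], ]
    if (nrow(g) == 0) {
      category[i] <- "intergenic"; nearest[i] <- NA_character_
      dist_tss[i] <- NA_real_
      next
    }
    dir <- ifelse(g$strand == "+", 1, -1)
    d <- dir * (mid[i] - g$tss)  # signed, positive downstream
    j <- order(abs(d), g$start)[1]
    nearest[i] <- g$gene_id[j]
    dist_tss[i] <- d[j]
    in_win <- function(anchor, win) {
      x <- dir * (mid[i] - anchor)
      x >= win[1] & x <= win[2]
    }
    category[i] <- if (any(in_win(g$tss, promoter))) "promoter"
      else if (any(in_win(g$tes, tts))) "tts"
      else if (any(mid[i] >= g$start & mid[i] < g$end)) "genic_body"
      else "intergenic"
  }
  tibble::tibble(
    name = if ("name" %in% names(peaks)) peaks$name else as.character(seq_len(n)),
    category = category, nearest_gene = nearest, dist_to_tss = dist_tss)
}

#' Feature distribution of a peak set
#'
#' Per-category peak fraction, alongside the genome-wide bp fraction of
#' each category (the background expectation for peaks placed uniformly at
#' random). Categories partition the peak set: fractions sum to 1.
#'
#' @param peaks Peak tibble.
#' @param genes Gene-model tibble.
#' @param assembly A [genome_assembly()].
#' @param ... Passed to [assign_feature()].
#' @return Tibble `category`, `n_peaks`, `peak_fraction`,
#'   `genome_fraction`.
#' @export
feature_distribution <- function(peaks, genes, assembly, ...) {
  ann <- assign_feature(peaks, genes, ...)
  cats <- c("promoter", "tts", "genic_body", "intergenic")
  counts <- table(factor(ann$category, levels = cats))
  gfrac <- genome_category_fractions(genes, assembly, ...)
  tibble::tibble(
    category = cats,
    n_peaks = as.integer(counts),
    peak_fraction = as.numeric(counts) / max(nrow(peaks), 1),
    genome_fraction = gfrac[cats]
  )
}

## bp fraction of the genome falling in each category when classified the
## same way as peak midpoints (priority promoter > tts > body > intergenic).
genome_category_fractions <- function(genes, assembly,
                                      promoter = c(-1000, 100),
                                      tts = c(-100, 1000)) {
  total <- sum(assembly$length)
  bp <- c(promoter = 0, tts = 0, genic_body = 0)
  for (cm in assembly$chrom) {
    g <- genes[genes$chrom == cm, ]
    if (nrow(g) == 0) next
    dir <- ifelse(g$strand == "+", 1, -1)
    prom <- cbind(g$tss + dir * promoter[1], g$tss + dir * promoter[2])
    ttsw <- cbind(g$tes + dir * tts[1], g$tes + dir * tts[2])
    prom <- t(apply(prom, 1, sort))
    ttsw <- t(apply(ttsw, 1, sort))
    clen <- assembly_length(assembly, cm)
    p_bp <- merged_length(prom, clen)
    ## tts bp outside promoter windows; body outside both
    t_bp <- merged_length(rbind(prom, ttsw), clen) - p_bp
    b_bp <- merged_length(rbind(prom, ttsw, cbind(g$start, g$end)), clen) -
      p_bp - t_bp
    bp <- bp + c(p_bp, t_bp, b_bp)
  }
  frac <- bp / total
  c(frac, intergenic = 1 - sum(frac))
}

merged_length <- function(ivl, clen) {
  if (nrow(ivl) == 0) return(0)
  ivl[, 1] <- pmax(ivl[, 1], 0)
  ivl[, 2] <- pmin(ivl[, 2], clen)
  ivl <- ivl[ivl[, 2] > ivl[, 1], , drop = FALSE]
  if (nrow(ivl) == 0) return(0)
  o <- order(ivl[, 1])
  s <- ivl[o, 1]; e <- ivl[o, 2]
  tot <- 0; cur_s <- s[1]; cur_e <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] > cur_e) { tot <- tot + cur_e - cur_s; cur_s <- s[i]; cur_e <- e[i] }
    else cur_e <- max(cur_e, e[i])
  }
  tot + cur_e - cur_s
}

#' Overlap intergenic peaks with enhancer and superenhancer sets
#'
#' Each peak is labelled `superenhancer`, `enhancer` or `none` by >= 1 bp
#' overlap, superenhancers taking priority. The three class counts sum to
#' the input size.
#'
#' @param peaks Peak tibble (typically the intergenic subset).
#' @param enhancers Enhancer intervals.
#' @param superenhancers Superenhancer intervals.
#' @return `peaks` with an `enhancer_class` column.
#' @export
overlap_enhancers <- function(peaks, enhancers, superenhancers) {
  in_se <- overlaps_any(peaks$chrom, peaks$start, peaks$end,
                        superenhancers)
  in_e <- overlaps_any(peaks$chrom, peaks$start, peaks$end, enhancers)
  dplyr::mutate(peaks, enhancer_class = dplyr::case_when(
    in_se ~ "superenhancer",
    in_e ~ "enhancer",
    TRUE ~ "none"))
}

#' Split bound genes into enrichment tertiles
#'
#' Genes ranked by the summed score of peaks overlapping their span
#' (TSS - 500 bp to TES), split at the 33.3/66.7 score percentiles
#' (order-statistic quantiles); tied scores all fall on the same side of a
#' cut, deterministically in the lower tertile.
#'
#' @param genes Gene-model tibble (typically the bound subset).
#' @param peaks Peak tibble with `score`.
#' @param pad Upstream pad in bp (default 500).
#' @return `genes` with `enrichment` (summed score) and `tertile`
#'   (`"low"`, `"mid"`, `"high"`).
#' @export
tertile_by_enrichment <- function(genes, peaks, pad = 500) {
  spans <- gene_spans(genes, pad)
  enr <- vapply(seq_len(nrow(spans)), function(i) {
    p <- peaks[peaks$chrom == spans$chrom[i], ]
    hit <- p$start < spans$end[i] & p$end > spans$start[i]
    sum(p$score[hit])
  }, 0)
  q <- stats::quantile(enr, c(1 / 3, 2 / 3), type = 1, names = FALSE)
  out <- genes
  out$enrichment <- enr
  out$tertile <- factor(
    dplyr::case_when(enr <= q[1] ~ "low", enr <= q[2] ~ "mid",
                     TRUE ~ "high"),
    levels = c("low", "mid", "high"))
  out
}
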