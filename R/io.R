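## Coordinate conventions, stated once and inherited everywhere:
## BED and bedGraph are 0-based half-open; GTF is 1-based closed and is
## converted to 0-based half-open on read. TSS = start on '+', end on '-';
## TES is the opposite terminus.

#' Read a BED3-BED6 file of peaks
#'
#' @param path Path to a BED file. Track/browser lines and `#` comments are
#'   ignored. Missing name/score columns are filled with `"."` / `0`.
#' @return A tibble of peaks: `chrom`, `start`, `end` (0-based half-open),
#'   `name`, `score`, `strand`, in input order.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), name = character(),
                          score = numeric(), strand = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("malformed BED line ", which(nf < 3)[1], ": fewer than 3 fields")
  }
  grab <- function(k, default) {
    vapply(fields, function(f) if (length(f) >= k) f[k] else default, "")
  }
  start <- suppressWarnings(as.numeric(grab(2, NA)))
  end <- suppressWarnings(as.numeric(grab(3, NA)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0) {
    stop("malformed BED line ", bad[1], ": non-numeric coordinates")
  }
  inv <- which(start >= end)
  if (length(inv) > 0) {
    stop("invalid interval on line ", inv[1], ": start >= end")
  }
  score <- suppressWarnings(as.numeric(grab(5, "0")))
  score[is.na(score)] <- 0
  tibble::tibble(
    chrom = grab(1, NA), start = start, end = end,
    name = grab(4, "."), score = score, strand = grab(6, ".")
  )
}

#' Write peaks to a BED6 file
#'
#' @param peaks Tibble with `chrom`, `start`, `end` and optionally `name`,
#'   `score`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  name <- if ("name" %in% names(peaks)) peaks$name else rep(".", nrow(peaks))
  score <- if ("score" %in% names(peaks)) peaks$score else rep(0, nrow(peaks))
  strand <- if ("strand" %in% names(peaks)) peaks$strand else rep(".", nrow(peaks))
  lines <- sprintf("%s\t%d\t%d\t%s\t%g\t%s", peaks$chrom,
                   as.integer(peaks$start), as.integer(peaks$end),
                   name, score, strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from BED12 or GTF
#'
#' One record per transcript; TSS/TES are derived from strand (TSS = start
#' on '+', end on '-'). GTF coordinates (1-based closed) are converted to
#' 0-based half-open. Callers wanting one transcript per gene deduplicate
#' downstream.
#'
#' @param path Path to the annotation file.
#' @param format `"bed12"` (also accepts BED6) or `"gtf"` (uses
#'   `transcript` features, falling back to `gene` features).
#' @return A tibble of gene models: `gene_id`, `chrom`, `strand`, `start`,
#'   `end`, `tss`, `tes`, `length`.
#' @export
read_gene_models <- function(path, format = c("bed12", "gtf")) {
  format <- match.arg(format)
  if (format == "bed12") {
    b <- read_bed(path)
    if (any(!b$strand %in% c("+", "-"))) {
      stop("gene records must have strand '+' or '-'")
    }
    g <- tibble::tibble(gene_id = b$name, chrom = b$chrom, strand = b$strand,
                        start = b$start, end = b$end)
  } else {
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 9)) stop("malformed GTF line ", which(nf < 9)[1])
    feat <- vapply(fields, `[`, "", 3)
    use <- feat == "transcript"
    if (!any(use)) use <- feat == "gene"
    fields <- fields[use]
    if (length(fields) == 0) stop("no transcript or gene features in ", path)
    strand <- vapply(fields, `[`, "", 7)
    if (any(!strand %in% c("+", "-"))) {
      stop("unknown strand character in GTF: ",
           paste(unique(setdiff(strand, c("+", "-"))), collapse = ","))
    }
    attr9 <- vapply(fields, `[`, "", 9)
    id <- sub('.*transcript_id "([^"]+)".*', "\\1", attr9)
    miss <- !grepl('transcript_id "', attr9, fixed = TRUE)
    id[miss] <- sub('.*gene_id "([^"]+)".*', "\\1", attr9[miss])
    g <- tibble::tibble(
      gene_id = id,
      chrom = vapply(fields, `[`, "", 1),
      strand = strand,
      start = as.numeric(vapply(fields, `[`, "", 4)) - 1,  # to 0-based
      end = as.numeric(vapply(fields, `[`, "", 5))
    )
  }
  if (any(g$start >= g$end)) stop("invalid gene interval: start >= end")
  finish_gene_models(g)
}

## Derive tss/tes/length from strand; shared by readers and the simulator.
finish_gene_models <- function(g) {
  dplyr::mutate(
    g,
    tss = ifelse(.data$strand == "+", .data$start, .data$end),
    tes = ifelse(.data$strand == "+", .data$end, .data$start),
    length = .data$end - .data$start
  )
}

#' Write gene models as BED12
#'
#' Single-exon BED12 records (one block spanning the gene), sufficient for
#' round-tripping through [read_gene_models()].
#' @param genes Gene-model tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_bed12 <- function(genes, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t1\t%d,\t0,",
                   genes$chrom, as.integer(genes$start), as.integer(genes$end),
                   genes$gene_id, genes$strand,
                   as.integer(genes$start), as.integer(genes$end),
                   as.integer(genes$length))
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph file into binned stranded coverage
#'
#' Interval values are interpreted as reads per `bin_size` bp and
#' distributed to bins pro-rata by overlap length, so
#' `sum(bins) * bin_size == sum(value * interval_length)` for every track.
#' Uncovered bins are 0.
#'
#' @param path Path to a 4-column bedGraph (track lines ignored).
#' @param assembly A [genome_assembly()]; every record's chromosome must be
#'   present in it.
#' @param bin_size Bin width in bp.
#' @param strand Which strand of the returned track to fill (`"+"` or `"-"`).
#' @param into Optionally, an existing `stranded_coverage` to add the second
#'   strand into.
#' @return A `stranded_coverage` with `total_reads` equal to the binned mass.
#' @export
read_bedgraph <- function(path, assembly, bin_size = 50, strand = c("+", "-"),
                          into = NULL) {
  strand <- match.arg(strand)
  cov <- if (is.null(into)) stranded_coverage(assembly, bin_size) else into
  stopifnot(cov$bin_size == bin_size)
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))]
  if (length(lines) > 0) {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 4)) stop("malformed bedGraph line ", which(nf < 4)[1])
    chrom <- vapply(fields, `[`, "", 1)
    s <- as.numeric(vapply(fields, `[`, "", 2))
    e <- as.numeric(vapply(fields, `[`, "", 3))
    val <- as.numeric(vapply(fields, `[`, "", 4))
    if (any(!chrom %in% assembly$chrom)) {
      stop("chromosome not in assembly: ",
           paste(unique(setdiff(chrom, assembly$chrom)), collapse = ", "))
    }
    if (any(s >= e)) stop("invalid bedGraph interval: start >= end")
    if (any(e > assembly_length(assembly, chrom))) {
      stop("bedGraph interval beyond chromosome end")
    }
    for (cm in unique(chrom)) {
      i <- chrom == cm
      v <- cov_values(cov, cm, strand)
      v <- v + prorata_bins(s[i], e[i], val[i], bin_size, length(v))
      cov$values[[strand]][[cm]] <- v
    }
  }
  refresh_total(cov)
}

## Distribute interval values (per-bin units) into nb bins pro-rata.
prorata_bins <- function(start, end, value, bin_size, nb) {
  out <- numeric(nb)
  for (j in seq_along(start)) {
    b0 <- floor(start[j] / bin_size)
    b1 <- ceiling(end[j] / bin_size) - 1
    bins <- b0:b1
    ov <- pmin(end[j], (bins + 1) * bin_size) - pmax(start[j], bins * bin_size)
    keep <- bins + 1 >= 1 & bins + 1 <= nb
    out[bins[keep] + 1] <- out[bins[keep] + 1] +
      value[j] * ov[keep] / bin_size
  }
  out
}

#' Write one strand of a coverage track as bedGraph
#'
#' Adjacent equal-valued bins are merged into one record; zero bins are
#' omitted. Reading the file back at the same bin size reproduces the track
#' exactly (when chromosome lengths are multiples of the bin size, so no
#' partial trailing bin is clipped).
#'
#' @param cov A `stranded_coverage`.
#' @param path Output path.
#' @param strand `"+"` or `"-"`.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(cov, path, strand = c("+", "-")) {
  strand <- match.arg(strand)
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in cov$assembly$chrom) {
    v <- cov_values(cov, cm, strand)
    if (length(v) == 0) next
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- c(0, ends[-length(ends)])
    keep <- r$values != 0
    if (!any(keep)) next
    clen <- assembly_length(cov$assembly, cm)
    lines <- sprintf("%s\t%d\t%d\t%.17g", cm,
                     as.integer(starts[keep] * cov$bin_size),
                     as.integer(pmin(ends[keep] * cov$bin_size, clen)),
                     r$values[keep])
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a spike-in count table
#'
#' @param path TSV with columns `species`, `abundance`, `condition`, `count`.
#' @return A tibble with those columns.
#' @export
read_spike_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    species = "c", abundance = "d",
                    condition = "c", count = "d"))
}
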