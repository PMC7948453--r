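#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a metagene profile
#'
#' @param x A `metagene_profile`.
#' @param ... Unused.
#' @return A tibble with `position` (bp relative to the anchor) and
#'   `density` (reads per million per bin).
#' @export
tidy.metagene_profile <- function(x, ...) {
  tibble::tibble(position = x$positions, density = x$values)
}

#' One-row summary of a metagene profile
#' @param x A `metagene_profile`.
#' @param ... Unused.
#' @return A tibble: anchor, window, bin size, number of genes, peak
#'   density.
#' @export
glance.metagene_profile <- function(x, ...) {
  tibble::tibble(anchor = x$anchor, window_start = x$window[1],
                 window_end = x$window[2], bin_size = x$bin_size,
                 n_genes = x$n_genes, peak_density = max(x$values))
}

#' Tidy a wave front
#' @param x A `wavefront`.
#' @param ... Unused.
#' @return A one-row tibble: `position`, `background`, `threshold`,
#'   `ci_low`, `ci_high` (NA when not bootstrapped).
#' @export
tidy.wavefront <- function(x, ...) {
  tibble::tibble(position = x$position, background = x$background,
                 threshold = x$threshold,
                 ci_low = if (is.null(x$ci)) NA_real_ else x$ci[1],
                 ci_high = if (is.null(x$ci)) NA_real_ else x$ci[2])
}

#' Tidy a rate estimate
#' @param x A `rate_estimate`.
#' @param ... Unused.
#' @return A one-row tibble: `rate` (kb/min), `method`, `ci_low`,
#'   `ci_high`.
#' @export
tidy.rate_estimate <- function(x, ...) {
  tibble::tibble(rate = x$rate, method = x$method,
                 ci_low = if (is.null(x$ci)) NA_real_ else x$ci[1],
                 ci_high = if (is.null(x$ci)) NA_real_ else x$ci[2])
}

#' @rdname tidy.rate_estimate
#' @export
glance.rate_estimate <- tidy.rate_estimate
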