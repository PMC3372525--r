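#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a PGLS fit
#'
#' @param x A `longscan_gls` object.
#' @param ... Unused.
#' @return A tibble with one row per model term: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @method tidy longscan_gls
#' @export
tidy.longscan_gls <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients),
         std.error = unname(x$se),
         statistic = unname(x$statistic),
         p.value = unname(x$p.value))
}

#' @rdname tidy.longscan_gls
#' @return For `glance()`: a one-row tibble with `nobs`, `df.residual`,
#'   `sigma2` and the `degenerate` flag.
#' @method glance longscan_gls
#' @export
glance.longscan_gls <- function(x, ...) {
  tibble(nobs = x$n, df.residual = x$df, sigma2 = x$sigma2,
         degenerate = x$degenerate)
}

#' Tidy a scan result
#'
#' `tidy()` returns the per-column table as a plain tibble; `glance()`
#' returns the scan-level counts and provenance hash.
#'
#' @param x A `longscan_scan` object.
#' @param ... Unused.
#' @method tidy longscan_scan
#' @export
tidy.longscan_scan <- function(x, ...) {
  as_tibble(x)
}

#' @rdname tidy.longscan_scan
#' @method glance longscan_scan
#' @export
glance.longscan_scan <- function(x, ...) {
  cnt <- attr(x, "counts")
  tibble(columns = cnt$columns, selected = cnt$selected, fit = cnt$fit,
         conserved = cnt$conserved,
         longevity_selected = cnt$longevity_selected,
         mass_selected = cnt$mass_selected,
         alpha = attr(x, "config")$alpha,
         reference = attr(x, "reference"),
         provenance = attr(x, "provenance"))
}
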