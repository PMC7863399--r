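#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Tidy methods for sympatric result objects
#'
#' Return the per-row content of a result object as a tibble: cells with
#' heights for occurrence distributions, coefficients for RUF fits,
#' per-individual proportions for activity tests, per-fold metrics for
#' cross-validation results, and long densities for overlap results.
#'
#' @param x A sympatric result object.
#' @param scale For `ruf_fit`: `"standardized"` (default) or `"raw"`.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy_sympatric
NULL

#' Glance methods for sympatric result objects
#'
#' One-row summaries: overlap coefficient, test statistics, fit diagnostics.
#'
#' @param x A sympatric result object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @name glance_sympatric
NULL
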