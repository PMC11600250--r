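#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a sort result into one row per spike
#'
#' @param x A `sort_result`.
#' @param ... Unused.
#' @return Tibble `spike`, `label`, `confidence` (the winning soft
#'   assignment).
#' @export
tidy.sort_result <- function(x, ...) {
  tibble::tibble(
    spike = seq_along(x$labels),
    label = x$labels,
    confidence = x$soft_assignments[cbind(seq_along(x$labels), x$labels)]
  )
}

#' One-row summary of a sort result
#'
#' @param x A `sort_result`.
#' @param ... Unused.
#' @export
glance.sort_result <- function(x, ...) {
  tibble::tibble(
    method = x$method, K = x$K, n_spikes = length(x$labels),
    converged = x$converged, n_iterations = x$n_iterations
  )
}

#' Tidy a benchmark result (per-set long table)
#'
#' @param x A `benchmark_result`.
#' @param ... Unused.
#' @export
tidy.benchmark_result <- function(x, ...) {
  x$per_set
}

#' Per-model summary of a benchmark result
#'
#' @param x A `benchmark_result`.
#' @param ... Unused.
#' @export
glance.benchmark_result <- function(x, ...) {
  x$summary
}

#' Tidy an accuracy report (cluster-to-neuron assignment)
#'
#' @param x An `accuracy_report`.
#' @param ... Unused.
#' @export
tidy.accuracy_report <- function(x, ...) {
  x$assignment
}
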