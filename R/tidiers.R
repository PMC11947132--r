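#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a MAIC weight set
#'
#' One row per patient: id, arm, raw weight and the weight rescaled to sum
#' to the number of patients.
#'
#' @param x A `maic_weights` object.
#' @param ... Unused.
#' @return A tibble with columns `id`, `arm`, `weight`, `weight_scaled`.
#' @method tidy maic_weights
#' @export
tidy.maic_weights <- function(x, ...) {
  tibble::tibble(id = x$id, arm = x$arm, weight = x$weights,
                 weight_scaled = x$weights * x$n / sum(x$weights))
}

#' One-row solver and ESS diagnostics for a MAIC weight set
#'
#' @param x A `maic_weights` object.
#' @param ... Unused.
#' @return A one-row tibble: patient count, ESS (total and per arm),
#'   convergence flag, iteration count, gradient max-norm, objective value.
#' @method glance maic_weights
#' @export
glance.maic_weights <- function(x, ...) {
  ess_arm <- as.list(stats::setNames(x$ess_by_arm,
                                     paste0("ess_", names(x$ess_by_arm))))
  tibble::tibble(n = x$n, ess_total = x$ess_total, !!!ess_arm,
                 converged = x$converged, iterations = x$iterations,
                 gradient_norm = x$gradient_norm,
                 objective_value = x$objective_value)
}

#' @method tidy indirect_result
#' @export
tidy.indirect_result <- function(x, ...) {
  dplyr::select(tibble::as_tibble(x), -"components")
}

#' @method glance indirect_result
#' @export
glance.indirect_result <- function(x, ...) {
  tibble::tibble(n_endpoints = nrow(x),
                 n_significant = sum(x$p_value < 0.05),
                 scales = paste(sort(unique(x$scale)), collapse = ","))
}
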