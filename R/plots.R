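#' Plot the distribution of MAIC weights by arm
#'
#' Histogram of rescaled weights (mean 1) faceted by arm, with the
#' per-arm effective sample size in the strip label. Long right tails are
#' the visual signature of ESS loss.
#'
#' @param object A `maic_weights` object.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot maic_weights
#' @export
autoplot.maic_weights <- function(object, bins = 30, ...) {
  tb <- generics::tidy(object)
  labs <- sprintf("%s (ESS %.1f)", names(object$ess_by_arm),
                  object$ess_by_arm)
  tb$arm_lab <- factor(labs[match(as.character(tb$arm),
                                  names(object$ess_by_arm))], levels = labs)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$weight_scaled)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35", colour = "white") +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$arm_lab)) +
    ggplot2::labs(x = "weight (rescaled to mean 1)", y = "patients",
                  title = "MAIC weight distribution") +
    ggplot2::theme_minimal()
}

#' Plot a before/after balance comparison
#'
#' Dot plot of pooled IPD values against the aggregate targets per
#' covariate, for one or two balance tables (e.g. before and after
#' matching).
#'
#' @param object A `balance_tbl` (treated as "after" when `before` is
#'   given).
#' @param before Optional second `balance_tbl` for the unweighted table.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot balance_tbl
#' @export
autoplot.balance_tbl <- function(object, before = NULL, ...) {
  tb <- dplyr::bind_rows(after = tibble::as_tibble(object),
                         before = if (!is.null(before)) tibble::as_tibble(before),
                         .id = "matching")
  tb <- dplyr::filter(tb, .data$group == "pooled")
  long <- tidyr::pivot_longer(tb, c("ipd_value", "agd_value"),
                              names_to = "source", values_to = "value")
  long$source <- ifelse(long$source == "ipd_value", "IPD (weighted)",
                        "AgD target")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$covariate,
                                     colour = .data$source,
                                     shape = .data$matching)) +
    ggplot2::geom_point(size = 2.5, position = ggplot2::position_dodge(0.4)) +
    ggplot2::labs(x = "pooled mean / proportion", y = NULL,
                  colour = NULL, shape = NULL,
                  title = "Baseline balance against aggregate targets") +
    ggplot2::theme_minimal()
}

#' Forest plot of anchored indirect-comparison results
#'
#' One row per endpoint with the combined estimate and 95% CI; odds-ratio
#' rows are drawn on a log x-axis reference of 1, difference rows on 0.
#'
#' @param object An `indirect_result` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot indirect_result
#' @export
autoplot.indirect_result <- function(object, ...) {
  tb <- dplyr::select(tibble::as_tibble(object), -"components")
  tb$endpoint <- factor(tb$endpoint, levels = rev(tb$endpoint))
  tb$null <- ifelse(tb$scale == "odds_ratio", 1, 0)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$estimate, y = .data$endpoint)) +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$null),
                        linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$scale), ncol = 1,
                        scales = "free") +
    ggplot2::labs(x = "anchored indirect estimate (95% CI)", y = NULL,
                  title = "Anchored indirect comparison") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.indirect_result
#' @param results An `indirect_result` tibble.
#' @export
plot_forest <- function(results, ...) {
  autoplot.indirect_result(results, ...)
}
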