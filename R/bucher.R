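z_norm <- 1.959964  # 97.5% normal quantile used for all 95% CIs

#' Anchored Bucher combination on the difference scale
#'
#' Combines two arm-versus-anchor contrasts from different trials into the
#' anchored indirect estimate of active-vs-active: the difference of the two
#' estimates, with variance the sum of the two variances. Orientation is
#' "first minus second", both contrasts oriented active-versus-anchor, so a
#' negative mean difference favors the first (IPD) treatment for
#' lower-is-better endpoints.
#'
#' @param c_active One-row `arm_contrast` for the IPD treatment (scale
#'   `"difference"`).
#' @param c_comparator One-row `arm_contrast` for the comparator treatment,
#'   same endpoint and scale.
#' @return A one-row `indirect_result` tibble: `endpoint`, `scale`,
#'   `estimate`, `ci_low`, `ci_high`, `se_combined`, `z`, `p_value`, plus a
#'   list column `components` holding the two inputs.
#' @export
bucher_difference <- function(c_active, c_comparator) {
  check_pair(c_active, c_comparator, "difference")
  est <- c_active$estimate - c_comparator$estimate
  se <- sqrt(c_active$se^2 + c_comparator$se^2)
  z <- est / se
  new_indirect_result(
    endpoint = c_active$endpoint, scale = "difference",
    estimate = est, ci_low = est - z_norm * se, ci_high = est + z_norm * se,
    se_combined = se, z = z,
    components = list(dplyr::bind_rows(c_active, c_comparator)))
}

#' Anchored Bucher combination on the odds-ratio scale
#'
#' As [bucher_difference()] but for binary endpoints: the two log-odds
#' contrasts are differenced and their variances summed on the log scale,
#' then the estimate and confidence bounds are exponentiated to the
#' odds-ratio scale. `se_combined` stays on the log scale.
#'
#' @param c_active,c_comparator One-row `arm_contrast`s on scale
#'   `"log_odds"`, same endpoint.
#' @return A one-row `indirect_result` tibble with scale `"odds_ratio"`.
#' @export
bucher_ratio <- function(c_active, c_comparator) {
  check_pair(c_active, c_comparator, "log_odds")
  d <- c_active$estimate - c_comparator$estimate
  se <- sqrt(c_active$se^2 + c_comparator$se^2)
  z <- d / se
  new_indirect_result(
    endpoint = c_active$endpoint, scale = "odds_ratio",
    estimate = exp(d),
    ci_low = exp(d - z_norm * se), ci_high = exp(d + z_norm * se),
    se_combined = se, z = z,
    components = list(dplyr::bind_rows(c_active, c_comparator)))
}

check_pair <- function(c1, c2, scale) {
  stopifnot(is.data.frame(c1), nrow(c1) == 1L,
            is.data.frame(c2), nrow(c2) == 1L)
  if (!identical(c1$endpoint, c2$endpoint)) {
    rlang::abort(sprintf("endpoint mismatch: `%s` vs `%s`",
                         c1$endpoint, c2$endpoint))
  }
  if (!identical(c1$scale, scale) || !identical(c2$scale, scale)) {
    rlang::abort(sprintf("both contrasts must be on scale \"%s\" (got \"%s\" and \"%s\")",
                         scale, c1$scale, c2$scale))
  }
  invisible(NULL)
}

new_indirect_result <- function(endpoint, scale, estimate, ci_low, ci_high,
                                se_combined, z, components) {
  tb <- tibble::tibble(endpoint = endpoint, scale = scale,
                       estimate = estimate,
                       ci_low = ci_low, ci_high = ci_high,
                       se_combined = se_combined, z = z,
                       p_value = 2 * stats::pnorm(-abs(z)),
                       components = components)
  class(tb) <- c("indirect_result", class(tb))
  tb
}

#' Combine all shared endpoints into an indirect-comparison table
#'
#' Matches IPD-derived contrasts to the comparator's published contrasts by
#' endpoint name and applies [bucher_difference()] (difference scale) or
#' [bucher_ratio()] (log-odds scale) to each pair. Endpoints present on only
#' one side are skipped with a message and recorded in the `skipped`
#' attribute.
#'
#' @param ipd_contrasts `arm_contrast` tibble of IPD-weighted contrasts.
#' @param published An `agd_summary` (its `contrasts` element is used) or an
#'   `arm_contrast` tibble of published contrasts.
#' @return An `indirect_result` tibble, one row per shared endpoint in the
#'   order of `ipd_contrasts`.
#' @export
compare_all <- function(ipd_contrasts, published) {
  pub <- if (inherits(published, "agd_summary")) published$contrasts
         else published
  shared <- ipd_contrasts$endpoint[ipd_contrasts$endpoint %in% pub$endpoint]
  skipped <- union(setdiff(ipd_contrasts$endpoint, pub$endpoint),
                   setdiff(pub$endpoint, ipd_contrasts$endpoint))
  for (s in skipped) {
    rlang::inform(sprintf("endpoint `%s` present in only one source; skipped", s))
  }
  out <- purrr::map_dfr(shared, function(ep) {
    c1 <- ipd_contrasts[ipd_contrasts$endpoint == ep, ][1, ]
    c2 <- pub[pub$endpoint == ep, ][1, ]
    if (identical(c1$scale, "log_odds")) {
      bucher_ratio(c1, c2)
    } else {
      bucher_difference(c1, c2)
    }
  })
  if (!nrow(out)) {
    out <- new_indirect_result(character(0), character(0), numeric(0),
                               numeric(0), numeric(0), numeric(0),
                               numeric(0), list())[0, ]
  }
  attr(out, "skipped") <- skipped
  class(out) <- unique(c("indirect_result", class(out)))
  out
}

#' Write indirect-comparison results as TSV and JSON
#'
#' The layout mirrors a published comparison table: per-trial estimate (SE)
#' columns next to the combined estimate with its 95% CI and p-value.
#'
#' @param results An `indirect_result` tibble.
#' @param path Output path without extension; `<path>.tsv` and `<path>.json`
#'   are written.
#' @return The flat table, invisibly.
#' @export
write_results <- function(results, path) {
  flat <- dplyr::mutate(
    dplyr::select(results, -"components"),
    ipd_estimate = purrr::map_dbl(results$components, ~ .x$estimate[1]),
    ipd_se = purrr::map_dbl(results$components, ~ .x$se[1]),
    comparator_estimate = purrr::map_dbl(results$components, ~ .x$estimate[2]),
    comparator_se = purrr::map_dbl(results$components, ~ .x$se[2]))
  readr::write_tsv(flat, paste0(path, ".tsv"))
  jsonlite::write_json(flat, paste0(path, ".json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(flat)
}
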