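#' Weighted mean/proportion summary of a baseline covariate
#'
#' Weighted mean `sum(w x) / sum(w)` with a weighted SD whose denominator is
#' based on the effective sample size, `var = sum(w (x - xbar)^2) / sum(w) *
#' ESS / (ESS - 1)`, so that unit weights reproduce the ordinary unbiased
#' mean and SD exactly.
#'
#' @param data Patient-level tibble.
#' @param weights Nonnegative per-patient weights (recycled unit weights if
#'   `NULL`).
#' @param covariate Column to summarize.
#' @param by_arm If `TRUE`, one row per arm plus the pooled row; otherwise
#'   pooled only.
#' @return A tibble with columns `group`, `value`, `sd`, `ess`.
#' @export
weighted_summary <- function(data, weights = NULL, covariate, by_arm = FALSE) {
  w <- resolve_weights(data, weights)
  x <- data[[covariate]]
  if (is.null(x)) rlang::abort(sprintf("covariate `%s` not found", covariate))
  groups <- if (by_arm) {
    c(stats::setNames(as.character(data$arm), NULL) |> unique() |> sort(),
      "pooled")
  } else "pooled"
  purrr::map_dfr(groups, function(g) {
    idx <- if (g == "pooled") rep(TRUE, length(x)) else data$arm == g
    wg <- w[idx]
    if (sum(wg) <= 0) {
      rlang::abort(sprintf("group `%s` has zero total weight", g))
    }
    xg <- x[idx]
    m <- sum(wg * xg) / sum(wg)
    ess <- effective_sample_size(wg)
    v <- sum(wg * (xg - m)^2) / sum(wg)
    sd_out <- if (ess > 1) sqrt(v * ess / (ess - 1)) else NA_real_
    tibble::tibble(group = g, value = m, sd = sd_out, ess = ess)
  })
}

resolve_weights <- function(data, weights) {
  if (is.null(weights)) return(rep(1, nrow(data)))
  if (inherits(weights, "maic_weights")) weights <- weights$weights
  if (length(weights) != nrow(data)) {
    rlang::abort("`weights` must have one entry per patient")
  }
  if (any(weights < 0) || anyNA(weights)) {
    rlang::abort("`weights` must be nonnegative and complete")
  }
  weights
}

#' Two-sample Wald test from summary statistics
#'
#' `z = (mean1 - mean2) / sqrt(sd1^2/n1 + sd2^2/n2)` with a two-sided normal
#' p-value; the comparison the published before/after-matching baseline
#' tables use for continuous covariates. Non-integer `n` (an effective
#' sample size) is allowed.
#'
#' @param mean1,sd1,n1 Summary of the first sample.
#' @param mean2,sd2,n2 Summary of the second sample.
#' @return A one-row tibble: `statistic` (z) and `p_value`.
#' @export
wald_two_sample <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 <= 0 || n2 <= 0) rlang::abort("sample sizes must be positive")
  if (sd1 <= 0 || sd2 <= 0) rlang::abort("SDs must be positive")
  z <- (mean1 - mean2) / sqrt(sd1^2 / n1 + sd2^2 / n2)
  tibble::tibble(statistic = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Chi-square or Fisher exact test on a 2 x k count table
#'
#' Pearson chi-square without continuity correction when every expected cell
#' count is at least 5; otherwise the Fisher exact test (two-sided by
#' summation of tables at most as probable as the observed one). The
#' returned `test_name` records which test ran.
#'
#' @param count_table A 2 x k matrix of nonnegative counts.
#' @return A one-row tibble: `test_name`, `statistic` (NA for Fisher) and
#'   `p_value`.
#' @export
categorical_test <- function(count_table) {
  tab <- as.matrix(count_table)
  if (any(tab < 0)) rlang::abort("counts must be nonnegative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    rlang::abort("test undefined: a table margin is zero")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(expected >= 5)) {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    tibble::tibble(test_name = "chi_square",
                   statistic = unname(ct$statistic),
                   p_value = unname(ct$p.value))
  } else {
    ft <- stats::fisher.test(round(tab))
    tibble::tibble(test_name = "fisher", statistic = NA_real_,
                   p_value = unname(ft$p.value))
  }
}

#' Baseline comparison table between IPD and aggregate targets
#'
#' Builds the before-matching (unit weights) or after-matching (MAIC
#' weights) analogue of a published baseline-characteristics table: per-arm
#' and pooled IPD summaries next to the aggregate targets, with a Wald test
#' for continuous covariates and a chi-square test (Fisher exact when any
#' expected count is below 5) for binary ones, computed on the pooled
#' grouping. After matching, effective sample sizes replace raw counts in
#' the tests, and binary counts are reconstructed as `round(p * n)`.
#'
#' @param data Patient-level tibble.
#' @param targets An `agd_summary` carrying the comparator's pooled baseline
#'   values (and SDs for continuous covariates).
#' @param covariates Covariates to tabulate.
#' @param weights `NULL` for the before-matching table, or a `maic_weights`
#'   object / numeric vector for the after-matching table.
#' @return A `balance_tbl` tibble: one row per covariate per grouping
#'   (active, anchor, pooled), with columns `covariate`, `kind`, `group`,
#'   `ipd_value`, `ipd_sd`, `ipd_n`, `agd_value`, `agd_sd`, `agd_n`,
#'   `test_name`, `statistic`, `p_value` (tests on the pooled rows only).
#' @export
balance_table <- function(data, targets, covariates = matching_covariates(),
                          weights = NULL) {
  stopifnot(inherits(targets, "agd_summary"))
  w <- resolve_weights(data, weights)
  agd_n <- targets$n_active + targets$n_anchor
  tt <- targets$baseline_targets

  rows <- purrr::map_dfr(covariates, function(cv) {
    trow <- tt[tt$covariate == cv, ]
    if (!nrow(trow)) {
      rlang::abort(sprintf("covariate `%s` absent from targets", cv))
    }
    smry <- weighted_summary(data, w, cv, by_arm = TRUE)
    kind <- if (all(data[[cv]] %in% c(0, 1))) "binary" else "continuous"
    out <- dplyr::mutate(smry,
      covariate = cv, kind = kind,
      agd_value = trow$value,
      agd_sd = trow$sd,
      agd_n = agd_n,
      test_name = NA_character_, statistic = NA_real_, p_value = NA_real_)
    pooled <- out$group == "pooled"
    if (kind == "continuous") {
      if (is.na(trow$sd)) {
        rlang::abort(sprintf("continuous covariate `%s` needs a target SD for the Wald test", cv))
      }
      tst <- wald_two_sample(out$value[pooled], out$sd[pooled],
                             out$ess[pooled], trow$value, trow$sd, agd_n)
      out$test_name[pooled] <- "wald"
      out$statistic[pooled] <- tst$statistic
      out$p_value[pooled] <- tst$p_value
    } else {
      ipd_events <- round(out$value[pooled] * out$ess[pooled])
      agd_events <- round(trow$value * agd_n)
      tab <- rbind(ipd = c(ipd_events, round(out$ess[pooled]) - ipd_events),
                   agd = c(agd_events, agd_n - agd_events))
      if (any(colSums(tab) == 0) &&
            abs(out$value[pooled] - trow$value) < 1e-12) {
        # both proportions at the same boundary (all 0 or all 1): the table
        # margin collapses and no test is informative — report no difference
        out$test_name[pooled] <- "chi_square"
        out$statistic[pooled] <- 0
        out$p_value[pooled] <- 1
      } else {
        tst <- categorical_test(tab)
        out$test_name[pooled] <- tst$test_name
        out$statistic[pooled] <- tst$statistic
        out$p_value[pooled] <- tst$p_value
      }
    }
    out
  })

  out <- dplyr::select(rows, "covariate", "kind", "group",
                       ipd_value = "value", ipd_sd = "sd", ipd_n = "ess",
                       "agd_value", "agd_sd", "agd_n",
                       "test_name", "statistic", "p_value")
  class(out) <- c("balance_tbl", class(out))
  out
}

#' Write a balance table (or before/after pair) to TSV and JSON
#'
#' @param before,after `balance_tbl` tibbles; `after` may be `NULL`.
#' @param path Output path without extension; `<path>.tsv` and `<path>.json`
#'   are written. When both tables are given they are stacked with a
#'   `matching` column.
#' @return The stacked tibble, invisibly.
#' @export
write_balance <- function(before, after = NULL, path) {
  tb <- dplyr::bind_rows(before = before, after = after, .id = "matching")
  readr::write_tsv(tb, paste0(path, ".tsv"))
  jsonlite::write_json(tb, paste0(path, ".json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(tb)
}
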