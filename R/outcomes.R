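#' Construct an arm-versus-anchor contrast
#'
#' One endpoint's treatment-versus-placebo estimate with its standard error
#' on a declared scale. Published comparator contrasts are entered this way;
#' IPD-derived contrasts come from [weighted_ancova()] and
#' [weighted_logodds()].
#'
#' @param endpoint Endpoint name.
#' @param estimate Estimate (endpoint units for `difference`, log odds for
#'   `log_odds`).
#' @param se Standard error on the same scale; must be positive.
#' @param scale `"difference"` or `"log_odds"`.
#' @param source `"published"` or `"ipd_weighted"`.
#' @param n_or_ess Sample size (or effective sample size) behind the
#'   estimate.
#' @return A one-row `arm_contrast` tibble.
#' @export
arm_contrast <- function(endpoint = character(0), estimate = numeric(0),
                         se = numeric(0),
                         scale = rep("difference", length(endpoint)),
                         source = rep("published", length(endpoint)),
                         n_or_ess = rep(NA_real_, length(endpoint))) {
  if (length(se) && any(se <= 0)) rlang::abort("`se` must be positive")
  if (length(scale) && !all(scale %in% c("difference", "log_odds"))) {
    rlang::abort('`scale` must be "difference" or "log_odds"')
  }
  tb <- tibble::tibble(endpoint = as.character(endpoint),
                       scale = as.character(scale),
                       estimate = as.numeric(estimate),
                       se = as.numeric(se),
                       source = as.character(source),
                       n_or_ess = as.numeric(n_or_ess),
                       model_terms = rep(list(character(0)), length(endpoint)))
  class(tb) <- c("arm_contrast", class(tb))
  tb
}

#' Weighted ANCOVA arm contrast for a continuous endpoint
#'
#' Weighted least squares of the endpoint change on the treatment indicator,
#' study-center fixed effects and baseline OFF time (the covariance model
#' behind published least-squares means). Under this parameterization — a
#' single treatment coefficient, no treatment-by-center interaction — the
#' treatment coefficient *is* the least-squares-mean difference between
#' arms. The default standard error is a heteroskedasticity-robust sandwich
#' (HC0) treating the weights as fixed; a patient-level bootstrap that
#' re-estimates the MAIC weights in every resample is available.
#'
#' @param data Patient-level tibble with `arm` and the endpoint.
#' @param weights Per-patient weights (a numeric vector or `maic_weights`);
#'   `NULL` for unit weights.
#' @param endpoint Name of the endpoint-change column.
#' @param adjusters Adjustment terms: any of `"center"` and
#'   `"off_baseline"`. Centers with a single observed level are dropped.
#' @param se_method `"sandwich"` (default) or `"bootstrap"`.
#' @param targets,covariates For `se_method = "bootstrap"`: the matching
#'   targets and covariate list, so the weights are re-estimated per
#'   resample. If omitted, weights are resampled alongside patients but not
#'   re-fit.
#' @param resamples Bootstrap resample count.
#' @param seed Bootstrap seed.
#' @return A one-row `arm_contrast` tibble (scale `"difference"`), with
#'   `n_or_ess` the effective sample size of the weights used.
#' @export
weighted_ancova <- function(data, weights = NULL, endpoint,
                            adjusters = c("center", "off_baseline"),
                            se_method = c("sandwich", "bootstrap"),
                            targets = NULL, covariates = matching_covariates(),
                            resamples = 1000L, seed = 1L) {
  se_method <- rlang::arg_match(se_method)
  w <- resolve_weights(data, weights)
  fit <- fit_ancova(data, w, endpoint, adjusters)
  est <- unname(stats::coef(fit$model)["armactive"])
  vc <- sandwich::vcovHC(fit$model, type = "HC0")
  se <- sqrt(vc["armactive", "armactive"])

  if (se_method == "bootstrap") {
    if (resamples < 100L) rlang::abort("use at least 100 bootstrap resamples")
    ests <- withr::with_seed(seed, {
      vapply(seq_len(resamples), function(i) {
        idx <- sample.int(nrow(data), replace = TRUE)
        d <- data[idx, , drop = FALSE]
        wb <- if (!is.null(targets)) {
          estimate_weights(d, targets, covariates)$weights
        } else {
          w[idx]
        }
        f <- fit_ancova(d, wb, endpoint, adjusters, refit = TRUE)
        unname(stats::coef(f$model)["armactive"])
      }, numeric(1))
    })
    se <- stats::sd(ests)
  }

  out <- arm_contrast(endpoint = endpoint, estimate = est, se = se,
                      scale = "difference", source = "ipd_weighted",
                      n_or_ess = effective_sample_size(w))
  out$model_terms <- list(fit$terms)
  out
}

fit_ancova <- function(data, w, endpoint, adjusters, refit = FALSE) {
  if (!endpoint %in% names(data)) {
    rlang::abort(sprintf("endpoint `%s` not found in data", endpoint))
  }
  if (!is.numeric(data[[endpoint]])) {
    rlang::abort(sprintf("endpoint `%s` must be numeric", endpoint))
  }
  arms <- droplevels(factor(data$arm, levels = c("anchor", "active")))
  if (nlevels(arms) < 2L) rlang::abort("both arms must be present")
  if (tapply(w, arms, sum)[["active"]] <= 0 ||
        tapply(w, arms, sum)[["anchor"]] <= 0) {
    rlang::abort("an arm has zero total weight (zero ESS)")
  }
  terms <- "arm"
  d <- tibble::tibble(.y = data[[endpoint]], arm = arms, .w = w)
  if ("center" %in% adjusters && "center" %in% names(data)) {
    cf <- droplevels(factor(data$center))
    if (nlevels(cf) > 1L) {
      d$center <- cf
      terms <- c(terms, "center")
    }
  }
  if ("off_baseline" %in% adjusters && "off_baseline" %in% names(data)) {
    d$off_baseline <- data$off_baseline
    terms <- c(terms, "off_baseline")
  }
  fml <- stats::reformulate(terms, response = ".y")
  model <- stats::lm(fml, data = d, weights = .w)
  cf <- stats::coef(model)
  if (anyNA(cf)) {
    if (refit) {
      # inside a bootstrap resample, retry without center effects rather
      # than failing the whole bootstrap on a resample that lost a center
      return(fit_ancova(data, w, endpoint, setdiff(adjusters, "center")))
    }
    rlang::abort(paste0("ANCOVA design is rank deficient; aliased term(s): ",
                        paste(names(cf)[is.na(cf)], collapse = ", ")))
  }
  list(model = model, terms = terms)
}

#' Weighted log-odds arm contrast for a binary safety endpoint
#'
#' Forms the weighted 2x2 table of effective counts (sums of weights by arm
#' and event status), rescales each arm's cells to sum to that arm's
#' effective sample size — so that precision reflects the information
#' actually carried by the weights, and the result is invariant to weight
#' rescaling — and returns the log odds ratio `log(ad/bc)` with
#' `se = sqrt(1/a + 1/b + 1/c + 1/d)`. If any rescaled cell is zero, the
#' Haldane-Anscombe correction adds 0.5 to every cell and the contrast is
#' flagged.
#'
#' @inheritParams weighted_ancova
#' @param event_flag Name of the 0/1 event column.
#' @return A one-row `arm_contrast` tibble (scale `"log_odds"`) with an
#'   extra logical column `continuity_correction`.
#' @export
weighted_logodds <- function(data, weights = NULL, event_flag) {
  w <- resolve_weights(data, weights)
  x <- data[[event_flag]]
  if (is.null(x)) rlang::abort(sprintf("endpoint `%s` not found", event_flag))
  if (!all(x %in% c(0, 1))) {
    rlang::abort(sprintf("`%s` must be a 0/1 event flag", event_flag))
  }
  arms <- factor(data$arm, levels = c("anchor", "active"))
  if (any(table(arms) == 0)) rlang::abort("both arms must be present")

  cells <- vapply(c("active", "anchor"), function(a) {
    idx <- arms == a
    if (sum(w[idx]) <= 0) {
      rlang::abort(sprintf("arm `%s` has zero total weight", a))
    }
    ess <- effective_sample_size(w[idx])
    k <- ess / sum(w[idx])
    c(event = sum(w[idx & x == 1]) * k, none = sum(w[idx & x == 0]) * k)
  }, numeric(2))
  a <- cells["event", "active"]; b <- cells["none", "active"]
  c_ <- cells["event", "anchor"]; d <- cells["none", "anchor"]

  corrected <- any(c(a, b, c_, d) == 0)
  if (corrected) {
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
  }
  out <- arm_contrast(endpoint = event_flag,
                      estimate = log((a * d) / (b * c_)),
                      se = sqrt(1 / a + 1 / b + 1 / c_ + 1 / d),
                      scale = "log_odds", source = "ipd_weighted",
                      n_or_ess = effective_sample_size(w))
  out$continuity_correction <- corrected
  out
}

#' Write arm contrasts as JSON records
#' @param contrasts An `arm_contrast` tibble (any number of rows).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contrasts <- function(contrasts, path) {
  obj <- dplyr::mutate(contrasts,
                       model_terms = purrr::map(.data$model_terms, identity))
  jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}
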