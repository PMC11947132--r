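#' Simulate individual patient data for a trial scenario
#'
#' Draws one realization of the trial described by `scenario`: baseline
#' covariates from truncated normals (baseline OFF time resampled until it
#' meets the inclusion threshold), endpoint changes from the scenario's
#' linear outcome model with center effects and a shared latent severity
#' factor, and Bernoulli safety flags with arm-specific probabilities.
#' Identical `(scenario, seed)` gives bit-identical output.
#'
#' @param scenario A [trial_scenario()].
#' @param seed Integer seed for this realization (independent of the
#'   scenario-level seed that fixes center effects).
#' @param max_tries Retry cap per patient for rejection sampling of truncated
#'   covariates.
#'
#' @return A tibble with one row per patient: `id`, `arm` (factor,
#'   anchor/active), `center`, the baseline covariates `age`, `male`, `bmi`,
#'   `off_baseline`, the seven endpoint change scores and the three safety
#'   flags.
#' @export
simulate_trial <- function(scenario, seed = 1L, max_tries = 1000L) {
  validate_scenario(scenario)
  n <- scenario$n_active + scenario$n_anchor

  # center effects belong to the scenario, not the realization
  center_eff <- withr::with_seed(scenario$seed, {
    matrix(stats::rnorm(scenario$n_centers * length(efficacy_endpoints()),
                        sd = rep(scenario$center_sd_frac * scenario$noise_sd,
                                 each = scenario$n_centers)),
           nrow = scenario$n_centers,
           dimnames = list(NULL, efficacy_endpoints()))
  })

  withr::with_seed(seed, {
    arm <- factor(rep(c("active", "anchor"),
                      c(scenario$n_active, scenario$n_anchor)),
                  levels = c("anchor", "active"))
    treat <- as.integer(arm == "active")
    center <- factor(sample.int(scenario$n_centers, n, replace = TRUE),
                     levels = seq_len(scenario$n_centers))

    age <- rnorm_truncated(n, scenario$age_mean, scenario$age_sd, 18, 90,
                           max_tries, "age")
    bmi <- rnorm_truncated(n, scenario$bmi_mean, scenario$bmi_sd, 13, 45,
                           max_tries, "bmi")
    off_baseline <- rnorm_truncated(n, scenario$off_mean, scenario$off_sd,
                                    scenario$off_min_inclusion, Inf,
                                    max_tries, "off_baseline")
    male <- stats::rbinom(n, 1L, scenario$male_prop)

    covs <- cbind(age = age, male = male, bmi = bmi,
                  off_baseline = off_baseline)
    latent <- stats::rnorm(n)
    lambda <- scenario$latent_loading

    changes <- lapply(efficacy_endpoints(), function(ep) {
      mc <- scenario$modifier_coeffs[[ep]]
      mod_term <- if (is.null(mc)) 0 else {
        drop(covs[, names(mc), drop = FALSE] %*% mc) * treat
      }
      eps <- stats::rnorm(n)
      scenario$effects[[ep]] * treat +
        scenario$baseline_slope[[ep]] * off_baseline +
        mod_term +
        center_eff[as.integer(center), ep] +
        scenario$noise_sd[[ep]] * (lambda * latent + sqrt(1 - lambda^2) * eps)
    })
    names(changes) <- efficacy_endpoints()

    flags <- lapply(scenario$event_probs, function(p) {
      stats::rbinom(n, 1L, ifelse(treat == 1L, p[["active"]], p[["anchor"]]))
    })

    tibble::tibble(
      id = sprintf("pt%04d", seq_len(n)),
      arm = arm, center = center,
      age = age, male = male, bmi = bmi, off_baseline = off_baseline,
      !!!changes, !!!flags)
  })
}

rnorm_truncated <- function(n, mean, sd, lower, upper, max_tries, what) {
  x <- stats::rnorm(n, mean, sd)
  tries <- 0L
  repeat {
    bad <- which(x < lower | x > upper)
    if (!length(bad)) return(x)
    tries <- tries + 1L
    if (tries > max_tries) {
      rlang::abort(sprintf(
        "rejection sampling for `%s` failed after %d tries: bounds [%g, %g] are far outside N(%g, %g)",
        what, max_tries, lower, upper, mean, sd))
    }
    x[bad] <- stats::rnorm(length(bad), mean, sd)
  }
}

#' Summarize an IPD trial into aggregate comparator data
#'
#' Collapses a patient-level table into the published-summary form an
#' aggregate-data (AgD) comparator trial would report: pooled (both-arm)
#' baseline means/proportions with SDs, and arm-versus-anchor contrasts per
#' endpoint — ordinary (unit-weight) ANCOVA least-squares mean differences
#' for continuous endpoints and unweighted log-odds contrasts for binary
#' safety endpoints.
#'
#' @param ipd Patient-level tibble as produced by [simulate_trial()].
#' @param endpoints Endpoint columns to publish contrasts for; binary 0/1
#'   columns are treated as safety endpoints on the log-odds scale.
#' @param covariate_names Baseline covariates to publish as matching targets.
#' @param label Trial label carried on the summary.
#'
#' @return An `agd_summary`: a list with `label`, `n_active`, `n_anchor`,
#'   `baseline_targets` (tibble: covariate, kind, value, sd) and `contrasts`
#'   (a tibble of published arm contrasts).
#' @export
aggregate_trial <- function(ipd,
                            endpoints = c(efficacy_endpoints(),
                                          safety_endpoints()),
                            covariate_names = matching_covariates(),
                            label = "comparator") {
  check_ipd(ipd, require_endpoints = intersect(endpoints, names(ipd)))
  n_by_arm <- table(ipd$arm)
  if (any(n_by_arm == 0)) {
    rlang::abort("both arms must contain at least one patient")
  }

  targets <- purrr::map_dfr(covariate_names, function(cv) {
    x <- ipd[[cv]]
    if (is.null(x)) rlang::abort(sprintf("covariate `%s` not found in ipd", cv))
    if (stats::var(x) == 0) {
      # a balance test against a constant column is non-identifiable
      if (!all(x %in% c(0, 1))) {
        rlang::abort(sprintf("covariate `%s` has zero variance; balance tests on it are non-identifiable", cv))
      }
    }
    binary <- all(x %in% c(0, 1))
    tibble::tibble(covariate = cv,
                   kind = if (binary) "binary" else "continuous",
                   value = mean(x),
                   sd = if (binary) NA_real_ else stats::sd(x))
  })

  unit_w <- rep(1, nrow(ipd))
  contrasts <- purrr::map_dfr(endpoints, function(ep) {
    x <- ipd[[ep]]
    if (is.null(x)) rlang::abort(sprintf("endpoint `%s` not found in ipd", ep))
    if (all(x %in% c(0, 1))) {
      out <- weighted_logodds(ipd, unit_w, ep)
    } else {
      out <- weighted_ancova(ipd, unit_w, ep)
    }
    out$source <- "published"
    out$model_terms <- list(character(0))
    out
  })

  new_agd_summary(label = label,
                  n_active = as.integer(n_by_arm[["active"]]),
                  n_anchor = as.integer(n_by_arm[["anchor"]]),
                  baseline_targets = targets,
                  contrasts = contrasts)
}

#' Construct an aggregate-data summary by hand
#'
#' Use this to enter a published comparator trial directly: its per-arm
#' sample sizes, pooled baseline means/proportions (with SDs where printed)
#' and the published arm-versus-placebo contrasts.
#'
#' @param label Trial label.
#' @param n_active,n_anchor Arm sizes.
#' @param baseline_targets Tibble with columns `covariate`, `kind`
#'   ("continuous"/"binary"), `value` (pooled mean or proportion) and `sd`
#'   (NA when unavailable).
#' @param contrasts Tibble of published contrasts as built by
#'   [arm_contrast()]; may be empty.
#' @return An `agd_summary` object.
#' @export
new_agd_summary <- function(label, n_active, n_anchor, baseline_targets,
                            contrasts = arm_contrast()[0, ]) {
  stopifnot(is.data.frame(baseline_targets),
            all(c("covariate", "kind", "value") %in% names(baseline_targets)))
  if (!"sd" %in% names(baseline_targets)) baseline_targets$sd <- NA_real_
  if (anyDuplicated(baseline_targets$covariate)) {
    rlang::abort("each covariate may appear only once in `baseline_targets`")
  }
  is_bin <- baseline_targets$kind == "binary"
  if (any(baseline_targets$value[is_bin] < 0 |
            baseline_targets$value[is_bin] > 1)) {
    rlang::abort("binary targets must be proportions in [0, 1]")
  }
  if (any(!is.na(baseline_targets$sd) & baseline_targets$sd <= 0)) {
    rlang::abort("target SDs must be > 0 when given")
  }
  structure(list(label = label,
                 n_active = as.integer(n_active),
                 n_anchor = as.integer(n_anchor),
                 baseline_targets = tibble::as_tibble(baseline_targets),
                 contrasts = tibble::as_tibble(contrasts)),
            class = "agd_summary")
}

#' @export
print.agd_summary <- function(x, ...) {
  cat(sprintf("<agd_summary> %s: active n=%d, anchor n=%d\n",
              x$label, x$n_active, x$n_anchor))
  cat("baseline targets:\n")
  print(x$baseline_targets, n = Inf)
  if (nrow(x$contrasts)) {
    cat("published contrasts:\n")
    print(dplyr::select(x$contrasts, "endpoint", "scale", "estimate", "se"),
          n = Inf)
  }
  invisible(x)
}

#' Read or write an aggregate-data summary as JSON
#' @param path File path.
#' @param agd An `agd_summary`.
#' @return `read_agd()` returns an `agd_summary`; `write_agd()` returns
#'   `path` invisibly.
#' @export
read_agd <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  contrasts <- if (!is.null(raw$contrasts) && length(raw$contrasts)) {
    tb <- tibble::as_tibble(raw$contrasts)
    tb$model_terms <- rep(list(character(0)), nrow(tb))
    tb
  } else arm_contrast()[0, ]
  new_agd_summary(label = raw$label, n_active = raw$n_active,
                  n_anchor = raw$n_anchor,
                  baseline_targets = tibble::as_tibble(raw$baseline_targets),
                  contrasts = contrasts)
}

#' @rdname read_agd
#' @export
write_agd <- function(agd, path) {
  stopifnot(inherits(agd, "agd_summary"))
  obj <- list(label = agd$label, n_active = agd$n_active,
              n_anchor = agd$n_anchor,
              baseline_targets = agd$baseline_targets,
              contrasts = dplyr::select(agd$contrasts,
                                        -dplyr::any_of("model_terms")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null", pretty = TRUE)
  invisible(path)
}
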