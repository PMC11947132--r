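#' Efficacy and safety endpoints recognised by the simulator
#'
#' Continuous endpoints are analysed as changes from baseline (negative is
#' improvement for all of them: OFF hours, UPDRS III points, PDQ-39 points).
#' Safety endpoints are binary event flags.
#'
#' @return A character vector of endpoint column names.
#' @export
efficacy_endpoints <- function() {
  c("off_change", "updrs3_change", "pdq39_summary_change", "adl_change",
    "emotional_change", "mobility_change", "stigma_change")
}

#' @rdname efficacy_endpoints
#' @export
safety_endpoints <- function() {
  c("ae", "sae", "dcae")
}

#' Baseline covariates available for matching
#' @return A character vector of covariate column names.
#' @export
matching_covariates <- function() {
  c("age", "male", "bmi", "off_baseline")
}

default_effects <- function() {
  c(off_change = -1.1, updrs3_change = -4.5, pdq39_summary_change = -4.0,
    adl_change = -6.7, emotional_change = -5.6, mobility_change = -6.0,
    stigma_change = -6.4)
}

default_baseline_slope <- function() {
  c(off_change = -0.3, updrs3_change = -0.5, pdq39_summary_change = -0.4,
    adl_change = -0.4, emotional_change = -0.4, mobility_change = -0.4,
    stigma_change = -0.4)
}

# residual SDs consistent with arm-contrast standard errors of roughly
# 0.28 h (OFF) up to 2 points (PDQ-39 dimensions) at ~150 patients per arm
default_noise_sd <- function() {
  c(off_change = 2.4, updrs3_change = 8.3, pdq39_summary_change = 9.4,
    adl_change = 15.1, emotional_change = 14.6, mobility_change = 13.6,
    stigma_change = 17.2)
}

default_event_probs <- function() {
  list(ae = c(anchor = 0.50, active = 0.60),
       sae = c(anchor = 0.04, active = 0.06),
       dcae = c(anchor = 0.05, active = 0.04))
}

#' Define a two-arm placebo-controlled trial scenario
#'
#' A scenario fixes the data-generating process for one randomized trial of an
#' active treatment versus a placebo anchor in patients with motor
#' fluctuations: baseline covariate distributions (age, sex, BMI, daily OFF
#' time at baseline, truncated at an inclusion threshold), true conditional
#' treatment effects per endpoint, optional covariate-by-treatment effect
#' modification, multicenter structure, and Bernoulli safety-event
#' probabilities. Defaults emulate a 305-patient safinamide-like trial
#' (OFF-time inclusion threshold 1.5 h/day).
#'
#' Endpoint changes are generated as
#' `effect * treat + slope * off_baseline + sum(modifier * covariate * treat)
#'  + center effect + noise`,
#' where the noise of the different endpoints shares a latent per-patient
#' severity factor so that quality-of-life dimensions co-move.
#'
#' @param n_active,n_anchor Patients per arm.
#' @param n_centers Number of study centers (patients assigned uniformly).
#' @param age_mean,age_sd Age distribution in years (normal truncated to
#'   18-90).
#' @param male_prop Proportion of male patients.
#' @param bmi_mean,bmi_sd BMI distribution in kg/m^2 (truncated to 13-45).
#' @param off_mean,off_sd Baseline daily OFF time in hours (normal, resampled
#'   until at least `off_min_inclusion`).
#' @param off_min_inclusion Inclusion threshold on baseline OFF time (h/day).
#' @param effects Named vector of true treatment effects, one per continuous
#'   endpoint, in endpoint units.
#' @param baseline_slope Named vector: coefficient of baseline OFF time on
#'   each endpoint change.
#' @param modifier_coeffs Named list: endpoint -> named vector of
#'   covariate-by-treatment interaction coefficients (effect modification).
#' @param noise_sd Named vector of residual SDs per endpoint.
#' @param event_probs Named list: safety endpoint -> c(anchor = p0,
#'   active = p1) event probabilities, each in (0, 1).
#' @param center_sd_frac Center-effect SD as a fraction of each endpoint's
#'   `noise_sd`.
#' @param latent_loading Loading of the shared latent severity factor in each
#'   endpoint's residual (marginal residual SD is preserved).
#' @param seed Scenario-level seed; fixes the center effects so the same
#'   scenario always describes the same centers.
#'
#' @return An object of class `trial_scenario`.
#' @seealso [simulate_trial()], [make_paired_scenarios()]
#' @export
trial_scenario <- function(n_active = 151L,
                           n_anchor = 154L,
                           n_centers = 10L,
                           age_mean = 61.6, age_sd = 9.3,
                           male_prop = 0.58,
                           bmi_mean = 23.9, bmi_sd = 3.0,
                           off_mean = 5.7, off_sd = 3.0,
                           off_min_inclusion = 1.5,
                           effects = default_effects(),
                           baseline_slope = default_baseline_slope(),
                           modifier_coeffs = list(),
                           noise_sd = default_noise_sd(),
                           event_probs = default_event_probs(),
                           center_sd_frac = 0.2,
                           latent_loading = 0.3,
                           seed = 1L) {
  eff <- default_effects()
  eff[names(effects)] <- effects
  slope <- default_baseline_slope()
  slope[names(baseline_slope)] <- baseline_slope
  nsd <- default_noise_sd()
  nsd[names(noise_sd)] <- noise_sd
  ep <- default_event_probs()
  ep[names(event_probs)] <- event_probs

  scen <- structure(
    list(n_active = as.integer(n_active), n_anchor = as.integer(n_anchor),
         n_centers = as.integer(n_centers),
         age_mean = age_mean, age_sd = age_sd, male_prop = male_prop,
         bmi_mean = bmi_mean, bmi_sd = bmi_sd,
         off_mean = off_mean, off_sd = off_sd,
         off_min_inclusion = off_min_inclusion,
         effects = eff, baseline_slope = slope,
         modifier_coeffs = modifier_coeffs, noise_sd = nsd,
         event_probs = ep, center_sd_frac = center_sd_frac,
         latent_loading = latent_loading, seed = as.integer(seed)),
    class = "trial_scenario")
  validate_scenario(scen)
  scen
}

validate_scenario <- function(scen) {
  if (scen$n_active < 1L || scen$n_anchor < 1L) {
    rlang::abort("arm sizes `n_active` and `n_anchor` must be at least 1")
  }
  if (scen$n_centers < 1L) rlang::abort("`n_centers` must be at least 1")
  sds <- c(age_sd = scen$age_sd, bmi_sd = scen$bmi_sd, off_sd = scen$off_sd,
           scen$noise_sd)
  if (any(sds <= 0)) {
    rlang::abort(paste0("all SDs must be > 0; offending: ",
                        paste(names(sds)[sds <= 0], collapse = ", ")))
  }
  if (scen$male_prop < 0 || scen$male_prop > 1) {
    rlang::abort("`male_prop` must lie in [0, 1]")
  }
  if (scen$off_min_inclusion < 0) {
    rlang::abort("`off_min_inclusion` must be nonnegative")
  }
  probs <- unlist(scen$event_probs)
  if (any(probs <= 0 | probs >= 1)) {
    rlang::abort("safety event probabilities must lie strictly in (0, 1)")
  }
  bad <- setdiff(names(scen$modifier_coeffs), efficacy_endpoints())
  if (length(bad)) {
    rlang::abort(paste0("unknown endpoints in `modifier_coeffs`: ",
                        paste(bad, collapse = ", ")))
  }
  invisible(scen)
}

#' @export
print.trial_scenario <- function(x, ...) {
  cat("<trial_scenario>\n")
  cat(sprintf("  arms: active n=%d, anchor n=%d across %d centers\n",
              x$n_active, x$n_anchor, x$n_centers))
  cat(sprintf("  baselines: age %.1f (%.1f), male %.0f%%, BMI %.1f (%.1f), OFF %.1f (%.1f) h (>= %.1f)\n",
              x$age_mean, x$age_sd, 100 * x$male_prop, x$bmi_mean, x$bmi_sd,
              x$off_mean, x$off_sd, x$off_min_inclusion))
  cat(sprintf("  primary effect (OFF change): %.2f h/day; %d modified endpoints\n",
              x$effects[["off_change"]], length(x$modifier_coeffs)))
  invisible(x)
}

#' Build a linked pair of trial scenarios for an anchored comparison
#'
#' Returns a scenario for the IPD trial (safinamide-like baselines) and a
#' comparator scenario (rasagiline-like baselines) that share conditional
#' treatment-effect structure. With shared effect-modifier coefficients the
#' true anchored difference between the two active treatments equals the
#' difference in base effects in *every* target population, so it is known by
#' construction: zero when `comparator_effects` is left equal to
#' `shared_effects`.
#'
#' @param shared_effects Named vector of base treatment effects used by both
#'   scenarios (defaults to the package's safinamide-like defaults).
#' @param covariate_shift Named numeric vector of additive shifts applied to
#'   the comparator scenario's scalar fields (e.g.
#'   `c(male_prop = 0.08, bmi_mean = -0.8)`). The default reproduces the
#'   observed cross-trial imbalance: older, more male, lower BMI, longer
#'   baseline OFF time, and a lower OFF-time inclusion threshold (1.0 vs
#'   1.5 h/day). Use `covariate_shift = c()` for identical populations.
#' @param modifier_coeffs Effect-modifier coefficients shared by both
#'   scenarios (see [trial_scenario()]).
#' @param comparator_effects Optional named vector overriding the comparator's
#'   base effects (distinct drugs); the true anchored difference per endpoint
#'   is then `shared_effects - comparator_effects`.
#' @param n_comparator Length-2 vector: comparator arm sizes (active, anchor).
#' @param seed Seed for the IPD scenario; the comparator uses `seed + 1000`.
#'
#' @return A list with elements `ipd`, `comparator` (both `trial_scenario`)
#'   and `true_difference` (named vector per endpoint).
#' @export
make_paired_scenarios <- function(shared_effects = default_effects(),
                                  covariate_shift = default_covariate_shift(),
                                  modifier_coeffs = list(),
                                  comparator_effects = NULL,
                                  n_comparator = c(163L, 158L),
                                  seed = 1L) {
  if (length(covariate_shift) && any(!is.finite(covariate_shift))) {
    rlang::abort("`covariate_shift` values must be finite")
  }
  ipd <- trial_scenario(effects = shared_effects,
                        modifier_coeffs = modifier_coeffs, seed = seed)
  comp_eff <- if (is.null(comparator_effects)) shared_effects else {
    tmp <- ipd$effects
    tmp[names(comparator_effects)] <- comparator_effects
    tmp
  }
  comp <- trial_scenario(n_active = n_comparator[[1]],
                         n_anchor = n_comparator[[2]],
                         effects = comp_eff,
                         modifier_coeffs = modifier_coeffs,
                         seed = seed + 1000L)
  shiftable <- c("age_mean", "age_sd", "male_prop", "bmi_mean", "bmi_sd",
                 "off_mean", "off_sd", "off_min_inclusion")
  bad <- setdiff(names(covariate_shift), shiftable)
  if (length(bad)) {
    rlang::abort(paste0("cannot shift scenario field(s): ",
                        paste(bad, collapse = ", ")))
  }
  for (nm in names(covariate_shift)) {
    comp[[nm]] <- comp[[nm]] + covariate_shift[[nm]]
  }
  validate_scenario(comp)
  truth <- ipd$effects - comp$effects
  list(ipd = ipd, comparator = comp, true_difference = truth)
}

#' @rdname make_paired_scenarios
#' @export
default_covariate_shift <- function() {
  c(age_mean = 0.6, age_sd = 0.1, male_prop = 0.08,
    bmi_mean = -0.8, bmi_sd = 0.2,
    off_mean = 0.4, off_sd = -0.4, off_min_inclusion = -0.5)
}

#' Read or write a trial scenario as YAML or JSON
#'
#' @param path File path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @param scenario A `trial_scenario`.
#' @return `read_scenario()` returns a validated `trial_scenario`;
#'   `write_scenario()` returns `path` invisibly.
#' @export
read_scenario <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  raw$effects <- unlist(raw$effects)
  raw$baseline_slope <- unlist(raw$baseline_slope)
  raw$noise_sd <- unlist(raw$noise_sd)
  raw$modifier_coeffs <- lapply(raw$modifier_coeffs, unlist)
  raw$event_probs <- lapply(raw$event_probs, unlist)
  do.call(trial_scenario, raw[!vapply(raw, is.null, logical(1))])
}

#' @rdname read_scenario
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "trial_scenario"))
  obj <- unclass(scenario)
  obj$effects <- as.list(obj$effects)
  obj$baseline_slope <- as.list(obj$baseline_slope)
  obj$noise_sd <- as.list(obj$noise_sd)
  obj$modifier_coeffs <- lapply(obj$modifier_coeffs, as.list)
  obj$event_probs <- lapply(obj$event_probs, as.list)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
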