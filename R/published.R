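#' Published safinamide / rasagiline comparison inputs
#'
#' The aggregate inputs of the motivating comparison, transcribed from the
#' published trial reports: the safinamide trial's (XINDI, NCT03881371;
#' N = 305) pooled and per-arm baseline summaries, the rasagiline comparator
#' trial's (Study 1 of Zhang et al., NCT01479530; N = 321 as tabulated)
#' baseline targets, and both trials' arm-versus-placebo results per
#' endpoint — least-squares mean changes (SE) for the efficacy endpoints and
#' the published safety values.
#'
#' Safety per-trial values are printed ambiguously in the source table; they
#' are stored here under the odds-ratio reading (value = OR, parenthetical =
#' SE of the log odds ratio), which reproduces the published combined SAE
#' and DCAE odds ratios at printed precision. See the package vignette.
#'
#' @return A list:
#' \describe{
#'   \item{ipd_summary}{tibble of the safinamide trial's baseline summaries
#'     (pooled and per arm).}
#'   \item{comparator_agd}{an `agd_summary` with the rasagiline trial's
#'     pooled baseline targets and published contrasts.}
#'   \item{ipd_contrasts}{`arm_contrast` tibble of the safinamide trial's
#'     weighted arm-versus-placebo results.}
#' }
#' @export
safinamide_rasagiline_example <- function() {
  ipd_summary <- tibble::tibble(
    covariate = rep(c("age", "male", "bmi", "off_baseline"), each = 3),
    group = rep(c("active", "anchor", "pooled"), times = 4),
    value = c(61.4, 61.8, 61.6,
              0.609, 0.552, 0.580,
              23.9, 23.9, 23.9,
              5.9, 5.6, 5.7),
    sd = c(9.3, 9.3, 9.3,
           NA, NA, NA,
           3.0, 3.1, 3.0,
           2.8, 3.1, 3.0),
    n = rep(c(151, 154, 305), times = 4))

  targets <- tibble::tibble(
    covariate = c("age", "male", "bmi", "off_baseline"),
    kind = c("continuous", "binary", "continuous", "continuous"),
    value = c(62.2, 0.660, 23.1, 6.1),
    sd = c(9.4, NA, 3.2, 2.6))

  comparator_eff <- arm_contrast(
    endpoint = efficacy_endpoints(),
    estimate = c(-0.5, -1.6, -1.8, -6.1, -2.4, -2.5, -2.5),
    se = c(0.22, 0.74, 1.12, 1.76, 2.00, 1.56, 1.92),
    scale = "difference", source = "published",
    n_or_ess = 321)
  comparator_safety <- arm_contrast(
    endpoint = safety_endpoints(),
    estimate = log(c(1.1, 1.4, 1.2)),
    se = c(0.23, 0.60, 0.62),
    scale = "log_odds", source = "published", n_or_ess = 321)

  ipd_eff <- arm_contrast(
    endpoint = efficacy_endpoints(),
    estimate = c(-1.2, -4.5, -4.0, -6.7, -5.6, -6.0, -6.4),
    se = c(0.28, 0.96, 1.08, 1.74, 1.69, 1.57, 1.99),
    scale = "difference", source = "ipd_weighted", n_or_ess = 271)
  ipd_safety <- arm_contrast(
    endpoint = safety_endpoints(),
    estimate = log(c(1.9, 1.5, 0.8)),
    se = c(0.26, 0.62, 0.52),
    scale = "log_odds", source = "ipd_weighted", n_or_ess = 271)

  list(
    ipd_summary = ipd_summary,
    comparator_agd = new_agd_summary(
      label = "rasagiline adjunct trial",
      n_active = 163L, n_anchor = 158L,
      baseline_targets = targets,
      contrasts = dplyr::bind_rows(comparator_eff, comparator_safety)),
    ipd_contrasts = dplyr::bind_rows(ipd_eff, ipd_safety))
}
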