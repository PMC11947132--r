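test_that("identical scenario and seed give bit-identical trials", {
  scen <- tiny_scenario()
  a <- simulate_trial(scen, seed = 5)
  b <- simulate_trial(scen, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a, simulate_trial(scen, seed = 6)))
})

test_that("baseline OFF time respects the inclusion threshold", {
  scen <- tiny_scenario(off_min_inclusion = 1.5)
  ipd <- simulate_trial(scen, seed = 2)
  expect_true(all(ipd$off_baseline >= 1.5))
  scen1 <- tiny_scenario(off_min_inclusion = 1.0)
  expect_true(all(simulate_trial(scen1, seed = 2)$off_baseline >= 1.0))
})

test_that("impossible truncation fails with an explicit error", {
  scen <- tiny_scenario(off_min_inclusion = 40)
  expect_error(simulate_trial(scen, seed = 1, max_tries = 25L),
               "rejection sampling")
})

test_that("arm sizes and arm levels are as declared", {
  scen <- tiny_scenario(n_active = 17L, n_anchor = 23L)
  ipd <- simulate_trial(scen, seed = 3)
  expect_equal(nrow(ipd), 40L)
  expect_equal(as.vector(table(ipd$arm)[c("active", "anchor")]), c(17L, 23L))
  expect_setequal(levels(ipd$arm), c("active", "anchor"))
  expect_false(anyNA(ipd[matching_covariates()]))
})

test_that("noise-free limit recovers the configured effect exactly", {
  scen <- tiny_scenario(
    effects = c(off_change = -1.1),
    baseline_slope = stats::setNames(rep(0, 7), efficacy_endpoints()),
    noise_sd = stats::setNames(rep(1e-10, 7), efficacy_endpoints()),
    center_sd_frac = 0, latent_loading = 0)
  ipd <- simulate_trial(scen, seed = 4)
  diff <- mean(ipd$off_change[ipd$arm == "active"]) -
    mean(ipd$off_change[ipd$arm == "anchor"])
  expect_equal(diff, -1.1, tolerance = 1e-6)
})

test_that("covariate sample moments match the configured distributions", {
  scen <- trial_scenario(n_active = 5000L, n_anchor = 5000L)
  ipd <- simulate_trial(scen, seed = 11)
  n <- nrow(ipd)
  expect_lt(abs(mean(ipd$age) - 61.6), 3 * 9.3 / sqrt(n))
  expect_lt(abs(mean(ipd$bmi) - 23.9), 3 * 3.0 / sqrt(n))
  expect_lt(abs(mean(ipd$male) - 0.58), 3 * 0.5 / sqrt(n))
  # OFF time is truncated at 1.5 h, so its target is the truncated-normal
  # mean mu + sd * phi(a) / (1 - Phi(a)), not the untruncated mu
  a <- (1.5 - 5.7) / 3.0
  trunc_mean <- 5.7 + 3.0 * stats::dnorm(a) / (1 - stats::pnorm(a))
  expect_lt(abs(mean(ipd$off_baseline) - trunc_mean), 3 * 3.0 / sqrt(n))
})

test_that("aggregate_trial reports pooled targets and null contrasts", {
  scen <- tiny_scenario(male_prop = 1)
  ipd <- simulate_trial(scen, seed = 7)
  ipd$male <- 1L  # every patient male
  agd <- aggregate_trial(ipd, endpoints = "off_change")
  tg <- agd$baseline_targets
  expect_equal(tg$value[tg$covariate == "male"], 1.0)
  expect_equal(tg$kind[tg$covariate == "male"], "binary")

  # endpoint identical in both arms -> zero published contrast
  ipd2 <- simulate_trial(tiny_scenario(), seed = 8)
  ipd2$off_change <- 2.5
  agd2 <- suppressWarnings(aggregate_trial(ipd2, endpoints = "off_change"))
  expect_equal(agd2$contrasts$estimate, 0, tolerance = 1e-10)
})

test_that("aggregate targets recover the comparator scenario configuration", {
  scen <- trial_scenario(n_active = 2500L, n_anchor = 2500L,
                         off_mean = 6.1, off_sd = 2.6, off_min_inclusion = 1.0,
                         male_prop = 0.66, bmi_mean = 23.1, bmi_sd = 3.2)
  agd <- aggregate_trial(simulate_trial(scen, seed = 9),
                         endpoints = "off_change")
  tg <- agd$baseline_targets
  n <- 5000
  expect_lt(abs(tg$value[tg$covariate == "male"] - 0.66), 3 * 0.5 / sqrt(n))
  expect_lt(abs(tg$value[tg$covariate == "bmi"] - 23.1), 3 * 3.2 / sqrt(n))
  a <- (1.0 - 6.1) / 2.6
  trunc_mean <- 6.1 + 2.6 * stats::dnorm(a) / (1 - stats::pnorm(a))
  expect_lt(abs(tg$value[tg$covariate == "off_baseline"] - trunc_mean),
            3 * 2.6 / sqrt(n))
})

test_that("aggregate_trial rejects degenerate inputs", {
  ipd <- simulate_trial(tiny_scenario(), seed = 10)
  expect_error(aggregate_trial(ipd[ipd$arm == "active", ]), "both arms")
  ipd$bmi <- 22.0
  expect_error(aggregate_trial(ipd), "zero variance")
})

test_that("paired scenarios share effects and differ only by the shift", {
  same <- make_paired_scenarios(covariate_shift = c())
  expect_equal(same$ipd$effects, same$comparator$effects)
  a <- unclass(same$ipd); b <- unclass(same$comparator)
  a$seed <- b$seed <- a$n_active <- b$n_active <- a$n_anchor <- b$n_anchor <- NULL
  expect_equal(a, b)
  expect_equal(unname(same$true_difference), rep(0, 7))

  shifted <- make_paired_scenarios()
  expect_gt(shifted$comparator$male_prop, shifted$ipd$male_prop)
  expect_lt(shifted$comparator$bmi_mean, shifted$ipd$bmi_mean)
  expect_gt(shifted$comparator$off_mean, shifted$ipd$off_mean)
  expect_lt(shifted$comparator$off_min_inclusion, shifted$ipd$off_min_inclusion)

  truth <- make_paired_scenarios(
    comparator_effects = c(off_change = -0.5))$true_difference
  expect_equal(truth[["off_change"]], -1.1 - -0.5)
})

test_that("scenario invariants are enforced", {
  expect_error(trial_scenario(n_active = 0L), "at least 1")
  expect_error(trial_scenario(age_sd = -1), "SDs must be > 0")
  expect_error(trial_scenario(male_prop = 1.2), "\\[0, 1\\]")
  expect_error(trial_scenario(event_probs = list(ae = c(anchor = 0, active = 0.5))),
               "strictly in")
  expect_error(make_paired_scenarios(covariate_shift = c(age_mean = Inf)),
               "finite")
})
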