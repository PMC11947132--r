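test_that("unit-weight ANCOVA equals ordinary least squares", {
  ipd <- simulate_trial(tiny_scenario(), seed = 1)
  ct <- weighted_ancova(ipd, NULL, "off_change")
  ref <- lm(off_change ~ arm + center + off_baseline,
            data = transform(ipd, arm = factor(arm, c("anchor", "active"))))
  expect_equal(ct$estimate, unname(coef(ref)["armactive"]), tolerance = 1e-10)
  expect_equal(ct$scale, "difference")
  expect_equal(ct$n_or_ess, nrow(ipd))
  expect_setequal(ct$model_terms[[1]], c("arm", "center", "off_baseline"))
})

test_that("with no adjusters the contrast is the difference of arm means", {
  ipd <- simulate_trial(tiny_scenario(), seed = 2)
  ct <- weighted_ancova(ipd, NULL, "off_change", adjusters = character(0))
  diff_means <- mean(ipd$off_change[ipd$arm == "active"]) -
    mean(ipd$off_change[ipd$arm == "anchor"])
  expect_equal(ct$estimate, diff_means, tolerance = 1e-10)
  # HC0 sandwich closed form for a two-group mean difference
  v <- vapply(c("active", "anchor"), function(a) {
    e <- ipd$off_change[ipd$arm == a]
    sum((e - mean(e))^2) / length(e)^2
  }, numeric(1))
  expect_equal(ct$se, sqrt(sum(v)), tolerance = 1e-10)
})

test_that("estimates and sandwich SEs are invariant to weight rescaling", {
  ipd <- simulate_trial(tiny_scenario(), seed = 3)
  tg <- c(age = mean(ipd$age) + 0.5, off_baseline = mean(ipd$off_baseline) + 0.3)
  w <- estimate_weights(ipd, tg, c("age", "off_baseline"))$weights
  a1 <- weighted_ancova(ipd, w, "updrs3_change")
  a2 <- weighted_ancova(ipd, 13.7 * w, "updrs3_change")
  expect_equal(a1$estimate, a2$estimate, tolerance = 1e-8)
  expect_equal(a1$se, a2$se, tolerance = 1e-8)
  l1 <- weighted_logodds(ipd, w, "ae")
  l2 <- weighted_logodds(ipd, 13.7 * w, "ae")
  expect_equal(l1$estimate, l2$estimate, tolerance = 1e-8)
  expect_equal(l1$se, l2$se, tolerance = 1e-8)
})

test_that("log-odds contrast matches the closed form on raw counts", {
  d <- tibble::tibble(
    arm = factor(rep(c("active", "anchor"), each = 100),
                 levels = c("anchor", "active")),
    ev = c(rep(1, 20), rep(0, 80), rep(1, 10), rep(0, 90)))
  ct <- weighted_logodds(d, NULL, "ev")
  expect_equal(exp(ct$estimate), 2.25, tolerance = 1e-10)
  expect_equal(ct$estimate, 0.8109, tolerance = 1e-4)
  expect_equal(ct$se, sqrt(1 / 20 + 1 / 80 + 1 / 10 + 1 / 90),
               tolerance = 1e-10)
  expect_equal(ct$se, 0.41667, tolerance = 1e-4)
  expect_false(ct$continuity_correction)

  same <- tibble::tibble(arm = d$arm,
                         ev = rep(c(rep(1, 10), rep(0, 90)), 2))
  expect_equal(weighted_logodds(same, NULL, "ev")$estimate, 0)
})

test_that("a zero cell triggers the Haldane-Anscombe correction and flag", {
  d <- tibble::tibble(
    arm = factor(rep(c("active", "anchor"), each = 50),
                 levels = c("anchor", "active")),
    ev = c(rep(0, 50), rep(1, 5), rep(0, 45)))
  ct <- weighted_logodds(d, NULL, "ev")
  expect_true(ct$continuity_correction)
  expect_equal(exp(ct$estimate), (0.5 * 45.5) / (50.5 * 5.5),
               tolerance = 1e-10)
  expect_error(weighted_logodds(d, NULL, "age"), "not found")
  expect_error(weighted_logodds(tibble::tibble(arm = d$arm, x = rnorm(100)),
                                NULL, "x"), "0/1")
})

test_that("a center aliased with treatment is reported as rank deficiency", {
  d <- tibble::tibble(
    arm = factor(rep(c("active", "anchor"), each = 20),
                 levels = c("anchor", "active")),
    center = factor(rep(c(2, 1), each = 20)),
    off_baseline = rnorm(40, 6), y = rnorm(40))
  expect_error(weighted_ancova(d, NULL, "y"), "rank deficient")
})

test_that("large-sample ANCOVA recovers the configured OFF-time effect", {
  scen <- trial_scenario(n_active = 2500L, n_anchor = 2500L,
                         effects = c(off_change = -1.1))
  ipd <- simulate_trial(scen, seed = 4)
  ct <- weighted_ancova(ipd, NULL, "off_change")
  expect_lt(abs(ct$estimate - -1.1), 3 * ct$se)
})

test_that("bootstrap SE that re-estimates weights agrees with the sandwich", {
  pair <- make_paired_scenarios(seed = 5)
  ipd <- simulate_trial(pair$ipd, seed = 51)
  agd <- aggregate_trial(simulate_trial(pair$comparator, seed = 52),
                         endpoints = "off_change")
  ws <- estimate_weights(ipd, agd)
  sand <- weighted_ancova(ipd, ws, "off_change")
  boot <- weighted_ancova(ipd, ws, "off_change", se_method = "bootstrap",
                          targets = agd, resamples = 1000L, seed = 53)
  expect_equal(boot$estimate, sand$estimate)
  expect_lt(abs(boot$se - sand$se) / sand$se, 0.15)
  expect_error(weighted_ancova(ipd, ws, "off_change",
                               se_method = "bootstrap", resamples = 10L),
               "at least 100")
})

test_that("sandwich-based ANCOVA confidence intervals are calibrated", {
  scen <- trial_scenario(n_active = 500L, n_anchor = 500L,
                         effects = c(off_change = -1.1))
  hits <- vapply(1:200, function(i) {
    ipd <- simulate_trial(scen, seed = 700 + i)
    ct <- weighted_ancova(ipd, NULL, "off_change")
    abs(ct$estimate - -1.1) <= 1.959964 * ct$se
  }, logical(1))
  expect_gte(mean(hits), 0.93)
  expect_lte(mean(hits), 0.97)
})
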