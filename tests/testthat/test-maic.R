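test_that("centering subtracts the aggregate targets column by column", {
  d <- tibble::tibble(x = c(4, 6))
  Xc <- center_covariates(d, c(x = 5), "x")
  expect_equal(as.vector(Xc), c(-1, 1))

  # published pooled means of the two motivating trials: centering the IPD
  # summaries on the comparator targets gives the cross-trial imbalances
  d2 <- tibble::tibble(age = 61.6 + c(-1, 1), male = 0.580 + c(-0.1, 0.1),
                       bmi = 23.9 + c(-1, 1), off_baseline = 5.7 + c(-1, 1))
  tg <- c(age = 62.2, male = 0.660, bmi = 23.1, off_baseline = 6.1)
  Xc2 <- center_covariates(d2, tg, names(tg))
  expect_equal(unname(colMeans(Xc2)), c(-0.6, -0.08, 0.8, -0.4))

  expect_error(center_covariates(d2, tg[-1], names(tg)), "age")
  expect_error(center_covariates(d2, tg, c("age", "updrs2")), "updrs2")
  d3 <- tibble::tibble(x = c(2, 2, 2))
  expect_error(center_covariates(d3, c(x = 1), "x"), "infeasible")
})

test_that("targets equal to IPD means give beta = 0 and ESS = n", {
  ipd <- simulate_trial(tiny_scenario(), seed = 1)
  tg <- vapply(matching_covariates(), function(cv) mean(ipd[[cv]]), numeric(1))
  ws <- estimate_weights(ipd, tg)
  expect_true(ws$converged)
  expect_equal(unname(ws$beta), rep(0, 4))
  expect_equal(ws$ess_total, nrow(ipd))
  expect_equal(diff(range(ws$weights)), 0)
})

test_that("one-covariate solution matches the bisection oracle", {
  d <- tibble::tibble(x = c(4, 4, 6))
  ws <- estimate_weights(d, c(x = 5), "x")
  # closed form: gradient -2 e^{-b} + e^{b} = 0  =>  b = log(2) / 2
  expect_equal(unname(ws$beta), log(2) / 2, tolerance = 1e-8)
  expect_equal(unname(ws$beta), bisect_tilting_1d(c(-1, -1, 1)),
               tolerance = 1e-8)
  expect_equal(ws$weights / ws$weights[1],
               c(1, 1, 2), tolerance = 1e-8)
  expect_equal(sum(ws$weights * d$x) / sum(ws$weights), 5, tolerance = 1e-10)
})

test_that("two-covariate solution matches a dense grid-search oracle", {
  set.seed(42)
  d <- tibble::tibble(x = rnorm(30), y = rbinom(30, 1, 0.5))
  tg <- c(x = mean(d$x) + 0.3, y = mean(d$y) - 0.1)
  ws <- estimate_weights(d, tg, c("x", "y"))
  oracle <- grid_tilting_2d(center_covariates(d, tg, c("x", "y")))
  expect_equal(unname(ws$beta), oracle, tolerance = 1e-4)
  bal <- check_balance(d, ws)
  expect_equal(bal$weighted_mean, bal$target, tolerance = 1e-10)
})

test_that("weighted pooled means match targets exactly on feasible instances", {
  for (rep in 1:8) {
    ipd <- simulate_trial(tiny_scenario(seed = rep), seed = 100 + rep)
    other <- simulate_trial(
      trial_scenario(n_active = 80L, n_anchor = 80L, off_mean = 6.1,
                     off_sd = 2.6, off_min_inclusion = 1.0, male_prop = 0.66,
                     bmi_mean = 23.1, bmi_sd = 3.2, age_mean = 62.2,
                     seed = rep), seed = 200 + rep)
    tg <- vapply(matching_covariates(), function(cv) mean(other[[cv]]),
                 numeric(1))
    ws <- estimate_weights(ipd, tg)
    expect_true(ws$converged)
    bal <- check_balance(ipd, ws)
    expect_lt(max(abs(bal$weighted_mean - bal$target) /
                    pmax(1, abs(bal$target))), 1e-8)
    # convexity sanity: optimum objective no larger than at beta = 0
    expect_lte(ws$objective_value, nrow(ipd))
    expect_gte(min(ws$weights), 0)
    expect_lte(ws$ess_total, nrow(ipd))
    expect_gte(ws$ess_total, 1)
  }
})

test_that("ESS equals hand values and is scale invariant", {
  expect_equal(effective_sample_size(rep(1, 10)), 10)
  expect_equal(effective_sample_size(c(3, 1)), 1.6)
  expect_equal(effective_sample_size(c(1, 1, 2)), 16 / 6)
  w <- stats::rexp(50)
  expect_equal(effective_sample_size(w), effective_sample_size(7.3 * w))
  expect_error(effective_sample_size(rep(0, 5)), "ESS undefined")
  expect_error(effective_sample_size(c(1, -1)), "nonnegative")
})

test_that("rescaling weights changes nothing statistical", {
  ipd <- simulate_trial(tiny_scenario(), seed = 3)
  tg <- c(age = mean(ipd$age) + 0.5, bmi = mean(ipd$bmi) - 0.3)
  ws <- estimate_weights(ipd, tg, c("age", "bmi"))
  for (mode in c("raw", "sum_to_n", "mean_one")) {
    rs <- rescale_weights(ws, mode)
    expect_equal(rs$ess_total, ws$ess_total)
    m1 <- sum(rs$weights * ipd$age) / sum(rs$weights)
    m0 <- sum(ws$weights * ipd$age) / sum(ws$weights)
    expect_equal(m1, m0, tolerance = 1e-12)
  }
  eq <- estimate_weights(ipd, vapply(c("age", "bmi"),
                                     function(cv) mean(ipd[[cv]]),
                                     numeric(1)), c("age", "bmi"))
  expect_equal(unique(rescale_weights(eq, "mean_one")$weights), 1)
  expect_error(rescale_weights(ws, "normalise"), "must be one of")
})

test_that("infeasible or collinear matching requests are rejected by name", {
  ipd <- simulate_trial(tiny_scenario(), seed = 4)
  expect_error(estimate_weights(ipd, c(bmi = 60), "bmi"),
               "outside the range.*bmi")
  ipd$bmi2 <- ipd$bmi * 2
  tg <- c(bmi = mean(ipd$bmi) + 0.1, bmi2 = 2 * (mean(ipd$bmi) + 0.1))
  expect_error(estimate_weights(ipd, tg, c("bmi", "bmi2")), "collinear")
  # a binary target at the boundary with both levels present is infeasible
  expect_error(estimate_weights(ipd, c(male = 1), "male"),
               "outside the range")
  expect_error(estimate_weights(ipd[1:3, ], c(age = 62, bmi = 23, male = 0.5,
                                              off_baseline = 6)),
               "more patients")
})

test_that("larger covariate shifts never increase the ESS", {
  ipd <- simulate_trial(trial_scenario(n_active = 100L, n_anchor = 100L),
                        seed = 6)
  base <- vapply(matching_covariates(), function(cv) mean(ipd[[cv]]),
                 numeric(1))
  shift_dir <- c(age = 0.6, male = 0.08, bmi = -0.8, off_baseline = 0.4)
  ess <- vapply(seq(0, 1, by = 0.2), function(delta) {
    estimate_weights(ipd, base + delta * shift_dir)$ess_total
  }, numeric(1))
  expect_true(all(diff(ess) <= 1e-8))
  expect_lt(ess[length(ess)], ess[1])
})

test_that("weight tidiers and CSV export expose per-patient weights", {
  ipd <- simulate_trial(tiny_scenario(), seed = 8)
  ws <- estimate_weights(ipd, c(age = mean(ipd$age) + 0.4), "age")
  tb <- tidy(ws)
  expect_equal(nrow(tb), nrow(ipd))
  expect_equal(sum(tb$weight_scaled), nrow(ipd))
  gl <- glance(ws)
  expect_true(gl$converged)
  expect_equal(gl$ess_total, ws$ess_total)
  expect_equal(gl$ess_active + gl$ess_anchor <= gl$n, TRUE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_weights(ws, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(back$weight, ws$weights)
})
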