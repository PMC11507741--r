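test_that("both generators are deterministic given spec and seed", {
  ks <- kinematic_cohort_spec(n_participants = 4, n_steps = 20, seed = 42)
  expect_identical(simulate_kinematic_cohort(ks), simulate_kinematic_cohort(ks))
  ms <- metabolic_cohort_spec(n_participants = 4, seed = 42)
  expect_identical(simulate_metabolic_cohort(ms), simulate_metabolic_cohort(ms))
  # a different seed changes the draw
  ks2 <- kinematic_cohort_spec(n_participants = 4, n_steps = 20, seed = 43)
  expect_false(identical(simulate_kinematic_cohort(ks)$truth,
                         simulate_kinematic_cohort(ks2)$truth))
})

test_that("kinematic trials have exact step counts and noiseless trials recover the true gains", {
  spec <- kinematic_cohort_spec(n_participants = 5, n_steps = 60,
                                step_noise_sd = 0, seed = 3)
  ck <- simulate_kinematic_cohort(spec)
  expect_true(all(vapply(ck$trials, nrow, integer(1)) == 60L))
  for (id in names(ck$trials)) {
    fit <- fit_foot_placement_jacobian(ck$trials[[id]])
    expect_equal(fit$gain, ck$gains[[id]], tolerance = 1e-10)
  }
})

test_that("a non-positive-definite pelvis covariance is rejected by name", {
  V <- matrix(c(1, 2, 0, 2, 1, 0, 0, 0, 1) * 1e-4, 3, 3)
  expect_error(kinematic_cohort_spec(pelvis_state_cov = V),
               "pelvis_state_cov")
})

test_that("between-participant variance of generated true parameters matches the spec", {
  # chi-square interval for a sample variance at n = 500
  n <- 500
  ci <- n / stats::qchisq(c(0.9995, 0.0005), df = n - 1)
  ks <- kinematic_cohort_spec(n_participants = n, n_steps = 7, seed = 11)
  ck <- simulate_kinematic_cohort(ks)
  ratio_k <- stats::var(ck$truth$true_value) / 0.08^2
  expect_gt(ratio_k, ci[1])
  expect_lt(ratio_k, ci[2])

  ms <- metabolic_cohort_spec(n_participants = n, trial_duration = 60, seed = 12)
  cm <- simulate_metabolic_cohort(ms)
  ratio_m <- stats::var(cm$truth$true_value) / ms$population_a0_sd^2
  expect_gt(ratio_m, ci[1])
  expect_lt(ratio_m, ci[2])
})

test_that("resting mode with zero noise emits the constant true rate", {
  spec <- resting_cohort_spec(n_participants = 4, measurement_noise_sd = 0,
                              seed = 5)
  cm <- simulate_metabolic_cohort(spec)
  expect_true(all(cm$params$a1 == 0))
  for (i in seq_along(cm$trials))
    expect_equal(cm$trials[[i]]$edot_w_kg,
                 rep(cm$params$a0[i], nrow(cm$trials[[i]])))
})

test_that("noise-free, jitter-free trials are exactly refit by the transient estimator", {
  spec <- metabolic_cohort_spec(n_participants = 4, measurement_noise_sd = 0,
                                breath_interval_jitter_sd = 0, seed = 6)
  cm <- simulate_metabolic_cohort(spec)
  for (i in seq_along(cm$trials)) {
    fit <- fit_exponential_transient(cm$trials[[i]])
    expect_equal(fit$a0, cm$params$a0[i], tolerance = 1e-6)
    expect_equal(fit$a1, cm$params$a1[i], tolerance = 1e-5)
    expect_equal(fit$tau, cm$params$tau[i], tolerance = 1e-5)
  }
})

test_that("back-computed gas pairs reproduce the emitted rate through the Brockway step", {
  cm <- simulate_metabolic_cohort(metabolic_cohort_spec(n_participants = 4, seed = 7))
  for (tr in cm$trials)
    expect_equal(brockway_rate(tr$vo2_mls_kg, tr$vco2_mls_kg), tr$edot_w_kg,
                 tolerance = 1e-9)
})

test_that("metabolic spec enforces minimum duration and trials carry enough breaths", {
  expect_error(metabolic_cohort_spec(trial_duration = 10,
                                     mean_breath_interval = 7.2),
               "too few samples")
  spec <- metabolic_cohort_spec(n_participants = 6, seed = 8)
  cm <- simulate_metabolic_cohort(spec)
  lens <- vapply(cm$trials, nrow, integer(1))
  floor_bound <- floor(spec$trial_duration /
                       (spec$mean_breath_interval + 3 * spec$breath_interval_jitter_sd))
  expect_true(all(lens >= floor_bound))
  expect_true(all(lens >= spec$min_breaths))
  # breath times strictly increasing
  for (tr in cm$trials) expect_true(all(diff(tr$t_s) > 0))
})
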