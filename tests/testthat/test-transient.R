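test_that("noiseless exponential data are recovered to optimizer tolerance", {
  tr <- make_exp_trial(a0 = 5, a1 = 3, tau = 40, duration = 390, dt = 7.2)
  fit <- fit_exponential_transient(tr)
  expect_equal(fit$a0, 5, tolerance = 1e-6)
  expect_equal(fit$a1, 3, tolerance = 1e-6)
  expect_equal(fit$tau, 40, tolerance = 1e-5)
  expect_true(fit$converged)
  expect_false(fit$flat)
})

test_that("a constant series falls back to its mean with no transient", {
  tr <- data.frame(t_s = seq(5, 200, by = 5), edot_w_kg = 2.0)
  fit <- fit_exponential_transient(tr)
  expect_equal(fit$a0, 2.0)
  expect_equal(fit$a1, 0)
  expect_true(fit$tau > 0)
  expect_true(fit$converged)
})

test_that("the profiled fit agrees with an independent iterative NLS optimizer", {
  for (s in 1:5) {
    tr <- make_exp_trial(a0 = 4.3, a1 = -2.8, tau = 40, noise_sd = 0.3, seed = s)
    fit <- fit_exponential_transient(tr)
    ref <- minpack.lm::nlsLM(
      edot_w_kg ~ a0 + a1 * exp(-t_s / tau), data = tr,
      start = list(a0 = mean(utils::tail(tr$edot_w_kg, 18)),
                   a1 = tr$edot_w_kg[1] - mean(utils::tail(tr$edot_w_kg, 18)),
                   tau = max(tr$t_s) / 3))
    co <- coef(ref)
    expect_equal(fit$a0, unname(co["a0"]), tolerance = 1e-5)
    expect_equal(fit$a1, unname(co["a1"]), tolerance = 1e-4)
    expect_equal(fit$tau, unname(co["tau"]), tolerance = 1e-4)
    expect_lte(fit$rss, sum(residuals(ref)^2) * (1 + 1e-8))
  }
})

test_that("steady-state error shrinks as the fitted window grows", {
  grid <- c(15, 27, 39, 51)
  errs <- matrix(NA_real_, 500, length(grid))
  for (r in 1:500) {
    tr <- make_exp_trial(a0 = 4.3, a1 = -2.8, tau = 40, noise_sd = 0.3,
                         seed = 1000 + r)
    for (gi in seq_along(grid))
      errs[r, gi] <- abs(fit_exponential_transient(tr, grid[gi])$a0 - 4.3)
  }
  med <- apply(errs, 2, stats::median)
  expect_true(all(diff(med) < 0))
})

test_that("window-size preconditions are enforced", {
  tr <- make_exp_trial(4, -2, 30)
  expect_error(fit_exponential_transient(tr, 3), "at least 4|>= 4")
  expect_error(fit_exponential_transient(tr, nrow(tr) + 1), "exceeds")
})

test_that("bootstrap variance is deterministic given a seed and collapses on noiseless data", {
  tr <- make_exp_trial(a0 = 4.3, a1 = -2.8, tau = 40, noise_sd = 0.3, seed = 2)
  e1 <- steady_state_estimate(tr, 30, n_boot = 200, seed = 7)
  e2 <- steady_state_estimate(tr, 30, n_boot = 200, seed = 7)
  expect_identical(e1$variance, e2$variance)
  e3 <- steady_state_estimate(tr, 30, n_boot = 200, seed = 8)
  expect_false(identical(e3$variance, e1$variance))

  clean <- make_exp_trial(a0 = 5, a1 = 3, tau = 40)
  e0 <- steady_state_estimate(clean, n_boot = 100, seed = 1)
  expect_lte(e0$variance, 1e-10)
})

test_that("bootstrap standard error calibrates against fresh-noise Monte Carlo", {
  # truth: spread of the full-window estimate over independent noise draws
  a0s <- vapply(1:400, function(r)
    fit_exponential_transient(make_exp_trial(4.3, -2.8, 40, noise_sd = 0.3,
                                             seed = 5000 + r))$a0, numeric(1))
  mc_sd <- stats::sd(a0s)
  tr <- make_exp_trial(4.3, -2.8, 40, noise_sd = 0.3, seed = 123)
  boot_sd <- sqrt(steady_state_estimate(tr, n_boot = 500, seed = 4)$variance)
  expect_gt(boot_sd / mc_sd, 1 / 1.5)
  expect_lt(boot_sd / mc_sd, 1.5)
})

test_that("residual resampling is available and behaves like case resampling on stable windows", {
  tr <- make_exp_trial(4.3, -2.8, 40, noise_sd = 0.3, seed = 3)
  ec <- steady_state_estimate(tr, n_boot = 300, seed = 5, resample = "case")
  er <- steady_state_estimate(tr, n_boot = 300, seed = 5, resample = "residual")
  expect_equal(ec$value, er$value)  # the point estimate never depends on the bootstrap
  expect_lt(abs(log(er$variance / ec$variance)), log(4))
})
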