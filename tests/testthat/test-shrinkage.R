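test_that("shrinkage reproduces hand arithmetic on a five-participant cohort", {
  est <- make_estimates(1:5, 1)
  res <- compute_shrinkage(est)
  expect_equal(res$grand_mean, 3)
  expect_equal(res$pooled_se2, 1)
  expect_equal(res$raw_c, 0.8)
  expect_equal(res$applied_c, 0.8)
  expect_equal(res$estimates$z, c(1.4, 2.2, 3.0, 3.8, 4.6))

  # larger error variances flip the factor negative; positive part clamps it
  noisy <- make_estimates(1:5, 10)
  res2 <- compute_shrinkage(noisy)
  expect_equal(res2$raw_c, -1)
  expect_equal(res2$applied_c, 0)
  expect_true(res2$positive_part_applied)
  expect_equal(res2$estimates$z, rep(3, 5))
  raw <- compute_shrinkage(noisy, positive_part = FALSE)
  expect_equal(raw$applied_c, -1)
})

test_that("perfect estimates are left untouched (c = 1 when pooled SE^2 = 0)", {
  est <- make_estimates(c(0.1, 0.4, 0.2, 0.5), 0)
  res <- compute_shrinkage(est)
  expect_equal(res$raw_c, 1)
  expect_identical(res$estimates$z, res$estimates$value)
})

test_that("mean preservation, contraction and order preservation hold on random cohorts", {
  withr::with_seed(202, {
    for (i in 1:1000) {
      k <- sample(4:30, 1)
      est <- make_estimates(rnorm(k, 0, runif(1, 0.1, 3)),
                            runif(k, 0.001, 2))
      res <- compute_shrinkage(est)
      y <- est$value; z <- res$estimates$z
      expect_equal(mean(z), res$grand_mean, tolerance = 1e-12)
      expect_equal(mean(z), mean(y), tolerance = 1e-12)
      cc <- res$applied_c
      expect_gte(cc, 0)
      if (cc <= 1)
        expect_true(all(abs(z - res$grand_mean) <=
                        abs(y - res$grand_mean) + 1e-12))
      if (cc > 0) expect_identical(order(z), order(y))
      else expect_true(all(abs(z - res$grand_mean) < 1e-12))
    }
  })
})

test_that("the raw factor rises with spread and falls with pooled error variance", {
  base <- make_estimates(1:6, 0.5)
  c0 <- compute_shrinkage(base)$raw_c
  wider <- make_estimates((1:6) * 2, 0.5)
  expect_gt(compute_shrinkage(wider)$raw_c, c0)
  noisier <- make_estimates(1:6, 1.5)
  expect_lt(compute_shrinkage(noisier)$raw_c, c0)
})

test_that("degenerate cohorts (no spread, positive error) are handled per mode", {
  est <- make_estimates(rep(2, 5), 1)
  expect_error(compute_shrinkage(est, positive_part = FALSE), "undefined")
  expect_warning(res <- compute_shrinkage(est), "full shrinkage")
  expect_equal(res$applied_c, 0)
  expect_equal(res$estimates$z, rep(2, 5))
})

test_that("cohort validation enforces size, uniqueness and a single method", {
  expect_error(compute_shrinkage(make_estimates(1:3, 1)), "k >= 4")
  dup <- make_estimates(1:4, 1)
  dup$participant_id[2] <- dup$participant_id[1]
  expect_error(compute_shrinkage(dup), "unique")
  mixed <- make_estimates(1:4, 1)
  mixed$method[1] <- "transient_a0"
  expect_error(compute_shrinkage(mixed), "same method")
})

test_that("accuracy comparison reproduces hand SSE arithmetic", {
  # sigma^2 = 5, k = 4 gives c = 1 - 5*(4-3)/10 = 0.5
  est <- make_estimates(c(-2, -1, 1, 2), 5)
  res <- compute_shrinkage(est)
  expect_equal(res$applied_c, 0.5)
  truths <- data.frame(participant_id = est$participant_id, true_value = 0)
  cmp <- compare_accuracy(truths, res)
  expect_equal(cmp$sse_mle, 10)
  expect_equal(cmp$sse_jse, 2.5)
  expect_equal(cmp$pct_reduction, 75)
})

test_that("identity shrinkage and perfect MLEs bound the reduction", {
  est <- make_estimates(c(0.3, 0.5, 0.8, 1.1), 0)   # c = 1
  res <- compute_shrinkage(est)
  truths <- data.frame(participant_id = est$participant_id,
                       true_value = c(0.2, 0.6, 0.7, 1.2))
  cmp <- compare_accuracy(truths, res)
  expect_equal(cmp$sse_jse, cmp$sse_mle)
  expect_equal(cmp$pct_reduction, 0)
  expect_true(is.na(cmp$p_paired_errors))  # identical paired errors: degenerate test

  # truths equal to the MLEs: no shrinkage can improve a perfect estimate
  est2 <- make_estimates(c(1, 2, 3, 4), 2)
  res2 <- compute_shrinkage(est2)
  cmp2 <- compare_accuracy(
    data.frame(participant_id = est2$participant_id, true_value = est2$value),
    res2)
  expect_equal(cmp2$sse_mle, 0)
  expect_lte(cmp2$pct_reduction, 0)
})

test_that("mismatched participant ids are reported", {
  est <- make_estimates(1:4, 1)
  res <- compute_shrinkage(est)
  truths <- data.frame(participant_id = c("P01", "P02", "P03", "P99"),
                       true_value = 1:4)
  expect_error(compare_accuracy(truths, res), "P04")
})

test_that("the Monte-Carlo risk check shows dominance and an exact error decomposition", {
  d <- stein_dominance_check(k = 8, sigma2 = 1, spread = 0.5, n_reps = 500,
                             seed = 21)
  expect_lt(d$mean_sse_jse, d$mean_sse_mle)
  dc <- d$decomposition
  expect_equal(dc$mse_mle, dc$bias2_mle + dc$variance_mle, tolerance = 1e-10)
  expect_equal(dc$mse_jse, dc$bias2_jse + dc$variance_jse, tolerance = 1e-10)
  # shrinkage buys variance reduction at the price of bias
  expect_lt(mean(dc$variance_jse), mean(dc$variance_mle))
  expect_gt(mean(dc$bias2_jse), mean(dc$bias2_mle))

  # no observation noise: both estimators are exact
  d0 <- stein_dominance_check(k = 8, sigma2 = 0, spread = 1, n_reps = 100,
                              seed = 3)
  expect_equal(d0$mean_sse_mle, 0)
  expect_equal(d0$mean_sse_jse, 0)
})
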