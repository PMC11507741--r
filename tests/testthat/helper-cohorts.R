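# Shared fixture builders. Everything is generated in code; no data files.

# Noise-free kinematic trial obeying an exact linear control law.
make_exact_kinematic_trial <- function(J, n_steps = 40, seed = 1,
                                       id = "P01") {
  withr::with_seed(seed, {
    dP <- cbind(rnorm(n_steps, 0, 0.01),
                rnorm(n_steps, 0, 0.03),
                rnorm(n_steps, 0, 0.03))
  })
  dS <- dP %*% t(J)
  data.frame(participant_id = id, step_index = seq_len(n_steps),
             x_pelvis = dP[, 1], vx_pelvis = dP[, 2], vy_pelvis = dP[, 3],
             x_foot = dS[, 1], y_foot = dS[, 2])
}

# Metabolic trial sampled exactly from the exponential model, regular
# breath spacing, optional Gaussian noise.
make_exp_trial <- function(a0, a1, tau, duration = 390, dt = 7.2,
                           noise_sd = 0, seed = 1, id = "P01",
                           condition = "walking") {
  t <- seq(dt, duration, by = dt)
  mu <- a0 + a1 * exp(-t / tau)
  y <- if (noise_sd > 0) withr::with_seed(seed, mu + rnorm(length(t), 0, noise_sd))
       else mu
  rer <- 0.85
  vo2 <- y / (16.58 + 4.51 * rer)
  data.frame(participant_id = id, condition = condition, t_s = t,
             vo2_mls_kg = vo2, vco2_mls_kg = rer * vo2, edot_w_kg = y)
}

# Cohort of point estimates straight from numbers.
make_estimates <- function(values, variances,
                           method = "resting_mean", n_used = 10) {
  do.call(rbind, lapply(seq_along(values), function(i)
    point_estimate(sprintf("P%02d", i), values[i],
                   rep_len(variances, length(values))[i], n_used, method)))
}

# Explicit normal-equations OLS oracle for the Jacobian regression:
# window-centered inputs/outputs, per-output solve, df = n - 3.
jacobian_oracle <- function(trial, n) {
  w <- trial[seq_len(n), ]
  X <- sweep(as.matrix(w[c("x_pelvis", "vx_pelvis", "vy_pelvis")]), 2,
             colMeans(as.matrix(w[c("x_pelvis", "vx_pelvis", "vy_pelvis")])))
  Y <- sweep(as.matrix(w[c("x_foot", "y_foot")]), 2,
             colMeans(as.matrix(w[c("x_foot", "y_foot")])))
  XtX_inv <- solve(t(X) %*% X)
  B <- XtX_inv %*% t(X) %*% Y
  res <- Y - X %*% B
  sig2 <- colSums(res^2) / (n - 3)
  list(gain = t(B), coef_variance = t(outer(diag(XtX_inv), sig2)))
}
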