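# Synthetic cohort generators. Every downstream stage (regression, transient
# fitting, shrinkage, sweeps) is validated against these, because the
# generative truth is known per participant.

participant_labels <- function(k) sprintf("P%02d", seq_len(k))

#' Simulate a foot-placement kinematic cohort with known control gains
#'
#' Draws one true 2x3 gain matrix per participant from the population stated
#' in the spec, then simulates steps: midstance pelvis-state deviations from
#' the stated covariance, next-foot-position deviations as gain times state
#' plus i.i.d. Gaussian step noise, and absolute coordinates by adding the
#' configured trial means. Deterministic given `spec` (which includes the
#' seed).
#'
#' @param spec a [kinematic_cohort_spec()].
#' @return A list of class `kinematic_cohort` with elements
#'   \describe{
#'     \item{trials}{named list of per-participant data frames with columns
#'       `participant_id`, `step_index`, `x_pelvis`, `vx_pelvis`,
#'       `vy_pelvis`, `x_foot`, `y_foot` (SI units).}
#'     \item{truth}{data frame `participant_id`, `true_value` — the true
#'       sideways-foot / sideways-pelvis-velocity gain, the element later
#'       targeted by shrinkage.}
#'     \item{gains}{named list of the full true 2x3 gain matrices.}
#'     \item{spec}{the input spec, for provenance.}
#'   }
#' @export
simulate_kinematic_cohort <- function(spec) {
  if (!inherits(spec, "kinematic_cohort_spec"))
    stopf("`spec` must be a kinematic_cohort_spec")
  ids <- participant_labels(spec$n_participants)
  withr::with_seed(spec$seed, {
    trials <- vector("list", spec$n_participants)
    gains <- vector("list", spec$n_participants)
    for (i in seq_len(spec$n_participants)) {
      J <- spec$population_gain_mean +
        matrix(stats::rnorm(6), 2, 3) * spec$population_gain_sd
      dP <- matrix(stats::rnorm(spec$n_steps * 3), spec$n_steps, 3) %*% spec$pelvis_chol
      eps <- matrix(stats::rnorm(spec$n_steps * 2), spec$n_steps, 2) *
        rep(spec$step_noise_sd, each = spec$n_steps)
      dS <- dP %*% t(J) + eps
      trials[[i]] <- data.frame(
        participant_id = ids[i],
        step_index = seq_len(spec$n_steps),
        x_pelvis = dP[, 1] + spec$pelvis_state_mean[1],
        vx_pelvis = dP[, 2] + spec$pelvis_state_mean[2],
        vy_pelvis = dP[, 3] + spec$pelvis_state_mean[3],
        x_foot = dS[, 1] + spec$foot_mean[1],
        y_foot = dS[, 2] + spec$foot_mean[2],
        stringsAsFactors = FALSE
      )
      dimnames(J) <- list(c("x_foot", "y_foot"),
                          c("x_pelvis", "vx_pelvis", "vy_pelvis"))
      gains[[i]] <- J
    }
  })
  names(trials) <- ids
  names(gains) <- ids
  truth <- data.frame(
    participant_id = ids,
    true_value = vapply(gains, function(J) J["x_foot", "vx_pelvis"], numeric(1)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  structure(list(trials = trials, truth = truth, gains = gains, spec = spec),
            class = "kinematic_cohort")
}

# Breath timestamps: mean interval plus Gaussian jitter, each interval
# re-drawn until strictly positive, accumulated until the trial ends.
# Sampling runs slightly past the nominal duration when needed so every
# trial carries at least `min_n` breaths.
breath_times <- function(duration, mean_int, jitter_sd, min_n = 4L) {
  ts <- numeric(0)
  t <- 0
  repeat {
    dt <- mean_int + if (jitter_sd > 0) stats::rnorm(1, 0, jitter_sd) else 0
    while (dt <= 0) dt <- mean_int + stats::rnorm(1, 0, jitter_sd)
    t <- t + dt
    if (t > duration && length(ts) >= min_n) break
    ts <- c(ts, t)
  }
  ts
}

#' Simulate a breath-by-breath metabolic cohort with known steady states
#'
#' Per participant, draws true \eqn{(a_0, a_1, \tau)} from the population in
#' the spec (\eqn{\tau} re-drawn until positive; \eqn{a_1 = 0} in resting
#' mode), emits jittered breath timestamps over the trial, and at each breath
#' an energy rate \eqn{a_0 + a_1 e^{-t/\tau}} plus measurement noise
#' (re-drawn for the rare sample that would go non-positive, so the
#' back-computed gas fluxes stay physical). The gas pair is back-computed at
#' the spec's fixed respiratory exchange ratio so that [brockway_rate()] on
#' it returns the emitted rate.
#'
#' @param spec a [metabolic_cohort_spec()] (or [resting_cohort_spec()]).
#' @return A list of class `metabolic_cohort` with elements
#'   \describe{
#'     \item{trials}{named list of per-participant data frames with columns
#'       `participant_id`, `condition` ("walking" or "resting"), `t_s`,
#'       `vo2_mls_kg`, `vco2_mls_kg`, `edot_w_kg`.}
#'     \item{truth}{data frame `participant_id`, `true_value` — the true
#'       steady-state (resting-mode: constant) rate \eqn{a_0}, W/kg.}
#'     \item{params}{data frame of the full generative `a0`, `a1`, `tau`.}
#'     \item{spec}{the input spec.}
#'   }
#' @export
simulate_metabolic_cohort <- function(spec) {
  if (!inherits(spec, "metabolic_cohort_spec"))
    stopf("`spec` must be a metabolic_cohort_spec")
  ids <- participant_labels(spec$n_participants)
  condition <- if (spec$resting_mode) "resting" else "walking"
  gas_denom <- .brockway_o2 + .brockway_co2 * spec$rer
  withr::with_seed(spec$seed, {
    trials <- vector("list", spec$n_participants)
    params <- data.frame(participant_id = ids, a0 = NA_real_, a1 = NA_real_,
                         tau = NA_real_, stringsAsFactors = FALSE)
    for (i in seq_len(spec$n_participants)) {
      a0 <- stats::rnorm(1, spec$population_a0_mean, spec$population_a0_sd)
      a1 <- if (spec$resting_mode) 0 else
        stats::rnorm(1, spec$population_a1_mean, spec$population_a1_sd)
      tau <- stats::rnorm(1, spec$population_tau_mean, spec$population_tau_sd)
      while (tau <= 0) tau <- stats::rnorm(1, spec$population_tau_mean,
                                           spec$population_tau_sd)
      ts <- breath_times(spec$trial_duration, spec$mean_breath_interval,
                         spec$breath_interval_jitter_sd, spec$min_breaths)
      mu <- a0 + a1 * exp(-ts / tau)
      edot <- mu + if (spec$measurement_noise_sd > 0)
        stats::rnorm(length(ts), 0, spec$measurement_noise_sd) else 0
      while (any(edot <= 0)) {       # keep rates (hence gas fluxes) physical
        j <- which(edot <= 0)
        edot[j] <- mu[j] + stats::rnorm(length(j), 0, spec$measurement_noise_sd)
      }
      vo2 <- edot / gas_denom
      trials[[i]] <- data.frame(
        participant_id = ids[i],
        condition = condition,
        t_s = ts,
        vo2_mls_kg = vo2,
        vco2_mls_kg = spec$rer * vo2,
        edot_w_kg = edot,
        stringsAsFactors = FALSE
      )
      params$a0[i] <- a0; params$a1[i] <- a1; params$tau[i] <- tau
    }
  })
  names(trials) <- ids
  truth <- data.frame(participant_id = ids, true_value = params$a0,
                      stringsAsFactors = FALSE)
  structure(list(trials = trials, truth = truth, params = params, spec = spec),
            class = "metabolic_cohort")
}
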