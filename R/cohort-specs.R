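# Specifications for the synthetic cohort generators. Defaults mirror the
# three study-scale cohorts the package targets: an 8-participant treadmill
# gait cohort with 100 steps per trial, an 11-participant circle-walking
# metabolic cohort with ~54 breaths over 6.5 min, and a 27-participant
# resting cohort with ~40 breaths.

#' Specification for a synthetic foot-placement (kinematic) cohort
#'
#' Each participant obeys a linear foot-placement control law: deviations of
#' the next stance-foot position (sideways, fore-aft) from its trial mean are
#' a 2x3 gain matrix J times deviations of the midstance pelvis state
#' (sideways position, sideways velocity, forward velocity), plus Gaussian
#' step noise. Participants differ in their true J, drawn entrywise from a
#' population normal.
#'
#' Default gains put the sideways-foot / sideways-pelvis-velocity sensitivity
#' (the element later targeted by shrinkage) at 0.30 s with a
#' between-participant s.d. of 0.08 s, in the range reported for young
#' adults walking on a treadmill; pelvis-state deviations have s.d. 1 cm /
#' 3 cm s^-1, and residual foot-placement noise 1 cm per axis.
#'
#' @param n_participants cohort size k (>= 4, so the shrinkage factor's k-3
#'   term is positive).
#' @param n_steps steps recorded per participant (>= 7 so a 3-regressor
#'   per-output regression is identifiable with residual degrees of freedom).
#' @param population_gain_mean,population_gain_sd 2x3 matrices: rows are the
#'   outputs (x_foot, y_foot), columns the inputs (x_pelvis, vx_pelvis,
#'   vy_pelvis); units dimensionless (position inputs) or s (velocity inputs).
#' @param pelvis_state_cov 3x3 symmetric positive-definite covariance of
#'   midstance pelvis-state deviations (m, m/s, m/s).
#' @param step_noise_sd residual foot-placement s.d. (m); scalar or one value
#'   per output axis.
#' @param pelvis_state_mean,foot_mean absolute offsets P* and S* added so
#'   trials carry realistic absolute coordinates (m, m/s, m/s and m, m).
#' @param seed integer RNG seed; the generator is deterministic given the
#'   spec.
#' @return An object of class `kinematic_cohort_spec`.
#' @seealso [simulate_kinematic_cohort()]
#' @export
kinematic_cohort_spec <- function(n_participants = 8,
                                  n_steps = 100,
                                  population_gain_mean = matrix(c(0.90, 0.30, 0.02,
                                                                  0.05, 0.02, 0.25),
                                                                nrow = 2, byrow = TRUE),
                                  population_gain_sd = matrix(c(0.15, 0.08, 0.02,
                                                                0.05, 0.02, 0.08),
                                                              nrow = 2, byrow = TRUE),
                                  pelvis_state_cov = diag(c(0.010, 0.030, 0.030)^2),
                                  step_noise_sd = c(0.010, 0.010),
                                  pelvis_state_mean = c(0, 0, 1.3),
                                  foot_mean = c(0.08, 0.72),
                                  seed = 1L) {
  spec <- list(
    n_participants = check_count(n_participants, "n_participants", min = 4L),
    n_steps = check_count(n_steps, "n_steps", min = 7L),
    population_gain_mean = as.matrix(population_gain_mean),
    population_gain_sd = as.matrix(population_gain_sd),
    pelvis_state_cov = as.matrix(pelvis_state_cov),
    step_noise_sd = rep_len(as.numeric(step_noise_sd), 2L),
    pelvis_state_mean = rep_len(as.numeric(pelvis_state_mean), 3L),
    foot_mean = rep_len(as.numeric(foot_mean), 2L),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (!all(dim(spec$population_gain_mean) == c(2, 3)))
    stopf("`population_gain_mean` must be a 2x3 matrix")
  if (!all(dim(spec$population_gain_sd) == c(2, 3)) ||
      any(spec$population_gain_sd < 0))
    stopf("`population_gain_sd` must be a 2x3 matrix of values >= 0")
  if (any(spec$step_noise_sd < 0)) stopf("`step_noise_sd` must be >= 0")
  V <- spec$pelvis_state_cov
  if (!all(dim(V) == c(3, 3)) || max(abs(V - t(V))) > 1e-10)
    stopf("`pelvis_state_cov` must be a symmetric 3x3 matrix")
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch))
    stopf("`pelvis_state_cov` is not positive-definite")
  spec$pelvis_chol <- ch
  structure(spec, class = "kinematic_cohort_spec")
}

#' Specification for a synthetic breath-by-breath metabolic cohort
#'
#' Each participant's metabolic rate follows an exponential approach to
#' steady state, \eqn{\dot{E}(t) = a_0 + a_1 e^{-t/\tau}}, sampled at
#' irregular breath times (mean interval plus Gaussian jitter, re-drawn until
#' positive) with additive Gaussian measurement noise. True \eqn{(a_0, a_1,
#' \tau)} vary between participants. In `resting_mode` the transient is
#' suppressed (\eqn{a_1 = 0}): trials represent quiet sitting at a constant
#' rate. Each emitted sample also carries a gas-exchange pair
#' \eqn{(\dot{V}_{O_2}, \dot{V}_{CO_2})} back-computed from \eqn{\dot{E}} at
#' a fixed respiratory exchange ratio, so that [brockway_rate()] reproduces
#' the emitted rate exactly.
#'
#' Walking defaults: 11 participants, 390 s trials, 7.2 s mean breath
#' interval (about 54 breaths), steady state 4.3 +/- 0.35 W/kg, transient
#' amplitude -2.8 +/- 0.4 W/kg (rates rise from near-resting toward steady
#' state), time constant 40 +/- 10 s, measurement noise 0.45 W/kg (about a 10% coefficient of variation, typical breath-to-breath scatter). For a
#' resting cohort see [resting_cohort_spec()].
#'
#' @param n_participants cohort size k.
#' @param trial_duration trial length (s).
#' @param mean_breath_interval mean breath spacing (s).
#' @param breath_interval_jitter_sd s.d. of breath-interval jitter (s).
#' @param population_a0_mean,population_a0_sd steady-state rate distribution
#'   (W/kg).
#' @param population_a1_mean,population_a1_sd transient amplitude
#'   distribution (W/kg); ignored (forced to 0) in `resting_mode`.
#' @param population_tau_mean,population_tau_sd time-constant distribution
#'   (s); draws are repeated until positive.
#' @param measurement_noise_sd additive breath-level noise (W/kg).
#' @param min_breaths guaranteed minimum breaths per trial; sampling extends
#'   slightly past `trial_duration` when jitter would otherwise leave a
#'   trial short. Defaults to the nominal count
#'   `floor(trial_duration / mean_breath_interval)`, mirroring studies that
#'   report a minimum number of breaths across participants.
#' @param rer fixed respiratory exchange ratio used to back-compute the gas
#'   pair from the emitted rate.
#' @param resting_mode logical; if `TRUE`, trials are quiet sitting
#'   (`a1 = 0`, condition "resting").
#' @param seed integer RNG seed.
#' @return An object of class `metabolic_cohort_spec`.
#' @seealso [simulate_metabolic_cohort()]
#' @export
metabolic_cohort_spec <- function(n_participants = 11,
                                  trial_duration = 390,
                                  mean_breath_interval = 7.2,
                                  breath_interval_jitter_sd = 1.5,
                                  population_a0_mean = 4.3,
                                  population_a0_sd = 0.35,
                                  population_a1_mean = -2.8,
                                  population_a1_sd = 0.4,
                                  population_tau_mean = 40,
                                  population_tau_sd = 10,
                                  measurement_noise_sd = 0.45,
                                  min_breaths = NULL,
                                  rer = 0.85,
                                  resting_mode = FALSE,
                                  seed = 1L) {
  spec <- list(
    n_participants = check_count(n_participants, "n_participants", min = 4L),
    trial_duration = check_number(trial_duration, "trial_duration", 0, strict = TRUE),
    mean_breath_interval = check_number(mean_breath_interval, "mean_breath_interval",
                                        0, strict = TRUE),
    breath_interval_jitter_sd = check_number(breath_interval_jitter_sd,
                                             "breath_interval_jitter_sd", 0),
    population_a0_mean = check_number(population_a0_mean, "population_a0_mean"),
    population_a0_sd = check_number(population_a0_sd, "population_a0_sd", 0),
    population_a1_mean = check_number(population_a1_mean, "population_a1_mean"),
    population_a1_sd = check_number(population_a1_sd, "population_a1_sd", 0),
    population_tau_mean = check_number(population_tau_mean, "population_tau_mean",
                                       0, strict = TRUE),
    population_tau_sd = check_number(population_tau_sd, "population_tau_sd", 0),
    measurement_noise_sd = check_number(measurement_noise_sd,
                                        "measurement_noise_sd", 0),
    rer = check_number(rer, "rer", 0, strict = TRUE),
    resting_mode = isTRUE(resting_mode),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (spec$trial_duration < 3 * spec$mean_breath_interval)
    stopf("`trial_duration` (%g s) is shorter than 3 mean breath intervals: too few samples to fit",
          spec$trial_duration)
  spec$min_breaths <- check_count(
    min_breaths %||% floor(spec$trial_duration / spec$mean_breath_interval),
    "min_breaths", min = 4L)
  structure(spec, class = "metabolic_cohort_spec")
}

#' Specification for a synthetic resting (quiet-sitting) metabolic cohort
#'
#' Convenience wrapper around [metabolic_cohort_spec()] with
#' `resting_mode = TRUE` and resting-scale defaults: 27 participants, 390 s
#' trials at a 9.75 s mean breath interval (about 40 breaths), resting rate
#' 1.45 +/- 0.15 W/kg and 0.12 W/kg breath noise — a deliberately low
#' within/between variance ratio, the regime in which shrinkage has the
#' least to offer.
#'
#' @param n_participants cohort size.
#' @param seed integer RNG seed.
#' @param ... further arguments passed to [metabolic_cohort_spec()].
#' @return An object of class `metabolic_cohort_spec` with `resting_mode`
#'   set.
#' @export
resting_cohort_spec <- function(n_participants = 27, seed = 1L, ...) {
  args <- list(...)
  defaults <- list(
    trial_duration = 390,
    mean_breath_interval = 9.75,
    breath_interval_jitter_sd = 2,
    population_a0_mean = 1.45,
    population_a0_sd = 0.15,
    population_a1_mean = 0,
    population_a1_sd = 0,
    measurement_noise_sd = 0.12
  )
  for (nm in names(defaults))
    if (is.null(args[[nm]])) args[[nm]] <- defaults[[nm]]
  args$n_participants <- n_participants
  args$seed <- seed
  args$resting_mode <- TRUE
  do.call(metabolic_cohort_spec, args)
}
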