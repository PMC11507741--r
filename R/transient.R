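# Steady-state metabolic rate from breath-by-breath data: exponential
# transient fit E(t) = a0 + a1*exp(-t/tau) by nonlinear least squares, with
# bootstrap standard errors for the steady-state asymptote a0.
#
# The fit profiles tau (variable projection): for any fixed tau the model is
# linear in (a0, a1), so the conditional least-squares solution and its RSS
# have closed forms. The profiled RSS is minimized over a bounded log-spaced
# tau grid and refined by golden-section search. This is exactly the
# least-squares optimum of the three-parameter model, found without
# iterative full-parameter optimization — important because the bootstrap
# refits the model thousands of times.

trial_edot <- function(trial) {
  if ("edot_w_kg" %in% names(trial)) return(trial$edot_w_kg)
  if (all(c("vo2_mls_kg", "vco2_mls_kg") %in% names(trial)))
    return(brockway_rate(trial$vo2_mls_kg, trial$vco2_mls_kg))
  stopf("trial has neither `edot_w_kg` nor gas-flux columns to convert")
}

# Conditional linear solve at fixed tau. Returns c(a0, a1, rss); a1 is NA
# when the exponential regressor is numerically collinear with the
# intercept (tau far above the window span).
.exp_profile <- function(tau, t, y, syy, sy) {
  n <- length(t)
  e <- exp(-t / tau)
  se <- sum(e); see <- sum(e * e); sey <- sum(e * y)
  det <- n * see - se * se
  if (det <= 1e-12 * n * max(see, 1e-300)) {
    a0 <- sy / n
    return(c(a0, NA_real_, syy - a0 * sy))
  }
  a0 <- (see * sy - se * sey) / det
  a1 <- (n * sey - se * sy) / det
  c(a0, a1, max(syy - a0 * sy - a1 * sey, 0))
}

#' Fit an exponential approach to metabolic steady state
#'
#' Fits \eqn{\dot{E}(t) = a_0 + a_1 e^{-t/\tau}} to the FIRST `n_points`
#' breaths of a trial by least squares, with the time constant bounded to
#' (0.1 s, 10 x window span). `a0` is the steady-state asymptote — the
#' estimand for walking metabolic trials. If the window carries no
#' resolvable transient (fitted `|a1|` below twice its asymptotic standard
#' error, or an unidentifiable exponential term), the fit falls back to the
#' sample mean with `a1 = 0`, which keeps `a0` well-defined on resting-like
#' data instead of letting `tau` wander.
#'
#' @param trial data frame with columns `t_s` and `edot_w_kg` (or gas-flux
#'   columns, converted via [brockway_rate()]).
#' @param n_points number of initial breaths to fit (>= 4); default all.
#' @return An object of class `transient_fit`: list with `a0`, `a1`, `tau`
#'   (s), `converged` (FALSE when the time constant ran to its bounds),
#'   `flat` (TRUE when the mean fallback was used), `rss`, `n_points_used`,
#'   `se` (asymptotic standard errors, named), `participant_id`.
#' @export
fit_exponential_transient <- function(trial, n_points = NULL) {
  if (!"t_s" %in% names(trial)) stopf("trial is missing the `t_s` column")
  y_all <- trial_edot(trial)
  n_avail <- nrow(trial)
  n_points <- if (is.null(n_points)) n_avail else check_count(n_points, "n_points", 4L)
  if (n_points < 4L) stopf("at least 4 breaths are needed; got %d", n_points)
  if (n_points > n_avail)
    stopf("n_points = %d exceeds the %d breaths available", n_points, n_avail)
  t <- trial$t_s[seq_len(n_points)]
  y <- y_all[seq_len(n_points)]
  if (is.unsorted(t)) stopf("breath times must be non-decreasing")
  pid <- if ("participant_id" %in% names(trial))
    as.character(trial$participant_id[1]) else NA_character_

  span <- max(t) - min(t)
  if (span <= 0) stopf("window has zero time span")
  lo <- 0.1
  hi <- 10 * span
  syy <- sum(y * y); sy <- sum(y)

  # profiled RSS on a log-spaced grid (vectorized), then golden-section
  # refinement of the best bracket
  taus <- exp(seq(log(lo), log(hi), length.out = 50L))
  E <- exp(outer(t, -1 / taus))
  n <- length(t)
  se_g <- colSums(E)
  see_g <- colSums(E * E)
  sey_g <- colSums(E * y)
  det_g <- n * see_g - se_g^2
  ok <- det_g > 1e-12 * n * pmax(see_g, 1e-300)
  a0_g <- ifelse(ok, (see_g * sy - se_g * sey_g) / det_g, sy / n)
  a1_g <- ifelse(ok, (n * sey_g - se_g * sy) / det_g, 0)
  rss_grid <- syy - a0_g * sy - a1_g * sey_g
  rss_of <- function(tau) .exp_profile(tau, t, y, syy, sy)[3]
  i <- which.min(rss_grid)
  bracket <- c(taus[max(i - 1L, 1L)], taus[min(i + 1L, length(taus))])
  opt <- stats::optimize(rss_of, interval = bracket,
                         tol = max(1e-9, 1e-8 * bracket[2]))
  tau_hat <- opt$minimum
  sol <- .exp_profile(tau_hat, t, y, syy, sy)
  a0 <- sol[1]; a1 <- sol[2]; rss <- sol[3]

  fallback <- function() {
    m <- mean(y)
    structure(list(a0 = m, a1 = 0, tau = span / 3, converged = TRUE,
                   flat = TRUE, rss = sum((y - m)^2),
                   n_points_used = n_points,
                   se = c(a0 = stats::sd(y) / sqrt(n_points), a1 = NA_real_,
                          tau = NA_real_),
                   participant_id = pid),
              class = "transient_fit")
  }
  if (!is.finite(a1)) return(fallback())

  # asymptotic covariance from the model Jacobian at the optimum
  e <- exp(-t / tau_hat)
  Jm <- cbind(a0 = 1, a1 = e, tau = a1 * t * e / tau_hat^2)
  sigma2 <- rss / max(n_points - 3L, 1L)
  cov <- tryCatch(chol2inv(chol(crossprod(Jm))) * sigma2,
                  error = function(e) NULL)
  se <- if (is.null(cov)) c(a0 = NA_real_, a1 = NA_real_, tau = NA_real_)
        else stats::setNames(sqrt(pmax(diag(cov), 0)), c("a0", "a1", "tau"))
  if (is.finite(se["a1"]) && se["a1"] > 0 && abs(a1) < 2 * se["a1"])
    return(fallback())

  at_bound <- tau_hat <= lo * (1 + 1e-6) || tau_hat >= hi * (1 - 1e-6)
  structure(list(a0 = a0, a1 = a1, tau = tau_hat, converged = !at_bound,
                 flat = FALSE, rss = rss, n_points_used = n_points,
                 se = se, participant_id = pid),
            class = "transient_fit")
}

#' @export
print.transient_fit <- function(x, ...) {
  cat("Exponential transient fit",
      if (!is.na(x$participant_id)) sprintf(" (%s)", x$participant_id), "\n",
      sep = "")
  cat(sprintf("  a0 = %.4f W/kg, a1 = %.4f W/kg, tau = %.2f s (%s%s)\n",
              x$a0, x$a1, x$tau,
              if (x$converged) "converged" else "tau at bounds",
              if (x$flat) ", flat fallback" else ""))
  invisible(x)
}

#' Steady-state metabolic rate with bootstrap standard error
#'
#' Estimates the steady-state rate `a0` from the first `n_points` breaths
#' via [fit_exponential_transient()], and its squared standard error as the
#' empirical variance of `a0` over `n_boot` bootstrap refits of the same
#' window. Case resampling (the default) resamples breaths with replacement
#' and re-sorts them by time before refitting; residual resampling keeps the
#' breath times and resamples fit residuals onto the fitted curve.
#' Deterministic given `seed`.
#'
#' @param trial metabolic trial data frame (see
#'   [fit_exponential_transient()]).
#' @param n_points breaths used for the estimate; default all.
#' @param n_boot number of bootstrap refits (>= 100).
#' @param seed integer seed for the bootstrap resampling.
#' @param resample `"case"` or `"residual"`.
#' @return A one-row data frame from [point_estimate()], method
#'   `"transient_a0"`, with the full-window fit attached as attribute
#'   `"fit"`.
#' @export
steady_state_estimate <- function(trial, n_points = NULL, n_boot = 1000,
                                  seed = 1L, resample = c("case", "residual")) {
  resample <- match.arg(resample)
  n_boot <- check_count(n_boot, "n_boot", min = 100L)
  fit <- fit_exponential_transient(trial, n_points)
  n <- fit$n_points_used
  t <- trial$t_s[seq_len(n)]
  y <- trial_edot(trial)[seq_len(n)]
  fitted <- fit$a0 + fit$a1 * exp(-t / fit$tau)
  resid <- y - fitted

  a0s <- numeric(n_boot)
  conv <- logical(n_boot)
  withr::with_seed(seed, {
    for (b in seq_len(n_boot)) {
      if (resample == "case") {
        idx <- sort(sample.int(n, n, replace = TRUE))
        tb <- t[idx]; yb <- y[idx]
      } else {
        tb <- t
        yb <- fitted + sample(resid, n, replace = TRUE)
      }
      fb <- tryCatch(
        fit_exponential_transient(data.frame(t_s = tb, edot_w_kg = yb), n),
        error = function(e) NULL)
      if (is.null(fb)) {
        conv[b] <- FALSE
        a0s[b] <- NA_real_
      } else {
        conv[b] <- fb$converged
        a0s[b] <- fb$a0
      }
    }
  })
  frac_bad <- mean(!conv)
  if (frac_bad > 0.2)
    stopf("%.0f%% of bootstrap refits failed to converge; use a larger n_points",
          100 * frac_bad)
  est <- point_estimate(fit$participant_id %||% NA_character_,
                        value = fit$a0,
                        variance = stats::var(a0s[conv]),
                        n_used = n,
                        method = "transient_a0")
  attr(est, "fit") <- fit
  est
}
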