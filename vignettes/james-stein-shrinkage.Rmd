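---
title: "Shrinking short-trial biomechanical estimates toward the cohort mean"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shrinking short-trial biomechanical estimates toward the cohort mean}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steinshrink)
```

## The estimation problem

Biomechanical and metabolic experiments estimate one parameter per
participant from a time series: a foot-placement control gain from a few
minutes of treadmill steps, a steady-state metabolic rate from
breath-by-breath gas exchange, a resting rate from quiet sitting. Short
trials make each per-participant estimate (an MLE: a regression
coefficient, a nonlinear-fit asymptote, or a plain mean) noisy. When a
cohort of $k$ participants is measured at once, the James-Stein estimator
(JSE) improves the *total* squared error across the cohort by pulling every
estimate toward the cohort grand mean.

Given estimates $y_i$ with error variances $\sigma_i^2$, $i = 1 \dots k$,
the shrunk estimates are

$$z_i = \bar{y} + c\,(y_i - \bar{y}), \qquad
  c = 1 - \frac{\overline{SE}^2\,(k-3)}{\sum_i (y_i - \bar{y})^2},$$

where $\bar{y}$ is the grand mean and $\overline{SE}^2$ the mean of the
$\sigma_i^2$ (the mean is used when variances are unequal). $c = 1$ leaves
the MLEs alone; $c = 0$ collapses everyone to $\bar{y}$. Accuracy is scored
by summed squared error against true values $x_i$:
$SSE_{MLE} = \sum_i (x_i - y_i)^2$ and $SSE_{JSE} = \sum_i (x_i - z_i)^2$.
`compute_shrinkage()` and `compare_accuracy()` implement exactly this;
`stein_dominance_check()` verifies by Monte Carlo that the positive-part
JSE's expected SSE never exceeds the MLE's (whose risk is exactly
$k\sigma^2$), for any configuration of true means.

Assumptions worth keeping in mind: the derivation treats the $y_i$ as
independent and roughly Gaussian around their true values, with
comparable error variances, and the cohort as one population. Normality is
not critical — violations mainly shave off some of the gain — but strongly
clustered cohorts (distinct subpopulations) erode it; shrinking within
clusters would then be preferable, which this package deliberately does not
automate.

### Design choices in the shrinkage core

* **Positive part by default.** A negative $c$ (possible when the pooled
  error variance is large relative to the spread) would push estimates
  *past* the grand mean. The positive-part variant replaces $c < 0$ with 0
  and dominates the raw estimator, so it is the default; raw mode is kept
  for exact reproduction of the formula.
* **$k - 3$, not $k - 2$.** Shrinking toward the *estimated* grand mean
  costs one more degree of freedom than shrinking toward a fixed origin;
  the grand-mean-targeted factor with $k - 3$ is implemented verbatim and
  requires $k \ge 4$.
* **Mean of variances.** With unequal $\sigma_i^2$ the mean enters the
  factor; inverse-variance weighting of the grand mean is deliberately
  *not* used — the estimator shrinks toward the unweighted mean.
* **Degenerate cohorts.** Zero pooled variance gives $c = 1$ (perfect MLEs
  are not shrunk). All-equal $y_i$ with positive pooled variance makes the
  raw factor undefined: raw mode errors, positive-part mode applies full
  shrinkage with a warning.
* **Paired tests.** The accuracy comparison reports a two-sided paired
  t-test on per-participant *squared* errors of the two estimators
  (absolute and signed variants are options), plus a truths-vs-MLEs paired
  t-test as a bias check. When a test degenerates (identical pairs, e.g.
  $c = 1$) the p-value is `NA` rather than an error.

## The three per-participant estimators

**Foot-placement Jacobian** (`fit_foot_placement_jacobian()`): the linear
control law $\Delta S = J\,\Delta P$ maps midstance pelvis-state deviations
$P = (X_{pelvis}, \dot X_{pelvis}, \dot Y_{pelvis})$ to next-foot-position
deviations $S = (X_{foot}, Y_{foot})$. Each output row of the $2 \times 3$
gain matrix is an ordinary least-squares fit on inputs and outputs centered
by their means over the fitted window; centering removes the intercept, so
coefficient variances use residual degrees of freedom $n - 3$. The element
carried into shrinkage is $\partial X_{foot} / \partial \dot X_{pelvis}$
(units s), the sideways-velocity sensitivity — configurable via
`extract_gain_element()`.

**Steady-state metabolic rate** (`fit_exponential_transient()`,
`steady_state_estimate()`): breath-by-breath gas fluxes convert to power
via the Brockway combination
$\dot E = 16.58\,\dot V_{O_2} + 4.51\,\dot V_{CO_2}$ (W/kg from
mL s$^{-1}$ kg$^{-1}$), and the transient toward steady state is
$\dot E(t) = a_0 + a_1 e^{-t/\tau}$ with $a_0$ the estimand. Its squared
standard error is the variance of $a_0$ over bootstrap refits of the same
window — case resampling of breaths by default (resample, re-sort by time,
refit), residual resampling as an option, B = 1000 by default,
deterministic given a seed.

**Resting rate** (`resting_mean_estimate()`): the mean of the first $n$
breaths. Because resting noise is comparable across people, one pooled
squared standard error is shared by the cohort: every participant's
deviations from their own window mean are pooled, and the variance of an
$n$-sample mean of those deviations is bootstrapped (B = 2000 default).

### Numerical choices

* **Truncation = first $n$ records.** Metabolic transients live at the
  start of a trial, so a truncated estimate must keep the start; any other
  window would change the estimand. Window means (the regression's
  $P^*, S^*$) are recomputed per truncation, so a short window is treated
  exactly as a short trial would have been.
* **The exponential fit profiles $\tau$.** For fixed $\tau$ the model is
  linear in $(a_0, a_1)$, so the fit minimizes the profiled RSS over
  $\tau \in (0.1\,\mathrm{s},\, 10 \times$ window span$)$ — a 50-point
  log-spaced grid scan followed by golden-section refinement, with the
  conditional linear solve in closed form. This reaches the same
  least-squares optimum as an iterative three-parameter optimizer (a test
  checks agreement with an independent Levenberg-Marquardt
  implementation) while being fast and initialization-free, which matters
  because the bootstrap refits the model thousands of times. A fit whose
  $\tau$ lands on the bounds is flagged non-converged; bootstrap refits
  failing at a rate above 20% abort with advice to enlarge the window.
* **Flat-signal fallback.** On resting-like windows the exponential term is
  unidentifiable. If the fitted $|a_1|$ is below twice its asymptotic
  standard error (from the model Jacobian at the optimum — chosen over a
  nested bootstrap for speed and determinism), or the exponential regressor
  is numerically collinear with the intercept, the fit falls back to the
  window mean with $a_1 = 0$. $a_0$ remains the estimand either way.
* **SSE decay fit.** The sweep summarises $SSE_{JSE}(n)$ by
  $a\,e^{-b n}$, fitted as ordinary least squares of $\log SSE$ on $n$
  (amplitude $e^{\mathrm{intercept}}$, rate $-$slope). Non-positive SSEs
  are dropped with a warning; fewer than three usable points is an error.

## Truth: full-trial proxy versus generative truth

True parameter values are unknowable from finite data. `run_sweep()`
follows the standard device: the estimate from the *full* trial
(100 steps / 54 breaths / 40 breaths by default) stands in for truth, and
shorter-window estimates are scored against it. With synthetic cohorts the
generative truth can be supplied instead (`truths =`), which
`recovery_study()` does across replicates.

Both conventions are kept because their disagreement is itself
informative: the proxy has error of its own, so as the MLE window
approaches the truth window the apparent percent reduction becomes
unreliable and can flip negative — a real artifact of the proxy, which the
sweep reproduces and a test demonstrates.

`recovery_study()` reports two reduction summaries per window size: the
mean of per-replicate percent reductions, and the *pooled* reduction
$100\,(1 - \overline{SSE}_{JSE} / \overline{SSE}_{MLE})$. The pooled form
matches how a percent reduction is naturally computed from cohort SSEs and
is far less noisy — the per-replicate ratio is heavy-tailed, since one
replicate with a near-zero MLE SSE dominates its mean. Trend statements in
the tests use the pooled form.

## What the synthetic cohorts emulate — and what they do not

The generators produce cohorts with the statistical structure the analysis
assumes, at the scale of the motivating datasets, with known truth:

* **Kinematic** (`kinematic_cohort_spec()`): k = 8 participants, 100 steps.
  Per participant a true gain matrix is drawn entrywise from a population
  normal; the shrinkage target element is centred at 0.30 s with
  between-participant s.d. 0.08 s, in the range reported for young adults.
  Pelvis-state deviations are zero-mean Gaussian (s.d. 1 cm, 3 cm/s,
  3 cm/s), step noise 1 cm per foot axis.
* **Walking metabolic** (`metabolic_cohort_spec()`): k = 11, 390 s trials,
  7.2 s mean breath interval with 1.5 s jitter (about 54 breaths; a
  per-trial minimum breath count is guaranteed, mirroring studies that
  quote minimum counts). Steady state 4.3 ± 0.35 W/kg between
  participants; transient amplitude −2.8 ± 0.4 W/kg (rates rise from
  near-resting); τ = 40 ± 10 s; breath noise 0.45 W/kg, about a 10%
  coefficient of variation — typical breath-to-breath scatter. These were
  chosen once so that short-window estimation error is comparable to or
  exceeds the between-participant spread, the regime in which shrinkage has
  a lot to offer and which the walking dataset exemplifies.
* **Resting** (`resting_cohort_spec()`): k = 27, about 40 breaths at
  9.75 s spacing, 1.45 ± 0.15 W/kg with 0.12 W/kg breath noise — a low
  within/between variance ratio, the regime where shrinkage helps least.
  Gas-flux pairs are back-computed from the emitted rate at a fixed
  respiratory exchange ratio (0.85) so the Brockway step is exercised
  end-to-end; the rare noise draw that would push a rate non-positive is
  redrawn to keep fluxes physical.

Not emulated: raw marker trajectories or respiratory waveforms (inputs are
step- and breath-level tables by design); drifting or autocorrelated
breath noise; outlier breaths; non-Gaussian or clustered populations.
Passing tests therefore demonstrate that the pipeline behaves correctly
under its own assumptions — not that real cohorts satisfy those
assumptions.

## What the replicated studies show

At the defaults above, replicated recovery studies (200 replicates for the
kinematic and resting cohorts; the walking cohort at smaller scale because
each replicate needs thousands of bootstrap refits) show: pooled percent
reduction decreasing as windows lengthen; the shrinkage factor rising
toward 1; expected SSE of the positive-part JSE at or below the MLE's
across the kinematic and resting grids; and the resting cohort gaining far
less than the kinematic one, as its variance ratio predicts.

Two honest caveats. First, the nonlinear transient fit carries a small
finite-sample bias in $a_0$ (of order 1% of its value at short windows,
well under a quarter of the estimator's own error spread) from skewed
$\tau$ estimates; the two linear estimators are exactly unbiased.
Second, for the walking cohort the bootstrap variance of $a_0$
is right-skew inflated at mid-size windows (occasional refits with long
$\tau$ extrapolate $a_0$ far). The inflated $\overline{SE}^2$ overshrinks,
and close to the truth size — where the attainable gain is tiny — the
expected SSE of the JSE can slightly exceed the MLE's. Dominance is a
theorem only when the error variances are known; with estimated, skewed
variances it can genuinely fail at the margin. Tests assert walking
dominance on the short-window range (15–27 of 54 breaths) where the
premise holds; users applying the pipeline very close to the full trial
length should expect little gain either way.

## Problem sizes in the test suite

Simulation-backed tests use sizes chosen to make each check sharp but
cheap: 1000 random cohorts for the shrinkage invariants; a
16-cell (k × spread) dominance grid at 2000 replicates; 100 random trials
for the regression-versus-normal-equations oracle; 500 replicates for
estimator-consistency medians; 200 replicates for the sweep trend curves;
200 participants at 1000 steps for the regression-variance calibration.
The acceptance script replays the pipeline at the default cohort scales
with 15–50 cohort replicates per snapshot.
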