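# steinshrink

James-Stein shrinkage for per-participant parameter estimates from short
biomechanical and metabolic time-series.

## The problem

Experiments in gait and exercise physiology estimate one parameter per
participant from a time series — a foot-placement control gain from a few
minutes of treadmill steps, a steady-state metabolic rate from
breath-by-breath indirect calorimetry, a resting rate from quiet sitting.
Short trials (desirable for vulnerable populations, or for the many
repeated trials of human-in-the-loop device optimization) make each
per-participant estimate noisy. When a cohort of k participants is measured,
each person's estimate can be improved *on average across the cohort* by
shrinking it toward the cohort grand mean.

Given per-participant MLEs $y_i$ with error variances $\sigma_i^2$,
$i = 1 \dots k$, the James-Stein estimates are

$$z_i = \bar{y} + c\,(y_i - \bar{y}), \qquad
  c = 1 - \frac{\overline{SE}^2 (k-3)}{\sum_i (y_i - \bar{y})^2},$$

with $\bar{y}$ the grand mean and $\overline{SE}^2$ the mean of the error
variances; negative $c$ is clamped to zero (the positive-part estimator,
the default). Accuracy is scored by summed squared error against true
values $x_i$: $SSE_{MLE} = \sum_i (x_i - y_i)^2$ versus
$SSE_{JSE} = \sum_i (x_i - z_i)^2$.

The package implements the full pipeline for three estimation problems:

- **foot-placement control**: per-output least-squares regression of
  next-foot-position deviations on midstance pelvis-state deviations
  (2×3 Jacobian; the sideways-velocity element is the shrinkage target);
- **walking metabolic rate**: Brockway conversion
  $\dot E = 16.58\,\dot V_{O_2} + 4.51\,\dot V_{CO_2}$, exponential
  transient fit $\dot E(t) = a_0 + a_1 e^{-t/\tau}$, bootstrap standard
  error for $a_0$;
- **resting metabolic rate**: window means with a pooled-deviation
  bootstrap standard error shared across the cohort;

plus trial-duration truncation sweeps against full-trial truth proxies,
exponential SSE-decay fits, Monte-Carlo dominance and bias–variance
checks, and synthetic cohort generators with known ground truth. See the
methods vignette (`vignettes/james-stein-shrinkage.Rmd`) for the model,
assumptions, and design choices.

## Worked example

Simulate a study-scale gait cohort (k = 8, 100 steps each), estimate the
foot-placement gain from only the first 25 steps of each trial, shrink,
and compare against the generative truth:

```r
library(steinshrink)

cohort <- simulate_kinematic_cohort(kinematic_cohort_spec(seed = 42))
est <- do.call(rbind, lapply(cohort$trials, function(tr)
  extract_gain_element(fit_foot_placement_jacobian(tr, n_steps = 25))))
(shr <- compute_shrinkage(est))
#> James-Stein shrinkage: k = 8 participants
#>   grand mean   = 0.34758
#>   pooled SE^2  = 0.0051041
#>   shrinkage c  = 0.6642 (raw 0.6642)
compare_accuracy(cohort$truth, shr)
#> SSE (MLE) = 0.03217, SSE (JSE) = 0.024496, reduction = 23.9%
#>   paired t on squared errors: p = 0.298; truth vs MLE: p = 0.6155
```

At 25 steps the cohort's estimates are shrunk about a third of the way
toward their mean (c = 0.66), cutting the cohort's total squared error by
24% on this draw. A truncation sweep shows how the gain concentrates at
short trials — and how comparisons against a *finite-trial* truth proxy
degrade as the window approaches the proxy's own length (the negative
values at 45–90 steps, an artifact of proxy error, not of the estimator):

```r
run_sweep(cohort$trials, sweep_spec("kinematic", truncation_grid = seq(15, 90, 15)))
#> Truncation sweep (kinematic): 6 sizes, truth at 100 records
#>   n sse_mle sse_jse pct_reduction applied_c
#>  15 0.07673 0.03791      50.59350   0.63867
#>  30 0.02335 0.01725      26.11496   0.71687
#>  45 0.01538 0.01634      -6.23824   0.74814
#>  60 0.00410 0.00573     -39.81250   0.83104
#>  75 0.00126 0.00235     -86.90428   0.86443
#>  90 0.00030 0.00056     -87.23384   0.89446
#>   SSE decay: amplitude 0.1094, rate 0.05359 per record
```

`recovery_study()` averages such sweeps over many generated cohorts
against generative truth; `stein_dominance_check()` verifies the risk
ordering directly (at k = 16 equal true means and unit noise, MLE risk
≈ 16 = kσ², JSE far below).

## Analysis scripts

`analysis/01_simulate_cohorts.R` … `04_dominance_study.R` run the package
end-to-end: generate the three study-scale cohorts, take single-duration
shrinkage snapshots (25 / 21 / 20 records), sweep all truncation grids
with decay fits, and tabulate the dominance Monte Carlo. Each writes tidy
CSV/JSON under `results/`.

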