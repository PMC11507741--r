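# Trial-duration truncation sweep: for each truncation size, estimate,
# shrink, compare to the full-duration "true" values, and fit the error
# decay. This is the package's orchestration layer; all substance lives in
# the estimator and shrinkage modules.

#' Specification for a trial-duration truncation sweep
#'
#' @param dataset_kind `"kinematic"` (foot-placement gains),
#'   `"walking_metabolic"` (steady-state rate), or `"resting_metabolic"`
#'   (resting mean).
#' @param truncation_grid strictly increasing truncation sizes (steps or
#'   breaths), all below `truth_size`. Defaults per kind: 15–90 steps in
#'   steps of 5 against 100-step truth; 15–51 breaths in steps of 3 against
#'   54; 10–34 breaths in steps of 3 against 40.
#' @param truth_size records defining the full-duration truth proxy.
#' @param n_boot bootstrap replicates for metabolic error variances.
#' @param seed root seed; bootstrap streams are derived per (participant,
#'   truncation size) so reruns are identical.
#' @param positive_part use the positive-part shrinkage factor.
#' @param element for kinematic sweeps, the Jacobian element to shrink:
#'   character vector `c(output, input)`; default the sideways-foot /
#'   sideways-pelvis-velocity sensitivity.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(dataset_kind = c("kinematic", "walking_metabolic",
                                        "resting_metabolic"),
                       truncation_grid = NULL,
                       truth_size = NULL,
                       n_boot = 1000,
                       seed = 1L,
                       positive_part = TRUE,
                       element = c("x_foot", "vx_pelvis")) {
  dataset_kind <- match.arg(dataset_kind)
  defaults <- switch(dataset_kind,
    kinematic = list(grid = seq(15L, 90L, by = 5L), truth = 100L),
    walking_metabolic = list(grid = seq(15L, 51L, by = 3L), truth = 54L),
    resting_metabolic = list(grid = seq(10L, 34L, by = 3L), truth = 40L))
  truncation_grid <- as.integer(truncation_grid %||% defaults$grid)
  truth_size <- check_count(truth_size %||% defaults$truth, "truth_size", min = 2L)
  if (length(truncation_grid) < 1L || any(diff(truncation_grid) <= 0))
    stopf("`truncation_grid` must be strictly increasing")
  if (any(truncation_grid >= truth_size))
    stopf("every truncation size must be below truth_size = %d", truth_size)
  structure(list(dataset_kind = dataset_kind,
                 truncation_grid = truncation_grid,
                 truth_size = truth_size,
                 n_boot = check_count(n_boot, "n_boot", min = 100L),
                 seed = check_count(seed, "seed", min = 0L),
                 positive_part = isTRUE(positive_part),
                 element = element),
            class = "sweep_spec")
}

# Per-participant estimates at one truncation size. Variances are skipped
# for truth-proxy estimates (need_variance = FALSE) since truth enters only
# through its values.
estimate_cohort_at <- function(trials, spec, n, need_variance = TRUE) {
  kind <- spec$dataset_kind
  if (kind == "kinematic") {
    out <- lapply(trials, function(tr)
      extract_gain_element(fit_foot_placement_jacobian(tr, n),
                           spec$element[1], spec$element[2]))
    est <- do.call(rbind, out)
  } else if (kind == "walking_metabolic") {
    est <- do.call(rbind, lapply(seq_along(trials), function(i) {
      if (need_variance) {
        steady_state_estimate(trials[[i]], n, n_boot = spec$n_boot,
                              seed = derive_seed(spec$seed, i, n))
      } else {
        f <- fit_exponential_transient(trials[[i]], n)
        point_estimate(f$participant_id, f$a0, NA_real_, n, "transient_a0")
      }
    }))
  } else {
    est <- resting_mean_estimate(trials, n, n_boot = spec$n_boot,
                                 seed = derive_seed(spec$seed, n))
  }
  rownames(est) <- NULL
  est
}

#' Run a trial-duration truncation sweep over a cohort
#'
#' For every truncation size in the grid: compute per-participant estimates
#' from the first n records, shrink them toward the cohort mean, and compare
#' both estimators against the "true" values. By default truth is the
#' estimate from the first `truth_size` records of each trial (the
#' full-duration proxy used when real truth is unknowable); pass `truths` to
#' compare against generative truth instead (recovery mode for synthetic
#' cohorts). Finishes by fitting an exponential decay to the shrinkage
#' estimator's SSE-versus-size curve.
#'
#' @param trials named list of per-participant trial data frames, or a
#'   cohort object from the simulators (its `$trials` is used).
#' @param spec a [sweep_spec()].
#' @param truths optional data frame `participant_id`, `true_value`.
#' @return An object of class `sweep_result`: list with
#'   \describe{
#'     \item{summary}{one row per truncation size: `n`, `sse_mle`,
#'       `sse_jse`, `pct_reduction`, `raw_c`, `applied_c`,
#'       `p_paired_errors`, `p_truth_vs_mle`.}
#'     \item{details}{per (size, participant): `y`, `z`, `x`.}
#'     \item{truth}{the truth table used.}
#'     \item{decay_fit}{[fit_sse_decay()] result on the JSE SSEs (NULL if
#'       not fittable).}
#'     \item{spec}{the sweep spec.}
#'   }
#' @export
run_sweep <- function(trials, spec, truths = NULL) {
  if (!inherits(spec, "sweep_spec")) stopf("`spec` must be a sweep_spec")
  if (is.list(trials) && !is.null(trials$trials)) trials <- trials$trials
  lens <- vapply(trials, nrow, integer(1))
  short <- names(trials)[lens < spec$truth_size]
  if (length(short))
    stopf("participants shorter than truth_size = %d: %s", spec$truth_size,
          paste(short, collapse = ", "))
  if (is.null(truths)) {
    tr_est <- estimate_cohort_at(trials, spec, spec$truth_size,
                                 need_variance = FALSE)
    truths <- data.frame(participant_id = tr_est$participant_id,
                         true_value = tr_est$value, stringsAsFactors = FALSE)
  }
  rows <- vector("list", length(spec$truncation_grid))
  details <- vector("list", length(spec$truncation_grid))
  for (gi in seq_along(spec$truncation_grid)) {
    n <- spec$truncation_grid[gi]
    est <- estimate_cohort_at(trials, spec, n)
    shr <- compute_shrinkage(est, positive_part = spec$positive_part)
    cmp <- compare_accuracy(truths, shr)
    rows[[gi]] <- data.frame(n = n,
                             sse_mle = cmp$sse_mle,
                             sse_jse = cmp$sse_jse,
                             pct_reduction = cmp$pct_reduction,
                             raw_c = shr$raw_c,
                             applied_c = shr$applied_c,
                             p_paired_errors = cmp$p_paired_errors,
                             p_truth_vs_mle = cmp$p_truth_vs_mle)
    details[[gi]] <- cbind(n = n, cmp$per_participant)
  }
  summary <- do.call(rbind, rows)
  decay <- tryCatch(
    suppressWarnings(fit_sse_decay(summary$n, summary$sse_jse)),
    error = function(e) NULL)
  structure(list(summary = summary,
                 details = do.call(rbind, details),
                 truth = truths,
                 decay_fit = decay,
                 spec = spec),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Truncation sweep (%s): %d sizes, truth at %d records\n",
              x$spec$dataset_kind, nrow(x$summary), x$spec$truth_size))
  print(round(x$summary[c("n", "sse_mle", "sse_jse", "pct_reduction",
                          "applied_c")], 5), row.names = FALSE)
  if (!is.null(x$decay_fit))
    cat(sprintf("  SSE decay: amplitude %.4g, rate %.4g per record\n",
                x$decay_fit$amplitude, x$decay_fit$rate))
  invisible(x)
}

#' Fit an exponential decay to an SSE-versus-size curve
#'
#' Fits \eqn{SSE(n) = a e^{-b n}} by ordinary least squares of
#' \eqn{\log SSE} on n: amplitude \eqn{a = e^{intercept}}, rate
#' \eqn{b = -slope}. Non-positive SSEs cannot be log-transformed and are
#' dropped with a warning; fewer than 3 usable points is an error.
#'
#' @param grid truncation sizes.
#' @param sse corresponding summed squared errors.
#' @return An object of class `decay_fit`: list with `amplitude`, `rate`,
#'   `n_used`.
#' @export
fit_sse_decay <- function(grid, sse) {
  if (length(grid) != length(sse)) stopf("`grid` and `sse` lengths differ")
  keep <- is.finite(sse) & sse > 0
  if (any(!keep))
    warning(sprintf("dropping %d non-positive SSE value(s) before the log-linear fit",
                    sum(!keep)), call. = FALSE)
  if (sum(keep) < 3L)
    stopf("need at least 3 positive SSE values to fit the decay; have %d",
          sum(keep))
  co <- stats::coef(stats::lm(log(sse[keep]) ~ grid[keep]))
  structure(list(amplitude = exp(unname(co[1])), rate = -unname(co[2]),
                 n_used = sum(keep)),
            class = "decay_fit")
}

#' Replicated recovery study: sweep synthetic cohorts against generative truth
#'
#' Repeats generate-then-sweep `n_reps` times, always comparing against the
#' generator's true parameters, and averages the resulting accuracy curves.
#' This gives the expected behaviour of the shrinkage pipeline under known
#' conditions: mean SSE of both estimators per truncation size, mean percent
#' reduction, the fraction of replicates where shrinkage helped, and the
#' mean applied shrinkage factor.
#'
#' @param cohort_spec a [kinematic_cohort_spec()] or
#'   [metabolic_cohort_spec()]; its seed is re-derived per replicate.
#' @param spec a [sweep_spec()] of the matching kind (default derived from
#'   the cohort spec).
#' @param n_reps replicates (>= 1).
#' @param seed root seed governing the whole study.
#' @return An object of class `recovery_study`: list with `curves` (one row
#'   per truncation size: `n`, `mean_sse_mle`, `mean_sse_jse`,
#'   `mean_pct_reduction` — the mean of per-replicate percent reductions —,
#'   `pooled_pct_reduction` — the reduction of the mean SSEs, the analog of
#'   computing percent reduction from cohort SSEs and the stabler summary —,
#'   `frac_positive_reduction`, `mean_applied_c`), `n_reps`, and the specs.
#' @export
recovery_study <- function(cohort_spec, spec = NULL, n_reps = 100, seed = 1L) {
  n_reps <- check_count(n_reps, "n_reps", min = 1L)
  seed <- check_count(seed, "seed", min = 0L)
  kinematic <- inherits(cohort_spec, "kinematic_cohort_spec")
  if (!kinematic && !inherits(cohort_spec, "metabolic_cohort_spec"))
    stopf("`cohort_spec` must be a kinematic or metabolic cohort spec")
  if (is.null(spec)) {
    kind <- if (kinematic) "kinematic"
            else if (cohort_spec$resting_mode) "resting_metabolic"
            else "walking_metabolic"
    spec <- sweep_spec(kind, seed = seed)
  }
  acc <- NULL
  for (r in seq_len(n_reps)) {
    cs <- cohort_spec
    cs$seed <- derive_seed(seed, r)
    cohort <- if (kinematic) simulate_kinematic_cohort(cs)
              else simulate_metabolic_cohort(cs)
    sp <- spec
    sp$seed <- derive_seed(seed, r, 1L)
    sw <- run_sweep(cohort$trials, sp, truths = cohort$truth)
    s <- sw$summary
    add <- cbind(s[c("n", "sse_mle", "sse_jse", "pct_reduction", "applied_c")],
                 positive = as.numeric(s$pct_reduction > 0))
    acc <- if (is.null(acc)) add else {
      acc[-1] <- acc[-1] + add[-1]
      acc
    }
  }
  curves <- data.frame(n = acc$n,
                       mean_sse_mle = acc$sse_mle / n_reps,
                       mean_sse_jse = acc$sse_jse / n_reps,
                       mean_pct_reduction = acc$pct_reduction / n_reps,
                       pooled_pct_reduction =
                         100 * (1 - acc$sse_jse / acc$sse_mle),
                       frac_positive_reduction = acc$positive / n_reps,
                       mean_applied_c = acc$applied_c / n_reps)
  structure(list(curves = curves, n_reps = n_reps, cohort_spec = cohort_spec,
                 sweep_spec = spec, seed = seed),
            class = "recovery_study")
}

#' @export
print.recovery_study <- function(x, ...) {
  cat(sprintf("Recovery study: %d replicates, %s cohort of %d\n",
              x$n_reps, x$sweep_spec$dataset_kind,
              x$cohort_spec$n_participants))
  print(round(x$curves, 4), row.names = FALSE)
  invisible(x)
}
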