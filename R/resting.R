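# Resting metabolic rate: per-participant window means with a single pooled
# bootstrap standard error shared by the cohort.

#' Resting metabolic rate estimates with a pooled-deviation bootstrap SE
#'
#' For each participant the estimate is the mean metabolic rate over the
#' FIRST `n_points` breaths of their resting trial. Because resting breath
#' noise is comparable across people, a single squared standard error is
#' assigned to every participant: each participant's deviations from their
#' own window mean are pooled across the cohort, and the variance of an
#' `n_points`-sample mean is estimated by bootstrap — `n_boot` draws of
#' `n_points` deviations with replacement from the pooled set, taking the
#' variance of the resampled means. Deterministic given `seed`.
#'
#' @param trials list of resting metabolic trial data frames (all with
#'   `condition == "resting"`), each with `t_s` and `edot_w_kg` (or gas-flux
#'   columns).
#' @param n_points breaths per participant used for the mean; default the
#'   shortest trial length. Must be >= 2 and at most the shortest trial.
#' @param n_boot bootstrap draws (>= 100).
#' @param seed integer seed for the bootstrap.
#' @return A data frame of point estimates (method `"resting_mean"`), one
#'   row per participant, all sharing the pooled variance.
#' @export
resting_mean_estimate <- function(trials, n_points = NULL, n_boot = 2000,
                                  seed = 1L) {
  if (!length(trials)) stopf("`trials` is empty")
  n_boot <- check_count(n_boot, "n_boot", min = 100L)
  conds <- vapply(trials, function(tr)
    if ("condition" %in% names(tr)) as.character(tr$condition[1]) else "resting",
    character(1))
  if (!all(conds == "resting"))
    stopf("all trials must be resting trials; found conditions: %s",
          paste(unique(conds), collapse = ", "))
  lens <- vapply(trials, nrow, integer(1))
  n_points <- if (is.null(n_points)) min(lens) else
    check_count(n_points, "n_points", min = 2L)
  if (n_points > min(lens))
    stopf("n_points = %d exceeds the shortest trial (%d breaths)",
          n_points, min(lens))

  windows <- lapply(trials, function(tr) trial_edot(tr)[seq_len(n_points)])
  means <- vapply(windows, mean, numeric(1))
  pooled <- unlist(lapply(windows, function(w) w - mean(w)), use.names = FALSE)

  boot_var <- withr::with_seed(seed, {
    draws <- matrix(sample(pooled, n_points * n_boot, replace = TRUE),
                    nrow = n_points)
    stats::var(colMeans(draws))
  })

  ids <- vapply(seq_along(trials), function(i) {
    tr <- trials[[i]]
    if ("participant_id" %in% names(tr)) as.character(tr$participant_id[1])
    else sprintf("P%02d", i)
  }, character(1))
  out <- do.call(rbind, lapply(seq_along(ids), function(i)
    point_estimate(ids[i], means[i], boot_var, n_points, "resting_mean")))
  rownames(out) <- NULL
  out
}
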