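# Point estimates: the common currency between the per-participant
# estimators and the shrinkage stage. A point estimate is one row of a tidy
# data frame (participant_id, method, n_used, value, variance); a cohort of
# estimates is the row-bound frame, validated by as_cohort_estimates().

#' Construct a single point estimate
#'
#' @param participant_id participant label.
#' @param value the estimate (MLE) in the units of the target parameter.
#' @param variance its squared standard error (same units squared); `NA`
#'   when no variance was computed (e.g. truth-proxy estimates).
#' @param n_used number of records (steps or breaths) used.
#' @param method one of `"jacobian_element"`, `"transient_a0"`,
#'   `"resting_mean"`.
#' @return A one-row data frame.
#' @export
point_estimate <- function(participant_id, value, variance, n_used, method) {
  method <- match.arg(method, c("jacobian_element", "transient_a0", "resting_mean"))
  if (!is.na(variance) && variance < 0)
    stopf("`variance` must be >= 0")
  data.frame(participant_id = as.character(participant_id),
             method = method,
             n_used = as.integer(n_used),
             value = as.numeric(value),
             variance = as.numeric(variance),
             stringsAsFactors = FALSE)
}

#' Validate a cohort of point estimates for shrinkage
#'
#' Checks the contract the James-Stein stage relies on: at least four
#' participants (so k - 3 > 0), unique participant ids, a single estimation
#' method (hence common units), and non-negative variances.
#'
#' @param estimates data frame with columns `participant_id`, `method`,
#'   `n_used`, `value`, `variance` (rows from [point_estimate()]).
#' @return The validated data frame, invisibly classed `cohort_estimates`.
#' @export
as_cohort_estimates <- function(estimates) {
  need <- c("participant_id", "method", "n_used", "value", "variance")
  miss <- setdiff(need, names(estimates))
  if (length(miss))
    stopf("estimates are missing columns: %s", paste(miss, collapse = ", "))
  k <- nrow(estimates)
  if (k < 4L)
    stopf("shrinkage needs k >= 4 participants (k - 3 must be positive); got k = %d", k)
  if (anyDuplicated(estimates$participant_id))
    stopf("participant ids must be unique")
  if (length(unique(estimates$method)) != 1L)
    stopf("all estimates must come from the same method (same units); got: %s",
          paste(unique(estimates$method), collapse = ", "))
  if (any(!is.na(estimates$variance) & estimates$variance < 0))
    stopf("variances must be >= 0")
  class(estimates) <- c("cohort_estimates", "data.frame")
  estimates
}
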