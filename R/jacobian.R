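# Foot-placement control regression: linear model from midstance pelvis-state
# deviations to next-foot-position deviations, estimated by ordinary least
# squares per output axis.

kin_input_cols <- c("x_pelvis", "vx_pelvis", "vy_pelvis")
kin_output_cols <- c("x_foot", "y_foot")

#' Estimate the foot-placement control Jacobian by least squares
#'
#' Fits the linear foot-placement control law \eqn{\Delta S = J \Delta P},
#' where \eqn{\Delta P} is the deviation of the midstance pelvis state
#' (sideways position, sideways velocity, forward velocity) from its mean
#' over the fitted window and \eqn{\Delta S} the deviation of the next
#' stance-foot position (sideways, fore-aft) from its window mean. Uses the
#' FIRST `n_steps` records — truncation always keeps the start of the trial —
#' and recenters within that window, so shorter windows estimate exactly
#' what a shorter trial would have. Each of the two output rows is an
#' ordinary least-squares fit on the three centered inputs with no
#' intercept (centering removes it); squared coefficient standard errors
#' use residual degrees of freedom `n_steps - 3`.
#'
#' @param trial data frame with columns `x_pelvis`, `vx_pelvis`,
#'   `vy_pelvis`, `x_foot`, `y_foot` (and optionally `participant_id`).
#' @param n_steps number of initial steps to use; default all. Must be >= 7
#'   and at most the trial length.
#' @return An object of class `jacobian_fit`: list with `gain` (2x3 matrix,
#'   rows `x_foot`, `y_foot`; columns `x_pelvis`, `vx_pelvis`,
#'   `vy_pelvis`), `coef_variance` (2x3, squared standard errors),
#'   `input_means` (P*), `output_means` (S*), `n_steps_used`,
#'   `participant_id`.
#' @export
fit_foot_placement_jacobian <- function(trial, n_steps = NULL) {
  miss <- setdiff(c(kin_input_cols, kin_output_cols), names(trial))
  if (length(miss))
    stopf("trial is missing columns: %s", paste(miss, collapse = ", "))
  n_avail <- nrow(trial)
  n_steps <- if (is.null(n_steps)) n_avail else check_count(n_steps, "n_steps", min = 7L)
  if (n_steps < 7L)
    stopf("at least 7 steps are needed to identify 6 gains plus means; got %d", n_steps)
  if (n_steps > n_avail)
    stopf("n_steps = %d exceeds the %d steps available", n_steps, n_avail)
  w <- trial[seq_len(n_steps), , drop = FALSE]
  P <- as.matrix(w[kin_input_cols])
  S <- as.matrix(w[kin_output_cols])
  if (any(!is.finite(P)) || any(!is.finite(S)))
    stopf("trial contains non-finite values in the fitted window")
  p_star <- colMeans(P)
  s_star <- colMeans(S)
  X <- sweep(P, 2, p_star)
  Y <- sweep(S, 2, s_star)
  qrX <- qr(X)
  if (qrX$rank < 3L) {
    sds <- apply(X, 2, stats::sd)
    degenerate <- kin_input_cols[which.min(sds)]
    stopf("pelvis-state design matrix is rank-deficient (rank %d); degenerate column: %s",
          qrX$rank, degenerate)
  }
  fit <- stats::lm.fit(X, Y)
  B <- fit$coefficients                       # 3 x 2
  res <- Y - X %*% B
  df <- n_steps - 3L
  XtX_inv <- chol2inv(qr.R(qrX))
  sigma2 <- colSums(res^2) / df               # per-output residual variance
  var_coef <- outer(diag(XtX_inv), sigma2)    # 3 x 2
  gain <- t(B)
  coef_variance <- t(var_coef)
  dimnames(gain) <- dimnames(coef_variance) <-
    list(kin_output_cols, kin_input_cols)
  structure(list(gain = gain,
                 coef_variance = coef_variance,
                 input_means = p_star,
                 output_means = s_star,
                 n_steps_used = n_steps,
                 participant_id = if ("participant_id" %in% names(trial))
                   as.character(trial$participant_id[1]) else NA_character_),
            class = "jacobian_fit")
}

#' @export
print.jacobian_fit <- function(x, ...) {
  cat("Foot-placement Jacobian fit",
      if (!is.na(x$participant_id)) sprintf(" (%s)", x$participant_id), "\n",
      sep = "")
  cat(sprintf("  steps used: %d\n", x$n_steps_used))
  cat("  gain (rows: foot outputs; cols: pelvis-state inputs):\n")
  print(round(x$gain, 4))
  invisible(x)
}

#' Extract one gain element as a point estimate
#'
#' Pulls a single element of the fitted control Jacobian, together with its
#' squared standard error, into the tidy point-estimate form consumed by the
#' shrinkage stage. The default element is the sideways-foot-placement
#' sensitivity to sideways pelvis velocity (units s), the standard
#' illustration target for shrinkage of gait control gains.
#'
#' @param fit a [fit_foot_placement_jacobian()] result.
#' @param out_name output row, `"x_foot"` or `"y_foot"`.
#' @param in_name input column, one of `"x_pelvis"`, `"vx_pelvis"`,
#'   `"vy_pelvis"`.
#' @return A one-row data frame from [point_estimate()], method
#'   `"jacobian_element"`.
#' @export
extract_gain_element <- function(fit, out_name = "x_foot", in_name = "vx_pelvis") {
  if (!inherits(fit, "jacobian_fit")) stopf("`fit` must be a jacobian_fit")
  if (!out_name %in% rownames(fit$gain))
    stopf("unknown output `%s`; expected one of: %s", out_name,
          paste(rownames(fit$gain), collapse = ", "))
  if (!in_name %in% colnames(fit$gain))
    stopf("unknown input `%s`; expected one of: %s", in_name,
          paste(colnames(fit$gain), collapse = ", "))
  point_estimate(fit$participant_id,
                 value = fit$gain[out_name, in_name],
                 variance = fit$coef_variance[out_name, in_name],
                 n_used = fit$n_steps_used,
                 method = "jacobian_element")
}
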