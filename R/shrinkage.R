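# The James-Stein core: shrink per-participant MLEs toward the cohort grand
# mean, compare accuracy against truth, and Monte-Carlo risk checks.

#' James-Stein shrinkage of a cohort of estimates toward their grand mean
#'
#' Given per-participant estimates \eqn{y_i} with error variances
#' \eqn{\sigma_i^2} (k participants), computes the shrinkage factor
#' \deqn{c = 1 - \frac{\bar{SE}^2 (k-3)}{\sum_i (y_i - \bar{y})^2},}
#' where \eqn{\bar{SE}^2} is the mean of the error variances (the mean is
#' used when variances are unequal), and the shrunk estimates
#' \deqn{z_i = \bar{y} + c\,(y_i - \bar{y}).}
#' With `positive_part = TRUE` (default) a negative factor is replaced by
#' zero — full shrinkage to the grand mean — which dominates the raw
#' estimator. `c = 1` leaves every estimate at its MLE; `c = 0` collapses
#' all of them to \eqn{\bar{y}}. When \eqn{\bar{SE}^2 = 0} the factor is 1
#' by convention (perfect MLEs are not shrunk). If all \eqn{y_i} are equal
#' while \eqn{\bar{SE}^2 > 0}, raw mode is an error; positive-part mode
#' applies full shrinkage with a warning.
#'
#' @param cohort a data frame of point estimates (see
#'   [as_cohort_estimates()]); k >= 4.
#' @param positive_part logical; replace a negative shrinkage factor by 0.
#' @return An object of class `shrinkage_result`: list with `grand_mean`,
#'   `pooled_se2`, `raw_c`, `applied_c`, `positive_part_applied`, `k`, and
#'   `estimates` — the input frame with a `z` column of shrunk values.
#' @examples
#' est <- do.call(rbind, lapply(1:5, function(i)
#'   point_estimate(paste0("P", i), i, 1, 10, "resting_mean")))
#' compute_shrinkage(est)   # c = 0.8
#' @export
compute_shrinkage <- function(cohort, positive_part = TRUE) {
  cohort <- as_cohort_estimates(cohort)
  y <- cohort$value
  s2 <- cohort$variance
  if (any(is.na(y))) stopf("estimates contain NA values")
  if (any(is.na(s2)))
    stopf("estimates contain NA variances; shrinkage needs every sigma_i^2")
  k <- nrow(cohort)
  ybar <- mean(y)
  se2 <- mean(s2)
  S <- sum((y - ybar)^2)
  positive_part_applied <- FALSE
  if (se2 == 0) {
    raw_c <- 1
    applied_c <- 1
  } else if (S == 0) {
    if (!positive_part)
      stopf("all estimates are identical with positive error variance; the raw shrinkage factor is undefined (use positive_part = TRUE for full shrinkage)")
    warning("all estimates identical with positive error variance; applying full shrinkage (c = 0)", call. = FALSE)
    raw_c <- NA_real_
    applied_c <- 0
    positive_part_applied <- TRUE
  } else {
    raw_c <- 1 - se2 * (k - 3) / S
    if (positive_part && raw_c < 0) {
      applied_c <- 0
      positive_part_applied <- TRUE
    } else {
      applied_c <- raw_c
    }
  }
  est <- as.data.frame(cohort)
  est$z <- ybar + applied_c * (y - ybar)
  structure(list(grand_mean = ybar, pooled_se2 = se2, raw_c = raw_c,
                 applied_c = applied_c,
                 positive_part_applied = positive_part_applied,
                 k = k, estimates = est),
            class = "shrinkage_result")
}

#' @export
print.shrinkage_result <- function(x, ...) {
  cat(sprintf("James-Stein shrinkage: k = %d participants\n", x$k))
  cat(sprintf("  grand mean   = %.5g\n", x$grand_mean))
  cat(sprintf("  pooled SE^2  = %.5g\n", x$pooled_se2))
  cat(sprintf("  shrinkage c  = %.4f (raw %s%s)\n", x$applied_c,
              if (is.na(x$raw_c)) "undefined" else sprintf("%.4f", x$raw_c),
              if (x$positive_part_applied) ", positive part applied" else ""))
  invisible(x)
}

safe_paired_p <- function(a, b) {
  tryCatch(stats::t.test(a, b, paired = TRUE)$p.value,
           error = function(e) NA_real_)
}

#' Compare shrunk and unshrunk estimates against true values
#'
#' Computes the summed squared errors of the MLEs \eqn{y_i} and the
#' James-Stein estimates \eqn{z_i} from the true values \eqn{x_i},
#' \deqn{SSE_{MLE} = \sum_i (x_i - y_i)^2, \quad SSE_{JSE} = \sum_i (x_i - z_i)^2,}
#' the percent reduction \eqn{100\,(SSE_{MLE} - SSE_{JSE}) / SSE_{MLE}}, a
#' two-sided paired t-test on the per-participant errors of the two
#' estimators (squared errors by default), and a paired t-test of truths
#' against MLEs (a bias check: shrinkage toward the grand mean presumes the
#' MLE sample is centred on the truth sample). p-values are `NA` when a
#' test degenerates (e.g. `c = 1` makes the paired differences all zero).
#'
#' @param truths data frame with `participant_id` and `true_value`, or a
#'   vector named by participant id.
#' @param result a [compute_shrinkage()] result.
#' @param error_type paired-test transform: `"squared"` (default),
#'   `"absolute"`, or `"signed"` errors.
#' @return An object of class `accuracy_comparison`: list with `sse_mle`,
#'   `sse_jse`, `pct_reduction`, `p_paired_errors`, `p_truth_vs_mle`,
#'   `error_type`, and `per_participant` (id, x, y, z, squared errors).
#' @export
compare_accuracy <- function(truths, result,
                             error_type = c("squared", "absolute", "signed")) {
  error_type <- match.arg(error_type)
  if (!inherits(result, "shrinkage_result"))
    stopf("`result` must come from compute_shrinkage()")
  est <- result$estimates
  if (is.numeric(truths) && !is.null(names(truths)))
    truths <- data.frame(participant_id = names(truths), true_value = unname(truths),
                         stringsAsFactors = FALSE)
  if (!all(c("participant_id", "true_value") %in% names(truths)))
    stopf("`truths` needs columns participant_id and true_value")
  extra <- setdiff(truths$participant_id, est$participant_id)
  missing <- setdiff(est$participant_id, truths$participant_id)
  if (length(extra) || length(missing))
    stopf("participant ids do not match; missing truth for: %s; truth without estimate: %s",
          paste(missing, collapse = ", ") %|e|% "none",
          paste(extra, collapse = ", ") %|e|% "none")
  x <- truths$true_value[match(est$participant_id, truths$participant_id)]
  y <- est$value
  z <- est$z
  sse_mle <- sum((x - y)^2)
  sse_jse <- sum((x - z)^2)
  pct <- if (sse_mle == 0) {
    if (sse_jse == 0) 0 else -Inf
  } else 100 * (sse_mle - sse_jse) / sse_mle
  err <- switch(error_type,
                squared = list((x - y)^2, (x - z)^2),
                absolute = list(abs(x - y), abs(x - z)),
                signed = list(x - y, x - z))
  structure(list(
    sse_mle = sse_mle,
    sse_jse = sse_jse,
    pct_reduction = pct,
    p_paired_errors = safe_paired_p(err[[1]], err[[2]]),
    p_truth_vs_mle = safe_paired_p(x, y),
    error_type = error_type,
    per_participant = data.frame(participant_id = est$participant_id,
                                 x = x, y = y, z = z,
                                 sq_err_mle = (x - y)^2,
                                 sq_err_jse = (x - z)^2,
                                 stringsAsFactors = FALSE)),
    class = "accuracy_comparison")
}

`%|e|%` <- function(a, b) if (nzchar(a)) a else b

#' @export
print.accuracy_comparison <- function(x, ...) {
  cat(sprintf("SSE (MLE) = %.5g, SSE (JSE) = %.5g, reduction = %.1f%%\n",
              x$sse_mle, x$sse_jse, x$pct_reduction))
  cat(sprintf("  paired t on %s errors: p = %.4g; truth vs MLE: p = %.4g\n",
              x$error_type, x$p_paired_errors, x$p_truth_vs_mle))
  invisible(x)
}

#' Monte-Carlo risk comparison of the James-Stein and maximum-likelihood estimators
#'
#' Draws a fixed vector of k true means with the given between-participant
#' spread, then simulates `n_reps` cohorts of noisy observations
#' \eqn{y_i = x_i + N(0, \sigma^2)}, shrinks each cohort with the known
#' noise variance as the pooled \eqn{\bar{SE}^2}, and accumulates the mean
#' summed squared errors of both estimators plus a per-participant
#' bias/variance decomposition (squared bias and variance of each estimator
#' across replicates; their sum is the per-participant mean squared error).
#' Stein's result is that for k >= 4 the shrinkage estimator's expected SSE
#' never exceeds the MLE's, whose risk is exactly \eqn{k \sigma^2},
#' whatever the true means are.
#'
#' @param k number of participants (>= 4).
#' @param sigma2 observation noise variance \eqn{\sigma^2}.
#' @param spread between-participant s.d. of the true means.
#' @param n_reps Monte-Carlo replicates (>= 100).
#' @param seed integer RNG seed.
#' @param mu0 centre of the true-mean distribution.
#' @param positive_part use the positive-part factor (default).
#' @return An object of class `dominance_check`: list with `mean_sse_mle`,
#'   `mean_sse_jse`, `truths`, `decomposition` (per-participant data frame
#'   with `bias2_*`, `variance_*`, `mse_*` for both estimators), and the
#'   settings.
#' @export
stein_dominance_check <- function(k, sigma2 = 1, spread = 1, n_reps = 2000,
                                  seed = 1L, mu0 = 0, positive_part = TRUE) {
  k <- check_count(k, "k", min = 4L)
  n_reps <- check_count(n_reps, "n_reps", min = 100L)
  sigma2 <- check_number(sigma2, "sigma2", 0)
  spread <- check_number(spread, "spread", 0)
  withr::with_seed(seed, {
    x <- stats::rnorm(k, mu0, spread)
    Y <- x + matrix(stats::rnorm(k * n_reps, 0, sqrt(sigma2)), k, n_reps)
  })
  ybar <- colMeans(Y)
  Dev <- sweep(Y, 2, ybar)
  S <- colSums(Dev^2)
  raw_c <- ifelse(S > 0, 1 - sigma2 * (k - 3) / S, if (sigma2 == 0) 1 else -Inf)
  app_c <- if (positive_part) pmax(raw_c, 0) else raw_c
  app_c[!is.finite(app_c)] <- 0
  Z <- sweep(Dev * rep(app_c, each = k), 2, ybar, `+`)

  sse_mle <- colSums((Y - x)^2)
  sse_jse <- colSums((Z - x)^2)

  decomp_of <- function(M) {
    m <- rowMeans(M)
    data.frame(bias2 = (m - x)^2,
               variance = rowMeans((M - m)^2),
               mse = rowMeans((M - x)^2))
  }
  d_mle <- decomp_of(Y)
  d_jse <- decomp_of(Z)
  decomposition <- data.frame(
    participant = seq_len(k), truth = x,
    bias2_mle = d_mle$bias2, variance_mle = d_mle$variance, mse_mle = d_mle$mse,
    bias2_jse = d_jse$bias2, variance_jse = d_jse$variance, mse_jse = d_jse$mse)

  structure(list(mean_sse_mle = mean(sse_mle),
                 mean_sse_jse = mean(sse_jse),
                 truths = x,
                 decomposition = decomposition,
                 k = k, sigma2 = sigma2, spread = spread,
                 n_reps = n_reps, positive_part = positive_part, seed = seed),
            class = "dominance_check")
}

#' @export
print.dominance_check <- function(x, ...) {
  cat(sprintf("Stein dominance Monte Carlo: k = %d, sigma^2 = %g, spread = %g, %d reps\n",
              x$k, x$sigma2, x$spread, x$n_reps))
  cat(sprintf("  mean SSE (MLE) = %.4f  [analytic k*sigma^2 = %g]\n",
              x$mean_sse_mle, x$k * x$sigma2))
  cat(sprintf("  mean SSE (JSE) = %.4f  (%.1f%% lower)\n", x$mean_sse_jse,
              100 * (1 - x$mean_sse_jse / x$mean_sse_mle)))
  invisible(x)
}
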