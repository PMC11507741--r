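# Internal helpers: argument checks and deterministic seed derivation.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min)
    stopf("`%s` must be a single integer >= %d", name, min)
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  if (if (strict) x <= min else x < min)
    stopf("`%s` must be %s %g", name, if (strict) ">" else ">=", min)
  as.numeric(x)
}

#' Derive a child RNG seed from a root seed and integer indices
#'
#' Sweeps and bootstrap loops need reproducible yet mutually independent
#' random streams, one per (participant, truncation size, replicate). This
#' folds the root seed and any number of integer indices through a
#' multiplicative congruential mix modulo 2^31 - 19, so the result is always
#' a valid 32-bit seed.
#'
#' @param root integer root seed.
#' @param ... integer indices (replicate number, participant index, ...).
#' @return A single integer seed in [0, 2^31 - 20].
#' @export
derive_seed <- function(root, ...) {
  idx <- c(...)
  s <- as.double(root) %% 2147483629
  for (i in seq_along(idx)) {
    s <- (s * 48271 + (as.double(idx[i]) + 1) * 1268861) %% 2147483629
  }
  as.integer(s)
}
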