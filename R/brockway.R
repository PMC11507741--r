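#' Convert gas-exchange fluxes to metabolic power (Brockway equation)
#'
#' Converts per-mass oxygen and carbon-dioxide volume fluxes to metabolic
#' energy rate using the standard Brockway combination
#' \deqn{\dot{E} = 16.58\,\dot{V}_{O_2} + 4.51\,\dot{V}_{CO_2},}
#' with fluxes in mL s^-1 kg^-1 and the result in W/kg. Vectorized over
#' breaths, so a whole trial converts in one call.
#'
#' @param vo2 numeric vector, oxygen flux (mL s^-1 kg^-1), non-negative.
#' @param vco2 numeric vector, carbon-dioxide flux (mL s^-1 kg^-1),
#'   non-negative; recycled against `vo2` if scalar.
#' @return Numeric vector of metabolic rates (W/kg).
#' @examples
#' brockway_rate(1, 0)    # 16.58
#' brockway_rate(1, 1)    # 21.09
#' @export
brockway_rate <- function(vo2, vco2) {
  if (length(vo2) != length(vco2)) {
    n <- max(length(vo2), length(vco2))
    vo2 <- rep_len(vo2, n)
    vco2 <- rep_len(vco2, n)
  }
  bad <- which(!is.finite(vo2) | !is.finite(vco2) | vo2 < 0 | vco2 < 0)
  if (length(bad))
    stopf("gas fluxes must be finite and >= 0; offending sample index: %s",
          paste(utils::head(bad, 5L), collapse = ", "))
  16.58 * vo2 + 4.51 * vco2
}

# Coefficients reused by the synthetic generator's gas back-computation.
.brockway_o2 <- 16.58
.brockway_co2 <- 4.51
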