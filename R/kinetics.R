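## Transition-state-theory kinetics.
##
## k_B/h in s^-1 K^-1 and the gas constant in kcal mol^-1 K^-1 (CODATA).
.KB_OVER_H <- 2.083661912e10
.R_KCAL <- 1.987204259e-3

#' Eyring transition-state-theory rate constant
#'
#' Converts a free energy of activation into a unimolecular rate constant:
#' `k = kappa * (k_B T / h) * exp(-dG / (R T))`, with the barrier in kcal/mol
#' and the temperature in kelvin. Units are fixed (no auto-detection): silent
#' unit mistakes dominate failure modes for this formula. The transmission
#' coefficient `kappa` defaults to 1, i.e. plain Eyring estimates.
#'
#' @param dg_barrier free energy of activation, kcal/mol (vectorized).
#' @param temperature absolute temperature, K (vectorized; must be > 0).
#' @param transmission dimensionless transmission coefficient, default 1.
#' @return rate constant(s) in s^-1.
#' @examples
#' eyring_rate(1.7, 39)    # ~2.42e2 /s: thermally accessible even at 39 K
#' eyring_rate(0, 100)     # the attempt frequency k_B T / h at 100 K
#' @export
eyring_rate <- function(dg_barrier, temperature, transmission = 1) {
  if (any(!is.finite(temperature)) || any(temperature <= 0))
    stop("domain error: temperature must be positive", call. = FALSE)
  transmission * .KB_OVER_H * temperature *
    exp(-dg_barrier / (.R_KCAL * temperature))
}

#' Eyring rates for a table of barriers
#'
#' @param barriers data.frame with columns `reaction_id`, `dg` (kcal/mol) and
#'   `temp` (K), e.g. read from a refinement workflow's barrier CSV.
#' @param transmission passed to [eyring_rate()].
#' @return the input with a `k_per_s` column appended.
#' @export
eyring_rate_table <- function(barriers, transmission = 1) {
  need <- c("reaction_id", "dg", "temp")
  if (!all(need %in% names(barriers)))
    stop("input error: barrier table needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  barriers$k_per_s <- eyring_rate(barriers$dg, barriers$temp, transmission)
  barriers
}
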