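# Unit conventions used throughout the package:
#   length      Angstrom
#   energy      kcal/mol
#   mass        Da (atomic mass units)
#   temperature "reduced" kcal/(mol*kB); Kelvin view via kB = 0.002 kcal/mol/K
#   time        reduced time units (t.u.); 1 t.u. corresponds to ~50 fs
# With these units Boltzmann's constant is 1 in reduced temperature, so
# velocity components at temperature T have variance T/m.

#' Boltzmann constant used for the Kelvin conversion
#'
#' The fixed constant 0.002 kcal/mol/K relating reduced temperatures in
#' kcal/(mol kB) to Kelvin, so that 0.35 corresponds to 175 K and 0.81 to
#' 405 K.
#' @export
kB_KCAL_MOL_K <- 0.002

#' Convert between reduced temperature and Kelvin
#'
#' Reduced temperatures are expressed in kcal/(mol kB); the Kelvin view
#' divides by `kB_KCAL_MOL_K` (0.002 kcal/mol/K), so 0.35 -> 175 K and
#' 0.6 -> 300 K.
#'
#' @param temperature numeric vector of temperatures, all > 0.
#' @param from units of the input, `"reduced"` or `"kelvin"`.
#' @return numeric vector in the other unit system.
#' @examples
#' convert_temperature(0.35)                  # 175 K
#' convert_temperature(300, from = "kelvin")  # 0.6
#' @export
convert_temperature <- function(temperature, from = c("reduced", "kelvin")) {
  from <- match.arg(from)
  if (!is.numeric(temperature) || any(!is.finite(temperature)) || any(temperature <= 0)) {
    stop("temperatures must be finite and > 0")
  }
  if (from == "reduced") temperature / kB_KCAL_MOL_K else temperature * kB_KCAL_MOL_K
}

#' Convert between DMD time steps and nanoseconds
#'
#' One DMD time step is one reduced time unit; 2e4 steps correspond to 1 ns
#' (5e-5 ns per step, i.e. ~50 fs).
#'
#' @param steps numeric vector of step counts (>= 0) when `from = "steps"`,
#'   or nanoseconds when `from = "ns"`.
#' @param from `"steps"` or `"ns"`.
#' @return nanoseconds (or steps for the inverse direction).
#' @examples
#' convert_time(2e4)  # 1 ns
#' convert_time(6e6)  # 300 ns
#' @export
convert_time <- function(steps, from = c("steps", "ns")) {
  from <- match.arg(from)
  if (!is.numeric(steps) || any(!is.finite(steps)) || any(steps < 0)) {
    stop("time values must be finite and >= 0")
  }
  if (from == "steps") steps * 5e-5 else steps / 5e-5
}
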