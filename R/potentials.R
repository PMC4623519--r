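#' Multistep square-well pair potential
#'
#' A piecewise-constant pair interaction: `thresholds` are the K boundary
#' distances (strictly increasing, in Angstrom) and `energies` the K + 1
#' energy levels (kcal/mol), where `energies[k]` applies between
#' `thresholds[k - 1]` and `thresholds[k]`. The innermost level may be `Inf`
#' (a hard core); the outermost level must be exactly 0 so the interaction
#' vanishes at large separation. This is the engine's entire force-field
#' abstraction: vdW-like attraction, Go-type native contacts and excluded
#' volume are all expressed as step tables.
#'
#' @param thresholds strictly increasing positive distances, Angstrom.
#' @param energies K + 1 energy levels, kcal/mol; at most one `Inf`, which
#'   must be the innermost level; outermost level must be 0.
#' @return an object of class `step_potential`.
#' @examples
#' # hard core at 4 A with an attractive well of depth 1 between 5.5 and 7 A
#' step_potential(c(4, 5.5, 7), c(Inf, 0, -1, 0))
#' @export
step_potential <- function(thresholds, energies) {
  thresholds <- as.numeric(thresholds)
  energies <- as.numeric(energies)
  if (length(thresholds) < 1L) stop("at least one threshold is required")
  if (any(thresholds <= 0) || any(diff(thresholds) <= 0)) {
    stop("thresholds must be positive and strictly increasing")
  }
  if (length(energies) != length(thresholds) + 1L) {
    stop("need exactly one more energy level than thresholds")
  }
  n_inf <- sum(is.infinite(energies))
  if (n_inf > 1L || (n_inf == 1L && !is.infinite(energies[1L]))) {
    stop("at most one infinite level is allowed and it must be the innermost")
  }
  if (energies[length(energies)] != 0) {
    stop("the outermost energy level must be exactly 0")
  }
  structure(list(thresholds = thresholds, energies = energies),
            class = "step_potential")
}

#' @export
print.step_potential <- function(x, ...) {
  cat("<step_potential> ", length(x$thresholds), " thresholds\n", sep = "")
  cat("  r (A):      ", paste(format(x$thresholds), collapse = " | "), "\n")
  cat("  U (kcal/mol):", paste(format(x$energies), collapse = " | "), "\n")
  invisible(x)
}

# Internal: an unvalidated step table (used for bond wells, whose *outer*
# wall is infinite and therefore intentionally fails the step_potential
# invariant -- bonds are their own pair class).
new_step_table <- function(thresholds, energies) {
  list(thresholds = as.numeric(thresholds), energies = as.numeric(energies))
}

# Energy level of a step table at separation r (vectorised over r).
step_energy_at <- function(pot, r) {
  idx <- findInterval(r, pot$thresholds) + 1L
  pot$energies[idx]
}

# Region (shell) index at separation r: 1 .. K + 1.
step_region_at <- function(pot, r) {
  findInterval(r, pot$thresholds) + 1L
}
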