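#' Specification of a synthetic statistical-mechanics ensemble
#'
#' Describes a system whose Boltzmann statistics are known in closed form,
#' used to test the WHAM / heat-capacity stage in isolation from the
#' dynamics:
#' \itemize{
#'   \item `two_level`: discrete states with energies `energies` and
#'     degeneracies `degeneracies`;
#'   \item `harmonic`: a 1-D harmonic oscillator with spring constant
#'     `spring_constant` (energy `k x^2 / 2`, so `<E> = T/2`);
#'   \item `gaussian_series`: per-temperature Gaussian energy marginals with
#'     the given `means` and `sds` -- the shape real replica-exchange energy
#'     series exhibit at equilibrium.
#' }
#'
#' @param kind one of `"two_level"`, `"harmonic"`, `"gaussian_series"`.
#' @param energies,degeneracies two_level state energies (kcal/mol) and
#'   degeneracies (>= 1).
#' @param spring_constant harmonic spring constant, kcal/mol/A^2.
#' @param means,sds per-temperature Gaussian parameters (recycled to the
#'   ladder length); `sds` > 0.
#' @param n_samples samples per temperature (> 0).
#' @param seed integer seed; all randomness flows through it.
#' @return an object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(kind = c("two_level", "harmonic", "gaussian_series"),
                          energies = c(0, 1), degeneracies = c(1, 1),
                          spring_constant = 1, means = 0, sds = 1,
                          n_samples = 1000L, seed = 1L) {
  kind <- match.arg(kind)
  if (n_samples <= 0) stop("n_samples must be > 0")
  if (kind == "two_level") {
    if (length(energies) != length(degeneracies)) {
      stop("energies and degeneracies must have equal length")
    }
    if (any(degeneracies < 1)) stop("degeneracies must be >= 1")
  }
  if (kind == "harmonic" && spring_constant <= 0) {
    stop("spring_constant must be > 0")
  }
  if (kind == "gaussian_series" && any(sds <= 0)) stop("sds must be > 0")
  structure(list(kind = kind, energies = energies,
                 degeneracies = degeneracies,
                 spring_constant = spring_constant, means = means, sds = sds,
                 n_samples = as.integer(n_samples), seed = as.integer(seed)),
            class = "ensemble_spec")
}

#' Draw per-temperature potential-energy series from a known ensemble
#'
#' For `two_level` and `harmonic` kinds the samples come from the exact
#' Boltzmann distribution of the named system at each ladder temperature
#' (direct sampling, no dynamics); `gaussian_series` draws the prescribed
#' Gaussian marginals. Reproducible under the spec's seed.
#'
#' @param spec an [ensemble_spec()].
#' @param ladder numeric vector of reduced temperatures (see
#'   [build_ladder()]).
#' @return an object of class `energy_series_set`: list with `temperatures`
#'   and `series` (one numeric vector per temperature).
#' @export
generate_energy_series <- function(spec, ladder) {
  stopifnot(inherits(spec, "ensemble_spec"))
  ladder <- as.numeric(ladder)
  if (any(ladder <= 0)) stop("temperatures must be > 0")
  set.seed(spec$seed)
  series <- lapply(ladder, function(Tk) {
    switch(spec$kind,
      two_level = {
        w <- spec$degeneracies * exp(-(spec$energies - min(spec$energies)) / Tk)
        spec$energies[sample.int(length(w), spec$n_samples, replace = TRUE,
                                 prob = w / sum(w))]
      },
      harmonic = {
        x <- stats::rnorm(spec$n_samples, 0, sqrt(Tk / spec$spring_constant))
        0.5 * spec$spring_constant * x^2
      },
      gaussian_series = {
        k <- which(abs(ladder - Tk) < 1e-12)[1L]
        mu <- rep(spec$means, length.out = length(ladder))[k]
        sd <- rep(spec$sds, length.out = length(ladder))[k]
        stats::rnorm(spec$n_samples, mu, sd)
      })
  })
  energy_series_set(ladder, series)
}

#' Container for per-temperature energy series
#'
#' @param temperatures reduced temperatures, one per series.
#' @param series list of numeric energy vectors (kcal/mol).
#' @return an `energy_series_set`.
#' @export
energy_series_set <- function(temperatures, series) {
  stopifnot(length(temperatures) == length(series))
  structure(list(temperatures = as.numeric(temperatures), series = series),
            class = "energy_series_set")
}

#' Sample (RMSD, Rg) reaction-coordinate pairs from a Gaussian mixture
#'
#' i.i.d. samples from a mixture of 2-D Gaussians with known weights, for
#' stage-isolated tests of the PMF machinery (the analytic PMF offset
#' between two well-separated equal-covariance basins is
#' `-kB T log(w1 / w2)`).
#'
#' @param weights mixture weights, non-negative, summing to 1.
#' @param means k x 2 matrix of component means (rmsd, rg), Angstrom.
#' @param sds k x 2 matrix (or recycled vector) of per-coordinate standard
#'   deviations.
#' @param n number of samples.
#' @param seed integer seed.
#' @return data.frame with columns `rmsd`, `rg` and a `component` column
#'   recording the generating component.
#' @export
generate_rc_samples <- function(weights, means, sds, n, seed = 1L) {
  weights <- as.numeric(weights)
  if (any(weights < 0)) stop("mixture weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-9) stop("mixture weights must sum to 1")
  means <- matrix(means, ncol = 2)
  sds <- matrix(rep(sds, length.out = 2L * nrow(means)), ncol = 2)
  set.seed(seed)
  comp <- sample.int(length(weights), n, replace = TRUE, prob = weights)
  data.frame(
    rmsd = stats::rnorm(n, means[comp, 1], sds[comp, 1]),
    rg = stats::rnorm(n, means[comp, 2], sds[comp, 2]),
    component = comp)
}
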