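# Drop the leading fraction of a series (equilibration discard).
drop_head <- function(e, fraction) {
  k <- floor(length(e) * fraction)
  if (k > 0L) e[-seq_len(k)] else e
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Histogram per-temperature energy series on a shared grid
#'
#' Bins are uniform, centred on integer multiples of `bin_width` (default
#' 1 kcal/mol, the width used for every energy histogram in the analyses).
#' The leading `equilibration_fraction` of every series is discarded as
#' system equilibration before counting (default 1/12, the scaled
#' equivalent of discarding the first 5e5 of 6e6 time steps).
#'
#' @param series_set an [energy_series_set()].
#' @param bin_width energy bin width, kcal/mol.
#' @param equilibration_fraction fraction of each series dropped from the
#'   front, in `[0, 1)`.
#' @return an `energy_histogram_set`: shared `bin_centers`, per-temperature
#'   counts matrix (temperatures x bins) and totals.
#' @export
energy_histograms <- function(series_set, bin_width = 1,
                              equilibration_fraction = 1 / 12) {
  stopifnot(inherits(series_set, "energy_series_set"))
  if (equilibration_fraction < 0 || equilibration_fraction >= 1) {
    stop("equilibration_fraction must be in [0, 1)")
  }
  series <- lapply(series_set$series, drop_head, equilibration_fraction)
  if (any(lengths(series) == 0L)) stop("empty energy series after discard")
  idx <- lapply(series, function(e) as.integer(round(e / bin_width)))
  rng <- range(unlist(idx))
  bins <- rng[1]:rng[2]
  counts <- t(vapply(idx, function(ix) {
    tabulate(ix - rng[1] + 1L, nbins = length(bins))
  }, integer(length(bins))))
  structure(list(temperatures = series_set$temperatures,
                 bin_centers = bins * bin_width, bin_width = bin_width,
                 counts = counts, totals = rowSums(counts)),
            class = "energy_histogram_set")
}

#' WHAM: reconstruct the relative density of states
#'
#' Self-consistent solution of
#' `Omega(E) = sum_k n_k(E) / sum_k N_k exp(f_k - beta_k E)` with
#' `f_k = -log sum_E Omega(E) exp(-beta_k E) dE`, iterated (direct
#' substitution, in log space) until the free energies move by less than
#' `tol`. Omega is reported on a relative scale, normalised so its maximum
#' bin is 1.
#'
#' @param hists an [energy_histograms()] result.
#' @param tol convergence tolerance on the per-temperature free energies.
#' @param max_iter iteration cap; exceeding it is an error carrying the
#'   residual.
#' @return a `wham_fit`: occupied-bin `energies`, `log_omega`, free
#'   energies `f`, `temperatures`, iteration count.
#' @export
wham_solve <- function(hists, tol = 1e-7, max_iter = 10000L) {
  stopifnot(inherits(hists, "energy_histogram_set"))
  K <- length(hists$temperatures)
  if (K < 1L || all(hists$counts == 0L)) stop("nonempty histograms required")
  beta <- 1 / hists$temperatures
  occ <- colSums(hists$counts) > 0L
  E <- hists$bin_centers[occ]
  counts <- hists$counts[, occ, drop = FALSE]
  # connectivity: temperatures sharing occupied bins must form one island
  if (K > 1L) {
    adj <- (counts > 0L) %*% t(counts > 0L) > 0L
    reach <- adj[1L, ]
    repeat {
      nxt <- colSums(adj[reach, , drop = FALSE]) > 0L
      if (all(nxt == reach)) break
      reach <- nxt
    }
    if (!all(reach)) {
      warning("non-overlapping histograms: temperatures ",
              paste(which(!reach), collapse = ", "),
              " are disconnected from temperature 1; WHAM solution is ",
              "only determined up to a constant per island")
    }
  }
  log_num <- log(colSums(counts))
  logN <- log(hists$totals)
  dE <- hists$bin_width
  f <- rep(0, K)
  converged <- FALSE
  nE <- length(E)
  bE <- outer(beta, E) # K x nE, fixed across iterations
  for (it in seq_len(max_iter)) {
    # log denominator per bin: logsumexp_k (log N_k + f_k - beta_k E)
    A <- (logN + f) - bE # column-recycled K x nE
    M <- do.call(pmax, lapply(seq_len(K), function(k) A[k, ]))
    log_den <- M + log(colSums(exp(A - rep(M, each = K))))
    log_omega <- log_num - log_den
    B <- rep(log_omega, each = K) - bE + log(dE)
    Mr <- do.call(pmax, lapply(seq_len(nE), function(m) B[, m]))
    f_new <- -(Mr + log(rowSums(exp(B - Mr))))
    f_new <- f_new - f_new[1L]
    resid <- max(abs(f_new - f))
    f <- f_new
    if (resid < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    stop("WHAM failed to converge in ", max_iter,
         " iterations (residual ", format(resid), ")")
  }
  structure(list(energies = E, log_omega = log_omega - max(log_omega),
                 f = f, temperatures = hists$temperatures,
                 bin_width = dE, n_iter = it),
            class = "wham_fit")
}

# Canonical mean and variance of E at reduced temperature T from a wham_fit.
canonical_moments <- function(fit, temperature) {
  lw <- fit$log_omega - fit$energies / temperature
  p <- exp(lw - logsumexp(lw))
  m <- sum(p * fit$energies)
  v <- sum(p * (fit$energies - m)^2)
  c(mean = m, var = v)
}

#' Heat-capacity curve from a density of states
#'
#' `Cv(T) = (<E^2> - <E>^2) / (kB T^2)` with canonical averages taken over
#' the WHAM density of states; in reduced units Cv is reported in units of
#' kB. Peaks and local minima (the metastable-state temperatures T1..T4)
#' are detected on the evaluation grid after a 3-point moving-average
#' smooth.
#'
#' @param fit a [wham_solve()] result.
#' @param T_grid evaluation temperatures (reduced); default the anchored
#'   analysis range 0.4 to 0.8 in steps of 0.002 (1 K).
#' @return a `cv_curve`: data.frame (`temperature`, `kelvin`, `cv`,
#'   `uncertainty`) with detected `peaks` and `minima` (reduced
#'   temperatures).
#' @export
heat_capacity <- function(fit, T_grid = seq(0.4, 0.8, by = 0.002)) {
  stopifnot(inherits(fit, "wham_fit"))
  if (any(T_grid <= 0)) stop("temperatures must be > 0")
  mom <- vapply(T_grid, function(Tk) canonical_moments(fit, Tk), numeric(2))
  cv <- mom[2L, ] / T_grid^2
  df <- data.frame(temperature = T_grid,
                   kelvin = convert_temperature(T_grid), cv = cv,
                   uncertainty = NA_real_)
  ex <- cv_extrema(T_grid, cv)
  structure(list(curve = df, peaks = ex$peaks, minima = ex$minima),
            class = "cv_curve")
}

# Local extrema of a Cv curve after a 3-point moving-average smooth.
cv_extrema <- function(T_grid, cv) {
  n <- length(cv)
  if (n < 3L) return(list(peaks = numeric(0), minima = numeric(0)))
  s <- cv
  s[2:(n - 1)] <- (cv[1:(n - 2)] + cv[2:(n - 1)] + cv[3:n]) / 3
  i <- 2:(n - 1)
  peaks <- i[s[i] > s[i - 1] & s[i] > s[i + 1]]
  minima <- i[s[i] < s[i - 1] & s[i] < s[i + 1]]
  list(peaks = T_grid[peaks], minima = T_grid[minima])
}

#' @export
print.cv_curve <- function(x, ...) {
  cat("<cv_curve> ", nrow(x$curve), " temperatures; peaks at ",
      if (length(x$peaks)) paste(round(convert_temperature(x$peaks)),
                                 "K", collapse = ", ") else "none",
      "\n", sep = "")
  invisible(x)
}

#' Bootstrap uncertainty band for the heat capacity
#'
#' Block bootstrap over contiguous segments of each temperature's energy
#' series: blocks are resampled with replacement, WHAM and Cv recomputed,
#' and the band is the standard deviation of Cv(T) across replicates.
#' Deterministic under `seed`.
#'
#' @param series_set an [energy_series_set()].
#' @param T_grid Cv evaluation grid (reduced temperatures).
#' @param n_blocks contiguous blocks per series (>= 4).
#' @param n_boot bootstrap replicates.
#' @param bin_width,equilibration_fraction passed to [energy_histograms()].
#' @param seed integer seed.
#' @return numeric vector (same length as `T_grid`) of Cv standard
#'   deviations, with the replicate curves as attribute `replicates`.
#' @export
cv_uncertainty <- function(series_set, T_grid = seq(0.4, 0.8, by = 0.002),
                           n_blocks = 20L, n_boot = 50L, bin_width = 1,
                           equilibration_fraction = 1 / 12, seed = 1L) {
  stopifnot(inherits(series_set, "energy_series_set"))
  if (n_blocks < 4L) stop("need at least 4 blocks")
  trimmed <- lapply(series_set$series, drop_head, equilibration_fraction)
  if (any(lengths(trimmed) < n_blocks)) {
    stop("too few frames per block: every series needs >= ", n_blocks,
         " retained samples")
  }
  blocks <- lapply(trimmed, function(e) {
    cuts <- floor(seq(0, length(e), length.out = n_blocks + 1L))
    lapply(seq_len(n_blocks), function(b) e[(cuts[b] + 1L):cuts[b + 1L]])
  })
  set.seed(seed)
  reps <- matrix(NA_real_, n_boot, length(T_grid))
  for (r in seq_len(n_boot)) {
    resampled <- lapply(blocks, function(bl) {
      unlist(bl[sample.int(n_blocks, n_blocks, replace = TRUE)])
    })
    ss <- energy_series_set(series_set$temperatures, resampled)
    h <- energy_histograms(ss, bin_width, equilibration_fraction = 0)
    fit <- wham_solve(h)
    reps[r, ] <- heat_capacity(fit, T_grid)$curve$cv
  }
  band <- apply(reps, 2L, stats::sd)
  attr(band, "replicates") <- reps
  band
}

#' Heat-capacity convergence across trajectory windows
#'
#' Splits every energy series into consecutive windows of `window_length`
#' samples (the last window ending at the series end), recomputes the Cv
#' curve on each, and reports the drift of the first-peak temperature
#' between windows -- the diagnostic used to decide that sampling has
#' converged.
#'
#' @param series_set an [energy_series_set()].
#' @param window_length window length in samples; must not exceed the
#'   series length.
#' @param T_grid,bin_width,equilibration_fraction as in [heat_capacity()] /
#'   [energy_histograms()]; the equilibration discard is applied per window.
#' @return list with `curves` (one `cv_curve` per window) and `drift`
#'   (data.frame of window index and first-peak temperature).
#' @export
convergence_windows <- function(series_set, window_length,
                                T_grid = seq(0.4, 0.8, by = 0.002),
                                bin_width = 1, equilibration_fraction = 1 / 12) {
  stopifnot(inherits(series_set, "energy_series_set"))
  L <- min(lengths(series_set$series))
  if (window_length > L) stop("window longer than trajectory")
  n_win <- floor(L / window_length)
  curves <- vector("list", n_win)
  first_peak <- rep(NA_real_, n_win)
  for (w in seq_len(n_win)) {
    # windows anchored at the end: the final window always uses the tail
    to <- L - (n_win - w) * window_length
    from <- to - window_length + 1L
    ss <- energy_series_set(series_set$temperatures,
                            lapply(series_set$series, function(e) e[from:to]))
    h <- energy_histograms(ss, bin_width, equilibration_fraction)
    curves[[w]] <- heat_capacity(wham_solve(h), T_grid)
    if (length(curves[[w]]$peaks)) first_peak[w] <- curves[[w]]$peaks[1L]
  }
  drift <- data.frame(window = seq_len(n_win), first_peak = first_peak)
  drift$drift <- c(NA, diff(first_peak))
  list(curves = curves, drift = drift)
}

#' Moment-based normality check of an energy distribution
#'
#' Omnibus skewness/kurtosis statistic (Jarque-Bera form):
#' `JB = n (S^2 / 6 + (K - 3)^2 / 24)`, asymptotically chi-squared with 2
#' degrees of freedom under normality. Replica-exchange energy series at
#' equilibrium should look Gaussian at every temperature, which is what
#' justifies treating the histograms as canonical partition-function
#' samples. The report includes a histogram at 1 kcal/mol bins.
#'
#' @param x numeric energy series (>= 100 samples), or an
#'   [energy_series_set()] together with `temperature`.
#' @param temperature when `x` is a series set: the ladder temperature
#'   whose series to test (nearest match).
#' @param alpha significance level for the verdict.
#' @param bin_width histogram bin width for the report, kcal/mol.
#' @return list with `statistic`, `p_value`, `skewness`, `kurtosis`,
#'   logical `normal`, and the report `histogram`.
#' @export
energy_normality <- function(x, temperature = NULL, alpha = 0.01,
                             bin_width = 1) {
  if (inherits(x, "energy_series_set")) {
    if (is.null(temperature)) stop("temperature required for a series set")
    k <- which.min(abs(x$temperatures - temperature))
    x <- x$series[[k]]
  }
  n <- length(x)
  if (n < 100L) stop("need >= 100 samples")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  S <- m3 / m2^1.5
  K <- m4 / m2^2
  jb <- n * (S^2 / 6 + (K - 3)^2 / 24)
  p <- stats::pchisq(jb, df = 2, lower.tail = FALSE)
  h <- graphics::hist(x, breaks = seq(floor(min(x)) - bin_width / 2,
                                      max(x) + bin_width, by = bin_width),
                      plot = FALSE)
  list(statistic = jb, p_value = p, skewness = S, kurtosis = K,
       normal = p > alpha, histogram = h)
}
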