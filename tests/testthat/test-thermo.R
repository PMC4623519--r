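# Build a wham_fit by hand from a known density of states.
manual_fit <- function(energies, log_omega, bin_width = 1) {
  structure(list(energies = energies, log_omega = log_omega - max(log_omega),
                 f = 0, temperatures = 1, bin_width = bin_width, n_iter = 0L),
            class = "wham_fit")
}

test_that("histogramming discards the equilibration head and keeps totals", {
  # first 1/12 of each series carries a marker value that must disappear
  series <- energy_series_set(c(0.5, 0.7),
                              list(c(rep(99, 10), rep(0, 110)),
                                   c(rep(99, 10), rep(1, 110))))
  h <- energy_histograms(series, bin_width = 1,
                         equilibration_fraction = 1 / 12)
  expect_false(99 %in% h$bin_centers[colSums(h$counts) > 0])
  expect_equal(h$totals, rowSums(h$counts))
  expect_equal(sum(h$counts), 220L)
})

test_that("single-temperature WHAM matches the closed form", {
  set.seed(1)
  e <- sample(c(0, 1, 2), 400, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  ss <- energy_series_set(0.8, list(e))
  fit <- wham_solve(energy_histograms(ss, 1, 0))
  # Omega proportional to n(E) exp(+beta E)
  expected <- log(tabulate(e + 1, 3)) + (0:2) / 0.8
  expect_equal(fit$log_omega, expected - max(expected), tolerance = 1e-6)
})

test_that("WHAM recovers known degeneracies from multi-temperature data", {
  spec <- ensemble_spec("two_level", energies = c(0, 1),
                        degeneracies = c(1, 1), n_samples = 20000, seed = 42)
  ss <- generate_energy_series(spec, seq(0.3, 1.5, by = 0.3))
  fit <- wham_solve(energy_histograms(ss, 1, 0))
  # equal degeneracies: Omega(1)/Omega(0) -> 1 (log-ratio se ~ sqrt(2/n_eff))
  expect_lt(abs(diff(fit$log_omega)), 3 * sqrt(2 / 5000))

  spec3 <- ensemble_spec("two_level", energies = c(0, 1),
                         degeneracies = c(1, 3), n_samples = 20000, seed = 43)
  ss3 <- generate_energy_series(spec3, seq(0.3, 1.5, by = 0.3))
  fit3 <- wham_solve(energy_histograms(ss3, 1, 0))
  expect_lt(abs(diff(fit3$log_omega) - log(3)), 3 * sqrt(2 / 5000))
})

test_that("duplicating a histogram leaves the WHAM solution unchanged", {
  spec <- ensemble_spec("two_level", n_samples = 5000, seed = 9)
  ss1 <- generate_energy_series(spec, 0.7)
  ss2 <- energy_series_set(c(0.7, 0.7 + 1e-9),
                           list(ss1$series[[1]], ss1$series[[1]]))
  f1 <- wham_solve(energy_histograms(ss1, 1, 0))
  f2 <- wham_solve(energy_histograms(ss2, 1, 0))
  expect_equal(f1$log_omega, f2$log_omega, tolerance = 1e-6)
})

test_that("disconnected histograms trigger the connectivity warning", {
  ss <- energy_series_set(c(0.4, 0.8),
                          list(rep(c(0, 1), 50), rep(c(40, 41), 50)))
  # the per-island constant is undetermined, so the solver may also refuse
  # to converge afterwards; the diagnostic must fire either way
  expect_warning(try(wham_solve(energy_histograms(ss, 1, 0)), silent = TRUE),
                 "non-overlapping")
  ok <- energy_series_set(c(0.4, 0.8),
                          list(rep(c(0, 1, 1), 50), rep(c(0, 1, 2), 50)))
  expect_error(wham_solve(energy_histograms(ok, 1, 0), max_iter = 1),
               "converge")
})

test_that("heat capacity reproduces closed-form model systems", {
  # delta-function density of states: zero variance, Cv identically 0
  flat <- manual_fit(5, 0)
  cv0 <- heat_capacity(flat, seq(0.4, 0.8, 0.01))
  expect_true(all(cv0$curve$cv == 0))

  # two-level system: Schottky anomaly, exact closed form
  fit2 <- manual_fit(c(0, 1), c(0, 0))
  grid <- seq(0.2, 1.2, by = 0.002)
  cv2 <- heat_capacity(fit2, grid)
  expect_equal(cv2$curve$cv, two_level_cv(grid), tolerance = 1e-9)
  peak_oracle <- stats::optimize(two_level_cv, c(0.2, 1.2),
                                 maximum = TRUE)$maximum
  expect_lt(abs(cv2$peaks[1] - peak_oracle), 0.05 * peak_oracle)

  # flat density of states (1-D harmonic oscillator): Cv = kB everywhere
  fith <- manual_fit(seq(0.005, 60, by = 0.01), rep(0, 6000),
                     bin_width = 0.01)
  cvh <- heat_capacity(fith, seq(0.4, 0.8, 0.05))
  expect_equal(cvh$curve$cv, rep(1, length(cvh$curve$cv)), tolerance = 1e-3)
  expect_error(heat_capacity(fit2, c(-0.1, 0.5)), "> 0")
})

test_that("Cv agrees with the direct single-temperature variance estimator", {
  spec <- ensemble_spec("two_level", n_samples = 20000, seed = 5)
  ladder <- seq(0.3, 1.1, by = 0.2)
  ss <- generate_energy_series(spec, ladder)
  fit <- wham_solve(energy_histograms(ss, 1, 0))
  cv <- heat_capacity(fit, ladder)
  for (k in seq_along(ladder)) {
    direct <- mean((ss$series[[k]] - mean(ss$series[[k]]))^2) / ladder[k]^2
    expect_lt(abs(cv$curve$cv[k] - direct), 0.1 * max(direct, 0.05))
  }
})

test_that("the sampled Schottky peak lands within 5% of the closed form", {
  spec <- ensemble_spec("two_level", n_samples = 30000, seed = 12)
  ss <- generate_energy_series(spec, seq(0.25, 1.25, by = 0.125))
  fit <- wham_solve(energy_histograms(ss, 1, 0))
  cv <- heat_capacity(fit, seq(0.2, 1.2, by = 0.002))
  peak_oracle <- stats::optimize(two_level_cv, c(0.2, 1.2),
                                 maximum = TRUE)$maximum
  expect_lt(abs(cv$peaks[1] - peak_oracle), 0.05 * peak_oracle)
})

test_that("the bootstrap band is zero for identical blocks and shrinks with data", {
  # twenty identical blocks: every resample reproduces the same histograms
  block <- rep(c(0, 0, 1), 20)
  ss <- energy_series_set(c(0.4, 0.8), list(rep(block, 20), rep(block, 20)))
  band <- cv_uncertainty(ss, seq(0.3, 0.9, 0.1), n_blocks = 20, n_boot = 20,
                         equilibration_fraction = 0, seed = 1)
  expect_true(all(band == 0))
  expect_error(cv_uncertainty(ss, n_blocks = 3), "4 blocks")

  grid <- seq(0.3, 1.0, by = 0.05)
  bands <- vapply(c(2000, 8000), function(n) {
    spec <- ensemble_spec("two_level", n_samples = n, seed = 31)
    s <- generate_energy_series(spec, seq(0.3, 1.2, by = 0.3))
    mean(cv_uncertainty(s, grid, n_boot = 40, equilibration_fraction = 0,
                        seed = 2))
  }, numeric(1))
  ratio <- bands[1] / bands[2] # expected sqrt(4) = 2
  expect_gt(ratio, 1.4)
  expect_lt(ratio, 2.8)

  spec <- ensemble_spec("two_level", n_samples = 2000, seed = 31)
  s <- generate_energy_series(spec, seq(0.3, 1.2, by = 0.3))
  b1 <- cv_uncertainty(s, grid, n_boot = 10, equilibration_fraction = 0,
                       seed = 7)
  b2 <- cv_uncertainty(s, grid, n_boot = 10, equilibration_fraction = 0,
                       seed = 7)
  expect_identical(as.numeric(b1), as.numeric(b2))
})

test_that("convergence windows reproduce the full curve and flag drift", {
  spec <- ensemble_spec("two_level", n_samples = 6000, seed = 17)
  ladder <- seq(0.3, 1.2, by = 0.3)
  ss <- generate_energy_series(spec, ladder)
  grid <- seq(0.25, 1.0, by = 0.002)

  # window = full length: identical to heat_capacity on the same histograms
  cw <- convergence_windows(ss, 6000, grid, equilibration_fraction = 0)
  full <- heat_capacity(wham_solve(energy_histograms(ss, 1, 0)), grid)
  expect_equal(cw$curves[[1]]$curve$cv, full$curve$cv)
  expect_error(convergence_windows(ss, 7000, grid), "longer than")

  # stationary data: first-peak drift within a few grid steps
  cw3 <- convergence_windows(ss, 2000, grid, equilibration_fraction = 0)
  expect_lt(max(abs(diff(cw3$drift$first_peak))), 0.05)

  # forced drift: the first third samples a two-level system with a larger
  # gap, so the first window's Schottky peak sits at a higher temperature
  spec_hot <- ensemble_spec("two_level", energies = c(0, 1.6),
                            n_samples = 2000, seed = 18)
  drifted <- energy_series_set(ladder, Map(function(a, b) c(a, b),
    generate_energy_series(spec_hot, ladder)$series,
    generate_energy_series(ensemble_spec("two_level", n_samples = 4000,
                                         seed = 19), ladder)$series))
  cwd <- convergence_windows(drifted, 2000, grid,
                             equilibration_fraction = 0)
  pk <- cwd$drift$first_peak
  expect_gt(pk[1] - pk[2], 0.1)          # first window differs
  expect_lt(abs(pk[3] - pk[2]), 0.05)    # trailing windows agree
})

test_that("the normality omnibus matches a direct moment recomputation", {
  set.seed(23)
  x <- stats::rnorm(5000, -40, 3)
  res <- energy_normality(x)
  expect_true(res$normal)

  bimodal <- c(stats::rnorm(2500, -10, 1), stats::rnorm(2500, 10, 1))
  expect_false(energy_normality(bimodal)$normal)

  v <- stats::rlnorm(100, 0, 0.6)
  res2 <- energy_normality(v)
  if (requireNamespace("e1071", quietly = TRUE)) {
    S <- e1071::skewness(v, type = 1)
    K <- e1071::kurtosis(v, type = 1) + 3
    expect_equal(res2$statistic, 100 * (S^2 / 6 + (K - 3)^2 / 24),
                 tolerance = 1e-12)
  }
  expect_error(energy_normality(stats::rnorm(50)), ">= 100")

  spec <- ensemble_spec("gaussian_series", means = -30, sds = 2,
                        n_samples = 500, seed = 2)
  ss <- generate_energy_series(spec, c(0.4, 0.6))
  expect_true(energy_normality(ss, temperature = 0.6)$normal)
})
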