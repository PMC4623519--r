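# Shared fixture builders: everything is generated in code at test time.

# A straight chain with no helices (bonds + hard cores only).
straight_chain <- function(n, mass = 1) {
  topo <- chain_topology(data.frame(label = "tail", start = 1, end = n),
                         bead_mass = mass)
  build_mini_bundle(topo, go_parameters())
}

# The default 56-bead four-helix bundle.
bundle <- function(...) {
  build_mini_bundle(topology_mini_bundle(), go_parameters(...))
}

# Give a state Maxwell-Boltzmann velocities under a fixed seed.
thermalise <- function(built, temperature, seed = 1) {
  st <- built$state
  set.seed(seed)
  st$velocities <- maxwell_velocities(built$model$n, built$model$masses,
                                      temperature)
  st
}

# Single-bead "frames" at given 1-D coordinates: with fit = FALSE the RMSD
# between two such frames is just |dx| (a controllable surrogate metric).
frames_1d <- function(x) {
  arr <- array(0, c(length(x), 1L, 3L))
  arr[, 1L, 1L] <- x
  arr
}

# Stack n x 3 coordinate matrices into a frames array.
as_frames <- function(...) {
  mats <- list(...)
  arr <- array(0, c(length(mats), nrow(mats[[1L]]), 3L))
  for (k in seq_along(mats)) arr[k, , ] <- mats[[k]]
  arr
}

# Random proper rotation matrix.
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

# Closed-form two-level Boltzmann quantities (energies 0 and eps).
two_level_mean <- function(Tk, eps = 1, g = c(1, 1)) {
  w <- g * exp(-c(0, eps) / Tk)
  sum(c(0, eps) * w) / sum(w)
}
two_level_cv <- function(Tk, eps = 1, g2 = 1) {
  r <- g2 * exp(-eps / Tk)
  p <- r / (1 + r)
  (eps / Tk)^2 * p * (1 - p)
}
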