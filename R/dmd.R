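#' Predict the next potential-boundary event of a pair
#'
#' In event-driven DMD, beads fly ballistically between events, so the next
#' event of a pair is the earliest positive root t of
#' `|r + v t|^2 = d^2` over the boundary distances d adjacent to the pair's
#' current shell. Grazing contacts (discriminant below 1e-12) are treated as
#' no crossing.
#'
#' @param rel_pos relative position `r_i - r_j` (length 3), Angstrom.
#' @param rel_vel relative velocity `v_i - v_j` (length 3).
#' @param potential a [step_potential()] or any list with `thresholds`.
#' @param region current shell index (1-based: region k lies between
#'   thresholds k-1 and k); inferred from `|rel_pos|` when `NULL`.
#' @return `NULL` if the relative motion never reaches a boundary, else a
#'   list with `time` (delay until the event), `boundary` (threshold index)
#'   and `direction` (+1 outward, -1 inward).
#' @examples
#' pot <- step_potential(4, c(Inf, 0))
#' predict_pair_event(c(10, 0, 0), c(-1, 0, 0), pot)$time  # 6
#' @export
predict_pair_event <- function(rel_pos, rel_vel, potential, region = NULL) {
  thr <- potential$thresholds
  rr <- sum(rel_pos^2)
  rv <- sum(rel_pos * rel_vel)
  vv <- sum(rel_vel^2)
  if (is.null(region)) region <- findInterval(sqrt(rr), thr) + 1L
  if (region < 1L || region > length(thr) + 1L ||
      (region <= length(thr) && sqrt(rr) > thr[region] + 1e-9) ||
      (region > 1L && sqrt(rr) < thr[region - 1L] - 1e-9)) {
    stop("inconsistent shell index: distance ", format(sqrt(rr)),
         " is not inside region ", region)
  }
  if (vv <= 0) return(NULL)
  best <- Inf; boundary <- NA_integer_; dir <- 0L
  if (region > 1L && rv < 0) {
    b2 <- thr[region - 1L]^2
    disc <- rv^2 - vv * (rr - b2)
    if (disc >= 1e-12) {
      t <- (-rv - sqrt(disc)) / vv
      if (t > 1e-12 && t < best) { best <- t; boundary <- region - 1L; dir <- -1L }
    }
  }
  if (region <= length(thr)) {
    b2 <- thr[region]^2
    disc <- rv^2 - vv * (rr - b2)
    if (disc > 0) {
      t <- (-rv + sqrt(disc)) / vv
      if (t > 1e-12 && t < best) { best <- t; boundary <- region; dir <- 1L }
    }
  }
  if (!is.finite(best)) return(NULL)
  list(time = best, boundary = boundary, direction = dir)
}

#' Resolve a two-body collision at a potential boundary
#'
#' The relative velocity is decomposed into its radial component along the
#' line of centres (the tangential part is untouched, so angular momentum is
#' conserved). With reduced mass mu and energy change dU across the
#' boundary: if `mu v_r^2 / 2 > dU` the pair crosses with sign-preserving
#' new radial speed `sqrt(v_r^2 - 2 dU / mu)`; otherwise (including
#' infinite dU at hard cores and bond walls) it reflects, `v_r' = -v_r`.
#' Total energy, linear momentum and angular momentum are conserved.
#'
#' @param r_i,r_j bead positions at the boundary (length 3), Angstrom.
#' @param v_i,v_j bead velocities (length 3).
#' @param m_i,m_j bead masses, Da.
#' @param delta_U energy change on crossing, kcal/mol (`Inf` for a wall).
#' @return list with updated `v_i`, `v_j`, logical `crossed`, and the
#'   radial speeds `v_r` (before) and `v_r_new` (after).
#' @export
resolve_collision <- function(r_i, r_j, v_i, v_j, m_i, m_j, delta_U) {
  rel <- r_i - r_j
  nhat <- rel / sqrt(sum(rel^2))
  v_r <- sum((v_i - v_j) * nhat)
  mu <- m_i * m_j / (m_i + m_j)
  if (is.finite(delta_U) && 0.5 * mu * v_r^2 > delta_U) {
    v_r_new <- sign(v_r) * sqrt(v_r^2 - 2 * delta_U / mu)
    if (v_r == 0) v_r_new <- sqrt(-2 * delta_U / mu) # dU < 0 pulls inward pairs together
    crossed <- TRUE
  } else {
    v_r_new <- -v_r
    crossed <- FALSE
  }
  dvr <- v_r_new - v_r
  list(v_i = v_i + (mu / m_i) * dvr * nhat,
       v_j = v_j - (mu / m_j) * dvr * nhat,
       crossed = crossed, v_r = v_r, v_r_new = v_r_new)
}

#' Andersen thermostat kick
#'
#' Redraws every velocity component of one bead from a zero-mean Gaussian
#' with variance `temperature / mass` (Maxwell-Boltzmann at the target
#' temperature). Momentum is deliberately not conserved across kicks; the
#' total energy changes only by the kinetic-energy delta. Uses R's RNG.
#'
#' @param velocity current velocity (length 3); only its length is used.
#' @param mass bead mass, Da.
#' @param temperature reduced temperature, > 0 (0 returns a zero velocity).
#' @return new velocity vector (length 3).
#' @export
andersen_kick <- function(velocity, mass, temperature) {
  if (temperature < 0) stop("temperature must be >= 0")
  stats::rnorm(3L, 0, sqrt(temperature / mass))
}

#' Run event-driven DMD
#'
#' Advances the system event by event over piecewise-constant pair
#' potentials: exact free flight between events, analytic event-time
#' prediction, collision resolution by the conservation laws, and a
#' Poisson-scheduled Andersen thermostat. Between thermostat kicks the total
#' energy is conserved to floating-point accuracy. Deterministic given
#' `seed`.
#'
#' @param model a `dmd_model` from [build_mini_bundle()].
#' @param state a `dmd_state` (positions, velocities, time).
#' @param temperature reduced thermostat temperature (ignored when
#'   `thermostat_rate = 0`).
#' @param n_timesteps horizon in reduced time units (> 0).
#' @param thermostat_rate Andersen kicks per bead per time unit (0 disables
#'   the thermostat).
#' @param frame_interval time units between recorded frames.
#' @param seed integer seed for the engine's internal RNG stream.
#' @param record_events record every collision event (for small systems /
#'   debugging; memory grows with the event count).
#' @param resync_interval scheduling horizon of the event queue; a resync
#'   event re-predicts all pairs this often. Affects speed only, never
#'   results.
#' @return a `dmd_trajectory`: frame times, positions (frames x beads x 3),
#'   potential and kinetic energies, the final `dmd_state`, and the number
#'   of processed collision events.
#' @export
dmd_run <- function(model, state, temperature, n_timesteps,
                    thermostat_rate = 0.1, frame_interval = 25, seed = 1L,
                    record_events = FALSE, resync_interval = 5) {
  stopifnot(inherits(model, "dmd_model"), n_timesteps > 0)
  if (thermostat_rate > 0 && temperature <= 0) {
    stop("temperature must be > 0 when the thermostat is active")
  }
  res <- .dmd_run_cpp(state$positions, state$velocities, model$masses,
                      model$pairs$i, model$pairs$j, model$pairs$pot,
                      lapply(model$pot_tables, `[[`, "thresholds"),
                      lapply(model$pot_tables, `[[`, "energies"),
                      temperature, n_timesteps, thermostat_rate,
                      frame_interval, resync_interval, as.numeric(seed),
                      record_events, state$time)
  if (res$n_events == 0 && thermostat_rate == 0) {
    warning("event queue starved (no collisions, no thermostat); ",
            "ran ballistically to the horizon")
  }
  final <- structure(list(positions = res$positions,
                          velocities = res$velocities, time = res$time),
                     class = "dmd_state")
  structure(list(times = res$frame_times, positions = res$frame_positions,
                 pe = res$frame_pe, ke = res$frame_ke,
                 final_state = final, final_pe = res$pe, final_ke = res$ke,
                 n_events = res$n_events,
                 temperature = temperature, seed = seed,
                 events = res$events),
            class = "dmd_trajectory")
}

#' @export
print.dmd_trajectory <- function(x, ...) {
  cat("<dmd_trajectory> ", length(x$times), " frames, ",
      format(x$n_events, big.mark = ","), " events, T = ",
      x$temperature, "\n", sep = "")
  invisible(x)
}

#' Naive reference DMD engine
#'
#' A deliberately simple O(n^2)-per-event loop (no event queue, no
#' thermostat): at every step it re-predicts all pairs, takes the earliest
#' event (ties broken by bead then pair index), advances, and resolves.
#' Used as the event-order oracle for the queued engine on small systems.
#'
#' @inheritParams dmd_run
#' @return list with `events` (data.frame matching [dmd_run()]'s event log),
#'   the final `state`, and `n_events`.
#' @export
dmd_run_reference <- function(model, state, n_timesteps) {
  pos <- state$positions
  vel <- state$velocities
  t_now <- state$time
  t_end <- t_now + n_timesteps
  pairs <- model$pairs
  pots <- model$pot_tables
  region <- integer(nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    r <- sqrt(sum((pos[pairs$i[p], ] - pos[pairs$j[p], ])^2))
    region[p] <- findInterval(r, pots[[pairs$pot[p]]]$thresholds) + 1L
  }
  ev <- list()
  repeat {
    best <- Inf; bp <- NA_integer_; binfo <- NULL
    for (p in seq_len(nrow(pairs))) {
      pred <- predict_pair_event(pos[pairs$i[p], ] - pos[pairs$j[p], ],
                                 vel[pairs$i[p], ] - vel[pairs$j[p], ],
                                 pots[[pairs$pot[p]]], region[p])
      if (!is.null(pred) && pred$time < best) {
        best <- pred$time; bp <- p; binfo <- pred
      }
    }
    if (!is.finite(best) || t_now + best > t_end) break
    t_now <- t_now + best
    pos <- pos + vel * best
    i <- pairs$i[bp]; j <- pairs$j[bp]
    pot <- pots[[pairs$pot[bp]]]
    new_region <- region[bp] + binfo$direction
    dU <- pot$energies[new_region] - pot$energies[region[bp]]
    res <- resolve_collision(pos[i, ], pos[j, ], vel[i, ], vel[j, ],
                             model$masses[i], model$masses[j], dU)
    vel[i, ] <- res$v_i; vel[j, ] <- res$v_j
    if (res$crossed) region[bp] <- new_region
    ev[[length(ev) + 1L]] <- data.frame(
      time = t_now, i = i, j = j, boundary = binfo$boundary,
      dir = binfo$direction, crossed = as.integer(res$crossed))
  }
  pos <- pos + vel * (t_end - t_now)
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(time = numeric(0), i = integer(0), j = integer(0),
               boundary = integer(0), dir = integer(0), crossed = integer(0))
  list(events = events,
       state = structure(list(positions = pos, velocities = vel,
                              time = t_end), class = "dmd_state"),
       n_events = nrow(events))
}
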