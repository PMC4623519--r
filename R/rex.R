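#' Build an arithmetic temperature ladder
#'
#' Inclusive grid from `t_min` to `t_max` in steps of `increment`, reduced
#' units. The production protocol uses 24 replicas from 0.35 to 0.81 with
#' 0.02 increments (175-405 K).
#'
#' @param t_min,t_max ladder end points, kcal/(mol kB), `t_min < t_max`.
#' @param increment ladder spacing (> 0); the span must be an integer
#'   multiple of it (to 1e-9).
#' @return numeric vector of temperatures, class `temperature_ladder`.
#' @examples
#' length(build_ladder(0.35, 0.81, 0.02)) # 24
#' @export
build_ladder <- function(t_min = 0.35, t_max = 0.81, increment = 0.02) {
  if (!(t_min > 0) || !(t_min < t_max) || !(increment > 0)) {
    stop("need 0 < t_min < t_max and increment > 0")
  }
  steps <- (t_max - t_min) / increment
  if (abs(steps - round(steps)) > 1e-9) {
    stop("ladder span is not an integer multiple of the increment")
  }
  structure(t_min + increment * (0:round(steps)), class = "temperature_ladder")
}

#' @export
print.temperature_ladder <- function(x, ...) {
  cat("<temperature_ladder> ", length(x), " temperatures, ",
      x[1], "-", x[length(x)], " (", convert_temperature(x[1]), "-",
      convert_temperature(x[length(x)]), " K)\n", sep = "")
  invisible(x)
}

#' Metropolis acceptance for a temperature swap
#'
#' Adjacent replicas exchange temperatures with probability
#' `min(1, exp((beta_i - beta_j) (E_i - E_j)))`.
#'
#' @param beta_i,beta_j inverse temperatures (1/T, reduced), > 0.
#' @param E_i,E_j potential energies at the attempt, kcal/mol.
#' @param u uniform deviate used for the decision (defaults to `runif(1)`,
#'   i.e. R's RNG stream).
#' @return list with logical `accepted` and the acceptance `prob`.
#' @export
attempt_swap <- function(beta_i, beta_j, E_i, E_j, u = stats::runif(1)) {
  if (beta_i <= 0 || beta_j <= 0) stop("inverse temperatures must be > 0")
  prob <- min(1, exp((beta_i - beta_j) * (E_i - E_j)))
  list(accepted = u < prob, prob = prob)
}

# Stack a list of (nf x n x 3) frame arrays along the frame axis.
bind_frames <- function(lst) {
  lst <- lst[vapply(lst, function(a) length(a) > 0 && dim(a)[1] > 0, TRUE)]
  if (!length(lst)) return(array(0, c(0, 0, 3)))
  n <- dim(lst[[1]])[2]
  nfs <- vapply(lst, function(a) dim(a)[1], 0)
  out <- array(0, c(sum(nfs), n, 3))
  at <- 0L
  for (a in lst) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

#' Replica-exchange DMD
#'
#' Runs one replica per ladder temperature; every `swap_interval` time
#' units, adjacent temperature pairs attempt a Metropolis swap (alternating
#' even / odd pair sweeps). Swap bookkeeping exchanges temperatures, not
#' configurations, with velocities rescaled by `sqrt(T_new / T_old)`.
#' Frames and energy series are collected per *temperature* (the quantity
#' WHAM and the landscape analyses consume). Deterministic under `seed`.
#'
#' @param model a `dmd_model`.
#' @param state initial `dmd_state`, replicated to every temperature.
#' @param ladder a [build_ladder()] result (or numeric vector of increasing
#'   temperatures).
#' @param n_timesteps horizon per replica, time units.
#' @param swap_interval time units between swap sweeps.
#' @param thermostat_rate,frame_interval passed to [dmd_run()].
#' @param seed master seed; every replica segment and the swap decisions
#'   derive their streams from it.
#' @param propagator optional replacement for the DMD engine, for toy
#'   systems: `function(state, temperature, t_span, seed)` returning
#'   `list(state=, energy=, samples=)`. The default propagates with
#'   [dmd_run()].
#' @param init_velocities draw Maxwell-Boltzmann initial velocities at each
#'   replica's starting temperature (default) instead of copying
#'   `state$velocities`.
#' @return a `replica_ensemble`: per-temperature frames and energy series,
#'   the replica-to-temperature assignment history, and the swap history.
#' @export
run_rex <- function(model, state, ladder, n_timesteps, swap_interval = 1000,
                    thermostat_rate = 0.1, frame_interval = 25, seed = 1L,
                    propagator = NULL, init_velocities = TRUE) {
  ladder <- as.numeric(ladder)
  M <- length(ladder)
  if (M < 1L || any(diff(ladder) <= 0) || any(ladder <= 0)) {
    stop("ladder must be a strictly increasing vector of positive temperatures")
  }
  if (n_timesteps <= 0 || swap_interval <= 0) stop("horizons must be > 0")
  n_seg <- ceiling(n_timesteps / swap_interval)

  set.seed(seed)
  replica_seeds <- sample.int(2^31 - 2, M)
  use_dmd <- is.null(propagator)
  t_start <- if (is.list(state) && !is.null(state$time)) state$time else 0
  states <- vector("list", M)
  for (r in seq_len(M)) {
    states[[r]] <- state
    if (use_dmd && init_velocities) {
      states[[r]]$velocities <-
        maxwell_velocities(model$n, model$masses, ladder[r])
    }
  }
  temp_of_replica <- seq_len(M)          # temperature index per replica
  assignment <- matrix(0L, n_seg + 1L, M)
  assignment[1L, ] <- temp_of_replica
  energy <- rep(NA_real_, M)             # current PE per replica
  frames_t <- replicate(M, list(), simplify = FALSE) # per temperature index
  times_t <- replicate(M, list(), simplify = FALSE)
  pe_t <- replicate(M, list(), simplify = FALSE)
  swaps <- list()

  for (seg in seq_len(n_seg)) {
    span <- min(swap_interval, n_timesteps - (seg - 1L) * swap_interval)
    for (r in seq_len(M)) {
      tindex <- temp_of_replica[r]
      seg_seed <- replica_seeds[r] * 1048576 + seg
      if (use_dmd) {
        traj <- dmd_run(model, states[[r]], ladder[tindex], span,
                        thermostat_rate = thermostat_rate,
                        frame_interval = frame_interval, seed = seg_seed)
        states[[r]] <- traj$final_state
        energy[r] <- traj$final_pe
        frames_t[[tindex]][[length(frames_t[[tindex]]) + 1L]] <- traj$positions
        times_t[[tindex]][[length(times_t[[tindex]]) + 1L]] <- traj$times
        pe_t[[tindex]][[length(pe_t[[tindex]]) + 1L]] <- traj$pe
      } else {
        out <- propagator(states[[r]], ladder[tindex], span, seg_seed)
        states[[r]] <- out$state
        energy[r] <- out$energy
        pe_t[[tindex]][[length(pe_t[[tindex]]) + 1L]] <- out$samples
      }
    }
    {
      replica_at_temp <- order(temp_of_replica)
      first <- if (seg %% 2L == 1L) 1L else 2L
      t_low <- if (M >= first + 1L) seq.int(first, M - 1L, by = 2L) else
        integer(0)
      for (tl in t_low) {
        a <- replica_at_temp[tl]; b <- replica_at_temp[tl + 1L]
        res <- attempt_swap(1 / ladder[tl], 1 / ladder[tl + 1L],
                            energy[a], energy[b])
        swaps[[length(swaps) + 1L]] <- data.frame(
          time = t_start + seg * swap_interval, temp_low = tl,
          replica_low = a, replica_high = b,
          E_low = energy[a], E_high = energy[b],
          prob = res$prob, accepted = res$accepted)
        if (res$accepted) {
          temp_of_replica[a] <- tl + 1L
          temp_of_replica[b] <- tl
          if (use_dmd) {
            states[[a]]$velocities <- states[[a]]$velocities *
              sqrt(ladder[tl + 1L] / ladder[tl])
            states[[b]]$velocities <- states[[b]]$velocities *
              sqrt(ladder[tl] / ladder[tl + 1L])
          }
        }
      }
    }
    assignment[seg + 1L, ] <- temp_of_replica
  }

  frames <- lapply(seq_len(M), function(t) {
    if (use_dmd) {
      list(temperature = ladder[t], positions = bind_frames(frames_t[[t]]),
           times = unlist(times_t[[t]]), pe = unlist(pe_t[[t]]))
    } else {
      list(temperature = ladder[t], pe = unlist(pe_t[[t]]))
    }
  })
  swaps <- if (length(swaps)) do.call(rbind, swaps) else
    data.frame(time = numeric(0), temp_low = integer(0),
               replica_low = integer(0), replica_high = integer(0),
               E_low = numeric(0), E_high = numeric(0), prob = numeric(0),
               accepted = logical(0))
  structure(list(ladder = ladder, frames = frames, assignment = assignment,
                 swaps = swaps, final_states = states, seed = seed,
                 swap_interval = swap_interval, n_timesteps = n_timesteps,
                 frame_interval = if (use_dmd) frame_interval else NA_real_),
            class = "replica_ensemble")
}

#' @export
print.replica_ensemble <- function(x, ...) {
  cat("<replica_ensemble> ", length(x$ladder), " replicas, ",
      x$n_timesteps, " t.u., ", nrow(x$swaps), " swap attempts (",
      round(100 * mean(x$swaps$accepted)), "% accepted)\n", sep = "")
  invisible(x)
}

#' Energy series per temperature from a replica ensemble
#'
#' @param ensemble a `replica_ensemble`.
#' @return an [energy_series_set()] with one potential-energy series per
#'   ladder temperature.
#' @export
ensemble_energy_series <- function(ensemble) {
  energy_series_set(ensemble$ladder, lapply(ensemble$frames, `[[`, "pe"))
}

#' Replica mobility through the temperature ladder
#'
#' Counts, for every replica, the number of distinct ladder temperatures it
#' visited over the whole run; a mixing sampler shows mean mobility well
#' above 1.
#'
#' @param ensemble a `replica_ensemble` (its swap/assignment history).
#' @return list with per-replica `counts`, `mean` and `sd`.
#' @export
replica_mobility <- function(ensemble) {
  if (is.null(ensemble$assignment)) stop("no swap history present")
  counts <- apply(ensemble$assignment, 2L, function(col) length(unique(col)))
  list(counts = counts, mean = mean(counts), sd = stats::sd(counts))
}
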