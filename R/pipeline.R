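#' Reproducible end-to-end run configuration
#'
#' Bundles every tunable of the build -> REX/DMD -> WHAM -> PMF -> cluster
#' -> report workflow. Serialises to YAML and round-trips bit-identically;
#' the YAML serialisation's MD5 is the config hash stamped into every
#' output.
#'
#' @param topology `"mini_bundle"`, `"apoe"`, or a `chain_topology`.
#' @param t_min,t_max,increment temperature ladder (reduced units).
#' @param horizon production length per replica, time units.
#' @param equilibration_fraction fraction of each series discarded as
#'   equilibration, in `[0, 1)` (default 1/12, the scaled analogue of
#'   dropping 5e5 of 6e6 steps).
#' @param swap_interval time units between swap sweeps.
#' @param thermostat_rate Andersen kicks per bead per time unit.
#' @param frame_interval time units between recorded frames.
#' @param energy_bin_width WHAM energy bin width, kcal/mol.
#' @param rc_bin_width PMF bin width in both reaction coordinates, Angstrom.
#' @param basin_depth basin extraction depth cutoff, kcal/mol.
#' @param analysis_t_min,analysis_t_max Cv analysis range (reduced); the
#'   default covers the ladder interior, since WHAM extrapolation beyond
#'   the sampled temperatures is unreliable.
#' @param well_depth,contact_cutoff,well_width Go-model parameters.
#' @param seed master seed for the whole run.
#' @return a `run_config` list.
#' @export
run_config <- function(topology = "mini_bundle", t_min = 0.35, t_max = 0.81,
                       increment = 0.02, horizon = 2e5,
                       equilibration_fraction = 1 / 12, swap_interval = 1000,
                       thermostat_rate = 0.1, frame_interval = 25,
                       energy_bin_width = 1, rc_bin_width = 1,
                       basin_depth = 1, analysis_t_min = 0.36,
                       analysis_t_max = 0.80, well_depth = 1.0,
                       contact_cutoff = 7.5, well_width = 1.5, seed = 1L) {
  cfg <- list(topology = topology, t_min = t_min, t_max = t_max,
              increment = increment, horizon = horizon,
              equilibration_fraction = equilibration_fraction,
              swap_interval = swap_interval,
              thermostat_rate = thermostat_rate,
              frame_interval = frame_interval,
              energy_bin_width = energy_bin_width,
              rc_bin_width = rc_bin_width, basin_depth = basin_depth,
              analysis_t_min = analysis_t_min,
              analysis_t_max = analysis_t_max, well_depth = well_depth,
              contact_cutoff = contact_cutoff, well_width = well_width,
              seed = as.integer(seed))
  num <- cfg[!names(cfg) %in% "topology"]
  if (any(!vapply(num, is.numeric, TRUE)) ||
      any(unlist(num[!names(num) %in% "equilibration_fraction"]) <= 0)) {
    stop("all physical parameters must be positive numbers")
  }
  if (equilibration_fraction < 0 || equilibration_fraction >= 1) {
    stop("equilibration_fraction must be in [0, 1)")
  }
  structure(cfg, class = "run_config")
}

#' Serialise / restore a run configuration
#'
#' @param config a [run_config()].
#' @param file YAML path.
#' @return `write_config` the path; `read_config` the restored
#'   `run_config`.
#' @export
write_config <- function(config, file) {
  obj <- unclass(config)
  if (inherits(obj$topology, "chain_topology")) {
    obj$topology <- list(segments = obj$topology$segment_map,
                         bead_mass = obj$topology$bead_mass,
                         bond_length = obj$topology$bond_length,
                         hard_core_diameter = obj$topology$hard_core_diameter)
  }
  yaml::write_yaml(obj, file, precision = 15L)
  invisible(file)
}

#' @rdname write_config
#' @export
read_config <- function(file) {
  obj <- yaml::read_yaml(file)
  if (is.list(obj$topology)) {
    obj$topology <- chain_topology(
      as.data.frame(obj$topology$segments), obj$topology$bead_mass,
      obj$topology$bond_length, obj$topology$hard_core_diameter)
  }
  do.call(run_config, obj[names(obj) %in% names(formals(run_config))])
}

#' MD5 hash of a run configuration
#'
#' @param config a [run_config()].
#' @return character MD5 of the YAML serialisation.
#' @export
config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  write_config(config, f)
  unname(tools::md5sum(f))
}

resolve_topology <- function(config) {
  if (inherits(config$topology, "chain_topology")) return(config$topology)
  switch(config$topology,
         mini_bundle = topology_mini_bundle(),
         apoe = topology_apoe(),
         stop("unknown topology preset '", config$topology, "'"))
}

#' Run the full pipeline
#'
#' Executes the whole workflow under one seeded configuration:
#' build the Go-model bundle, replica-exchange DMD over the ladder, WHAM
#' heat capacity over the analysis range with extrema labelling, PMF
#' surfaces over (RMSD, Rg) at the labelled state temperatures, basin
#' extraction and leader clustering with the data-driven cutoff, distance
#' matrices, native-contact occupancy, geometry series and helicity
#' profiles. When `output_dir` is given, every stage's outputs are written
#' there (TSV/JSON/PDB) together with a manifest carrying the config hash.
#' Reruns with the same config are bit-identical.
#'
#' @param config a [run_config()].
#' @param output_dir optional report directory (created if missing).
#' @param progress print per-stage timing.
#' @return a `pipeline_report` list; see Details.
#' @details The report contains `config`, `model`, `ensemble` (the
#'   `replica_ensemble`), `cv` (with bootstrap `cv_band`), the labelled
#'   `state_temperatures`, per-state `landscapes` (PMF surface, basin
#'   frames, clustering, centroid RMSD to start), `mobility`,
#'   `swap_acceptance`, `distance_matrices`, `native_occupancy`,
#'   `geometry`, and `helicity`.
#' @export
run_pipeline <- function(config = run_config(), output_dir = NULL,
                         progress = FALSE) {
  say <- function(...) if (progress) message(sprintf(...))
  stopifnot(inherits(config, "run_config"))
  post_eq_span <- config$horizon * (1 - config$equilibration_fraction)
  if (post_eq_span < 2 * config$frame_interval) {
    stop("horizon below the equilibration cutoff: fewer than two frames ",
         "would survive the equilibration discard")
  }
  if (config$horizon <= config$swap_interval) {
    stop("horizon must exceed the swap interval")
  }
  topo <- resolve_topology(config)
  params <- go_parameters(native_contact_cutoff = config$contact_cutoff,
                          well_width = config$well_width,
                          native_well_depth = config$well_depth)
  say("stage build: %d beads", topo$n_beads)
  built <- build_mini_bundle(topo, params)
  ladder <- build_ladder(config$t_min, config$t_max, config$increment)

  say("stage rex: %d replicas x %g t.u.", length(ladder), config$horizon)
  ens <- run_rex(built$model, built$state, ladder, config$horizon,
                 swap_interval = config$swap_interval,
                 thermostat_rate = config$thermostat_rate,
                 frame_interval = config$frame_interval, seed = config$seed)
  series <- ensemble_energy_series(ens)

  say("stage wham")
  hists <- energy_histograms(series, config$energy_bin_width,
                             config$equilibration_fraction)
  fit <- wham_solve(hists)
  T_grid <- seq(config$analysis_t_min, config$analysis_t_max, by = 0.002)
  cv <- heat_capacity(fit, T_grid)
  band <- cv_uncertainty(series, T_grid,
                         bin_width = config$energy_bin_width,
                         equilibration_fraction = config$equilibration_fraction,
                         seed = config$seed)
  cv$curve$uncertainty <- band
  states <- assign_state_temperatures(cv)
  if (length(states) < 2L) {
    # a single-transition toy landscape has no Cv minima above the peak;
    # keep the unfolded ensemble visible via the top analysis temperature
    states <- c(states, Thigh = config$analysis_t_max)
  }

  say("stage landscape: states %s", paste(names(states), collapse = " "))
  sel <- helix_beads(topo)
  n_eq <- floor(config$horizon * config$equilibration_fraction /
                config$frame_interval)
  landscapes <- lapply(states, function(Tst) {
    k <- which.min(abs(ens$ladder - Tst))
    frames <- ens$frames[[k]]$positions
    keep <- setdiff(seq_len(dim(frames)[1L]), seq_len(n_eq))
    frames <- frames[keep, , , drop = FALSE]
    rc <- rc_series(frames, built$model$reference, sel, ens$ladder[k])
    surf <- compute_pmf(rc, ens$ladder[k],
                        rep(config$rc_bin_width, 2L))
    basin <- extract_basin(surf, config$basin_depth)
    # the pairwise-RMSD stage is O(frames^2); thin evenly to at most 1500
    # basin frames (statistics of the dominant cluster are unaffected)
    basin_used <- if (length(basin) > 1500L) {
      basin[unique(round(seq(1L, length(basin), length.out = 1500L)))]
    } else basin
    basin_frames <- frames[basin_used, , , drop = FALSE]
    cutoff <- if (length(basin) >= 2L) {
      pairwise_rmsd_cutoff(basin_frames, sel, bin_width = 1)
    } else 0
    clust <- if (length(basin) >= 2L) {
      leader_cluster(basin_frames, max(cutoff, 0.5), sel)
    } else NULL
    centroid_frame <- if (!is.null(clust)) {
      basin_frames[clust$clusters$centroid[1L], , ]
    } else NULL
    centroid_rmsd <- if (!is.null(centroid_frame)) {
      superpose_rmsd(centroid_frame, built$model$reference, sel)
    } else NA_real_
    list(temperature = ens$ladder[k], rc = rc, surface = surf,
         basin = basin, cutoff = cutoff, clusters = clust,
         centroid = centroid_frame, centroid_rmsd = centroid_rmsd,
         basin_rg = if (length(basin)) stats::median(rc$rg[basin]) else NA)
  })

  say("stage structure analytics")
  lowT <- 1L
  highT <- which.min(abs(ens$ladder - states[length(states)]))
  post_eq <- function(k) {
    fr <- ens$frames[[k]]$positions
    keep <- setdiff(seq_len(dim(fr)[1L]), seq_len(n_eq))
    fr[keep, , , drop = FALSE]
  }
  dmats <- list(low = distance_matrix(post_eq(lowT)),
                high = distance_matrix(post_eq(highT)))
  native <- built$model$native_contacts
  occ <- list(
    low = contact_occupancy(post_eq(lowT), native[, c("i", "j")],
                            threshold = config$contact_cutoff),
    high = contact_occupancy(post_eq(highT), native[, c("i", "j")],
                             threshold = config$contact_cutoff))
  geom <- geometry_report(post_eq(lowT), topo)
  hel_frames <- lapply(c(low = lowT, high = highT), post_eq)
  names(hel_frames) <- format(ens$ladder[c(lowT, highT)])
  hel <- helicity_profile(hel_frames, topo)

  report <- structure(list(
    config = config, config_hash = config_hash(config), model = built$model,
    ensemble = ens, cv = cv, state_temperatures = states,
    landscapes = landscapes, mobility = replica_mobility(ens),
    swap_acceptance = mean(ens$swaps$accepted),
    distance_matrices = dmats, native_occupancy = occ, geometry = geom,
    helicity = hel), class = "pipeline_report")

  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

# Write every stage's outputs plus a manifest into a report directory.
write_report <- function(report, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(output_dir, ...)
  topo <- report$model$topology
  write_config(report$config, p("config.yaml"))
  write_pdb_ca(report$model$reference, topo, p("start_structure.pdb"))
  write_potential_tables(report$model, p("potentials.json"))
  write_cv_tsv(report$cv, p("cv_curve.tsv"))
  utils::write.table(report$ensemble$swaps, p("swap_history.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  outputs <- c("config.yaml", "start_structure.pdb", "potentials.json",
               "cv_curve.tsv", "swap_history.tsv")
  for (nm in names(report$landscapes)) {
    ls <- report$landscapes[[nm]]
    write_pmf_tsv(ls$surface, p(paste0("pmf_", nm, ".tsv")))
    writeLines(as.character(ls$basin), p(paste0("basin_frames_", nm, ".txt")))
    outputs <- c(outputs, paste0("pmf_", nm, ".tsv"),
                 paste0("basin_frames_", nm, ".txt"))
    if (!is.null(ls$clusters)) {
      write_clusters_tsv(ls$clusters, p(paste0("clusters_", nm, ".tsv")))
      write_pdb_ca(ls$centroid, topo, p(paste0("centroid_", nm, ".pdb")))
      outputs <- c(outputs, paste0("clusters_", nm, ".tsv"),
                   paste0("centroid_", nm, ".pdb"))
    }
  }
  states_json <- list(
    labels = as.list(report$state_temperatures),
    kelvin = as.list(convert_temperature(report$state_temperatures)),
    cv_peaks = report$cv$peaks, cv_minima = report$cv$minima)
  jsonlite::write_json(states_json, p("state_temperatures.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(
    config_hash = report$config_hash,
    stages = c("build", "rex", "wham", "landscape", "structure"),
    n_replicas = length(report$ensemble$ladder),
    swap_acceptance = report$swap_acceptance,
    mobility_mean = report$mobility$mean,
    outputs = c(outputs, "state_temperatures.json"))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(output_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> ", length(x$ensemble$ladder), " replicas, ",
      "Cv peaks at ",
      paste(round(convert_temperature(x$cv$peaks)), "K", collapse = ", "),
      "; states ", paste(names(x$state_temperatures), collapse = " "),
      "\n", sep = "")
  invisible(x)
}
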