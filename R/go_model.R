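#' Go-type parameter set for the coarse-grained surrogate force field
#'
#' Attractive square wells are restricted to native contacts of the built
#' reference geometry (a Go model); everything else is excluded volume.
#' The engine only ever sees step-potential tables, so a richer multistep
#' force field can be dropped in without touching the dynamics.
#'
#' @param native_contact_cutoff native-contact distance cutoff, Angstrom;
#'   must exceed the topology's hard-core diameter.
#' @param well_width width of the attractive square well, Angstrom; the well
#'   is centred on each contact's reference distance.
#' @param native_well_depth well depth, kcal/mol (>= 0).
#' @param nonnative_core_only must be `TRUE`: non-native pairs interact by
#'   hard core only (reserved flag).
#' @param bond_tolerance half-width of the covalent bond well as a fraction
#'   of the bond length.
#' @return an object of class `go_parameters`.
#' @export
go_parameters <- function(native_contact_cutoff = 7.5, well_width = 1.0,
                          native_well_depth = 1.0, nonnative_core_only = TRUE,
                          bond_tolerance = 0.02) {
  if (native_well_depth < 0) stop("well depth must be >= 0")
  if (well_width <= 0) stop("well_width must be > 0")
  if (native_contact_cutoff <= 0) stop("cutoff must be > 0")
  if (bond_tolerance <= 0 || bond_tolerance >= 1) {
    stop("bond_tolerance must be in (0, 1)")
  }
  if (!isTRUE(nonnative_core_only)) {
    stop("only hard-core non-native interactions are implemented")
  }
  structure(list(native_contact_cutoff = native_contact_cutoff,
                 well_width = well_width,
                 native_well_depth = native_well_depth,
                 nonnative_core_only = TRUE,
                 bond_tolerance = bond_tolerance),
            class = "go_parameters")
}

# Idealized alpha-helix C-alpha geometry (canonical values): 1.5 A rise and
# 100 degree turn per residue on a 2.3 A-radius cylinder, giving a 3.83 A
# virtual bond, consistent with the 3.8 A +/- 2% bond well.
HELIX_RISE <- 1.5
HELIX_TURN_DEG <- 100
HELIX_RADIUS <- 2.3
BUNDLE_SPACING <- 10 # inter-axis distance of adjacent helices, A

# Build idealized coordinates for a topology: helices packed as an
# antiparallel bundle on a square arrangement, connectors and tail extended
# away from the bundle.
idealized_coordinates <- function(topology) {
  seg <- topology$segment_map
  n <- topology$n_beads
  pos <- matrix(NA_real_, n, 3)
  is_helix <- grepl("^H[0-9]+$", seg$label)
  if (any(seg$end[is_helix] - seg$start[is_helix] + 1L < 4L)) {
    stop("segment too short to form a helix (< 4 beads)")
  }
  if (!any(is_helix)) { # degenerate chain with no helices: fully extended
    return(cbind((seq_len(n) - 1L) * topology$bond_length, 0, 0))
  }
  grid <- matrix(c(0, 0, BUNDLE_SPACING, 0,
                   BUNDLE_SPACING, BUNDLE_SPACING, 0, BUNDLE_SPACING),
                 ncol = 2, byrow = TRUE)
  helix_no <- 0L
  bl <- topology$bond_length
  centre <- c(mean(grid[, 1]), mean(grid[, 2]), 0)
  z_top <- 0 # running z extent, set by the first helix
  for (k in seq_len(nrow(seg))) {
    idx <- seg$start[k]:seg$end[k]
    len <- length(idx)
    if (is_helix[k]) {
      helix_no <- helix_no + 1L
      axis_xy <- grid[((helix_no - 1L) %% 4L) + 1L, ]
      up <- helix_no %% 2L == 1L # antiparallel: odd helices run up, even down
      z0 <- if (up) 0 else HELIX_RISE * (len - 1L)
      dir <- if (up) 1 else -1
      # the turn sense follows the chain direction so every helix is
      # right-handed (virtual C-alpha torsion ~ +50 degrees) in chain order
      ang <- dir * (seq_len(len) - 1L) * HELIX_TURN_DEG * pi / 180
      pos[idx, 1] <- axis_xy[1] + HELIX_RADIUS * cos(ang)
      pos[idx, 2] <- axis_xy[2] + HELIX_RADIUS * sin(ang)
      pos[idx, 3] <- z0 + dir * HELIX_RISE * (seq_len(len) - 1L)
      z_top <- max(z_top, HELIX_RISE * (len - 1L))
    } else if (k == 1L) {
      # leading segment: extended, built backwards from the next segment
      nxt <- seg$start[k + 1L]
      # placed after the loop once the anchor exists
    } else {
      anchor <- pos[seg$start[k] - 1L, ]
      d <- anchor - c(centre[1], centre[2], z_top / 2)
      nd <- sqrt(sum(d^2))
      d <- if (nd < 1e-9) c(0, 0, -1) else d / nd
      pos[idx, ] <- rep(anchor, each = len) +
        outer(seq_len(len) * bl, d)
    }
  }
  if (!is_helix[1L] && anyNA(pos[seg$start[1L], ])) {
    idx <- seg$start[1L]:seg$end[1L]
    len <- length(idx)
    anchor <- pos[seg$end[1L] + 1L, ]
    d <- anchor - c(centre[1], centre[2], z_top / 2)
    nd <- sqrt(sum(d^2))
    d <- if (nd < 1e-9) c(0, 0, -1) else d / nd
    pos[rev(idx), ] <- rep(anchor, each = len) + outer(seq_len(len) * bl, d)
  }
  if (anyNA(pos)) stop("internal error: incomplete geometry")
  dimnames(pos) <- NULL
  pos
}

#' Build the synthetic Go-model helix bundle
#'
#' Constructs the idealized conformation for `topology` (helical segments
#' packed as an antiparallel bundle, connectors and tail extended) and the
#' full pair-interaction table set:
#' \itemize{
#'   \item consecutive beads: infinitely deep bond well at
#'     `bond_length * (1 +/- bond_tolerance)`; the three helix-helix
#'     junctions, whose idealized separation exceeds the bond ceiling, get a
#'     flat-bottomed tether well reaching their built distance instead;
#'   \item native contacts (pairs within `native_contact_cutoff` in the
#'     built geometry, sequence separation >= 3, plus intra-helix
#'     `(i, i+2)` pairs -- the standard DMD restraint standing in for
#'     backbone angular stiffness, which a distance-only chain lacks):
#'     hard core plus one attractive square well of depth
#'     `native_well_depth` centred on the pair's reference distance;
#'   \item all remaining pairs: hard core only.
#' }
#'
#' @param topology a [chain_topology()].
#' @param params a [go_parameters()].
#' @param seed integer; used only when `init_temperature` is given, to draw
#'   Maxwell-Boltzmann velocities.
#' @param init_temperature reduced temperature for initial velocities, or
#'   `NULL` (default) for a system at rest.
#' @return a list with components `model` (class `dmd_model`: pair tables,
#'   native-contact list, reference coordinates) and `state` (class
#'   `dmd_state`: positions, velocities, time 0).
#' @export
build_mini_bundle <- function(topology, params = go_parameters(), seed = 1L,
                              init_temperature = NULL) {
  stopifnot(inherits(topology, "chain_topology"),
            inherits(params, "go_parameters"))
  hc <- topology$hard_core_diameter
  if (params$native_contact_cutoff <= hc) {
    stop("native_contact_cutoff must exceed the hard-core diameter")
  }
  pos <- idealized_coordinates(topology)
  n <- topology$n_beads
  bl <- topology$bond_length
  tol <- params$bond_tolerance
  # beads belonging to a helical segment, by segment id (0 = non-helix):
  # (i, i+2) pairs inside one helix get a restraint well like a native
  # contact, the usual DMD surrogate for backbone angular stiffness --
  # without it a distance-only chain has no helical rigidity at all
  seg <- topology$segment_map
  helix_id <- integer(n)
  for (k in seq_len(nrow(seg))) {
    if (grepl("^H[0-9]+$", seg$label[k])) {
      helix_id[seg$start[k]:seg$end[k]] <- k
    }
  }

  dmat <- as.matrix(stats::dist(pos))
  pair_i <- integer(0); pair_j <- integer(0); pair_pot <- integer(0)
  pot_tables <- list(new_step_table(hc, c(Inf, 0)))           # 1: hard core
  pot_tables[[2]] <- new_step_table(c(bl * (1 - tol), bl * (1 + tol)),
                                    c(Inf, 0, Inf))           # 2: bond well
  pair_class <- character(0)
  native <- list()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        d0 <- dmat[i, j]
        if (j == i + 1L) {
          if (d0 < bl * (1 - tol)) {
            stop("bonded pair ", i, "-", j, " shorter than the bond floor")
          }
          if (d0 <= bl * (1 + tol)) {
            pid <- 2L
          } else {
            # junction tether: flat bottom out to the built distance
            pot_tables[[length(pot_tables) + 1L]] <-
              new_step_table(c(bl * (1 - tol), d0 * (1 + tol)), c(Inf, 0, Inf))
            pid <- length(pot_tables)
          }
          cls <- "bond"
        } else if ((j - i >= 3L ||
                    (j == i + 2L && helix_id[i] > 0L &&
                     helix_id[i] == helix_id[j])) &&
                   d0 <= params$native_contact_cutoff) {
          lo <- max(hc, d0 - params$well_width / 2)
          hi <- d0 + params$well_width / 2
          thr <- if (lo > hc) c(hc, lo, hi) else c(hc, hi)
          en <- if (lo > hc) c(Inf, 0, -params$native_well_depth, 0) else
            c(Inf, -params$native_well_depth, 0)
          pot_tables[[length(pot_tables) + 1L]] <- new_step_table(thr, en)
          pid <- length(pot_tables)
          cls <- "native"
          native[[length(native) + 1L]] <- c(i, j, d0)
        } else {
          if (d0 <= hc) {
            stop("non-bonded pair ", i, "-", j,
                 " violates the hard core in the built geometry")
          }
          pid <- 1L
          cls <- "core"
        }
        pair_i <- c(pair_i, i); pair_j <- c(pair_j, j)
        pair_pot <- c(pair_pot, pid); pair_class <- c(pair_class, cls)
      }
    }
  }
  native <- if (length(native)) {
    m <- do.call(rbind, native)
    data.frame(i = as.integer(m[, 1]), j = as.integer(m[, 2]), r0 = m[, 3])
  } else data.frame(i = integer(0), j = integer(0), r0 = numeric(0))

  model <- structure(list(
    topology = topology, params = params, n = n,
    masses = rep(topology$bead_mass, n),
    pairs = data.frame(i = pair_i, j = pair_j, class = pair_class,
                       pot = pair_pot, stringsAsFactors = FALSE),
    pot_tables = pot_tables, native_contacts = native,
    reference = pos), class = "dmd_model")

  vel <- matrix(0, n, 3)
  if (!is.null(init_temperature)) {
    set.seed(seed)
    vel <- maxwell_velocities(n, topology$bead_mass, init_temperature)
  }
  state <- structure(list(positions = pos, velocities = vel, time = 0),
                     class = "dmd_state")
  list(model = model, state = state)
}

#' @export
print.dmd_model <- function(x, ...) {
  cat("<dmd_model> ", x$n, " beads, ", sum(x$pairs$class == "bond"),
      " bonds, ", nrow(x$native_contacts), " native contacts\n", sep = "")
  invisible(x)
}

#' Maxwell-Boltzmann velocities
#'
#' Draws each velocity component from a zero-mean Gaussian with variance
#' `temperature / mass` (reduced units). Uses R's RNG stream; call
#' `set.seed()` first for reproducibility.
#'
#' @param n number of beads.
#' @param mass bead mass (scalar or length-n), Da.
#' @param temperature reduced temperature, kcal/(mol kB).
#' @return n x 3 matrix of velocities, Angstrom per time unit.
#' @export
maxwell_velocities <- function(n, mass, temperature) {
  if (temperature < 0) stop("temperature must be >= 0")
  sd <- sqrt(temperature / rep(mass, length.out = n))
  matrix(stats::rnorm(3L * n, 0, rep(sd, 3L)), n, 3)
}

#' Potential energy of a configuration under a model
#'
#' Sums the step-table energy level of every pair at its current
#' separation. Infinite (forbidden) levels raise an error, since they mark
#' an inconsistent configuration rather than a physical energy.
#'
#' @param model a `dmd_model`.
#' @param positions n x 3 coordinate matrix.
#' @return potential energy, kcal/mol.
#' @export
potential_energy <- function(model, positions) {
  d <- as.matrix(stats::dist(positions))
  r <- d[cbind(model$pairs$i, model$pairs$j)]
  e <- vapply(seq_along(r), function(k) {
    step_energy_at(model$pot_tables[[model$pairs$pot[k]]], r[k])
  }, numeric(1))
  if (any(is.infinite(e))) {
    bad <- which(is.infinite(e))[1L]
    stop("pair ", model$pairs$i[bad], "-", model$pairs$j[bad],
         " is in a forbidden region (distance ", format(r[bad]), " A)")
  }
  sum(e)
}
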