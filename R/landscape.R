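# Optimal proper rotation aligning centred coordinate set P onto Q (Kabsch,
# via SVD; reflections are rejected by negating the smallest singular
# direction).
kabsch_rotation <- function(P, Q) {
  H <- t(P) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$u) * det(sv$v))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

#' Least-squares superposition RMSD
#'
#' Removes the centroids, finds the optimal proper rotation (closed-form
#' Kabsch solution) and returns the minimised root-mean-square deviation
#' over the selected beads. Symmetric in its arguments and invariant under
#' rigid transformation of either structure.
#'
#' @param coords,reference n x 3 coordinate matrices.
#' @param selection bead indices to superpose (default all); must be
#'   identical for both structures, >= 3 beads and non-collinear for a
#'   unique rotation.
#' @param fit superpose before measuring (`TRUE`, default); `FALSE` gives
#'   the plain coordinate RMSD.
#' @return RMSD in Angstrom.
#' @export
superpose_rmsd <- function(coords, reference, selection = NULL, fit = TRUE) {
  coords <- as.matrix(coords); reference <- as.matrix(reference)
  if (!is.null(selection)) {
    coords <- coords[selection, , drop = FALSE]
    reference <- reference[selection, , drop = FALSE]
  }
  if (nrow(coords) != nrow(reference)) stop("mismatched selection sizes")
  if (!fit) return(sqrt(mean(rowSums((coords - reference)^2))))
  if (nrow(coords) < 3L) stop("need >= 3 beads for a unique superposition")
  P <- sweep(coords, 2L, colMeans(coords))
  Q <- sweep(reference, 2L, colMeans(reference))
  R <- kabsch_rotation(P, Q)
  sqrt(mean(rowSums((P %*% R - Q)^2)))
}

#' Radius of gyration
#'
#' Mass-weighted root-mean-square distance of the selected beads from their
#' centre of mass. With uniform masses (the coarse-grained default) this is
#' the geometric Rg.
#'
#' @param coords n x 3 coordinate matrix.
#' @param selection bead indices (default all, >= 2 beads).
#' @param masses per-bead masses (recycled; default uniform).
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(coords, selection = NULL, masses = NULL) {
  coords <- as.matrix(coords)
  if (!is.null(selection)) coords <- coords[selection, , drop = FALSE]
  n <- nrow(coords)
  if (n < 2L) stop("need >= 2 beads")
  m <- if (is.null(masses)) rep(1, n) else rep(masses, length.out = n)
  if (sum(m) <= 0) stop("total mass must be > 0")
  com <- colSums(coords * m) / sum(m)
  sqrt(sum(m * rowSums(sweep(coords, 2L, com)^2)) / sum(m))
}

#' Reaction-coordinate series over a trajectory
#'
#' Per-frame (RMSD, Rg) over a bead selection -- by convention the C-alpha
#' beads of the four helices, excluding the highly flexible tail -- with
#' RMSD measured against a fixed reference (the run's starting structure).
#'
#' @param frames frames x beads x 3 array (e.g. one temperature's frames
#'   from [run_rex()]).
#' @param reference n x 3 reference coordinates.
#' @param selection bead indices entering both coordinates.
#' @param temperature optional reduced-temperature label carried along.
#' @return data.frame with columns `rmsd`, `rg` (Angstrom) and attribute
#'   `temperature`.
#' @export
rc_series <- function(frames, reference, selection = NULL,
                      temperature = NA_real_) {
  nf <- dim(frames)[1L]
  if (is.null(selection)) selection <- seq_len(dim(frames)[2L])
  sub <- frames[, selection, , drop = FALSE]
  ref <- array(reference[selection, , drop = FALSE],
               c(1L, length(selection), 3L))
  rmsd <- as.numeric(.rmsd_to_refs_cpp(sub, ref, TRUE))
  rg <- vapply(seq_len(nf), function(f) {
    radius_of_gyration(sub[f, , ])
  }, numeric(1))
  out <- data.frame(rmsd = rmsd, rg = rg)
  attr(out, "temperature") <- temperature
  out
}

#' Potential of mean force over (RMSD, Rg)
#'
#' `PMF(RMSD, Rg) = -kB T log W(RMSD, Rg) + C`, where W is the normalised
#' 2-D bin occupancy and the constant C shifts the lowest occupied bin to
#' zero (the partition-function term is a constant absorbed into C). Empty
#' bins are NA, not zero.
#'
#' @param series data.frame with `rmsd` and `rg` columns (see
#'   [rc_series()]), or any two-column object.
#' @param temperature reduced temperature; `kB T` is the PMF unit scale in
#'   kcal/mol.
#' @param bin_width length-2 (RMSD, Rg) bin widths, Angstrom; default 1 A.
#' @return a `free_energy_surface`: bin edges, PMF matrix (RMSD bins x Rg
#'   bins, kcal/mol), occupancy counts, temperature.
#' @export
compute_pmf <- function(series, temperature, bin_width = c(1, 1)) {
  rmsd <- series[[1L]]; rg <- series[[2L]]
  if (!length(rmsd)) stop("empty reaction-coordinate series")
  bin_width <- rep(bin_width, length.out = 2L)
  ix <- as.integer(floor(rmsd / bin_width[1L]))
  iy <- as.integer(floor(rg / bin_width[2L]))
  rx <- range(ix); ry <- range(iy)
  counts <- matrix(0L, rx[2L] - rx[1L] + 1L, ry[2L] - ry[1L] + 1L)
  for (k in seq_along(ix)) {
    counts[ix[k] - rx[1L] + 1L, iy[k] - ry[1L] + 1L] <-
      counts[ix[k] - rx[1L] + 1L, iy[k] - ry[1L] + 1L] + 1L
  }
  W <- counts / sum(counts)
  pmf <- -temperature * log(W)
  pmf[counts == 0L] <- NA_real_
  pmf <- pmf - min(pmf, na.rm = TRUE)
  structure(list(
    rmsd_edges = (rx[1L]:(rx[2L] + 1L)) * bin_width[1L],
    rg_edges = (ry[1L]:(ry[2L] + 1L)) * bin_width[2L],
    pmf = pmf, counts = counts, temperature = temperature,
    bin_index = cbind(ix - rx[1L] + 1L, iy - ry[1L] + 1L)),
    class = "free_energy_surface")
}

#' @export
print.free_energy_surface <- function(x, ...) {
  cat("<free_energy_surface> ", nrow(x$pmf), " x ", ncol(x$pmf),
      " bins at T = ", x$temperature, "; max PMF ",
      round(max(x$pmf, na.rm = TRUE), 2), " kcal/mol\n", sep = "")
  invisible(x)
}

#' Label the metastable-state temperatures T1..T4 from a Cv curve
#'
#' T1 is the lowest analysis temperature; T2 the local minimum below the
#' first Cv peak; T3 the minimum between the first and second peaks (the
#' intermediate-state temperature); T4 the final local minimum. Fewer
#' detected extrema yield as many labels as exist; a monotone curve yields
#' T1 only, with a diagnostic attribute.
#'
#' @param cv a `cv_curve` from [heat_capacity()].
#' @return named numeric vector (reduced temperatures), subset of
#'   `c(T1, T2, T3, T4)`.
#' @export
assign_state_temperatures <- function(cv) {
  stopifnot(inherits(cv, "cv_curve"))
  grid <- cv$curve$temperature
  out <- c(T1 = grid[1L])
  peaks <- cv$peaks; minima <- cv$minima
  if (!length(peaks)) {
    attr(out, "diagnostic") <- "monotone Cv: no peaks detected"
    return(out)
  }
  below <- minima[minima < peaks[1L]]
  if (length(below)) out <- c(out, T2 = max(below))
  if (length(peaks) >= 2L) {
    between <- minima[minima > peaks[1L] & minima < peaks[2L]]
    if (length(between)) out <- c(out, T3 = between[1L])
  }
  after <- minima[minima > peaks[length(peaks)]]
  last_min <- if (length(minima)) max(minima) else NA_real_
  if (!is.na(last_min) && !last_min %in% out) out <- c(out, T4 = last_min)
  out
}

#' Frames in the lowest free-energy basin
#'
#' The basin is the 4-connected component of occupied bins containing the
#' global PMF minimum, restricted to bins with PMF at most `depth_cutoff`;
#' the function returns the indices of the frames that fall in it.
#'
#' @param surface a [compute_pmf()] result built from `series`.
#' @param depth_cutoff basin depth, kcal/mol above the minimum.
#' @return integer vector of frame indices (rows of the series used to
#'   build the surface).
#' @export
extract_basin <- function(surface, depth_cutoff = 1) {
  stopifnot(inherits(surface, "free_energy_surface"))
  pmf <- surface$pmf
  ok <- !is.na(pmf) & pmf <= depth_cutoff
  start <- which(pmf == 0)[1L]
  nr <- nrow(pmf)
  member <- matrix(FALSE, nr, ncol(pmf))
  queue <- start
  member[start] <- TRUE
  while (length(queue)) {
    cell <- queue[1L]; queue <- queue[-1L]
    r <- (cell - 1L) %% nr + 1L
    c <- (cell - 1L) %/% nr + 1L
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      rr <- r + d[1L]; cc <- c + d[2L]
      if (rr >= 1L && rr <= nr && cc >= 1L && cc <= ncol(pmf)) {
        idx <- rr + (cc - 1L) * nr
        if (ok[idx] && !member[idx]) {
          member[idx] <- TRUE
          queue <- c(queue, idx)
        }
      }
    }
  }
  bi <- surface$bin_index
  which(member[bi[, 1L] + (bi[, 2L] - 1L) * nr])
}

#' RMSD of trajectory frames to reference centroids
#'
#' Per-frame superposition RMSD to each supplied centroid plus the nearest
#' centroid label; with two centroids this realises the "native-like" vs
#' "intermediate-like" state assignment.
#'
#' @param frames frames x beads x 3 array.
#' @param centroids list of n x 3 coordinate matrices (or a single matrix).
#' @param selection bead indices shared by frames and centroids.
#' @return list with `rmsd` (frames x centroids matrix) and `label`
#'   (integer nearest-centroid index per frame).
#' @export
rmsd_to_centroids <- function(frames, centroids, selection = NULL) {
  if (is.matrix(centroids)) centroids <- list(centroids)
  if (is.null(selection)) selection <- seq_len(dim(frames)[2L])
  sub <- frames[, selection, , drop = FALSE]
  nr <- length(centroids)
  refs <- array(0, c(nr, length(selection), 3L))
  for (r in seq_len(nr)) {
    refs[r, , ] <- as.matrix(centroids[[r]])[selection, , drop = FALSE]
  }
  m <- .rmsd_to_refs_cpp(sub, refs, TRUE)
  list(rmsd = m, label = max.col(-m, ties.method = "first"))
}
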