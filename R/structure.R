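#' Pairwise-RMSD matrix over trajectory frames
#'
#' @param frames frames x beads x 3 array.
#' @param selection bead indices (default all).
#' @param fit superpose each pair before measuring (default) or use plain
#'   coordinate RMSD.
#' @return symmetric frames x frames matrix of RMSDs, Angstrom.
#' @export
pairwise_rmsd_matrix <- function(frames, selection = NULL, fit = TRUE) {
  if (!is.null(selection)) frames <- frames[, selection, , drop = FALSE]
  .rmsd_matrix_cpp(frames, fit)
}

#' Data-driven clustering cutoff from the pairwise-RMSD distribution
#'
#' Histograms all unordered pairwise RMSDs of the selected beads and
#' returns the centre of the modal bin -- the highest peak of the pairwise
#' RMSD distribution. Ties pick the lower bin.
#'
#' @param frames frames x beads x 3 array (>= 2 frames).
#' @param selection bead indices.
#' @param bin_width histogram bin width, Angstrom (default 1).
#' @param fit superpose before measuring (default TRUE).
#' @return cutoff in Angstrom.
#' @export
pairwise_rmsd_cutoff <- function(frames, selection = NULL, bin_width = 1,
                                 fit = TRUE) {
  if (dim(frames)[1L] < 2L) stop("need >= 2 frames")
  m <- pairwise_rmsd_matrix(frames, selection, fit)
  r <- m[upper.tri(m)]
  if (all(r < 1e-12)) {
    warning("all frames identical; cutoff 0")
    return(0)
  }
  idx <- as.integer(floor(r / bin_width))
  tab <- table(idx)
  modal <- as.integer(names(tab)[which.max(tab)]) # which.max: first = lower bin
  (modal + 0.5) * bin_width
}

#' Leader-algorithm conformational clustering
#'
#' Single pass in frame order: a frame joins the first existing leader
#' within `cutoff` RMSD, otherwise it founds a new cluster. Every member is
#' therefore within `cutoff` of its leader. Per cluster, the centroid is
#' the member with minimal summed RMSD to its co-members. Clusters are
#' reported sorted by size (descending, ties by earliest leader frame).
#'
#' @param frames frames x beads x 3 array.
#' @param cutoff leader cutoff, Angstrom (>= 0); see
#'   [pairwise_rmsd_cutoff()] for the data-driven choice.
#' @param selection bead indices used for the RMSD metric.
#' @param fit superpose before measuring (default TRUE); `FALSE` gives the
#'   plain coordinate metric.
#' @return a `cluster_result`: per-frame `assignment` (cluster rank),
#'   `clusters` data.frame (size, leader frame, centroid frame), and the
#'   cutoff used.
#' @export
leader_cluster <- function(frames, cutoff, selection = NULL, fit = TRUE) {
  if (cutoff < 0) stop("cutoff must be >= 0")
  sub <- if (is.null(selection)) frames else frames[, selection, , drop = FALSE]
  res <- .leader_pass_cpp(sub, cutoff, fit)
  raw_assign <- res$assignment
  leaders <- res$leaders
  sizes <- tabulate(raw_assign, nbins = length(leaders))
  ord <- order(-sizes, leaders)
  rank_of_raw <- integer(length(leaders))
  rank_of_raw[ord] <- seq_along(ord)
  assignment <- rank_of_raw[raw_assign]
  centroid <- integer(length(leaders))
  for (cl in seq_along(leaders)) {
    members <- which(raw_assign == cl)
    if (length(members) == 1L) {
      centroid[cl] <- members
    } else {
      dm <- .rmsd_matrix_cpp(sub[members, , , drop = FALSE], fit)
      centroid[cl] <- members[which.min(rowSums(dm))]
    }
  }
  clusters <- data.frame(cluster = seq_along(ord), size = sizes[ord],
                         leader = leaders[ord], centroid = centroid[ord])
  structure(list(assignment = assignment, clusters = clusters,
                 cutoff = cutoff), class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> ", nrow(x$clusters), " clusters over ",
      length(x$assignment), " frames (cutoff ", x$cutoff, " A); largest ",
      x$clusters$size[1L], "\n", sep = "")
  invisible(x)
}

#' Mean / standard-deviation pairwise-distance matrix
#'
#' Ensemble statistics of all inter-bead distances: entry (i, j) with
#' i < j holds the mean distance over frames, entry (j, i) the standard
#' deviation (the triangular mean/std encoding of inter-residue distance
#' maps); the diagonal is 0. Only the C-alpha bead mode is computable on a
#' coarse-grained model; the side-chain-centroid mode requires side-chain
#' atoms and raises an error here.
#'
#' @param frames frames x beads x 3 array.
#' @param mode `"ca"` (bead positions) or `"sidechain_centroid"`
#'   (unsupported on bead models).
#' @return a `distance_matrix_pair`: n x n matrix with the triangular
#'   encoding, plus `mean` and `sd` full matrices as attributes.
#' @export
distance_matrix <- function(frames, mode = c("ca", "sidechain_centroid")) {
  mode <- match.arg(mode)
  if (mode == "sidechain_centroid") {
    stop("sidechain_centroid mode needs side-chain atoms; ",
         "a C-alpha bead model supports mode = \"ca\" only")
  }
  nf <- dim(frames)[1L]; n <- dim(frames)[2L]
  s1 <- matrix(0, n, n); s2 <- matrix(0, n, n)
  for (f in seq_len(nf)) {
    d <- as.matrix(stats::dist(frames[f, , ]))
    s1 <- s1 + d
    s2 <- s2 + d^2
  }
  mean_d <- s1 / nf
  # ensemble (population) standard deviation: a bead displaced by 2 A in
  # one of two frames yields sd exactly 1 for that pair
  sd_d <- sqrt(pmax(s2 / nf - mean_d^2, 0))
  tri <- matrix(0, n, n)
  tri[upper.tri(tri)] <- mean_d[upper.tri(mean_d)]
  tri[lower.tri(tri)] <- sd_d[lower.tri(sd_d)]
  structure(tri, mean = mean_d, sd = sd_d, mode = mode,
            class = c("distance_matrix_pair", "matrix"))
}

#' Contact occupancy over an ensemble
#'
#' Fraction of frames in which each pair sits within `threshold`, plus a
#' per-pair distance histogram at 1 Angstrom bins -- the salt-bridge
#' occupancy analysis in coarse-grained form.
#'
#' @param frames frames x beads x 3 array.
#' @param pairs data.frame (or 2-column matrix) of bead index pairs.
#' @param threshold contact distance, Angstrom (> 0).
#' @param bin_width histogram bin width (default 1 A).
#' @return data.frame with `i`, `j`, `occupancy`, and the distance
#'   histograms as attribute `histograms`.
#' @export
contact_occupancy <- function(frames, pairs, threshold, bin_width = 1) {
  if (threshold <= 0) stop("threshold must be > 0")
  pairs <- as.matrix(pairs)[, 1:2, drop = FALSE]
  nf <- dim(frames)[1L]
  occ <- numeric(nrow(pairs))
  hists <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    d <- sqrt(rowSums((frames[, pairs[k, 1L], , drop = FALSE] -
                       frames[, pairs[k, 2L], , drop = FALSE])^2, dims = 1L))
    occ[k] <- mean(d <= threshold)
    hists[[k]] <- graphics::hist(
      d, breaks = seq(floor(min(d)), max(d) + bin_width, by = bin_width),
      plot = FALSE)
  }
  out <- data.frame(i = pairs[, 1L], j = pairs[, 2L], occupancy = occ)
  attr(out, "histograms") <- hists
  out
}

# Angle (degrees, in [0, 180]) at vertex b of points a-b-c.
three_point_angle <- function(a, b, c) {
  u <- a - b; v <- c - b
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Signed dihedral angle of four points
#'
#' Standard convention: the angle between the planes (p1, p2, p3) and
#' (p2, p3, p4), signed by the handedness of the twist, in (-180, 180].
#' For two axis vectors b1 = p2 - p1 and b3 = p4 - p3 joined tail-to-head,
#' an anti-parallel arrangement gives 0 degrees and a parallel one +/-180.
#'
#' @param p1,p2,p3,p4 length-3 coordinate vectors.
#' @return dihedral in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  x <- sum(n1 * n2)
  y <- sum(c(n1[2] * n2[3] - n1[3] * n2[2], n1[3] * n2[1] - n1[1] * n2[3],
             n1[1] * n2[2] - n1[2] * n2[1]) * b2) / sqrt(sum(b2^2))
  atan2(y, x) * 180 / pi
}

#' Geometric observables of an ensemble
#'
#' End-to-end distance series (between the terminal beads), centre-of-mass
#' distances between named segment pairs, the inter-domain angle theta
#' (three anchor beads) and the signed inter-domain dihedral phi (four
#' anchor beads, N- to C-terminal directionality: 0 degrees is an
#' anti-parallel domain arrangement). Histograms use 1 A / 1 degree bins.
#'
#' @param frames frames x beads x 3 array.
#' @param topology the `chain_topology` (terminal beads and segments).
#' @param segment_pairs list of 2-element character vectors naming segment
#'   pairs for centre-of-mass distances; default pairs every non-helix
#'   segment with H4.
#' @param theta_anchors three bead indices (default: mid-H4, end-H4,
#'   mid-tail).
#' @param phi_anchors four bead indices defining the two domain axis
#'   vectors (default: start-H1, end-H4, start-tail, end-tail).
#' @return a `geometry_report`: series (`end_to_end`, `theta`, `phi`,
#'   per-pair `com_distance`) and matching histograms.
#' @export
geometry_report <- function(frames, topology, segment_pairs = NULL,
                            theta_anchors = NULL, phi_anchors = NULL) {
  n <- topology$n_beads
  seg <- topology$segment_map
  labels <- seg$label
  if (is.null(segment_pairs)) {
    others <- labels[!grepl("^H[0-9]+$", labels)]
    if (!"H4" %in% labels) stop("missing anchor segment: H4")
    segment_pairs <- lapply(others, function(l) c(l, "H4"))
  }
  pick_mid <- function(lbl) {
    b <- segment_beads(topology, lbl)
    b[ceiling(length(b) / 2)]
  }
  if (is.null(theta_anchors)) {
    for (lbl in c("H4", "tail")) {
      if (!lbl %in% labels) stop("missing anchor segment: ", lbl)
    }
    h4 <- segment_beads(topology, "H4")
    theta_anchors <- c(pick_mid("H4"), h4[length(h4)], pick_mid("tail"))
  }
  if (is.null(phi_anchors)) {
    for (lbl in c("H1", "H4", "tail")) {
      if (!lbl %in% labels) stop("missing anchor segment: ", lbl)
    }
    h1 <- segment_beads(topology, "H1")
    h4 <- segment_beads(topology, "H4")
    tl <- segment_beads(topology, "tail")
    phi_anchors <- c(h1[1L], h4[length(h4)], tl[1L], tl[length(tl)])
  }
  nf <- dim(frames)[1L]
  first <- matrix(frames[, 1L, ], ncol = 3L)
  last <- matrix(frames[, n, ], ncol = 3L)
  e2e <- sqrt(rowSums((first - last)^2))
  theta <- vapply(seq_len(nf), function(f) {
    three_point_angle(frames[f, theta_anchors[1L], ],
                      frames[f, theta_anchors[2L], ],
                      frames[f, theta_anchors[3L], ])
  }, numeric(1))
  phi <- vapply(seq_len(nf), function(f) {
    dihedral_angle(frames[f, phi_anchors[1L], ], frames[f, phi_anchors[2L], ],
                   frames[f, phi_anchors[3L], ], frames[f, phi_anchors[4L], ])
  }, numeric(1))
  com <- lapply(segment_pairs, function(pr) {
    a <- segment_beads(topology, pr[1L]); b <- segment_beads(topology, pr[2L])
    vapply(seq_len(nf), function(f) {
      ca <- colMeans(frames[f, a, , drop = FALSE][1, , ])
      cb <- colMeans(frames[f, b, , drop = FALSE][1, , ])
      sqrt(sum((ca - cb)^2))
    }, numeric(1))
  })
  names(com) <- vapply(segment_pairs, paste, "", collapse = "-")
  hist1 <- function(x, w) {
    graphics::hist(x, breaks = seq(floor(min(x)) - w, max(x) + w, by = w),
                   plot = FALSE)
  }
  structure(list(
    end_to_end = e2e, theta = theta, phi = phi, com_distance = com,
    anchors = list(theta = theta_anchors, phi = phi_anchors),
    histograms = list(end_to_end = hist1(e2e, 1), theta = hist1(theta, 1),
                      phi = hist1(phi, 1))),
    class = "geometry_report")
}

# Virtual C-alpha dihedral/angle based secondary-structure surrogate for one
# frame: H if the (i-1..i+2) virtual dihedral is helical (30..70 deg) and
# both flanking virtual bond angles are canonical (75..105 deg), B if the
# dihedral is extended (|tau| >= 150 deg), else L. This is a CG stand-in,
# not an all-atom hydrogen-bond assignment.
frame_ss <- function(pos) {
  n <- nrow(pos)
  ss <- rep("L", n)
  if (n < 4L) return(ss)
  tau <- vapply(2:(n - 2L), function(i) {
    dihedral_angle(pos[i - 1L, ], pos[i, ], pos[i + 1L, ], pos[i + 2L, ])
  }, numeric(1))
  ang <- vapply(2:(n - 1L), function(i) {
    three_point_angle(pos[i - 1L, ], pos[i, ], pos[i + 1L, ])
  }, numeric(1))
  for (i in 2:(n - 2L)) {
    t <- tau[i - 1L]
    a1 <- ang[i - 1L]; a2 <- ang[i]
    if (t >= 30 && t <= 70 && a1 >= 75 && a1 <= 105 && a2 >= 75 && a2 <= 105) {
      ss[i] <- "H"
    } else if (abs(t) >= 150) {
      ss[i] <- "B"
    }
  }
  ss
}

#' Per-residue secondary-structure content
#'
#' Coarse-grained secondary-structure surrogate over an ensemble: per
#' residue, the fraction of frames assigned helix (H), extended/strand (B)
#' or loop (L) from the virtual C-alpha dihedral and bond angles. When a
#' named list of frame arrays is supplied the profile is computed per
#' temperature.
#'
#' @param frames frames x beads x 3 array, or a named list of such arrays
#'   (one per temperature).
#' @param topology the `chain_topology` (>= 5 beads).
#' @return data.frame of per-residue H/B/L fractions (with a `temperature`
#'   column when a list was supplied).
#' @export
helicity_profile <- function(frames, topology) {
  if (topology$n_beads < 5L) stop("chain too short for a helicity profile")
  one <- function(arr, label = NA) {
    nf <- dim(arr)[1L]
    m <- vapply(seq_len(nf), function(f) frame_ss(arr[f, , ]),
                character(topology$n_beads))
    data.frame(residue = seq_len(topology$n_beads),
               H = rowMeans(m == "H"), B = rowMeans(m == "B"),
               L = rowMeans(m == "L"), temperature = label)
  }
  if (is.list(frames)) {
    labs <- names(frames)
    if (is.null(labs)) labs <- as.character(seq_along(frames))
    do.call(rbind, lapply(seq_along(frames), function(k) {
      one(frames[[k]], labs[k])
    }))
  } else {
    one(frames)[, -5L]
  }
}

# Deterministic quasi-uniform sphere points (Fibonacci spiral).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area of labelled residues
#'
#' Shrake-Rupley style numerical SASA: each bead carries a sphere of
#' radius `radius + probe` sampled with a fixed quasi-uniform point set;
#' points buried inside any neighbour's expanded sphere are discarded. The
#' total over the hydrophobic label set tracks hydrophobic burial.
#'
#' @param frame n x 3 coordinate matrix (one conformation).
#' @param radii per-bead radii, Angstrom (recycled; default half the
#'   topology hard core, 2 A).
#' @param probe probe radius, Angstrom (default 1.4, a water molecule).
#' @param hydrophobic bead indices carrying the hydrophobic label (default
#'   all beads).
#' @param n_points sample points per sphere (default 960).
#' @return total SASA over the labelled beads, Angstrom^2; per-bead values
#'   as attribute `per_bead`.
#' @export
hydrophobic_sasa <- function(frame, radii = 2, probe = 1.4,
                             hydrophobic = NULL, n_points = 960L) {
  frame <- as.matrix(frame)
  n <- nrow(frame)
  radii <- rep(radii, length.out = n)
  if (is.null(hydrophobic)) hydrophobic <- seq_len(n)
  pts <- fibonacci_sphere(n_points)
  expanded <- radii + probe
  per <- numeric(length(hydrophobic))
  for (k in seq_along(hydrophobic)) {
    i <- hydrophobic[k]
    sphere <- sweep(pts * expanded[i], 2L, frame[i, ], `+`)
    exposed <- rep(TRUE, n_points)
    for (j in seq_len(n)) {
      if (j == i) next
      d2 <- sum((frame[i, ] - frame[j, ])^2)
      reach <- expanded[i] + expanded[j]
      if (d2 >= reach^2) next
      dj <- rowSums(sweep(sphere, 2L, frame[j, ])^2)
      # points exactly on a neighbour's surface (coincident spheres) are
      # assigned to the lower bead index so shared surface is counted once
      lim <- expanded[j]^2
      exposed <- exposed &
        if (j < i) dj > lim + 1e-9 else dj > lim - 1e-9
    }
    per[k] <- 4 * pi * expanded[i]^2 * mean(exposed)
  }
  structure(sum(per), per_bead = stats::setNames(per, hydrophobic))
}
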