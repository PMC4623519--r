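test_that("the clustering cutoff is the modal pairwise-RMSD bin centre", {
  # two frames: a single pair, cutoff = that RMSD's bin centre
  set.seed(2)
  base <- matrix(stats::rnorm(30), 10, 3)
  shifted <- base + matrix(stats::rnorm(30, sd = 1.4), 10, 3)
  fr <- as_frames(base, shifted)
  r <- superpose_rmsd(base, shifted)
  expect_equal(pairwise_rmsd_cutoff(fr), (floor(r) + 0.5))

  # pairwise distances concentrated near 3 A: cutoff in the 3 A bin
  set.seed(3)
  mats <- lapply(1:8, function(k) base + matrix(stats::rnorm(30, sd = 1.9),
                                                10, 3))
  fr2 <- do.call(as_frames, mats)
  m <- pairwise_rmsd_matrix(fr2)
  modal <- floor(stats::median(m[upper.tri(m)]))
  expect_equal(pairwise_rmsd_cutoff(fr2), modal + 0.5)

  # modal-bin tie: the lower bin wins (1-D surrogate distances 1, 2, 3)
  fr3 <- frames_1d(c(0, 1, 2, 3))
  expect_equal(pairwise_rmsd_cutoff(fr3, bin_width = 2, fit = FALSE), 1)

  expect_warning(c0 <- pairwise_rmsd_cutoff(as_frames(base, base)),
                 "identical")
  expect_equal(c0, 0)
  expect_error(pairwise_rmsd_cutoff(as_frames(base)), ">= 2 frames")
})

test_that("leader clustering follows the single-pass rule", {
  set.seed(4)
  base <- matrix(stats::rnorm(24), 8, 3)
  fr_same <- do.call(as_frames, rep(list(base), 5))
  res <- leader_cluster(fr_same, cutoff = 0.5)
  expect_equal(nrow(res$clusters), 1L)
  expect_equal(res$clusters$size, 5L)

  distinct <- do.call(as_frames, lapply(1:4, function(k) {
    base + matrix(stats::rnorm(24, sd = 3), 8, 3)
  }))
  res0 <- leader_cluster(distinct, cutoff = 0)
  expect_equal(nrow(res0$clusters), 4L)

  # hand-run of the leader pass on 1-D surrogate distances
  fr <- frames_1d(c(0, 0.5, 3, 3.2, 10))
  res1 <- leader_cluster(fr, cutoff = 1, fit = FALSE)
  expect_equal(res1$clusters$size, c(2L, 2L, 1L))
  expect_equal(res1$clusters$leader, c(1L, 3L, 5L))
  expect_equal(res1$assignment, c(1L, 1L, 2L, 2L, 3L))
})

test_that("leader clustering matches a brute-force re-simulation", {
  set.seed(6)
  base <- matrix(stats::rnorm(30), 10, 3)
  mats <- lapply(1:30, function(k) base + matrix(stats::rnorm(30, sd = 1.5),
                                                 10, 3))
  fr <- do.call(as_frames, mats)
  cutoff <- 2.2
  res <- leader_cluster(fr, cutoff)

  # naive oracle pass
  leaders <- integer(0)
  raw <- integer(30)
  for (f in 1:30) {
    hit <- 0L
    for (l in seq_along(leaders)) {
      if (superpose_rmsd(fr[f, , ], fr[leaders[l], , ]) <= cutoff) {
        hit <- l; break
      }
    }
    if (hit == 0L) { leaders <- c(leaders, f); hit <- length(leaders) }
    raw[f] <- hit
  }
  sizes <- tabulate(raw)
  ord <- order(-sizes, leaders)
  remap <- integer(length(leaders)); remap[ord] <- seq_along(ord)
  expect_equal(res$assignment, remap[raw])
  expect_equal(sort(res$clusters$leader), sort(leaders))

  # post-hoc audit: every member within cutoff of its own leader
  for (cl in seq_len(nrow(res$clusters))) {
    lead <- res$clusters$leader[cl]
    members <- which(res$assignment == res$clusters$cluster[cl])
    for (f in members) {
      expect_lte(superpose_rmsd(fr[f, , ], fr[lead, , ]), cutoff + 1e-9)
    }
  }
})

test_that("distance matrices carry means above and deviations below", {
  set.seed(8)
  f1 <- matrix(stats::rnorm(18), 6, 3)
  dm1 <- distance_matrix(as_frames(f1))
  expect_true(all(dm1[lower.tri(dm1)] == 0)) # single frame: zero sd

  # one bead displaced 2 A along the pair axis in the second frame
  f2 <- f1
  axis <- (f1[2, ] - f1[1, ]) / sqrt(sum((f1[2, ] - f1[1, ])^2))
  f2[2, ] <- f1[2, ] + 2 * axis
  dm <- distance_matrix(as_frames(f1, f2))
  expect_equal(dm[2, 1], 1) # population sd of {d, d + 2}
  d0 <- sqrt(sum((f1[2, ] - f1[1, ])^2))
  expect_equal(dm[1, 2], d0 + 1)

  # invariance under a global rigid motion of every frame
  R <- random_rotation()
  g1 <- f1 %*% t(R) + 5; g2 <- f2 %*% t(R) + 5
  expect_equal(unclass(distance_matrix(as_frames(g1, g2))), unclass(dm),
               tolerance = 1e-9, ignore_attr = TRUE)

  expect_error(distance_matrix(as_frames(f1), mode = "sidechain_centroid"),
               "C-alpha")
})

test_that("contact occupancy counts frames within threshold", {
  b <- straight_chain(4)
  fr <- do.call(as_frames, lapply(c(0, 0.05, -0.05), function(dz) {
    b$state$positions + dz
  }))
  # bonded neighbours always within any threshold above the bond ceiling
  occ <- contact_occupancy(fr, cbind(1, 2), threshold = 3.9)
  expect_equal(occ$occupancy, 1)
  # a pair held beyond 20 A never registers as a salt bridge
  far <- contact_occupancy(fr, cbind(1, 4), threshold = 4.5)
  expect_equal(far$occupancy, 0)

  set.seed(9)
  pos <- lapply(1:10, function(k) matrix(stats::rnorm(6, sd = 3), 2, 3))
  fr10 <- do.call(as_frames, pos)
  occ10 <- contact_occupancy(fr10, cbind(1, 2), threshold = 4)
  manual <- mean(vapply(pos, function(p) {
    sqrt(sum((p[1, ] - p[2, ])^2)) <= 4
  }, logical(1)))
  expect_equal(occ10$occupancy, manual)
  expect_error(contact_occupancy(fr10, cbind(1, 2), threshold = -1), "> 0")
})

test_that("geometry report measures angles with the documented conventions", {
  expect_equal(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0),
                              c(1, 1, 1)), 90) # staircase quarter-turn
  expect_equal(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0),
                              c(0, 1, 0)), 0)   # anti-parallel axes
  expect_equal(abs(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0),
                                  c(2, 1, 0))), 180) # parallel axes

  topo <- topology_mini_bundle()
  b <- build_mini_bundle(topo, go_parameters())
  fr <- as_frames(b$state$positions, b$state$positions + 3)
  rep1 <- geometry_report(fr, topo)
  expect_length(rep1$end_to_end, 2)
  expect_equal(rep1$end_to_end[1], rep1$end_to_end[2]) # rigid translation
  expect_true(all(rep1$theta >= 0 & rep1$theta <= 180))
  expect_true(all(rep1$phi > -180 & rep1$phi <= 180))
  # collinear theta anchors lie on the extended tail: angle 180
  tail_beads <- segment_beads <- 47:56
  rep2 <- geometry_report(fr, topo, theta_anchors = c(48, 50, 52))
  expect_equal(rep2$theta, c(180, 180), tolerance = 1e-6)

  topo_no_tail <- chain_topology(data.frame(
    label = c("H1", "H2", "H3", "H4"),
    start = c(1, 11, 21, 31), end = c(10, 20, 30, 40)))
  b2 <- build_mini_bundle(topo_no_tail, go_parameters())
  expect_error(geometry_report(as_frames(b2$state$positions), topo_no_tail),
               "tail")
})

test_that("centre-of-mass segment distances match a direct computation", {
  topo <- topology_mini_bundle()
  b <- build_mini_bundle(topo, go_parameters())
  fr <- as_frames(b$state$positions)
  rep1 <- geometry_report(fr, topo, segment_pairs = list(c("tail", "H4")))
  pos <- b$state$positions
  expect_equal(rep1$com_distance[["tail-H4"]][1],
               sqrt(sum((colMeans(pos[47:56, ]) - colMeans(pos[31:40, ]))^2)))
})

test_that("the helicity surrogate classifies canonical geometries", {
  topo <- topology_mini_bundle()
  b <- build_mini_bundle(topo, go_parameters())
  hp <- helicity_profile(as_frames(b$state$positions), topo)
  # interior helix residues (virtual dihedral fully inside one helix): 100% H
  for (l in c("H1", "H2", "H3", "H4")) {
    beads <- segment_beads <- dmdrex:::segment_beads(topo, l)
    interior <- beads[2:(length(beads) - 2)]
    expect_equal(hp$H[interior], rep(1, length(interior)))
  }
  # the extended tail carries no helix assignments
  expect_equal(hp$H[48:55], rep(0, 8))

  chain <- straight_chain(12)
  hp2 <- helicity_profile(as_frames(chain$state$positions),
                          chain$model$topology)
  expect_true(all(hp2$H == 0)) # fully extended: 0% helix

  # planar zig-zag (trans, torsion 180): extended-strand assignment
  zig <- cbind((0:11) * 3.1, rep(c(0, 1), 6), 0)
  hpz <- helicity_profile(as_frames(zig), chain$model$topology)
  expect_true(all(hpz$B[2:10] == 1))
  expect_true(all(hpz$H == 0))

  # helix-coil block chain: H fractions follow the block layout
  mixed_topo <- chain_topology(data.frame(label = c("H1", "tail"),
                                          start = c(1, 13), end = c(12, 24)))
  bm <- build_mini_bundle(mixed_topo, go_parameters())
  hpm <- helicity_profile(as_frames(bm$state$positions), mixed_topo)
  expect_true(all(hpm$H[2:10] == 1))
  expect_true(all(hpm$H[14:22] == 0))

  # per-temperature aggregation keeps labels
  hp3 <- helicity_profile(list(`0.35` = as_frames(b$state$positions),
                               `0.81` = as_frames(b$state$positions)), topo)
  expect_equal(unique(hp3$temperature), c("0.35", "0.81"))
})

test_that("the bundle stays helical in a short low-temperature run", {
  b <- bundle()
  st <- thermalise(b, 0.35, seed = 9)
  tr <- dmd_run(b$model, st, 0.35, 5000, thermostat_rate = 0.1,
                frame_interval = 25, seed = 11)
  topo <- b$model$topology
  hp <- helicity_profile(tr$positions[-(1:40), , ], topo)
  interior <- unlist(lapply(c("H1", "H2", "H3", "H4"), function(l) {
    beads <- dmdrex:::segment_beads(topo, l)
    beads[3:(length(beads) - 2)]
  }))
  expect_gte(mean(hp$H[interior]), 0.95)
})

test_that("numerical SASA matches closed-form sphere arithmetic", {
  r <- 2; w <- 1.4
  single <- hydrophobic_sasa(matrix(0, 1, 3), radii = r, probe = w)
  expect_equal(as.numeric(single), 4 * pi * (r + w)^2, tolerance = 1e-9)

  # fully overlapping beads: the shared surface is counted once
  twin <- hydrophobic_sasa(rbind(c(0, 0, 0), c(0, 0, 0)), radii = r,
                           probe = w)
  expect_equal(as.numeric(twin), 4 * pi * (r + w)^2, tolerance = 1e-9)

  # partially overlapping equal spheres: spherical-cap closed form
  d <- 3
  cap <- function(R, d) 2 * pi * R * (R - d / 2)
  expected <- 2 * (4 * pi * (r + w)^2 - cap(r + w, d))
  got <- hydrophobic_sasa(rbind(c(0, 0, 0), c(d, 0, 0)), radii = r,
                          probe = w)
  expect_lt(abs(got - expected) / expected, 0.01)
  # and against a dense-grid numerical oracle
  dense <- hydrophobic_sasa(rbind(c(0, 0, 0), c(d, 0, 0)), radii = r,
                            probe = w, n_points = 20000)
  expect_lt(abs(got - dense) / dense, 0.01)

  # invariance under rigid motion and label subsetting
  set.seed(10)
  pts <- matrix(stats::rnorm(15, sd = 3), 5, 3)
  R <- random_rotation()
  # the sampling grid is fixed in space, so rigid-motion invariance holds
  # to the point-sampling resolution
  expect_equal(as.numeric(hydrophobic_sasa(pts %*% t(R) + 2)),
               as.numeric(hydrophobic_sasa(pts)), tolerance = 5e-3)
  sub <- hydrophobic_sasa(pts, hydrophobic = c(2, 4))
  per <- attr(hydrophobic_sasa(pts), "per_bead")
  expect_equal(as.numeric(sub), sum(per[c(2, 4)]), tolerance = 1e-9)
})
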