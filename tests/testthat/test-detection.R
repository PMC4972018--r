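# Detector acceptance, POCA vertexing, kinematics, histogramming.

test_that("rectangular solid angle matches a 2-D numerical integration oracle", {
  # oracle: integrate cos(theta)/r^2 over the aperture
  omega_numeric <- function(a, b, d, n = 500) {
    dx <- a / n; dy <- b / n
    xs <- seq(-a / 2 + dx / 2, a / 2 - dx / 2, length.out = n)
    ys <- seq(-b / 2 + dy / 2, b / 2 - dy / 2, length.out = n)
    g <- outer(xs, ys, function(x, y) d / (x^2 + y^2 + d^2)^1.5)
    sum(g) * dx * dy
  }
  expect_equal(solid_angle(tracker(60, 40, 20, 20)),
               omega_numeric(20, 20, 40), tolerance = 1e-4)
  expect_equal(solid_angle(tracker(60, 40, 20, 20)), 0.2354,
               tolerance = 1e-3)
  expect_equal(solid_angle(tracker(90, 70, 1.5, 1.5)),
               omega_numeric(1.5, 1.5, 70), tolerance = 1e-4)
  # far-field limit: Omega -> area / d^2 for small apertures
  expect_equal(solid_angle(tracker(90, 100, 5, 5)), 25 / 1e4,
               tolerance = 0.01)
  # vanishing aperture
  expect_lt(solid_angle(tracker(90, 40, 1e-4, 1e-4)), 1e-10)
})

test_that("detection keeps geometric crossings, thins by efficiency and smears nothing at zero resolution", {
  # tracks aimed straight at the detector centre from the origin
  tk <- tracker(90, 50, 10, 10)
  trk <- tibble::tibble(species = "proton", x_cm = 0, y_cm = 0,
                        z_cm = c(0, 0, 0), dx = c(1, 1, -1), dy = 0,
                        dz = c(0, 0.5, 0), E_MeV = 100, weight = 1)
  trk$dx <- trk$dx / sqrt(trk$dx^2 + trk$dy^2 + trk$dz^2)
  trk$dz <- trk$dz * abs(trk$dx[2])
  # renormalise row 2 properly
  n2 <- sqrt(sum(c(trk$dx[2], trk$dy[2], trk$dz[2])^2))
  trk$dx[2] <- trk$dx[2] / n2; trk$dz[2] <- trk$dz[2] / n2
  det <- detect(trk, tk, seed = 1)
  # row 1 hits the centre; row 2 exits at z = 50*tan(angle) > 5 (miss);
  # row 3 goes the other way
  expect_equal(nrow(det), 1)
  expect_equal(c(det$hit_x, det$hit_y, det$hit_z), c(50, 0, 0),
               tolerance = 1e-9)
  # unchanged direction with zero resolution: line passes through vertex
  expect_equal(c(det$dx, det$dy, det$dz), c(1, 0, 0))
  # zero efficiency: nothing
  det0 <- detect(trk, tracker(90, 50, 10, 10, efficiency = 0), seed = 1)
  expect_equal(nrow(det0), 0)
})

test_that("acceptance fraction of isotropic tracks matches the solid angle", {
  tk <- tracker(90, 40, 12, 12)
  n <- 50000
  set.seed(31)
  u <- runif(n, -1, 1); phi <- runif(n, 0, 2 * pi)
  s <- sqrt(1 - u^2)
  trk <- tibble::tibble(species = "proton", x_cm = 0, y_cm = 0, z_cm = 0,
                        dx = s * cos(phi), dy = s * sin(phi), dz = u,
                        E_MeV = 100, weight = 1)
  det <- detect(trk, tk, seed = 2)
  frac <- nrow(det) / n
  want <- solid_angle(tk) / (4 * pi)
  expect_equal(frac, want, tolerance = 3 * sqrt(want * (1 - want) / n) / want)
})

test_that("POCA vertexing solves textbook skew-line cases and matches a brute-force scan", {
  # perpendicular intersecting lines
  r <- poca_vertex(c(50, 0, 5), c(1, 0, 0), c(0, 0, 0), c(0, 0, 1))
  expect_equal(r$point, c(0, 0, 5), tolerance = 1e-12)
  expect_equal(r$doca_cm, 0, tolerance = 1e-12)
  # unit-offset skew pair
  r <- poca_vertex(c(50, 1, 5), c(1, 0, 0), c(0, 0, 0), c(0, 0, 1))
  expect_equal(r$point, c(0, 0, 5), tolerance = 1e-12)
  expect_equal(r$doca_cm, 1, tolerance = 1e-12)
  # parallel lines are rejected
  expect_error(poca_vertex(c(1, 0, 0), c(0, 0, 1), c(0, 0, 0), c(0, 0, 1)),
               "parallel")

  # brute-force oracle: nested scan over both line parameters
  brute <- function(p0, v, b0, u) {
    ss <- seq(-30, 30, by = 0.01)
    best <- c(Inf, 0)
    for (s in ss) {
      pb <- b0 + s * u
      # distance from pb to the track line (analytic point-line distance)
      w <- pb - p0
      d2 <- sum(w^2) - sum(w * v)^2
      if (d2 < best[1]) best <- c(d2, s)
    }
    list(point = b0 + best[2] * u, doca = sqrt(max(best[1], 0)))
  }
  set.seed(17)
  for (k in 1:20) {
    p0 <- runif(3, -10, 10); b0 <- runif(3, -5, 5)
    v <- random_unit(); u <- random_unit()
    if (abs(sum(u * v)) > 0.99) next
    got <- poca_vertex(p0, v, b0, u)
    want <- brute(p0, v, b0, u)
    expect_equal(got$point, want$point, tolerance = 1e-2)
    expect_equal(got$doca_cm, want$doca, tolerance = 1e-3)
  }
})

test_that("ToF kinematics recovers beta and kinetic energy", {
  c_cm_ns <- 29.9792458
  # beta = 0.5 proton: E = m (1/sqrt(0.75) - 1) = 145.10 MeV
  k <- kinematics(70 / (0.5 * c_cm_ns), 70, 938.272)
  expect_equal(k$beta, 0.5, tolerance = 1e-12)
  expect_equal(k$E_kin_MeV, 938.272 * (1 / sqrt(0.75) - 1), tolerance = 1e-9)
  # scale invariance: doubling path and ToF leaves beta unchanged
  k2 <- kinematics(2 * 70 / (0.5 * c_cm_ns), 140, 938.272)
  expect_equal(k2$beta, 0.5, tolerance = 1e-12)
  # light-speed boundary
  expect_error(kinematics(70 / c_cm_ns, 70, 938.272), "beta")
})

test_that("profile histogramming conserves weights and respects half-open bins", {
  edges <- seq(0, 1, by = 0.1)
  pts <- tibble::tibble(z_cm = c(0.05, 0.1, 0.999, -0.2, 1.0),
                        weight = c(2, 1, 1, 5, 7))
  prof <- longitudinal_profile(pts, edges)
  expect_equal(sum(prof$count), 4)  # under/overflow excluded
  expect_equal(attr(prof, "underflow"), 5)
  expect_equal(attr(prof, "overflow"), 7)
  # 0.1 goes into [0.1, 0.2), not [0, 0.1)
  expect_equal(prof$count[1], 2)
  expect_equal(prof$count[2], 1)
  # per-bin error is the root of the summed squared weights
  expect_equal(prof$err[1], 2)
  expect_error(longitudinal_profile(pts, c(0, 0, 1)), "increasing")
})

test_that("a zero-resolution chain reproduces the vertex histogram exactly", {
  bm <- gsi_beam(sigma_beam = 0)
  trk <- sample_tracks(bm, pmma_block, n_tracks = 4000, theta_aim = 90,
                       seed = 13)
  tk <- tracker(90, 40, 60, 60, efficiency = 1)   # wide open, no smearing
  det <- detect(trk, tk, seed = 1)
  det <- reconstruct_vertices(det, bm)
  edges <- seq(-8.2, 6.2, by = 0.2)
  prof_reco <- longitudinal_profile(det, edges, coord = "z_reco")
  # restrict the vertex histogram to the accepted tracks
  acc <- trk[trk$z_cm %in% det$true_z, ]
  prof_true <- longitudinal_profile(acc, edges, coord = "z_cm")
  expect_equal(prof_reco$count, prof_true$count)
  # POCA coordinates coincide with the vertices on the axis
  expect_equal(det$z_reco, det$true_z, tolerance = 1e-9)
  expect_lt(max(det$doca_cm), 1e-9)
})

test_that("longitudinal blur from angular smearing stays under the geometric bound", {
  bm <- gsi_beam(sigma_beam = 0)
  trk <- sample_tracks(bm, pmma_block, n_tracks = 4000, theta_aim = 90,
                       seed = 13)
  sig <- 0.01
  tk <- tracker(90, 40, 20, 20, sigma_dir_rad = sig)
  det <- reconstruct_vertices(detect(trk, tk, seed = 3), bm)
  blur <- sd(det$z_reco - det$true_z)
  # lever arm: detector distance plus at most the half-diagonal of the
  # active area
  expect_lt(blur, (40 + sqrt(2) * 10) * sig)
  expect_gt(blur, 0.5 * 40 * sig)
})
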