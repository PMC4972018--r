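# Emission density, track sampling, survival, scattering and rate
# arithmetic.

test_that("emission density rises at the entrance and its fit observables track the Bragg depth", {
  bm <- gsi_beam()
  dens <- emission_density(bm, pmma_block)
  p <- attr(dens, "params")
  # rising-edge midpoint at the entrance face by construction
  expect_equal(p[["p3"]], -6.15, tolerance = 1e-9)
  # far upstream: background only (wide margin so the rising tail has died)
  dens4 <- emission_density(bm, pmma_block, margin = 4)
  expect_equal(dens4(-9.6), p[["p5"]], tolerance = 1e-2)
  # outside the window: zero
  expect_equal(dens(-20), 0)
  # the density's own Delta40 approximates the reference 6.60 cm width
  # (0.74 of the 8.90 cm Bragg depth) within 10%
  obs <- range_observables(p)
  expect_equal(obs$delta40, 6.60, tolerance = 0.10)
  # and the falling edge precedes the Bragg depth
  expect_lt(obs$x_right, attr(dens, "z_bp"))
})

test_that("beam range marching matches plain CSDA in a homogeneous block and handles inserts", {
  bm <- gsi_beam()
  br <- beam_range_in_phantom(bm, pmma_block)
  expect_equal(br$z_entry, -6.15, tolerance = 1e-9)
  # WET marching through homogeneous PMMA at catalogue density reproduces
  # the direct PMMA range (same 1.16 length equivalence)
  expect_equal(br$delta_beam, csda_range(carbon, 220, pmma),
               tolerance = 0.01)
  # nested spheres: the low-density core extends the range beyond the
  # value in solid PMMA at rho = 1.2
  br2 <- beam_range_in_phantom(sphere_beam(), nested_spheres)
  expect_equal(br2$z_entry, -10, tolerance = 1e-9)
  dense_only <- phantom(region(solid_sphere(c(0, 0, 0), 10), pmma,
                               density = 1.2))
  br3 <- beam_range_in_phantom(sphere_beam(), dense_only)
  expect_gt(br2$delta_beam, br3$delta_beam)
  # hand arithmetic: 7 cm at 1.2*rsp then the rest at 0.6*rsp
  R_w <- csda_range(carbon, 220, water)
  f <- pmma$rsp_mass
  want <- 7 + (R_w - 7 * 1.2 * f) / (0.6 * f)
  expect_equal(br2$delta_beam, want, tolerance = 1e-6)
})

test_that("track sampling is deterministic, respects the spot size and follows the density", {
  bm <- gsi_beam()
  t1 <- sample_tracks(bm, pmma_block, n_tracks = 500, seed = 11)
  t2 <- sample_tracks(bm, pmma_block, n_tracks = 500, seed = 11)
  expect_identical(t1, t2)
  t3 <- sample_tracks(bm, pmma_block, n_tracks = 500, seed = 12)
  expect_false(identical(t1$z_cm, t3$z_cm))

  # zero spot size: vertices exactly on the beam axis
  bm0 <- gsi_beam(sigma_beam = 0)
  t0 <- sample_tracks(bm0, pmma_block, n_tracks = 200, seed = 5)
  expect_equal(max(abs(t0$x_cm)), 0)
  expect_equal(max(abs(t0$y_cm)), 0)

  # the vertex z histogram matches the density (chi-square GOF, 1% level)
  big <- sample_tracks(bm, pmma_block, n_tracks = 50000, seed = 21)
  dens <- emission_density(bm, pmma_block)
  sup <- attr(dens, "support")
  edges <- seq(sup[1], sup[2], length.out = 30)
  obs <- table(cut(big$z_cm, edges))
  expd <- vapply(seq_len(length(edges) - 1), function(i) {
    integrate(dens, edges[i], edges[i + 1])$value
  }, numeric(1))
  expd <- expd / sum(expd) * nrow(big)
  chi2 <- sum((as.numeric(obs) - expd)^2 / expd)
  expect_lt(chi2, qchisq(0.99, df = length(expd) - 1))

  # emission energies respect the configured truncation
  expect_gte(min(big$E_MeV), 7)
  expect_lte(max(big$E_MeV), 250)
  # analytic mean of the truncated shifted exponential
  s <- 90 - 7; q <- exp(-(250 - 7) / s)
  expect_equal(mean(big$E_MeV), 7 + s - (250 - 7) * q / (1 - q),
               tolerance = 0.01)
})

test_that("survival probability is the range cut times nuclear attenuation", {
  m <- emission_model()
  trk <- tibble::tibble(species = "proton", x_cm = 0, y_cm = 0, z_cm = 0,
                        dx = 1, dy = 0, dz = 0, E_MeV = 100, weight = 1)
  # zero thickness -> certain survival
  s0 <- survival_probability(trk, nested_spheres, m, x_exit = 0)
  expect_equal(s0$p_survive, 1)
  # below the range cut -> zero
  s1 <- survival_probability(dplyr::mutate(trk, E_MeV = 20),
                             nested_spheres, m, x_exit = 10)
  expect_equal(s1$p_survive, 0)
  # analytic check at 5 cm WET: E_min from the inverse water range,
  # survival = exp(-5/80) for energies above it
  s2 <- survival_probability(trk, nested_spheres, m, x_exit = 5)
  expect_equal(s2$p_survive, exp(-5 / 80), tolerance = 1e-6)
  # monotone in thickness at fixed energy
  xs <- c(0, 2, 5, 8, 12)
  ps <- vapply(xs, function(x) {
    survival_probability(trk, nested_spheres, m, x_exit = x)$p_survive
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("mean survival over the spectrum drops by about an order of magnitude from shallow to deep paths", {
  m <- emission_model()
  bm <- gsi_beam()
  trk <- sample_tracks(bm, pmma_block, m, n_tracks = 20000, seed = 3)
  mean_surv <- function(x) {
    mean(survival_probability(trk, pmma_block, m,
                              x_exit = rep(x, nrow(trk)))$p_survive)
  }
  shallow <- mean_surv(2.5)
  deep <- mean_surv(22)
  expect_gt(shallow / deep, 5)
  expect_lt(shallow / deep, 25)
  # analytic oracle for the mean survival: P(E > Emin(x)) * exp(-x/80)
  # under the truncated shifted exponential spectrum
  emin <- fragmon:::min_escape_energy()(22)
  s <- m$E_mean - m$E_min
  pE <- (exp(-(emin - m$E_min) / s) - exp(-(m$E_max - m$E_min) / s)) /
    (1 - exp(-(m$E_max - m$E_min) / s))
  expect_equal(deep, pE * exp(-22 / 80), tolerance = 0.05)
})

test_that("multiple-scattering smearing has the configured Highland width", {
  bm <- gsi_beam()
  trk <- sample_tracks(bm, pmma_block, n_tracks = 10000, seed = 9)
  trk$E_MeV <- 120  # fixed energy so theta0 is common
  x <- rep(6, nrow(trk))
  sm <- scatter_direction(trk, pmma_block, seed = 4, x_exit = x)
  th0 <- attr(sm, "theta0_rad")[1]
  # angle between original and smeared directions, projected RMS ~ theta0
  dots <- rowSums(sm * cbind(trk$dx, trk$dy, trk$dz))
  ang <- acos(pmin(dots, 1))
  # 2-D Gaussian: E[theta^2] = 2 theta0^2
  expect_equal(sqrt(mean(ang^2) / 2), th0, tolerance = 0.03)
  # zero thickness: unchanged
  sm0 <- scatter_direction(trk, pmma_block, seed = 4,
                           x_exit = rep(0, nrow(trk)))
  expect_equal(sm0[, 1], trk$dx)
  # theta0 falls with energy at fixed thickness
  th_lo <- fragmon:::highland_theta0(60, 6)
  th_hi <- fragmon:::highland_theta0(200, 6)
  expect_gt(th_lo, th_hi)
})

test_that("rate arithmetic reproduces the required primaries at both angles", {
  m <- emission_model()
  # four 1.5 x 1.5 cm2 crystals at 70 cm
  omega <- 4 * solid_angle(tracker(90, 70, 1.5, 1.5))
  n90 <- expected_detected(m, 90, omega, n_detected = 1000)
  n60 <- expected_detected(m, 60, omega, n_detected = 1000)
  expect_equal(n90, 2.3e8, tolerance = 0.20)
  expect_equal(n60, 4.7e7, tolerance = 0.20)
  # forward/inverse consistency and linearity
  expect_equal(expected_detected(m, 90, omega, n_primaries = n90), 1000,
               tolerance = 1e-9)
  expect_equal(expected_detected(m, 60, 2 * omega, n_detected = 1000),
               n60 / 2, tolerance = 1e-9)
  expect_error(expected_detected(m, 30, omega, n_detected = 1000),
               "outside")
})

test_that("large-area tracker rate agrees with the clinical-scenario order of magnitude", {
  # 20 x 20 cm tracker at 40 cm and 60 degrees: protons per primary within
  # a factor ~1.5 of the treatment-simulation value 6.4e5 / 2.7e8
  m <- emission_model()
  perprimary <- expected_detected(m, 60, solid_angle(tracker(60, 40, 20, 20)),
                                  n_primaries = 1)
  ref <- 6.4e5 / 2.7e8
  expect_gt(perprimary / ref, 1 / 1.6)
  expect_lt(perprimary / ref, 1.6)
})
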