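# Double-logistic evaluation, erfc and double-logistic fits, range
# observables and their resampling dispersion.

# independent brute-force oracle: dense scan of the profile for the
# outermost 40%-level crossings and the tangent intercept
scan_observables <- function(p, step = 1e-5) {
  lo <- p[["p3"]] - 10 * max(p[["p4"]], 0.1)
  hi <- p[["p1"]] + 10 * max(p[["p2"]], 0.1)
  zg <- seq(lo, hi, by = step)
  fv <- eval_double_logistic(zg, p)
  fmax <- max(fv)
  level <- p[["p5"]] + 0.4 * (fmax - p[["p5"]])
  above <- which(fv >= level)
  x_left <- zg[above[1]]
  x_right <- zg[above[length(above)]]
  slope <- (eval_double_logistic(x_right + step, p) -
              eval_double_logistic(x_right - step, p)) / (2 * step)
  x_tan <- x_right + (p[["p5"]] - level) / slope
  c(x_left = x_left, x_right = x_right, delta40 = x_right - x_left,
    delta40_tan = x_tan - x_left)
}

random_params <- function() {
  p3 <- runif(1, -8, -2)
  dl_params(p0 = runif(1, 100, 2000), p1 = p3 + runif(1, 3, 10),
            p2 = runif(1, 0.2, 2), p3 = p3, p4 = runif(1, 0.1, 1),
            p5 = runif(1, 0, 50))
}

test_that("double-logistic evaluation has the textbook plateau and midpoint values", {
  p <- dl_params(1000, 9, 0.3, 0, 0.2, 50)
  # plateau midway between well-separated edges
  expect_equal(eval_double_logistic(4.5, p), 1050, tolerance = 1e-6)
  # falling-edge midpoint with the rising edge saturated
  expect_equal(eval_double_logistic(9, p), 550, tolerance = 1e-4)
  # convolution with sigma = sigma_beam * cot(90 deg) = 0 changes nothing
  expect_identical(eval_double_logistic(c(2, 9), p, conv_sigma = 0),
                   eval_double_logistic(c(2, 9), p))
  # a genuine convolution preserves the plateau but softens the edges
  pc <- eval_double_logistic(c(4.5, 9.3), p, conv_sigma = 0.5)
  expect_equal(pc[1], 1050, tolerance = 1e-4)
  expect_gt(pc[2], eval_double_logistic(9.3, p))
})

test_that("beam-spot sigma follows cot(theta)", {
  expect_identical(beam_spot_sigma(0.4, 90), 0)
  expect_equal(beam_spot_sigma(0.4, 60), 0.4 / sqrt(3), tolerance = 1e-12)
  expect_equal(beam_spot_sigma(0.4, 45), 0.4, tolerance = 1e-12)
  expect_equal(beam_spot_sigma(0.4, 120), beam_spot_sigma(0.4, 60),
               tolerance = 1e-12)
  expect_error(beam_spot_sigma(0.4, 0), "diverges")
  expect_error(beam_spot_sigma(0.4, 180), "diverges")
})

test_that("erfc fit recovers noiseless parameters and flags profiles without a fall-off", {
  edges <- seq(0, 12, by = 0.2)
  z <- (head(edges, -1) + tail(edges, -1)) / 2
  truth <- c(a = 20, b = 400, c = 1.1, d = 8.2)
  y <- truth[["a"]] + truth[["b"]] *
    2 * pnorm(-sqrt(2) * truth[["c"]] * (z - truth[["d"]]))
  prof <- tibble::tibble(bin_lo = head(edges, -1), bin_hi = tail(edges, -1),
                         count = y, err = sqrt(y))
  ft <- fit_erfc(prof)
  expect_equal(unname(ft$params[c("a", "b", "c", "d")]),
               unname(truth), tolerance = 1e-6)
  # monotone rising profile: no falling edge to fit
  bad <- prof
  bad$count <- seq(1, 400, length.out = nrow(bad))
  expect_error(fit_erfc(bad), "falling edge")
})

test_that("erfc inflection-point uncertainty has near-nominal coverage on Poisson data", {
  edges <- seq(0, 12, by = 0.2)
  z <- (head(edges, -1) + tail(edges, -1)) / 2
  mu <- 20 + 60 * 2 * pnorm(-sqrt(2) * 1.1 * (z - 8.2))
  set.seed(99)
  covered <- 0; n_rep <- 200
  for (r in seq_len(n_rep)) {
    y <- rpois(length(mu), mu)
    prof <- tibble::tibble(bin_lo = head(edges, -1),
                           bin_hi = tail(edges, -1),
                           count = y, err = sqrt(pmax(y, 1)))
    ft <- tryCatch(fit_erfc(prof), error = function(e) NULL)
    if (is.null(ft)) next
    se_d <- sqrt(ft$cov["d", "d"])
    if (abs(ft$params[["d"]] - 8.2) < 1.96 * se_d) covered <- covered + 1
  }
  expect_gt(covered / n_rep, 0.90)
  expect_lt(covered / n_rep, 0.99)
})

test_that("double-logistic fit recovers noiseless parameters to high precision", {
  edges <- seq(-8, 6, by = 0.2)
  z <- (head(edges, -1) + tail(edges, -1)) / 2
  truth <- dl_params(1200, 0.5, 1.7, -6.15, 0.4, 60)
  y <- eval_double_logistic(z, truth)
  prof <- tibble::tibble(bin_lo = head(edges, -1), bin_hi = tail(edges, -1),
                         count = y, err = sqrt(y))
  ft <- fit_profile(prof)
  expect_equal(as.numeric(ft$params), as.numeric(truth), tolerance = 1e-6)
  # with a convolved model the convolved truth is recovered too
  yc <- eval_double_logistic(z, truth, conv_sigma = 0.3)
  profc <- tibble::tibble(bin_lo = head(edges, -1), bin_hi = tail(edges, -1),
                          count = yc, err = sqrt(yc))
  ftc <- fit_profile(profc, conv_sigma = 0.3)
  expect_equal(as.numeric(ftc$params), as.numeric(truth), tolerance = 1e-4)
})

test_that("edge-position pulls are unit-variance on Poisson replicas at the kilotrack scale", {
  edges <- seq(-8, 6, by = 0.2)
  z <- (head(edges, -1) + tail(edges, -1)) / 2
  truth <- dl_params(1, 0.5, 1.7, -6.15, 0.4, 0.05)
  shape <- eval_double_logistic(z, truth)
  mu <- shape * 1000 / sum(shape)   # ~1e3 tracks in the histogram
  set.seed(123)
  pulls1 <- c(); pulls3 <- c()
  for (r in 1:200) {
    y <- rpois(length(mu), mu)
    prof <- tibble::tibble(bin_lo = head(edges, -1),
                           bin_hi = tail(edges, -1),
                           count = y, err = sqrt(pmax(y, 1)))
    ft <- tryCatch(fit_profile(prof), error = function(e) NULL)
    if (is.null(ft)) next
    se <- sqrt(pmax(diag(ft$cov), 0))
    pulls1 <- c(pulls1, (ft$params[["p1"]] - 0.5) / se[2])
    pulls3 <- c(pulls3, (ft$params[["p3"]] + 6.15) / se[4])
  }
  expect_gt(length(pulls1), 180)
  expect_equal(sd(pulls1), 1, tolerance = 0.20)
  expect_equal(sd(pulls3), 1, tolerance = 0.20)
  expect_lt(abs(mean(pulls1)), 0.35)
})

test_that("range observables match the frozen closed-form example", {
  p <- dl_params(1000, 9.0, 0.3, 0.0, 0.2, 0)
  obs <- range_observables(p)
  # closed forms: X_right = p1 + p2 ln 1.5, X_left = p3 - p4 ln 1.5,
  # delta40_tan = delta40 + (5/3) p2
  expect_equal(obs$x_left, -0.2 * log(1.5), tolerance = 1e-6)
  expect_equal(obs$x_right, 9 + 0.3 * log(1.5), tolerance = 1e-6)
  expect_equal(obs$delta40, 9 + 0.5 * log(1.5), tolerance = 1e-6)
  expect_equal(obs$delta40_tan, obs$delta40 + 5 / 3 * 0.3, tolerance = 1e-6)
  # frozen decimals
  expect_equal(obs$x_left, -0.0811, tolerance = 1e-4 / 0.0811)
  expect_equal(obs$x_right, 9.1216, tolerance = 1e-4)
  expect_equal(obs$delta40, 9.2027, tolerance = 1e-4)
  expect_equal(obs$delta40_tan, 9.7027, tolerance = 1e-4)
})

test_that("range observables agree with a dense brute-force scan on random parameter sets", {
  set.seed(2024)
  for (k in 1:50) {
    p <- random_params()
    obs <- range_observables(p)
    want <- scan_observables(p)
    expect_equal(obs$x_left, want[["x_left"]], tolerance = 1e-4)
    expect_equal(obs$x_right, want[["x_right"]], tolerance = 1e-4)
    expect_equal(obs$delta40, want[["delta40"]], tolerance = 1e-4)
    expect_equal(obs$delta40_tan, want[["delta40_tan"]], tolerance = 2e-4)
    # the tangent intercept always lies beyond the 40% crossing
    expect_gte(obs$delta40_tan, obs$delta40)
  }
})

test_that("closed forms hold exactly in the well-separated limit", {
  set.seed(7)
  for (k in 1:10) {
    p2 <- runif(1, 0.1, 0.3); p4 <- runif(1, 0.1, 0.25)
    p3 <- runif(1, -2, 0)
    p1 <- p3 + 31 * max(p2, p4) + runif(1, 0, 3)
    p <- dl_params(runif(1, 200, 2000), p1, p2, p3, p4, 0)
    obs <- range_observables(p)
    expect_equal(obs$x_left, p3 - p4 * log(1.5), tolerance = 1e-6)
    expect_equal(obs$x_right, p1 + p2 * log(1.5), tolerance = 1e-6)
    expect_equal(obs$delta40_tan, obs$delta40 + (5 / 3) * p2,
                 tolerance = 1e-5)
  }
})

test_that("delta40 is invariant under a background shift", {
  p <- dl_params(800, 1.2, 1.5, -6, 0.5, 10)
  shifted <- dl_params(800, 1.2, 1.5, -6, 0.5, 10 + 200)
  a <- range_observables(p)
  b <- range_observables(shifted)
  expect_equal(a$delta40, b$delta40, tolerance = 1e-6)
  expect_equal(a$x_left, b$x_left, tolerance = 1e-6)
})

test_that("uncertainty propagation responds to the fit covariance", {
  p <- dl_params(1000, 0.5, 1.7, -6.15, 0.4, 50)
  cov <- diag(c(100, 0.01, 0.01, 0.0025, 0.0025, 25))
  obs <- range_observables(p, cov = cov)
  expect_true(all(is.finite(c(obs$se_x_left, obs$se_delta40,
                              obs$se_delta40_tan))))
  expect_gt(obs$se_delta40, 0)
  # x_left depends mostly on p3: its error tracks se(p3) = 0.05
  expect_equal(obs$se_x_left, 0.05, tolerance = 0.15)
})

test_that("resampling dispersion contracts: disjoint exhaustion and degenerate cases", {
  set.seed(5)
  trk <- tibble::tibble(z_cm = runif(2500, -6, 2))
  expect_error(resample_dispersion(trk, seq(-8, 4, 0.2), n_tracks = 3000),
               "at least")
  expect_error(resample_dispersion(trk, seq(-8, 4, 0.2), n_tracks = 1000,
                                   n_samples = 5), "disjoint")
})

test_that("resampling dispersion is seed-reproducible and reports NA sigma for one sample", {
  bm <- gsi_beam(sigma_beam = 0)
  trk <- sample_tracks(bm, pmma_block, n_tracks = 6000, seed = 55)
  edges <- seq(-8.2, 6.2, by = 0.2)
  d1 <- resample_dispersion(trk, edges, n_tracks = 1500, seed = 3)
  d2 <- resample_dispersion(trk, edges, n_tracks = 1500, seed = 3)
  expect_identical(d1$summary, d2$summary)
  expect_equal(d1$summary$n_samples, 4)
  one <- resample_dispersion(trk, edges, n_tracks = 1500, n_samples = 1,
                             seed = 3)
  expect_true(is.na(one$summary$sigma_delta40))
  expect_false(is.na(one$summary$mean_delta40))
})

test_that("fit accessors expose broom-style summaries", {
  edges <- seq(-8, 6, by = 0.2)
  z <- (head(edges, -1) + tail(edges, -1)) / 2
  y <- eval_double_logistic(z, dl_params(1200, 0.5, 1.7, -6.15, 0.4, 60))
  prof <- tibble::tibble(bin_lo = head(edges, -1), bin_hi = tail(edges, -1),
                         count = y, err = sqrt(y))
  ft <- fit_profile(prof)
  td <- tidy(ft)
  expect_equal(td$term, c("p0", "p1", "p2", "p3", "p4", "p5"))
  expect_true(all(is.finite(td$estimate)))
  gl <- glance(ft)
  expect_equal(nrow(gl), 1)
  expect_lt(gl$chisq.red, 0.1)  # noiseless data
  obs_td <- tidy(range_observables(ft))
  expect_equal(nrow(obs_td), 4)
})
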