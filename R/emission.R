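# Fragment-emission Monte Carlo calibrated on measured large-angle yields.
# The longitudinal emission density is tied to the Bragg depth of the primary
# beam; energies, angular yields, nuclear absorption and multiple scattering
# are simple parametric models whose defaults are documented calibrations,
# not microscopic physics.

#' Fragment-emission model
#'
#' Bundles the calibrated ingredients of the emission Monte Carlo:
#'
#' * the longitudinal shape (double-logistic; rising edge at the phantom
#'   entrance, falling edge at a fixed fraction of the Bragg depth),
#' * the per-primary per-steradian angular yield table (defaults: the
#'   measured Z=1 fluxes for a 220 MeV/u carbon beam, 12.59e-3/sr at 60
#'   degrees and 2.74e-3/sr at 90 degrees),
#' * the emission-energy spectrum (shifted exponential, mean 90 MeV,
#'   truncated to 7-250 MeV: the lower edge is the detection threshold, the
#'   mean reflects that protons above 50-60 MeV dominate escape),
#' * the nuclear absorption length along the exit path (80 cm WET), and
#' * the fraction of flat background under the profile.
#'
#' @param rise_width rising-edge logistic width, cm.
#' @param fall_frac falling-edge midpoint as a fraction of the Bragg depth
#'   beyond the entrance.
#' @param fall_width falling-edge logistic width, cm.
#' @param background_frac flat background as a fraction of the plateau.
#' @param yields data frame `theta_deg`, `yield_sr` (per primary per sr).
#' @param E_min,E_mean,E_max emission-spectrum parameters, MeV.
#' @param lambda_nuc nuclear absorption length, cm WET.
#' @param cone_half_angle_deg half-angle of the importance-sampling cone
#'   around the detector direction.
#' @return an object of class `emission_model`.
#' @examples
#' emission_model()
#' @export
emission_model <- function(rise_width = 0.4, fall_frac = 0.65,
                           fall_width = 1.7, background_frac = 0.05,
                           yields = NULL,
                           E_min = 7, E_mean = 90, E_max = 250,
                           lambda_nuc = 80, cone_half_angle_deg = 25) {
  yields <- yields %||% data.frame(theta_deg = c(60, 90),
                                   yield_sr = c(12.59e-3, 2.74e-3))
  stopifnot(all(yields$yield_sr >= 0), lambda_nuc > 0,
            E_min > 0, E_max > E_min, E_mean > E_min,
            rise_width > 0, fall_width > 0, background_frac >= 0)
  structure(list(rise_width = rise_width, fall_frac = fall_frac,
                 fall_width = fall_width, background_frac = background_frac,
                 yields = tibble::as_tibble(yields),
                 E_min = E_min, E_mean = E_mean, E_max = E_max,
                 lambda_nuc = lambda_nuc,
                 cone_half_angle_deg = cone_half_angle_deg),
            class = "emission_model")
}

#' @export
print.emission_model <- function(x, ...) {
  cat(sprintf(
    "<emission model> fall at %.2f of Bragg depth (width %.2f cm), spectrum %g-%g MeV (mean %g), lambda_nuc %g cm\n",
    x$fall_frac, x$fall_width, x$E_min, x$E_max, x$E_mean, x$lambda_nuc))
  invisible(x)
}

# Longitudinal coordinate: signed projection on the beam axis.
beam_coord <- function(points, beam) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  as.numeric(points %*% beam$direction)
}

# Ordered (t0, t1, region) segments of the beam ray through the phantom.
ray_segments <- function(origin, direction, phantom) {
  d <- check_unit(as.numeric(direction))
  o <- as.numeric(origin)
  ivals <- lapply(phantom$regions, function(r) solid_interval(r$solid, o, d))
  ts <- c(0)
  for (iv in ivals) if (!is.null(iv)) ts <- c(ts, iv)
  ts <- sort(unique(pmax(ts, 0)))
  segs <- list()
  for (k in seq_len(max(length(ts) - 1, 0))) {
    tm <- (ts[k] + ts[k + 1]) / 2
    owner <- 0L
    for (i in seq_along(ivals)) {
      iv <- ivals[[i]]
      if (!is.null(iv) && tm > iv[1] && tm < iv[2]) owner <- i
    }
    if (owner > 0L) {
      segs[[length(segs) + 1]] <- data.frame(t0 = ts[k], t1 = ts[k + 1],
                                             region = owner)
    }
  }
  if (length(segs) == 0) {
    return(tibble::tibble(t0 = numeric(), t1 = numeric(), region = integer()))
  }
  tibble::as_tibble(do.call(rbind, segs))
}

#' Beam entrance and Bragg depth inside a phantom
#'
#' Traces the beam axis through the phantom and finds the depth at which the
#' cumulative water-equivalent thickness equals the beam's CSDA range in
#' water. Returns entrance and Bragg-peak positions as longitudinal
#' (beam-axis) coordinates; the Bragg position is capped at the phantom exit
#' if the beam punches through.
#'
#' @param beam a [beam()].
#' @param phantom a [phantom()].
#' @return list with `z_entry`, `z_bp`, `delta_beam = z_bp - z_entry` (cm).
#' @export
beam_range_in_phantom <- function(beam, phantom) {
  segs <- ray_segments(beam$entry_point, beam$direction, phantom)
  if (nrow(segs) == 0) {
    stop("beam axis does not intersect the phantom", call. = FALSE)
  }
  R_w <- csda_range(beam$particle, beam$E_u, material("water"))
  t_entry <- segs$t0[1]
  wet <- 0
  t_bp <- segs$t1[nrow(segs)]
  for (i in seq_len(nrow(segs))) {
    r <- phantom$regions[[segs$region[i]]]
    f <- region_density(r) / 1.0 * r$material$rsp_mass
    seg_wet <- (segs$t1[i] - segs$t0[i]) * f
    if (wet + seg_wet >= R_w) {
      t_bp <- segs$t0[i] + (R_w - wet) / f
      wet <- R_w
      break
    }
    wet <- wet + seg_wet
  }
  p_entry <- beam$entry_point + t_entry * beam$direction
  p_bp <- beam$entry_point + t_bp * beam$direction
  s0 <- beam_coord(beam$entry_point, beam)
  list(z_entry = s0 + t_entry, z_bp = s0 + t_bp,
       delta_beam = t_bp - t_entry,
       z_exit = s0 + segs$t1[nrow(segs)],
       entry_point = p_entry, bp_point = p_bp)
}

#' True longitudinal emission density
#'
#' The pre-absorption emission density along the beam axis: a
#' double-logistic shape whose rising edge sits at the phantom entrance and
#' whose falling edge sits at `fall_frac` of the Bragg depth beyond it (the
#' emission fall-off precedes the Bragg peak), over a flat background. The
#' density is zero beyond the Bragg depth and below the display margin.
#'
#' @param beam a [beam()].
#' @param phantom a [phantom()].
#' @param model an [emission_model()].
#' @param margin how far upstream of the entrance the (background-only)
#'   density extends, cm.
#' @return a function `z -> density` (arbitrary units, plateau = 1) with
#'   attributes `params` (a [dl_params()]), `z_entry`, `z_bp`, `support`
#'   (the in-phantom interval used for track sampling, entrance to phantom
#'   exit: the signal component dies out at the Bragg depth, while the flat
#'   background - ambient and tail tracks - persists through the phantom).
#' @export
emission_density <- function(beam, phantom, model = emission_model(),
                             margin = 2) {
  br <- beam_range_in_phantom(beam, phantom)
  p <- dl_params(p0 = 1,
                 p1 = br$z_entry + model$fall_frac * br$delta_beam,
                 p2 = model$fall_width,
                 p3 = br$z_entry,
                 p4 = model$rise_width,
                 p5 = max(model$background_frac, 1e-12))
  lo <- br$z_entry - margin
  hi <- br$z_exit
  f <- function(z) {
    out <- eval_double_logistic(z, p)
    out[z < lo | z > hi] <- 0
    out
  }
  attr(f, "params") <- p
  attr(f, "z_entry") <- br$z_entry
  attr(f, "z_bp") <- br$z_bp
  attr(f, "support") <- c(lo, hi)
  attr(f, "in_phantom") <- c(br$z_entry, br$z_exit)
  f
}

#' Sample fragment tracks
#'
#' Draws emission vertices from the longitudinal density (signal vertices
#' inside the phantom, flat background across the full window), scatters them transversely with the beam-spot sigma,
#' aims directions into a cone around the requested detection angle (uniform
#' in solid angle - importance sampling toward the detector, so desk-scale
#' runs need 1e4-1e5 tracks rather than 1e8 primaries), and draws emission
#' energies from the model spectrum. Deterministic under a fixed seed.
#'
#' @param beam a [beam()].
#' @param phantom a [phantom()].
#' @param model an [emission_model()].
#' @param n_tracks number of tracks to generate.
#' @param theta_aim detection angle to aim at, degrees from the beam axis
#'   (the cone axis lies in the x-z plane).
#' @param seed integer seed.
#' @return tibble of class `fragment_tracks` with columns `species`, `x_cm`,
#'   `y_cm`, `z_cm`, `dx`, `dy`, `dz`, `E_MeV`, `weight`; attribute
#'   `cone_solid_angle_sr`.
#' @export
sample_tracks <- function(beam, phantom, model = emission_model(),
                          n_tracks, theta_aim = 90, seed = 1) {
  stopifnot(n_tracks >= 1)
  dens <- emission_density(beam, phantom, model)
  sup <- attr(dens, "support")
  if (!(sup[2] > sup[1])) stop("empty emission support", call. = FALSE)
  with_seed(seed, {
    # longitudinal: inverse-CDF on a fine grid
    zg <- seq(sup[1] + 1e-6, sup[2] - 1e-6, length.out = 2000)
    cdf <- cumsum(dens(zg)); cdf <- cdf / cdf[length(cdf)]
    keep <- !duplicated(cdf)
    z <- approx(cdf[keep], zg[keep], runif(n_tracks), rule = 2)$y

    # transverse: Gaussian spot around the beam axis; in-phantom (signal)
    # vertices that would land outside the phantom are redrawn, then zeroed
    # as a last resort - the sliver at the curved entrance is tiny
    basis <- perp_basis(beam$direction)
    u <- rnorm(n_tracks, 0, beam$sigma_beam)
    v <- rnorm(n_tracks, 0, beam$sigma_beam)
    s0 <- beam_coord(beam$entry_point, beam)
    pos <- function(z, u, v) {
      t(vapply(seq_along(z), function(i) {
        beam$entry_point + (z[i] - s0) * beam$direction +
          u[i] * basis$e1 + v[i] * basis$e2
      }, numeric(3)))
    }
    P <- pos(z, u, v)
    inph <- attr(dens, "in_phantom")
    sig <- z > inph[1] & z < inph[2]
    if (beam$sigma_beam > 0) {
      for (it in 1:20) {
        bad <- which(sig & !vapply(seq_len(n_tracks),
                                   function(i) point_in_phantom(phantom,
                                                                P[i, ]),
                                   logical(1)))
        if (length(bad) == 0) break
        u[bad] <- rnorm(length(bad), 0, beam$sigma_beam)
        v[bad] <- rnorm(length(bad), 0, beam$sigma_beam)
        P[bad, ] <- pos(z[bad], u[bad], v[bad])
      }
      bad <- which(sig & !vapply(seq_len(n_tracks),
                                 function(i) point_in_phantom(phantom,
                                                              P[i, ]),
                                 logical(1)))
      if (length(bad) > 0) {
        u[bad] <- 0; v[bad] <- 0
        P[bad, ] <- pos(z[bad], u[bad], v[bad])
      }
    }

    # directions: uniform in solid angle within a cone about the aim axis
    th <- theta_aim * pi / 180
    axis <- c(sin(th), 0, cos(th))
    alpha <- model$cone_half_angle_deg * pi / 180
    cosw <- runif(n_tracks, cos(alpha), 1)
    phi <- runif(n_tracks, 0, 2 * pi)
    sinw <- sqrt(pmax(1 - cosw^2, 0))
    ab <- perp_basis(axis)
    dirs <- t(vapply(seq_len(n_tracks), function(i) {
      cosw[i] * axis + sinw[i] * (cos(phi[i]) * ab$e1 + sin(phi[i]) * ab$e2)
    }, numeric(3)))

    # emission energies: truncated shifted exponential
    s <- model$E_mean - model$E_min
    umax <- 1 - exp(-(model$E_max - model$E_min) / s)
    E <- model$E_min - s * log(1 - runif(n_tracks) * umax)

    out <- tibble::tibble(species = "proton",
                          x_cm = P[, 1], y_cm = P[, 2], z_cm = P[, 3],
                          dx = dirs[, 1], dy = dirs[, 2], dz = dirs[, 3],
                          E_MeV = E, weight = 1)
    attr(out, "cone_solid_angle_sr") <- 2 * pi * (1 - cos(alpha))
    class(out) <- c("fragment_tracks", class(out))
    out
  })
}

# E_min(x): minimum proton energy to traverse x cm of water, as a fast
# interpolator built from the CSDA range table.
min_escape_energy <- function(species = particle("proton")) {
  itp <- range_interpolators(species, material("water"))
  function(x) {
    E_u <- itp$energy(pmin(pmax(x, 0), itp$R_max * 0.999))
    E_u[x <= itp$range(.E_CUTOFF)] <- .E_CUTOFF
    out <- E_u * species$A
    out[x >= itp$R_max * 0.999] <- Inf
    out
  }
}

#' Exit-path survival probability
#'
#' Probability that a fragment escapes the phantom: a hard range cut (the
#' emission energy must exceed the minimum energy needed to traverse the
#' exit water-equivalent thickness) times exponential nuclear attenuation
#' `exp(-x / lambda_nuc)`. Non-increasing in the exit thickness at fixed
#' emission energy.
#'
#' @param tracks a `fragment_tracks` tibble (or any tibble with `x_cm`,
#'   `y_cm`, `z_cm`, `dx`, `dy`, `dz`, `E_MeV`).
#' @param phantom a [phantom()].
#' @param model an [emission_model()].
#' @param x_exit optional precomputed exit thicknesses, cm WET (skips ray
#'   tracing).
#' @return tibble with columns `x_exit_cm` and `p_survive`.
#' @export
survival_probability <- function(tracks, phantom, model = emission_model(),
                                 x_exit = NULL) {
  n <- nrow(tracks)
  if (is.null(x_exit)) {
    # background vertices upstream of the entrance lie outside the phantom
    # and cross whatever material the ray still meets (usually none)
    x_exit <- vapply(seq_len(n), function(i) {
      water_equivalent_thickness(
        c(tracks$x_cm[i], tracks$y_cm[i], tracks$z_cm[i]),
        c(tracks$dx[i], tracks$dy[i], tracks$dz[i]), phantom)
    }, numeric(1))
  }
  emin <- min_escape_energy()(x_exit)
  p <- as.numeric(tracks$E_MeV >= emin) * exp(-x_exit / model$lambda_nuc)
  tibble::tibble(x_exit_cm = x_exit, p_survive = p)
}

#' Multiple-scattering smearing of exit directions
#'
#' Gaussian angular smearing with the Highland width
#' `theta0 = 13.6 MeV / (beta c p) * sqrt(t) * (1 + 0.038 ln t)`, where `t`
#' is the exit path in radiation lengths (water-equivalent thickness over
#' the water radiation length) and `beta c p` is evaluated at the mean of
#' the emission and exit energies. Tracks with zero exit thickness pass
#' through unchanged.
#'
#' @inheritParams survival_probability
#' @param seed integer seed.
#' @return matrix `n x 3` of smeared unit directions, with attribute
#'   `theta0_rad`.
#' @export
scatter_direction <- function(tracks, phantom, seed = 1, x_exit = NULL) {
  n <- nrow(tracks)
  if (is.null(x_exit)) {
    x_exit <- survival_probability(tracks, phantom, x_exit = NULL)$x_exit_cm
  }
  th0 <- highland_theta0(tracks$E_MeV, x_exit)
  dirs <- cbind(tracks$dx, tracks$dy, tracks$dz)
  out <- with_seed(seed, smear_directions(dirs, th0))
  attr(out, "theta0_rad") <- th0
  out
}

# Highland angular width for protons crossing x cm WET.
highland_theta0 <- function(E_MeV, x_wet) {
  p <- particle("proton")
  itp <- range_interpolators(p, material("water"))
  E_exit <- pmax(itp$energy(pmax(itp$range(pmin(E_MeV, itp$E_max)) - x_wet,
                                 1e-9)), .E_CUTOFF)
  E_exit[x_wet <= 0] <- E_MeV[x_wet <= 0]
  Em <- (E_MeV + E_exit) / 2
  gamma <- 1 + Em / p$m_u
  beta <- sqrt(1 - 1 / gamma^2)
  pc <- sqrt(Em^2 + 2 * p$m_u * Em)
  t <- x_wet / .const$X0_water  # water: 36.08 g/cm2 at unit density
  th0 <- 13.6 / (beta * pc) * sqrt(pmax(t, 0)) *
    pmax(1 + 0.038 * log(pmax(t, 1e-12)), 0.25)
  th0[x_wet <= 0] <- 0
  th0
}

#' Expected detected-track count and required primaries
#'
#' Rate arithmetic from the measured angular yield table:
#' `count = n_primaries * yield(theta) * solid_angle`. Supply either
#' `n_primaries` (forward query) or `n_detected` (inverse query: the number
#' of primaries needed for that many detected tracks).
#'
#' @param model an [emission_model()] carrying the yield table.
#' @param theta_deg detection angle, degrees; linear interpolation between
#'   tabulated angles, no extrapolation.
#' @param solid_angle_sr detector solid angle, sr.
#' @param n_primaries number of primary ions (forward query).
#' @param n_detected target detected-track count (inverse query).
#' @return expected count, or required primaries for the inverse query.
#' @examples
#' m <- emission_model()
#' expected_detected(m, 90, 1.8e-3, n_detected = 1000)
#' @export
expected_detected <- function(model, theta_deg, solid_angle_sr,
                              n_primaries = NULL, n_detected = NULL) {
  stopifnot(solid_angle_sr > 0, xor(is.null(n_primaries),
                                    is.null(n_detected)))
  yt <- model$yields[order(model$yields$theta_deg), ]
  if (theta_deg < min(yt$theta_deg) || theta_deg > max(yt$theta_deg)) {
    stop("theta = ", theta_deg,
         " degrees is outside the yield table support [",
         min(yt$theta_deg), ", ", max(yt$theta_deg), "]", call. = FALSE)
  }
  y <- approx(yt$theta_deg, yt$yield_sr, theta_deg)$y
  if (!is.null(n_primaries)) {
    n_primaries * y * solid_angle_sr
  } else {
    n_detected / (y * solid_angle_sr)
  }
}
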