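# Detector acceptance, measurement smearing, POCA vertexing and ToF
# kinematics.

#' Tracking-detector description
#'
#' A planar rectangular tracker at angle `theta` from the beam axis (in the
#' x-z plane), at a given distance from the phantom centre, facing the
#' phantom. Direction and crossing-point resolutions are Gaussian sigmas
#' applied per transverse axis.
#'
#' @param theta_deg detector angle from the beam (+z) axis, degrees,
#'   in (0, 180).
#' @param distance_cm phantom centre to detector centre, cm.
#' @param width_cm,height_cm active area, cm.
#' @param sigma_dir_rad direction resolution (angular sigma), rad.
#' @param sigma_point_cm transverse crossing-point resolution, cm.
#' @param efficiency detection efficiency in [0, 1].
#' @param sigma_tof_ns time-of-flight resolution, ns.
#' @return an object of class `tracker_spec`.
#' @examples
#' tracker(60, 40, 20, 20)                    # large-area tracker
#' tracker(90, 70, 3, 3, efficiency = 1)      # four-crystal-scale aperture
#' @export
tracker <- function(theta_deg, distance_cm, width_cm, height_cm,
                    sigma_dir_rad = 0, sigma_point_cm = 0, efficiency = 1,
                    sigma_tof_ns = 0) {
  stopifnot(theta_deg > 0, theta_deg < 180, distance_cm > 0,
            width_cm > 0, height_cm > 0,
            efficiency >= 0, efficiency <= 1)
  th <- theta_deg * pi / 180
  normal <- -c(sin(th), 0, cos(th))          # toward the phantom
  center <- distance_cm * c(sin(th), 0, cos(th))
  e_a <- c(cos(th), 0, -sin(th))             # width axis, in the x-z plane
  e_b <- c(0, 1, 0)                          # height axis
  structure(list(theta_deg = theta_deg, distance_cm = distance_cm,
                 width_cm = width_cm, height_cm = height_cm,
                 sigma_dir_rad = sigma_dir_rad,
                 sigma_point_cm = sigma_point_cm,
                 efficiency = efficiency, sigma_tof_ns = sigma_tof_ns,
                 center = center, normal = normal, e_a = e_a, e_b = e_b),
            class = "tracker_spec")
}

#' @export
print.tracker_spec <- function(x, ...) {
  cat(sprintf(
    "<tracker> %g x %g cm at %g cm, theta = %g deg, eff = %g\n",
    x$width_cm, x$height_cm, x$distance_cm, x$theta_deg, x$efficiency))
  invisible(x)
}

#' Solid angle of a rectangular aperture
#'
#' Exact solid angle of the tracker's rectangle seen from the phantom
#' reference point on its axis (the pyramid formula
#' `Omega = 4 atan(ab / (2d sqrt(4d^2 + a^2 + b^2)))`), not the flat-area
#' `a b / d^2` approximation, which overestimates by several percent at
#' monitoring distances.
#'
#' @param tracker a [tracker()].
#' @return solid angle, sr.
#' @examples
#' solid_angle(tracker(60, 40, 20, 20))  # 0.2354 sr
#' @export
solid_angle <- function(tracker) {
  if (tracker$distance_cm <= 0) stop("distance must be > 0", call. = FALSE)
  a <- tracker$width_cm; b <- tracker$height_cm; d <- tracker$distance_cm
  4 * atan(a * b / (2 * d * sqrt(4 * d^2 + a^2 + b^2)))
}

#' Propagate tracks to the detector and apply measurement effects
#'
#' Keeps tracks whose straight line crosses the active area, thins by the
#' detection efficiency, and smears the measured direction and crossing
#' point by the tracker resolutions. The time of flight is the true flight
#' time of the fragment at its post-phantom energy plus Gaussian noise.
#' Deterministic under a fixed seed.
#'
#' @param tracks a `fragment_tracks` tibble; if it carries an `x_exit_cm`
#'   column the ToF and measured energy account for the energy lost in the
#'   phantom, otherwise the emission energy is used.
#' @param tracker a [tracker()].
#' @param seed integer seed.
#' @return tibble of class `detected_tracks` with columns `hit_x/y/z` (cm),
#'   `dx/dy/dz` (measured direction), `tof_ns`, `E_meas_MeV`, `weight`, and
#'   the true vertex columns `true_x/y/z` for diagnostics.
#' @export
detect <- function(tracks, tracker, seed = 1) {
  n <- nrow(tracks)
  if (n == 0) return(empty_detected())
  P <- cbind(tracks$x_cm, tracks$y_cm, tracks$z_cm)
  D <- cbind(tracks$dx, tracks$dy, tracks$dz)
  # plane crossing
  denom <- D %*% tracker$normal
  tpar <- as.numeric(((matrix(tracker$center, n, 3, byrow = TRUE) - P) %*%
                        tracker$normal) / denom)
  ok <- is.finite(tpar) & tpar > 0
  X <- P + D * tpar
  rel <- X - matrix(tracker$center, n, 3, byrow = TRUE)
  ua <- as.numeric(rel %*% tracker$e_a)
  ub <- as.numeric(rel %*% tracker$e_b)
  ok <- ok & abs(ua) <= tracker$width_cm / 2 &
    abs(ub) <= tracker$height_cm / 2
  out <- with_seed(seed, {
    keep <- ok & (runif(n) < tracker$efficiency)
    idx <- which(keep)
    m <- length(idx)
    dirs <- D[idx, , drop = FALSE]
    if (m > 0 && tracker$sigma_dir_rad > 0) {
      dirs <- smear_directions(dirs, rep(tracker$sigma_dir_rad, m))
    }
    hua <- ua[idx]; hub <- ub[idx]
    if (m > 0 && tracker$sigma_point_cm > 0) {
      hua <- hua + rnorm(m, 0, tracker$sigma_point_cm)
      hub <- hub + rnorm(m, 0, tracker$sigma_point_cm)
    }
    hits <- matrix(tracker$center, max(m, 1), 3,
                   byrow = TRUE)[seq_len(m), , drop = FALSE] +
      outer(hua, tracker$e_a) + outer(hub, tracker$e_b)
    # kinematic quantities at the detector
    E_det <- if ("x_exit_cm" %in% names(tracks)) {
      prt <- particle("proton")
      itp <- range_interpolators(prt, material("water"))
      pmax(itp$energy(pmax(itp$range(pmin(tracks$E_MeV[idx], itp$E_max)) -
                             tracks$x_exit_cm[idx], 1e-9)), .E_CUTOFF)
    } else {
      tracks$E_MeV[idx]
    }
    gamma <- 1 + E_det / particle("proton")$m_u
    beta <- sqrt(1 - 1 / gamma^2)
    path <- sqrt(rowSums((hits - P[idx, , drop = FALSE])^2))
    tof <- path / (beta * .const$c_cm_ns)
    if (m > 0 && tracker$sigma_tof_ns > 0) {
      tof <- tof + rnorm(m, 0, tracker$sigma_tof_ns)
    }
    res <- tibble::tibble(
      hit_x = hits[, 1], hit_y = hits[, 2], hit_z = hits[, 3],
      dx = dirs[, 1], dy = dirs[, 2], dz = dirs[, 3],
      tof_ns = tof, E_meas_MeV = E_det,
      weight = tracks$weight[idx],
      true_x = P[idx, 1], true_y = P[idx, 2], true_z = P[idx, 3])
    if ("x_exit_cm" %in% names(tracks)) res$x_exit_cm <- tracks$x_exit_cm[idx]
    res
  })
  class(out) <- c("detected_tracks", class(out))
  out
}

empty_detected <- function() {
  out <- tibble::tibble(hit_x = numeric(), hit_y = numeric(),
                        hit_z = numeric(), dx = numeric(), dy = numeric(),
                        dz = numeric(), tof_ns = numeric(),
                        E_meas_MeV = numeric(), weight = numeric(),
                        true_x = numeric(), true_y = numeric(),
                        true_z = numeric())
  class(out) <- c("detected_tracks", class(out))
  out
}

#' Point of closest approach to the beam line
#'
#' Emission-point estimate for a measured track: the point on the known
#' beam line closest to the track line, plus the line-line distance as a
#' quality metric. The beam transverse position is known from the delivery
#' system, so the estimate sits on the beam axis rather than at the segment
#' midpoint.
#'
#' @param track_point,track_dir a point on the measured track line and its
#'   unit direction.
#' @param beam_point,beam_dir a point on the beam line and its unit
#'   direction.
#' @return list with `point` (3-vector on the beam line, cm) and `doca_cm`
#'   (distance of closest approach).
#' @examples
#' poca_vertex(c(50, 1, 5), c(1, 0, 0), c(0, 0, 0), c(0, 0, 1))
#' @export
poca_vertex <- function(track_point, track_dir, beam_point = c(0, 0, 0),
                        beam_dir = c(0, 0, 1)) {
  u <- check_unit(as.numeric(beam_dir), "beam direction")
  v <- check_unit(as.numeric(track_dir), "track direction")
  d <- sum(u * v)
  if (1 - d^2 < 1e-18) {
    stop("degenerate geometry: track is parallel to the beam line",
         call. = FALSE)
  }
  w0 <- as.numeric(beam_point) - as.numeric(track_point)
  s <- (d * sum(w0 * v) - sum(w0 * u)) / (1 - d^2)
  t <- (sum(w0 * v) - d * sum(w0 * u)) / (1 - d^2)
  pb <- as.numeric(beam_point) + s * u
  pt <- as.numeric(track_point) + t * v
  list(point = pb, doca_cm = sqrt(sum((pb - pt)^2)))
}

#' Reconstruct emission points for a set of detected tracks
#'
#' Vectorised [poca_vertex()] against a common beam line; adds the POCA
#' coordinates, the distance of closest approach and the longitudinal
#' coordinate `z_reco` (projection of the POCA on the beam axis).
#'
#' @param detected a `detected_tracks` tibble.
#' @param beam a [beam()] (the known beam line).
#' @return the input with columns `poca_x/y/z`, `doca_cm`, `z_reco` added.
#' @export
reconstruct_vertices <- function(detected, beam) {
  n <- nrow(detected)
  res <- lapply(seq_len(n), function(i) {
    poca_vertex(c(detected$hit_x[i], detected$hit_y[i], detected$hit_z[i]),
                c(detected$dx[i], detected$dy[i], detected$dz[i]),
                beam$entry_point, beam$direction)
  })
  pts <- t(vapply(res, `[[`, numeric(3), "point"))
  detected$poca_x <- pts[, 1]
  detected$poca_y <- pts[, 2]
  detected$poca_z <- pts[, 3]
  detected$doca_cm <- vapply(res, `[[`, numeric(1), "doca_cm")
  detected$z_reco <- beam_coord(pts, beam)
  detected
}

#' Time-of-flight kinematics
#'
#' Velocity ratio and kinetic energy from a time of flight and flight path:
#' `beta = path / (c tof)` with `c = 29.9792 cm/ns`, then
#' `E_kin = m (gamma - 1)`.
#'
#' @param tof_ns time of flight, ns (> 0).
#' @param flight_path_cm flight path, cm (> 0).
#' @param rest_mass_MeV particle rest mass, MeV.
#' @return list with `beta` and `E_kin_MeV`.
#' @examples
#' kinematics(70 / (0.5 * 29.9792458), 70, 938.272)  # beta = 0.5
#' @export
kinematics <- function(tof_ns, flight_path_cm, rest_mass_MeV) {
  stopifnot(tof_ns > 0, flight_path_cm > 0, rest_mass_MeV > 0)
  beta <- flight_path_cm / (.const$c_cm_ns * tof_ns)
  if (any(beta >= 1)) {
    stop("unphysical velocity: beta >= 1 (check the flight path and ToF)",
         call. = FALSE)
  }
  gamma <- 1 / sqrt(1 - beta^2)
  list(beta = beta, E_kin_MeV = rest_mass_MeV * (gamma - 1))
}
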