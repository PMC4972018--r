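# Absorption unfolding: look-up tables of profile parameters versus crossed
# thickness, the generalized two-variable emission function f(z, x), per-track
# weights w(z, x) = f(z, x0) / f(z, x), and profile recovery.

#' Build an absorption look-up table
#'
#' For each thickness on the grid, simulates fragment emission, applies the
#' survival model for a constant exit thickness (a uniform slab between the
#' emission region and the detector), histograms the surviving vertices,
#' fits the double-logistic model, and finally models each fitted parameter
#' as a low-order polynomial in the water-equivalent thickness `x`. The
#' thickness axis is WET so that one table serves mixed-density geometries
#' through [exit_path_thickness()]. Amplitude-like parameters are stored per
#' generated track (per-primary normalisation).
#'
#' @param beam a [beam()].
#' @param phantom a [phantom()] fixing the emission region (entrance and
#'   Bragg depth).
#' @param model an [emission_model()].
#' @param thicknesses strictly increasing WET grid, cm; at least 4 points
#'   (default 2.5 to 10 cm in 1.5 cm steps).
#' @param edges histogram bin edges, cm; default 0.2 cm bins over the
#'   emission support.
#' @param n_tracks generated tracks per thickness node.
#' @param degree polynomial degree for the parameter trends (1-3).
#' @param x0 reference thickness, cm (default: the grid minimum).
#' @param theta_aim aim angle for track generation, degrees.
#' @param seed integer seed.
#' @return an object of class `absorption_lut`: `grid`, `nodes` (per-node
#'   fitted parameters and uncertainties), `poly` (per-parameter
#'   coefficients), `degree`, `x0`, `seed`.
#' @export
build_lut <- function(beam, phantom, model = emission_model(),
                      thicknesses = seq(2.5, 10, by = 1.5), edges = NULL,
                      n_tracks = 20000, degree = 2, x0 = NULL,
                      theta_aim = 90, seed = 1) {
  stopifnot(length(thicknesses) >= 4, !is.unsorted(thicknesses,
                                                   strictly = TRUE),
            degree >= 1, degree <= 3)
  x0 <- x0 %||% min(thicknesses)
  dens <- emission_density(beam, phantom, model)
  sup <- attr(dens, "support")
  # bins cover exactly the sampling support: bins outside it would be
  # structurally empty and bias the background estimate
  edges <- edges %||% seq(sup[1], sup[2], by = 0.2)
  emin_fun <- min_escape_energy()
  nodes <- lapply(seq_along(thicknesses), function(j) {
    xj <- thicknesses[j]
    trk <- sample_tracks(beam, phantom, model, n_tracks,
                         theta_aim = theta_aim,
                         seed = derive_seed(seed, "lut") + j)
    p_surv <- as.numeric(trk$E_MeV >= emin_fun(xj)) *
      exp(-xj / model$lambda_nuc)
    kept <- with_seed(derive_seed(seed, "survival") + j,
                      runif(nrow(trk)) < p_surv)
    prof <- longitudinal_profile(trk[kept, ], edges)
    ft <- tryCatch(fit_profile(prof), error = function(e) {
      stop("profile fit failed at thickness ", xj, " cm: ",
           conditionMessage(e), call. = FALSE)
    })
    se <- sqrt(pmax(diag(ft$cov), 0))
    tibble::tibble(
      x = xj,
      p0 = ft$params[["p0"]] / n_tracks, p1 = ft$params[["p1"]],
      p2 = ft$params[["p2"]], p3 = ft$params[["p3"]],
      p4 = ft$params[["p4"]], p5 = ft$params[["p5"]] / n_tracks,
      se_p0 = se[1] / n_tracks, se_p1 = se[2], se_p2 = se[3],
      se_p3 = se[4], se_p4 = se[5], se_p5 = se[6] / n_tracks,
      chisq = ft$chisq, ndf = ft$ndf, n_kept = sum(kept))
  })
  nodes <- dplyr::bind_rows(nodes)
  poly_fits <- lapply(c("p0", "p1", "p2", "p3", "p4", "p5"), function(pn) {
    fit <- lm(nodes[[pn]] ~ poly(nodes$x, degree, raw = TRUE))
    unname(coef(fit))
  })
  names(poly_fits) <- c("p0", "p1", "p2", "p3", "p4", "p5")
  structure(list(grid = thicknesses, nodes = nodes, poly = poly_fits,
                 degree = degree, x0 = x0, edges = edges, seed = seed,
                 n_tracks = n_tracks),
            class = "absorption_lut")
}

#' @export
print.absorption_lut <- function(x, ...) {
  cat(sprintf(
    "<absorption LUT> %d nodes on [%.1f, %.1f] cm WET, degree-%d polynomials, x0 = %.1f cm\n",
    length(x$grid), min(x$grid), max(x$grid), x$degree, x$x0))
  print(x$nodes[, 1:7])
  invisible(x)
}

eval_poly <- function(coefs, x) {
  out <- 0
  for (k in seq_along(coefs)) out <- out + coefs[k] * x^(k - 1)
  out
}

#' Profile parameters at an arbitrary thickness
#'
#' Evaluates the per-parameter polynomials of an [build_lut()] table at a
#' thickness `x`. Extrapolation outside the grid span is refused unless
#' explicitly allowed (`extrapolate = TRUE` evaluates the polynomials as-is;
#' `clamp = TRUE` clamps `x` into the span first, the safer choice for the
#' thin slivers of geometry that fall just outside it).
#'
#' @param lut an `absorption_lut`.
#' @param x thickness, cm WET.
#' @param extrapolate,clamp out-of-span behaviour (see above).
#' @return a [dl_params()] object.
#' @export
params_at <- function(lut, x, extrapolate = FALSE, clamp = FALSE) {
  if (x < min(lut$grid) || x > max(lut$grid)) {
    if (clamp) {
      x <- min(max(x, min(lut$grid)), max(lut$grid))
    } else if (!extrapolate) {
      stop("thickness ", x, " cm is outside the LUT span [",
           min(lut$grid), ", ", max(lut$grid),
           "] cm; pass extrapolate = TRUE or clamp = TRUE to override",
           call. = FALSE)
    }
  }
  v <- vapply(lut$poly, eval_poly, numeric(1), x = x)
  dl_params(max(v[["p0"]], 1e-12), v[["p1"]], max(v[["p2"]], 1e-12),
            v[["p3"]], max(v[["p4"]], 1e-12), max(v[["p5"]], 0))
}

#' Generalised emission function f(z, x)
#'
#' The double-logistic emission model as a function of both the emission
#' point `z` and the crossed thickness `x`, through the LUT's parameter
#' polynomials.
#'
#' @param z longitudinal coordinate, cm (vectorised).
#' @param x thickness, cm WET (scalar).
#' @param lut an `absorption_lut`.
#' @inheritParams params_at
#' @return model values.
#' @export
f_zx <- function(z, x, lut, extrapolate = FALSE, clamp = FALSE) {
  eval_double_logistic(z, params_at(lut, x, extrapolate, clamp))
}

#' Per-track absorption weight w(z, x)
#'
#' The multiplicative correction restoring counts attenuated along a
#' thickness-`x` exit path: `w(z, x) = f(z, x0) / f(z, x)`, equal to 1 at
#' the reference thickness. The denominator is floored (default at 1e-3 of
#' the reference peak) and the weight capped (default 20): in the far tails
#' the ratio is ill-conditioned, and a capped weight with a warning is
#' preferred to a silent near-infinity.
#'
#' @param z emission coordinate(s), cm.
#' @param x crossed thickness(es), cm WET (recycled against `z`).
#' @param lut an `absorption_lut`.
#' @param w_max weight cap.
#' @param floor_frac denominator floor as a fraction of the reference-curve
#'   maximum.
#' @param clamp clamp out-of-span thicknesses into the LUT span.
#' @return numeric weights with attribute `n_capped`.
#' @export
track_weight <- function(z, x, lut, w_max = 20, floor_frac = 1e-3,
                         clamp = FALSE) {
  n <- max(length(z), length(x))
  z <- rep_len(z, n); x <- rep_len(x, n)
  p_ref <- params_at(lut, lut$x0)
  zg <- seq(p_ref[["p3"]] - 5 * p_ref[["p4"]],
            p_ref[["p1"]] + 5 * p_ref[["p2"]], length.out = 200)
  floor_val <- floor_frac * max(eval_double_logistic(zg, p_ref))
  num <- eval_double_logistic(z, p_ref)
  den <- vapply(seq_len(n), function(i) {
    f_zx(z[i], x[i], lut, clamp = clamp)
  }, numeric(1))
  low <- den < floor_val
  den[low] <- floor_val
  w <- num / den
  capped <- w > w_max | low
  w[w > w_max] <- w_max
  if (any(capped)) {
    warning(sum(capped), " of ", n,
            " absorption weights hit the cap or the denominator floor",
            call. = FALSE)
  }
  attr(w, "n_capped") <- sum(capped)
  w
}

#' Recover the true emission profile from absorption-distorted tracks
#'
#' Histograms reconstructed emission points twice: once as measured
#' (uncorrected) and once with each track multiplied by its absorption
#' weight `w(z_reco, x_exit)`, which restores the counts removed by
#' thickness-dependent absorption. Tracks missing an exit thickness are
#' skipped and counted.
#'
#' @param tracks data frame with `z_reco` (or `z_cm`) and `x_exit_cm`
#'   columns; an existing `weight` column multiplies the correction.
#' @param lut an `absorption_lut`.
#' @param edges histogram bin edges, cm (default: the LUT's).
#' @param w_max,floor_frac see [track_weight()].
#' @param clamp clamp out-of-span thicknesses (default TRUE: geometry edges
#'   routinely graze the span).
#' @return an object of class `unfold_result`: `$corrected` and
#'   `$uncorrected` profiles, `$n_skipped`, `$capped_fraction`.
#' @export
unfold_profile <- function(tracks, lut, edges = NULL, w_max = 20,
                           floor_frac = 1e-3, clamp = TRUE) {
  edges <- edges %||% lut$edges
  coord <- if ("z_reco" %in% names(tracks)) "z_reco" else "z_cm"
  if (!"x_exit_cm" %in% names(tracks)) {
    stop("tracks need an x_exit_cm column (see exit_path_thickness)",
         call. = FALSE)
  }
  ok <- is.finite(tracks$x_exit_cm)
  n_skipped <- sum(!ok)
  trk <- tracks[ok, ]
  base_w <- trk[["weight"]] %||% rep(1, nrow(trk))
  w <- track_weight(trk[[coord]], trk$x_exit_cm, lut, w_max = w_max,
                    floor_frac = floor_frac, clamp = clamp)
  uncorr <- longitudinal_profile(
    tibble::tibble(z = trk[[coord]], weight = base_w), edges, coord = "z")
  corr <- longitudinal_profile(
    tibble::tibble(z = trk[[coord]], weight = base_w * w), edges,
    coord = "z")
  structure(list(corrected = corr, uncorrected = uncorr,
                 n_skipped = n_skipped,
                 capped_fraction = attr(w, "n_capped") / max(length(w), 1)),
            class = "unfold_result")
}

#' @export
print.unfold_result <- function(x, ...) {
  cat(sprintf(
    "<unfolding> corrected total %.1f vs uncorrected %.1f; %d tracks skipped, %.2f%% weights capped\n",
    sum(x$corrected$count), sum(x$uncorrected$count), x$n_skipped,
    100 * x$capped_fraction))
  invisible(x)
}
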