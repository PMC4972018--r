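# Analytic phantoms: boxes, cylinders and spheres with exact ray tracing.
# Nested regions resolve by list order (later regions win inside earlier
# ones), which covers the sphere-in-sphere and slab geometries used for
# absorption studies without full constructive solid geometry.

.TANGENT_EPS <- 1e-12  # discriminant below this -> treated as a miss

#' Phantom solids
#'
#' Primitive solids for [phantom()] regions. All lengths in cm; the
#' coordinate frame is right-handed with the beam nominally along `+z`.
#'
#' @param center 3-vector, cm.
#' @param radius sphere/cylinder radius, cm.
#' @param half 3-vector of box half-widths, cm.
#' @param half_length cylinder half-length along its axis, cm.
#' @param axis cylinder axis unit vector.
#' @return a `solid` object.
#' @name solids
#' @examples
#' solid_sphere(c(0, 0, 0), 10)
#' solid_box(c(0, 0, 0), c(2.5, 2.5, 6.15))
NULL

#' @rdname solids
#' @export
solid_sphere <- function(center, radius) {
  stopifnot(length(center) == 3, radius > 0)
  structure(list(type = "sphere", center = as.numeric(center),
                 radius = radius), class = "solid")
}

#' @rdname solids
#' @export
solid_box <- function(center, half) {
  stopifnot(length(center) == 3, length(half) == 3, all(half > 0))
  structure(list(type = "box", center = as.numeric(center),
                 half = as.numeric(half)), class = "solid")
}

#' @rdname solids
#' @export
solid_cylinder <- function(center, radius, half_length, axis = c(0, 0, 1)) {
  stopifnot(length(center) == 3, radius > 0, half_length > 0)
  axis <- as.numeric(axis) / sqrt(sum(axis^2))
  structure(list(type = "cylinder", center = as.numeric(center),
                 radius = radius, half_length = half_length, axis = axis),
            class = "solid")
}

#' Analytic phantom
#'
#' An ordered list of regions, each a solid filled with a material (with an
#' optional density override). The outermost region comes first; later
#' regions take precedence inside earlier ones, so a low-density insert is
#' simply listed after its host.
#'
#' @param ... region lists as produced by [region()].
#' @return an object of class `phantom`.
#' @examples
#' ph <- phantom(
#'   region(solid_sphere(c(0, 0, 0), 10), material("pmma"), density = 1.2),
#'   region(solid_sphere(c(0, 0, 0), 3), material("pmma"), density = 0.6)
#' )
#' @export
phantom <- function(...) {
  regions <- list(...)
  stopifnot(length(regions) >= 1)
  for (r in regions) {
    stopifnot(inherits(r$solid, "solid"), inherits(r$material, "material"))
  }
  structure(list(regions = regions), class = "phantom")
}

#' @rdname phantom
#' @param solid a solid from [solids].
#' @param material a [material()].
#' @param density optional density override, g/cm3 (e.g. a
#'   low-density insert).
#' @export
region <- function(solid, material, density = NULL) {
  if (!is.null(density)) stopifnot(density > 0)
  list(solid = solid, material = material, density = density)
}

region_density <- function(r) r$density %||% r$material$density

#' @export
print.phantom <- function(x, ...) {
  cat("<phantom>", length(x$regions), "region(s)\n")
  for (i in seq_along(x$regions)) {
    r <- x$regions[[i]]
    cat(sprintf("  %d: %s of %s (rho=%.3f)\n", i, r$solid$type,
                r$material$name, region_density(r)))
  }
  invisible(x)
}

check_unit <- function(v, what = "direction") {
  if (abs(sqrt(sum(v^2)) - 1) > 1e-12) {
    stop(what, " must be a unit vector", call. = FALSE)
  }
  v
}

# Entry/exit parameters of a ray (origin o, unit direction d) with a solid.
# Returns c(t_in, t_out) (possibly negative) or NULL on a miss. Tangential
# grazes count as misses.
solid_interval <- function(solid, o, d) {
  switch(solid$type,
    sphere = {
      oc <- o - solid$center
      b <- sum(oc * d)
      cc <- sum(oc^2) - solid$radius^2
      disc <- b^2 - cc
      if (disc <= .TANGENT_EPS) return(NULL)
      s <- sqrt(disc)
      c(-b - s, -b + s)
    },
    box = {
      lo <- solid$center - solid$half
      hi <- solid$center + solid$half
      t1 <- -Inf; t2 <- Inf
      for (k in 1:3) {
        if (abs(d[k]) < 1e-15) {
          if (o[k] <= lo[k] || o[k] >= hi[k]) return(NULL)
        } else {
          ta <- (lo[k] - o[k]) / d[k]; tb <- (hi[k] - o[k]) / d[k]
          t1 <- max(t1, min(ta, tb)); t2 <- min(t2, max(ta, tb))
        }
      }
      if (t2 - t1 <= .TANGENT_EPS) return(NULL)
      c(t1, t2)
    },
    cylinder = {
      a <- solid$axis
      oc <- o - solid$center
      # radial part
      dperp <- d - sum(d * a) * a
      operp <- oc - sum(oc * a) * a
      A <- sum(dperp^2)
      if (A < 1e-15) {
        # ray parallel to axis
        if (sum(operp^2) >= solid$radius^2) return(NULL)
        trad <- c(-Inf, Inf)
      } else {
        B <- sum(operp * dperp)
        C <- sum(operp^2) - solid$radius^2
        disc <- B^2 - A * C
        if (disc <= .TANGENT_EPS) return(NULL)
        s <- sqrt(disc)
        trad <- c((-B - s) / A, (-B + s) / A)
      }
      # axial caps
      dax <- sum(d * a); oax <- sum(oc * a)
      if (abs(dax) < 1e-15) {
        if (abs(oax) >= solid$half_length) return(NULL)
        tax <- c(-Inf, Inf)
      } else {
        ta <- (-solid$half_length - oax) / dax
        tb <- (solid$half_length - oax) / dax
        tax <- c(min(ta, tb), max(ta, tb))
      }
      t1 <- max(trad[1], tax[1]); t2 <- min(trad[2], tax[2])
      if (t2 - t1 <= .TANGENT_EPS) return(NULL)
      c(t1, t2)
    },
    stop("unknown solid type ", solid$type)
  )
}

point_in_solid <- function(solid, p) {
  switch(solid$type,
    sphere = sum((p - solid$center)^2) < solid$radius^2,
    box = all(abs(p - solid$center) < solid$half),
    cylinder = {
      oc <- p - solid$center
      ax <- sum(oc * solid$axis)
      perp <- oc - ax * solid$axis
      abs(ax) < solid$half_length && sum(perp^2) < solid$radius^2
    }
  )
}

point_in_phantom <- function(phantom, p) {
  for (r in phantom$regions) if (point_in_solid(r$solid, p)) return(TRUE)
  FALSE
}

#' Per-region chord lengths along a ray
#'
#' Exact analytic intersection lengths of a ray with each phantom region,
#' from the ray origin (clipped at the origin when it lies inside) to the
#' phantom exit. Overlaps resolve by region precedence: the last listed
#' region containing a segment owns it.
#'
#' @param origin 3-vector, cm.
#' @param direction unit 3-vector.
#' @param phantom a [phantom()].
#' @return tibble with columns `region` (index into the phantom's region
#'   list) and `length_cm`; zero rows when the ray misses everything.
#' @examples
#' ph <- phantom(region(solid_sphere(c(0, 0, 0), 10), material("water")))
#' chord_lengths(c(0, 0, 0), c(1, 0, 0), ph)
#' @export
chord_lengths <- function(origin, direction, phantom) {
  d <- check_unit(as.numeric(direction), "ray direction")
  o <- as.numeric(origin)
  ivals <- lapply(phantom$regions, function(r) solid_interval(r$solid, o, d))
  ts <- c(0)
  for (iv in ivals) if (!is.null(iv)) ts <- c(ts, iv)
  ts <- sort(unique(pmax(ts, 0)))
  if (length(ts) < 2) return(tibble::tibble(region = integer(),
                                            length_cm = numeric()))
  lens <- numeric(length(phantom$regions))
  for (k in seq_len(length(ts) - 1)) {
    tm <- (ts[k] + ts[k + 1]) / 2
    owner <- 0L
    for (i in seq_along(ivals)) {
      iv <- ivals[[i]]
      if (!is.null(iv) && tm > iv[1] && tm < iv[2]) owner <- i
    }
    if (owner > 0L) lens[owner] <- lens[owner] + (ts[k + 1] - ts[k])
  }
  keep <- which(lens > 0)
  tibble::tibble(region = keep, length_cm = lens[keep])
}

#' Water-equivalent thickness along a ray
#'
#' Sum of per-region chords scaled by `(density / rho_water) * rsp_mass`,
#' where `rsp_mass` is the material's mass stopping power relative to water
#' (1.0 for water, about 0.975 for PMMA so that the usual 1.16
#' length-equivalence holds at bulk density).
#'
#' @inheritParams chord_lengths
#' @return water-equivalent thickness, cm.
#' @examples
#' ph <- phantom(region(solid_sphere(c(0, 0, 0), 10), material("water")))
#' water_equivalent_thickness(c(0, 0, 0), c(1, 0, 0), ph)
#' @export
water_equivalent_thickness <- function(origin, direction, phantom) {
  ch <- chord_lengths(origin, direction, phantom)
  if (nrow(ch) == 0) return(0)
  f <- vapply(ch$region, function(i) {
    r <- phantom$regions[[i]]
    region_density(r) / 1.0 * r$material$rsp_mass
  }, numeric(1))
  sum(ch$length_cm * f)
}

#' Exit-path water-equivalent thickness from an emission vertex
#'
#' The water-equivalent thickness a fragment emitted at `vertex` crosses
#' before escaping the phantom along `direction` - the `x` that enters the
#' absorption weighting `w(z, x)`.
#'
#' @param vertex 3-vector inside the phantom, cm.
#' @param direction unit 3-vector.
#' @param phantom a [phantom()].
#' @return water-equivalent thickness, cm.
#' @export
exit_path_thickness <- function(vertex, direction, phantom) {
  if (!point_in_phantom(phantom, as.numeric(vertex))) {
    stop("vertex lies outside the phantom", call. = FALSE)
  }
  water_equivalent_thickness(vertex, direction, phantom)
}
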