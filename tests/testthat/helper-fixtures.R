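# Shared fixtures: materials, beams and phantoms used across the suite.

water <- material("water")
pmma <- material("pmma")
proton <- particle("proton")
carbon <- particle("c12")

# PMMA block with its entrance face at z = -6.15 cm (centre at the origin)
pmma_block <- phantom(region(solid_box(c(0, 0, 0), c(2.5, 2.5, 6.15)), pmma))

gsi_beam <- function(sigma_beam = 0.4) {
  beam(carbon, 220, entry_point = c(0, 0, -7.15), direction = c(0, 0, 1),
       sigma_beam = sigma_beam)
}

# Nested-sphere system: 10 cm PMMA sphere (rho = 1.2) with a 3 cm
# low-density (rho = 0.6) concentric insert
nested_spheres <- phantom(
  region(solid_sphere(c(0, 0, 0), 10), pmma, density = 1.2),
  region(solid_sphere(c(0, 0, 0), 3), pmma, density = 0.6)
)

sphere_beam <- function(sigma_beam = 0.4) {
  beam(carbon, 220, entry_point = c(0, 0, -11), direction = c(0, 0, 1),
       sigma_beam = sigma_beam)
}

# Brute-force ray marcher: per-region path lengths by sampling points along
# the ray at a fixed step; independent oracle for the analytic tracer.
march_chords <- function(origin, direction, phantom, step = 1e-4,
                         t_max = 60) {
  ts <- seq(step / 2, t_max, by = step)
  lens <- numeric(length(phantom$regions))
  for (t in ts) {
    p <- origin + t * direction
    owner <- 0L
    for (i in seq_along(phantom$regions)) {
      if (fragmon:::point_in_solid(phantom$regions[[i]]$solid, p)) owner <- i
    }
    if (owner > 0L) lens[owner] <- lens[owner] + step
  }
  lens
}

random_unit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}
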