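#' Projectile and fragment species
#'
#' Builds the particle description used by the transport and emission code:
#' charge number `Z`, mass number `A` and rest mass per nucleon `m_u` (MeV).
#' The built-in table covers the species relevant for carbon-ion therapy
#' monitoring: the beam ions and the light charged fragments they produce.
#'
#' @param name one of `"proton"`, `"deuteron"`, `"triton"`, `"he4"`, `"c12"`,
#'   `"o16"`, or any label when `Z`, `A`, `m_u` are supplied explicitly.
#' @param Z,A,m_u override the built-in charge number, mass number and rest
#'   mass per nucleon (MeV).
#' @return an object of class `particle_spec`.
#' @examples
#' particle("c12")
#' particle("proton")
#' @export
particle <- function(name, Z = NULL, A = NULL, m_u = NULL) {
  builtin <- list(
    proton   = list(Z = 1, A = 1, m_u = 938.272),
    deuteron = list(Z = 1, A = 2, m_u = 937.810),
    triton   = list(Z = 1, A = 3, m_u = 936.280),
    he4      = list(Z = 2, A = 4, m_u = 931.494),
    c12      = list(Z = 6, A = 12, m_u = 931.494),
    o16      = list(Z = 8, A = 16, m_u = 931.494)
  )
  if (is.null(Z) || is.null(A) || is.null(m_u)) {
    if (!name %in% names(builtin)) {
      stop("unknown particle '", name, "'; supply Z, A and m_u explicitly",
           call. = FALSE)
    }
    b <- builtin[[name]]
    Z <- Z %||% b$Z; A <- A %||% b$A; m_u <- m_u %||% b$m_u
  }
  stopifnot(Z >= 1, A >= Z)
  ref <- if (A == 1 && Z == 1) 938.3 else 931.5
  if (abs(m_u - ref) / ref > 0.01) {
    stop("rest mass per nucleon ", m_u, " MeV is more than 1% from ", ref,
         " MeV", call. = FALSE)
  }
  structure(list(name = name, Z = Z, A = A, m_u = m_u),
            class = "particle_spec")
}

#' Target and phantom materials
#'
#' A material carries everything the stopping-power and path-length code
#' needs: bulk density, mean excitation energy `I`, elemental composition by
#' mass fraction, radiation length, and the relative mass stopping power used
#' to convert geometric path to water-equivalent thickness.
#'
#' Built-ins: `material("water")` and `material("pmma")` (C5H8O2,
#' rho = 1.19 g/cm3, I = 74 eV). The PMMA `rsp_mass` is set so that
#' `density * rsp_mass = 1.16`, the usual length-equivalence factor of PMMA
#' relative to water.
#'
#' @param name `"water"`, `"pmma"`, or any label for a user material.
#' @param density g/cm3.
#' @param I mean excitation energy, eV.
#' @param composition data frame with columns `Z`, `A`, `frac` (mass
#'   fractions summing to 1).
#' @param X0 radiation length, g/cm2.
#' @param rsp_mass mass stopping power relative to water (used for WET).
#' @return an object of class `material`.
#' @examples
#' material("pmma")
#' @export
material <- function(name, density = NULL, I = NULL, composition = NULL,
                     X0 = NULL, rsp_mass = NULL) {
  if (name == "water" && is.null(composition)) {
    density <- density %||% 1.0
    I <- I %||% 75
    composition <- data.frame(
      Z = c(1, 8), A = c(1.008, 15.999),
      frac = c(2 * 1.008, 15.999) / 18.015
    )
    X0 <- X0 %||% 36.08
    rsp_mass <- rsp_mass %||% 1.0
  } else if (name == "pmma" && is.null(composition)) {
    # C5H8O2, molar mass 100.117 g/mol
    density <- density %||% 1.19
    I <- I %||% 74
    composition <- data.frame(
      Z = c(6, 1, 8), A = c(12.011, 1.008, 15.999),
      frac = c(5 * 12.011, 8 * 1.008, 2 * 15.999) / 100.117
    )
    X0 <- X0 %||% 40.55
    rsp_mass <- rsp_mass %||% (1.16 / 1.19)
  }
  if (is.null(density) || is.null(I) || is.null(composition)) {
    stop("user materials need density, I and composition", call. = FALSE)
  }
  stopifnot(density > 0, I > 0)
  if (abs(sum(composition$frac) - 1) > 1e-9) {
    stop("mass fractions must sum to 1 (got ", sum(composition$frac), ")",
         call. = FALSE)
  }
  structure(list(name = name, density = density, I = I,
                 composition = tibble::as_tibble(composition),
                 X0 = X0 %||% 36.08, rsp_mass = rsp_mass %||% 1.0),
            class = "material")
}

#' Pencil-beam description
#'
#' @param particle a [particle()] object (the beam ion).
#' @param E_u kinetic energy per nucleon, MeV/u.
#' @param entry_point 3-vector, cm; nominal beam position at the phantom
#'   surface (or upstream of it).
#' @param direction unit 3-vector; the beam axis, nominally `+z`.
#' @param sigma_beam transverse Gaussian spot sigma, cm.
#' @return an object of class `beam_spec`.
#' @examples
#' beam(particle("c12"), 220, entry_point = c(0, 0, -6.15), sigma_beam = 0.4)
#' @export
beam <- function(particle, E_u, entry_point = c(0, 0, 0),
                 direction = c(0, 0, 1), sigma_beam = 0) {
  stopifnot(inherits(particle, "particle_spec"), E_u > 0, sigma_beam >= 0,
            length(entry_point) == 3, length(direction) == 3)
  if (abs(sqrt(sum(direction^2)) - 1) > 1e-12) {
    stop("beam direction must be a unit vector", call. = FALSE)
  }
  structure(list(particle = particle, E_u = E_u,
                 entry_point = as.numeric(entry_point),
                 direction = as.numeric(direction),
                 sigma_beam = sigma_beam),
            class = "beam_spec")
}

#' @export
print.particle_spec <- function(x, ...) {
  cat(sprintf("<particle> %s  Z=%d A=%d m_u=%.3f MeV\n",
              x$name, x$Z, x$A, x$m_u))
  invisible(x)
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("<material> %s  rho=%.3f g/cm3  I=%.1f eV  rsp=%.4f\n",
              x$name, x$density, x$I, x$rsp_mass))
  invisible(x)
}

#' @export
print.beam_spec <- function(x, ...) {
  cat(sprintf("<beam> %s at %.1f MeV/u, entry (%.2f, %.2f, %.2f) cm, sigma_beam %.2f cm\n",
              x$particle$name, x$E_u, x$entry_point[1], x$entry_point[2],
              x$entry_point[3], x$sigma_beam))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
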