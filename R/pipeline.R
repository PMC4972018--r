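# Configuration-driven orchestration: simulate -> survive -> scatter ->
# detect -> reconstruct -> fit -> observables -> (optionally) unfold.

#' Validate a run configuration
#'
#' Schema and physics-sanity checks for a [run_monitor()] configuration:
#' required sections, detector angle inside (0, 180) degrees (the beam-spot
#' cot(theta) term diverges at the ends), beam energy inside the transport
#' validity window, and - when unfolding is enabled - a LUT span that covers
#' the phantom's exit thicknesses along the beam path.
#'
#' @param config a configuration list, or the path to a YAML file.
#' @return tibble of findings with columns `level` (`"error"`/`"warning"`),
#'   `where`, `message`; zero rows means the configuration is valid.
#' @export
validate_config <- function(config) {
  config <- load_config(config)
  f <- list()
  note <- function(level, where, message) {
    f[[length(f) + 1]] <<- tibble::tibble(level = level, where = where,
                                          message = message)
  }
  for (sec in c("beam", "phantom", "tracker")) {
    if (is.null(config[[sec]])) note("error", sec, "missing section")
  }
  if (is.null(config$seed)) {
    note("error", "seed", "explicit seed required (no wall-clock seeding)")
  }
  if (!is.null(config$beam)) {
    E <- config$beam$energy_MeV_u
    if (is.null(E) || E < 0.5 || E > 500) {
      note("error", "beam",
           "energy_MeV_u must lie in the transport validity range [0.5, 500]")
    }
  }
  th <- config$tracker$theta_deg
  if (!is.null(config$tracker)) {
    if (is.null(th) || th <= 0 || th >= 180) {
      note("error", "tracker",
           "theta_deg must lie strictly inside (0, 180): the beam-spot term sigma_beam*cot(theta) diverges at 0 and 180 degrees")
    }
  }
  if (length(f) == 0 && isTRUE(config$unfold$enabled)) {
    objs <- build_objects(config)
    span <- range(config$unfold$thicknesses %||% seq(2.5, 10, by = 1.5))
    dens <- emission_density(objs$beam, objs$phantom, objs$model)
    sup <- attr(dens, "support")
    zs <- seq(sup[1] + 0.05 * diff(sup), sup[2] - 1e-3, length.out = 15)
    th_rad <- objs$tracker$theta_deg * pi / 180
    dirv <- c(sin(th_rad), 0, cos(th_rad))
    s0 <- beam_coord(objs$beam$entry_point, objs$beam)
    xs <- vapply(zs, function(z) {
      v <- objs$beam$entry_point + (z - s0) * objs$beam$direction
      if (!point_in_phantom(objs$phantom, v)) return(NA_real_)
      exit_path_thickness(v, dirv, objs$phantom)
    }, numeric(1))
    xs <- xs[is.finite(xs)]
    if (length(xs) > 0 && (max(xs) > span[2] || min(xs) < span[1])) {
      note("warning", "unfold",
           sprintf("phantom exit thicknesses [%.2f, %.2f] cm exceed the LUT span [%.2f, %.2f]; out-of-span tracks will be clamped",
                   min(xs), max(xs), span[1], span[2]))
    }
  }
  if (length(f) == 0) {
    tibble::tibble(level = character(), where = character(),
                   message = character())
  } else {
    dplyr::bind_rows(f)
  }
}

load_config <- function(config) {
  if (is.character(config)) {
    config <- tryCatch(yaml::read_yaml(config), error = function(e) {
      stop("cannot parse configuration: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  stopifnot(is.list(config))
  config
}

build_objects <- function(config) {
  b <- config$beam
  bm <- beam(particle(b$particle %||% "c12"), b$energy_MeV_u,
             entry_point = unlist(b$entry_point %||% c(0, 0, 0)),
             direction = unlist(b$direction %||% c(0, 0, 1)),
             sigma_beam = b$sigma_beam_cm %||% 0)
  regions <- lapply(config$phantom$regions, function(r) {
    s <- r$solid
    solid <- switch(s$type,
      sphere = solid_sphere(unlist(s$center), s$radius),
      box = solid_box(unlist(s$center), unlist(s$half)),
      cylinder = solid_cylinder(unlist(s$center), s$radius, s$half_length,
                                unlist(s$axis %||% c(0, 0, 1))),
      stop("unknown solid type '", s$type, "'", call. = FALSE))
    region(solid, material(r$material %||% "pmma"), density = r$density)
  })
  ph <- do.call(phantom, regions)
  margs <- config$model %||% list()
  mdl <- do.call(emission_model, margs)
  tr <- config$tracker
  tk <- tracker(tr$theta_deg, tr$distance_cm, tr$width_cm, tr$height_cm,
                sigma_dir_rad = tr$sigma_dir_rad %||% 0,
                sigma_point_cm = tr$sigma_point_cm %||% 0,
                efficiency = tr$efficiency %||% 1,
                sigma_tof_ns = tr$sigma_tof_ns %||% 0)
  list(beam = bm, phantom = ph, model = mdl, tracker = tk)
}

# djb2-style hash of the deparsed configuration, for output provenance
# lines (double arithmetic stays exact below 2^53).
config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

write_with_hash <- function(df, path, hash) {
  con <- file(path, "w")
  writeLines(paste0("# config_hash: ", hash), con)
  write.csv(df, con, row.names = FALSE)
  close(con)
}

#' Run the full monitoring chain
#'
#' Executes simulate, survive, scatter, detect, reconstruct, fit,
#' observables and (if configured) LUT building plus absorption unfolding,
#' from a single configuration. All randomness derives from the
#' configuration seed through fixed per-stage streams, so identical
#' configurations give identical outputs. When `out_dir` is given, track
#' and profile tables are written as CSV (with a config-hash header line)
#' and the fit report as JSON.
#'
#' @param config configuration list or YAML path; see the packaged examples
#'   under `system.file("extdata", package = "fragmon")`.
#' @param out_dir optional output directory.
#' @return a list of class `monitor_run`: `tracks`, `detected`, `profile`,
#'   `fit`, `observables`, `unfold` (or NULL), `seeds`, `warnings`,
#'   `config_hash`, per-stage `counts`.
#' @export
run_monitor <- function(config, out_dir = NULL) {
  config <- load_config(config)
  findings <- validate_config(config)
  if (any(findings$level == "error")) {
    stop("invalid configuration:\n", paste0("  [", findings$where, "] ",
                                            findings$message,
                                            collapse = "\n"), call. = FALSE)
  }
  objs <- build_objects(config)
  seed <- config$seed
  an <- config$analysis %||% list()
  n_tracks <- an$n_tracks %||% 20000
  apply_survival <- an$apply_survival %||% TRUE
  apply_scattering <- an$apply_scattering %||% TRUE
  warnings <- character()
  hash <- config_hash(config)
  seeds <- vapply(names(.STAGES), function(s) derive_seed(seed, s),
                  integer(1))

  # --- emission ---------------------------------------------------------
  trk <- sample_tracks(objs$beam, objs$phantom, objs$model, n_tracks,
                       theta_aim = objs$tracker$theta_deg,
                       seed = seeds[["emission"]])

  # --- survival along the exit path ------------------------------------
  sv <- survival_probability(trk, objs$phantom, objs$model)
  trk$x_exit_cm <- sv$x_exit_cm
  if (apply_survival) {
    kept <- with_seed(seeds[["survival"]], runif(nrow(trk)) < sv$p_survive)
  } else {
    kept <- rep(TRUE, nrow(trk))
  }
  surv <- trk[kept, ]

  # --- multiple scattering at the phantom exit point -------------------
  lines <- surv
  if (apply_scattering && nrow(surv) > 0) {
    newdir <- scatter_direction(surv, objs$phantom,
                                seed = seeds[["scatter"]],
                                x_exit = surv$x_exit_cm)
    # geometric exit point: the measured line pivots where the track leaves
    # the phantom, giving the scattering its proper lever arm
    tgeo <- vapply(seq_len(nrow(surv)), function(i) {
      ch <- chord_lengths(c(surv$x_cm[i], surv$y_cm[i], surv$z_cm[i]),
                          c(surv$dx[i], surv$dy[i], surv$dz[i]),
                          objs$phantom)
      sum(ch$length_cm)
    }, numeric(1))
    exitp <- cbind(surv$x_cm + surv$dx * tgeo,
                   surv$y_cm + surv$dy * tgeo,
                   surv$z_cm + surv$dz * tgeo)
    lines$x_cm <- exitp[, 1]; lines$y_cm <- exitp[, 2]
    lines$z_cm <- exitp[, 3]
    lines$dx <- newdir[, 1]; lines$dy <- newdir[, 2]; lines$dz <- newdir[, 3]
  }

  # --- detection and vertexing -----------------------------------------
  det <- detect(lines, objs$tracker, seed = seeds[["detection"]])
  det <- reconstruct_vertices(det, objs$beam)

  # --- profile, fit, observables ---------------------------------------
  bw <- an$bin_width_cm %||% 0.2
  dens <- emission_density(objs$beam, objs$phantom, objs$model)
  sup <- attr(dens, "support")
  edges <- seq(sup[1], sup[2], by = bw)
  prof <- longitudinal_profile(det, edges, coord = "z_reco")
  conv_sigma <- an$conv_sigma %||% "auto"
  if (identical(conv_sigma, "auto")) {
    conv_sigma <- beam_spot_sigma(objs$beam$sigma_beam,
                                  objs$tracker$theta_deg)
  }
  ft <- tryCatch(fit_profile(prof, conv_sigma = conv_sigma),
                 error = function(e) {
                   warnings <<- c(warnings, paste("profile fit failed:",
                                                  conditionMessage(e)))
                   NULL
                 })
  obs <- if (!is.null(ft)) range_observables(ft) else NULL

  # --- absorption unfolding --------------------------------------------
  unfold <- NULL
  if (isTRUE(config$unfold$enabled)) {
    uf <- config$unfold
    lut <- build_lut(objs$beam, objs$phantom, objs$model,
                     thicknesses = unlist(uf$thicknesses %||%
                                            seq(2.5, 10, by = 1.5)),
                     edges = edges,
                     n_tracks = uf$n_tracks_per_node %||% 20000,
                     degree = uf$degree %||% 2,
                     x0 = uf$x0, theta_aim = objs$tracker$theta_deg,
                     seed = seeds[["lut"]])
    unfold <- withCallingHandlers(
      unfold_profile(det, lut, edges = edges),
      warning = function(w) {
        warnings <<- c(warnings, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    unfold$lut <- lut
  }

  out <- structure(list(
    tracks = trk, detected = det, profile = prof, fit = ft,
    observables = obs, unfold = unfold,
    density = dens,
    seeds = seeds, warnings = warnings, config_hash = hash,
    counts = c(generated = nrow(trk), survived = nrow(surv),
               detected = nrow(det))),
    class = "monitor_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_with_hash(trk, file.path(out_dir, "tracks.csv"), hash)
    write_with_hash(det, file.path(out_dir, "detected.csv"), hash)
    write_with_hash(prof, file.path(out_dir, "profile.csv"), hash)
    if (!is.null(obs)) {
      write_with_hash(obs, file.path(out_dir, "observables.csv"), hash)
    }
    if (!is.null(ft)) {
      rep <- list(config_hash = hash, seeds = as.list(seeds),
                  params = as.list(ft$params),
                  cov = unclass(ft$cov), chisq = ft$chisq, ndf = ft$ndf,
                  conv_sigma = ft$conv_sigma,
                  observables = if (!is.null(obs)) as.list(obs) else NULL,
                  warnings = warnings)
      jsonlite::write_json(rep, file.path(out_dir, "fit_report.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    if (!is.null(unfold)) {
      write_with_hash(unfold$corrected,
                      file.path(out_dir, "profile_corrected.csv"), hash)
      write_with_hash(unfold$uncorrected,
                      file.path(out_dir, "profile_uncorrected.csv"), hash)
      lut_doc <- list(config_hash = hash, grid = unfold$lut$grid,
                      x0 = unfold$lut$x0, degree = unfold$lut$degree,
                      nodes = unfold$lut$nodes, poly = unfold$lut$poly,
                      seed = unfold$lut$seed)
      jsonlite::write_json(lut_doc, file.path(out_dir, "lut.json"),
                           auto_unbox = TRUE, digits = NA, dataframe = "columns")
    }
  }
  out
}

#' @export
print.monitor_run <- function(x, ...) {
  cat(sprintf(
    "<monitor run> %d generated -> %d survived -> %d detected tracks\n",
    x$counts[["generated"]], x$counts[["survived"]],
    x$counts[["detected"]]))
  if (!is.null(x$observables)) print(x$observables)
  if (length(x$warnings) > 0) {
    cat("warnings:\n"); for (w in x$warnings) cat("  -", w, "\n")
  }
  invisible(x)
}
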