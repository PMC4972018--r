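# Weighted least-squares fits of longitudinal emission profiles: the
# four-parameter erfc fall-off model and the six-parameter double-logistic
# model. Fits run on bin centres with Poisson weights via
# Levenberg-Marquardt: a first pass with empirical variances max(count, 1)
# followed by one Pearson reweighting pass with model variances
# max(fitted, 1), which removes the low-count bias of purely empirical
# weights. A fixed ladder of deterministic jittered restarts handles
# non-convergence.

.JITTER <- c(1, 0.8, 1.25, 0.6, 1.6)  # multiplicative restart factors

fit_error <- function(msg, diagnostics = NULL) {
  structure(class = c("fragmon_fit_error", "error", "condition"),
            list(message = msg, call = NULL, diagnostics = diagnostics))
}

#' Fit the erfc fall-off model
#'
#' Fits `f(z) = a + b * erfc(c (z - d))` to a profile's falling edge; the
#' inflection position `d` tracks the primary-ion range. Weighted least
#' squares on bin centres with Poisson weights.
#'
#' @param profile an [longitudinal_profile()] tibble.
#' @param init optional named list/vector with starting values `a`, `b`,
#'   `c`, `d`.
#' @return an object of class `erfc_fit`: parameters, covariance,
#'   chi-square, degrees of freedom.
#' @export
fit_erfc <- function(profile, init = NULL) {
  prof <- profile[profile$count > 0 | profile$err > 0, ]
  if (nrow(prof) < 8) {
    stop(fit_error("need at least 8 non-empty bins spanning the fall-off"))
  }
  z <- profile_centers(profile)
  y <- profile$count
  # a falling edge must exist: the profile tail must drop well below the peak
  ipk <- which.max(y)
  if (mean(tail(y, 3)) > 0.6 * y[ipk] || ipk >= length(y) - 2) {
    stop(fit_error("no falling edge in the profile; erfc model undefined"))
  }
  wts <- 1 / pmax(y, 1)
  if (is.null(init)) {
    a0 <- max(min(y), 1e-3)
    b0 <- (max(y) - a0) / 2
    half <- a0 + (max(y) - a0) / 2
    after <- which(z > z[ipk] & y < half)
    d0 <- if (length(after) > 0) z[after[1]] else z[ipk] + profile_binwidth(profile)
    c0 <- 1 / (2 * profile_binwidth(profile))
    init <- c(a = a0, b = b0, c = c0, d = d0)
  }
  model <- function(z, a, b, c, d) a + b * erfc_fun(c * (z - d))
  df <- data.frame(z = z, y = y)
  fit <- NULL
  for (j in .JITTER) {
    st <- list(a = init[["a"]] * j, b = init[["b"]] * j,
               c = init[["c"]] * j, d = init[["d"]])
    fit <- tryCatch({
      f1 <- minpack.lm::nlsLM(y ~ model(z, a, b, c, d), data = df,
                              start = st, weights = wts,
                              control = nls.control(maxiter = 200,
                                                    tol = 1e-8))
      # Pearson pass: model-based variances
      minpack.lm::nlsLM(y ~ model(z, a, b, c, d), data = df,
                        start = as.list(coef(f1)),
                        weights = 1 / pmax(predict(f1), 1),
                        control = nls.control(maxiter = 200, tol = 1e-8))
    }, error = function(e) NULL)
    if (!is.null(fit) && coef(fit)[["c"]] > 0) break
    fit <- NULL
  }
  if (is.null(fit)) {
    stop(fit_error("erfc fit did not converge after restarts",
                   diagnostics = list(init = init, n_bins = nrow(prof))))
  }
  cf <- coef(fit)
  resid <- (y - predict(fit)) / sqrt(pmax(predict(fit), 1))
  structure(list(params = cf, cov = vcov(fit), chisq = sum(resid^2),
                 ndf = length(y) - 4, fit = fit),
            class = "erfc_fit")
}

erfc_fun <- function(x) 2 * pnorm(-sqrt(2) * x)

#' Fit the double-logistic profile model
#'
#' Fits the six-parameter double-logistic model (optionally convolved with a
#' Gaussian of width `conv_sigma`, the beam-spot projection term) to a
#' longitudinal emission profile. Initialisation is automatic from profile
#' quantiles: plateau from the 90th-percentile bin content, background from
#' the outer-bin median, edge midpoints from the 40 percent crossings of the
#' raw histogram, widths at three bin widths; five deterministic jittered
#' restarts on failure.
#'
#' @param profile an [longitudinal_profile()] tibble.
#' @param conv_sigma Gaussian convolution sigma, cm (0 disables; use
#'   [beam_spot_sigma()] for the beam-spot term).
#' @param init optional [dl_params()] or named vector of starting values.
#' @return an object of class `dl_fit`: `params` (a [dl_params()]), `cov`,
#'   `chisq`, `ndf`, `conv_sigma`, `convergence`.
#' @export
fit_profile <- function(profile, conv_sigma = 0, init = NULL) {
  prof <- profile[profile$count > 0 | profile$err > 0, ]
  if (nrow(prof) < 8) {
    stop(fit_error("need at least 8 non-empty bins spanning both edges"))
  }
  z <- profile_centers(profile)
  y <- profile$count
  wts <- 1 / pmax(y, 1)
  bw <- profile_binwidth(profile)
  if (is.null(init)) {
    p0 <- quantile(y, 0.9, names = FALSE)
    p5 <- max(median(c(head(y, 3), tail(y, 3))), 1e-3)
    lev40 <- p5 + 0.4 * (p0 - p5)
    lev80 <- p5 + 0.8 * (p0 - p5)
    ab40 <- which(y > lev40)
    ab80 <- which(y > lev80)
    if (length(ab40) < 2) {
      stop(fit_error("profile has no resolvable plateau above background"))
    }
    # edge widths from the 80% -> 40% crossing separation: a logistic drops
    # from 0.8 to 0.4 of the plateau over 1.79 widths
    w_fall <- if (length(ab80) >= 1) {
      max((z[ab40[length(ab40)]] - z[ab80[length(ab80)]]) / 1.79, bw)
    } else 3 * bw
    w_rise <- if (length(ab80) >= 1) {
      max((z[ab80[1]] - z[ab40[1]]) / 1.79, bw)
    } else 3 * bw
    init <- c(p0 = max(p0 - p5, 1e-3), p1 = z[ab40[length(ab40)]],
              p2 = w_fall, p3 = z[ab40[1]], p4 = w_rise, p5 = p5)
  } else {
    init <- c(p0 = init[["p0"]], p1 = init[["p1"]], p2 = init[["p2"]],
              p3 = init[["p3"]], p4 = init[["p4"]], p5 = init[["p5"]])
  }
  model <- function(z, p0, p1, p2, p3, p4, p5) {
    p <- c(p0 = p0, p1 = p1, p2 = abs(p2), p3 = p3, p4 = abs(p4),
           p5 = abs(p5))
    eval_double_logistic(z, p, conv_sigma = conv_sigma)
  }
  df <- data.frame(z = z, y = y)
  # multi-start: the jitter ladder also rescales the width guesses; the
  # best-chi-square valid fit wins
  best <- NULL; best_chi <- Inf
  for (j in .JITTER) {
    st <- list(p0 = init[["p0"]] * j, p1 = init[["p1"]],
               p2 = init[["p2"]] * j, p3 = init[["p3"]],
               p4 = init[["p4"]] * j, p5 = init[["p5"]])
    fit <- tryCatch({
      f1 <- minpack.lm::nlsLM(y ~ model(z, p0, p1, p2, p3, p4, p5),
                              data = df, start = st, weights = wts,
                              control = nls.control(maxiter = 500,
                                                    tol = 1e-8))
      minpack.lm::nlsLM(y ~ model(z, p0, p1, p2, p3, p4, p5), data = df,
                        start = as.list(coef(f1)),
                        weights = 1 / pmax(predict(f1), 1),
                        control = nls.control(maxiter = 500, tol = 1e-8))
    }, error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- coef(fit)
      chi <- sum((y - predict(fit))^2 / pmax(predict(fit), 1))
      if (cf[["p0"]] > 0 && cf[["p1"]] > cf[["p3"]] && chi < best_chi) {
        best <- fit; best_chi <- chi
        # a fit this good will not be improved by further restarts
        if (best_chi < 1.2 * (length(y) - 6)) break
      }
    }
  }
  fit <- best
  if (is.null(fit)) {
    stop(fit_error("double-logistic fit did not converge after restarts",
                   diagnostics = list(init = init, n_bins = nrow(prof))))
  }
  cf <- coef(fit)
  cf[c("p2", "p4", "p5")] <- abs(cf[c("p2", "p4", "p5")])
  params <- dl_params(cf[["p0"]], cf[["p1"]], cf[["p2"]], cf[["p3"]],
                      cf[["p4"]], cf[["p5"]], conv_sigma = conv_sigma)
  resid <- (y - predict(fit)) / sqrt(pmax(predict(fit), 1))
  structure(list(params = params, cov = vcov(fit), chisq = sum(resid^2),
                 ndf = length(y) - 6, conv_sigma = conv_sigma,
                 convergence = fit$convInfo, fit = fit),
            class = "dl_fit")
}

#' @export
print.dl_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<double-logistic fit> chi2/ndf = %.2f/%d\n  p0=%.3g p1=%.4f p2=%.4f p3=%.4f p4=%.4f p5=%.3g (conv_sigma=%.3f)\n",
    x$chisq, x$ndf, p[["p0"]], p[["p1"]], p[["p2"]], p[["p3"]], p[["p4"]],
    p[["p5"]], x$conv_sigma))
  invisible(x)
}

#' @export
print.erfc_fit <- function(x, ...) {
  cat(sprintf(
    "<erfc fit> chi2/ndf = %.2f/%d  a=%.3g b=%.3g c=%.3f d=%.4f\n",
    x$chisq, x$ndf, x$params[["a"]], x$params[["b"]], x$params[["c"]],
    x$params[["d"]]))
  invisible(x)
}
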