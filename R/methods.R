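# Broom-style accessors and ggplot2 displays for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a double-logistic profile fit
#'
#' @param x a `dl_fit` from [fit_profile()].
#' @param ... unused.
#' @return tibble with `term`, `estimate`, `std.error`.
#' @export
tidy.dl_fit <- function(x, ...) {
  se <- sqrt(pmax(diag(x$cov), 0))
  tibble::tibble(term = names(x$params), estimate = as.numeric(x$params),
                 std.error = as.numeric(se))
}

#' @rdname tidy.dl_fit
#' @export
tidy.erfc_fit <- function(x, ...) {
  se <- sqrt(pmax(diag(x$cov), 0))
  tibble::tibble(term = names(x$params), estimate = as.numeric(x$params),
                 std.error = as.numeric(se))
}

#' Tidy the range observables
#'
#' @param x a `range_observables` row.
#' @param ... unused.
#' @return tibble with `term`, `estimate`, `std.error`.
#' @export
tidy.range_observables <- function(x, ...) {
  terms <- c("x_left", "x_right", "delta40", "delta40_tan")
  tibble::tibble(term = terms,
                 estimate = as.numeric(x[1, terms]),
                 std.error = as.numeric(x[1, paste0("se_", terms)]))
}

#' One-row fit summaries
#'
#' @param x a `dl_fit` or `erfc_fit`.
#' @param ... unused.
#' @return one-row tibble with `chisq`, `ndf`, `chisq.red`.
#' @export
glance.dl_fit <- function(x, ...) {
  tibble::tibble(chisq = x$chisq, ndf = x$ndf, chisq.red = x$chisq / x$ndf,
                 conv_sigma = x$conv_sigma)
}

#' @rdname glance.dl_fit
#' @export
glance.erfc_fit <- function(x, ...) {
  tibble::tibble(chisq = x$chisq, ndf = x$ndf, chisq.red = x$chisq / x$ndf)
}

#' Plot an emission profile
#'
#' Step histogram with error bars; optionally overlays a fitted model.
#'
#' @param object an `emission_profile`.
#' @param fit optional `dl_fit` or `erfc_fit` to overlay.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.emission_profile <- function(object, fit = NULL, ...) {
  df <- tibble::tibble(z = profile_centers(object), count = object$count,
                       err = object$err)
  g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$z, y = .data$count)) +
    ggplot2::geom_step(direction = "mid") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$count - .data$err,
                                        ymax = .data$count + .data$err),
                           width = 0, alpha = 0.5) +
    ggplot2::labs(x = "longitudinal coordinate z [cm]", y = "counts")
  if (!is.null(fit)) {
    zg <- seq(min(df$z), max(df$z), length.out = 400)
    yg <- if (inherits(fit, "dl_fit")) {
      eval_double_logistic(zg, fit$params, conv_sigma = fit$conv_sigma)
    } else {
      fit$params[["a"]] + fit$params[["b"]] *
        erfc_fun(fit$params[["c"]] * (zg - fit$params[["d"]]))
    }
    g <- g + ggplot2::geom_line(data = tibble::tibble(z = zg, count = yg),
                                colour = "red")
  }
  g
}

#' Plot a depth-dose curve
#'
#' @param object a `depth_dose_curve` from [depth_dose()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.depth_dose_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$depth_cm,
                                       y = .data$dose_MeV_cm)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = attr(object, "peak_depth"),
                        linetype = "dashed") +
    ggplot2::labs(x = "depth [cm]", y = "dose [MeV/cm]")
}

#' Plot an unfolding result
#'
#' Uncorrected and absorption-corrected profiles side by side, optionally
#' with the true emission profile.
#'
#' @param object an `unfold_result` from [unfold_profile()].
#' @param truth optional `emission_profile` of true vertices for comparison.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.unfold_result <- function(object, truth = NULL, ...) {
  mk <- function(p, lab) {
    tibble::tibble(z = profile_centers(p), count = p$count, which = lab)
  }
  df <- dplyr::bind_rows(mk(object$uncorrected, "uncorrected"),
                         mk(object$corrected, "corrected"))
  if (!is.null(truth)) {
    tr <- mk(truth, "true emission")
    tr$count <- tr$count * sum(object$corrected$count) / sum(tr$count)
    df <- dplyr::bind_rows(df, tr)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z, y = .data$count,
                                   colour = .data$which)) +
    ggplot2::geom_step(direction = "mid") +
    ggplot2::labs(x = "longitudinal coordinate z [cm]", y = "counts",
                  colour = NULL)
}

#' Plot the LUT parameter trends
#'
#' Fitted double-logistic parameters at each thickness node with the
#' polynomial models superimposed.
#'
#' @param object an `absorption_lut`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.absorption_lut <- function(object, ...) {
  long <- tidyr::pivot_longer(object$nodes[, c("x", "p0", "p1", "p2", "p3",
                                               "p4", "p5")],
                              -"x", names_to = "param",
                              values_to = "value")
  xg <- seq(min(object$grid), max(object$grid), length.out = 100)
  curves <- dplyr::bind_rows(lapply(names(object$poly), function(pn) {
    tibble::tibble(x = xg, param = pn,
                   value = eval_poly(object$poly[[pn]], xg))
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curves, colour = "red") +
    ggplot2::facet_wrap(~param, scales = "free_y") +
    ggplot2::labs(x = "crossed thickness x [cm WET]", y = "parameter value")
}
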