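#' Plotting methods
#'
#' Quick-look ggplot2 graphics for each result type: log-log spectra with
#' the fitted power law, domain-size distributions, finite-size collapse
#' curves, velocity-correlation curves with the zero crossing, and
#' per-residue involvement profiles.
#'
#' @name idpcrit-plots
NULL

#' @param object a `power_spectrum` tibble.
#' @param fit optional `spectral_fit` drawn as a reference line.
#' @param ... ignored.
#' @rdname idpcrit-plots
#' @method autoplot power_spectrum
#' @export
autoplot.power_spectrum <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$frequency, y = .data$power)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency", y = "S(f)")
  if (!is.null(fit)) {
    fl <- tibble(frequency = c(fit$f_min, fit$f_max))
    fl$power <- 10^(fit$intercept - fit$beta * log10(fl$frequency))
    p <- p + ggplot2::geom_line(data = fl, color = "red") +
      ggplot2::ggtitle(sprintf("beta = %.2f (r^2 = %.3f)", fit$beta, fit$r_squared))
  }
  p
}

#' @rdname idpcrit-plots
#' @method autoplot size_distribution
#' @export
autoplot.size_distribution <- function(object, ...) {
  ggplot2::ggplot(object$table, ggplot2::aes(x = .data$size, y = .data$p)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "domain size s", y = "P(s)",
                  title = if (is.na(object$tau_hat)) "size distribution"
                          else sprintf("tau_hat = %.2f", object$tau_hat))
}

#' @rdname idpcrit-plots
#' @method autoplot scaling_collapse
#' @export
autoplot.scaling_collapse <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$x, y = .data$y,
                               color = factor(.data$N))) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "s / N", y = expression(P(s) * s^tau), color = "N",
                  title = sprintf("collapse score %.3g at tau = %.2f",
                                  object$collapse_score, object$tau))
}

#' @rdname idpcrit-plots
#' @method autoplot correlation_curve
#' @export
autoplot.correlation_curve <- function(object, ...) {
  xi <- correlation_length(object)
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$r, y = .data$C)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey50") +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "r (nm)", y = "C(r)")
  if (!is.na(xi)) {
    p <- p + ggplot2::geom_vline(xintercept = xi, linetype = 3, color = "red") +
      ggplot2::ggtitle(sprintf("xi = %.2f nm", xi))
  }
  p
}

#' @rdname idpcrit-plots
#' @method autoplot involvement_profile
#' @export
autoplot.involvement_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$residue, y = .data$involvement)) +
    ggplot2::geom_col(width = 1, fill = "steelblue") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "residue", y = "dominant-domain involvement")
}
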