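#' Power spectra of conformational time series
#'
#' The temporal fingerprint of the pipeline is the power spectrum S(f) of a
#' scalar conformational coordinate (typically the end-to-end distance).
#' S(f) is defined as the Fourier transform of the time-averaged
#' autocorrelation of the signal; numerically it is computed as the
#' periodogram |DFT(x)|^2 * dt / n, which at the Fourier frequencies equals
#' the discrete Fourier transform of the biased autocorrelation estimate
#' (Wiener-Khinchin). A power-law spectrum S(f) ~ f^-beta with beta near 1
#' ("1/f noise") signals scale-free temporal correlation, intermediate
#' between white (beta = 0) and Brownian (beta = 2) noise.
#'
#' @name spectral
NULL

new_power_spectrum <- function(frequency, power, n_averaged = 1L) {
  if (any(diff(frequency) <= 0)) abort("frequencies must be strictly increasing")
  if (any(!is.finite(power)) || any(power < 0)) abort("power must be finite and >= 0")
  structure(
    tibble(frequency = frequency, power = power),
    class = c("power_spectrum", class(tibble())),
    n_averaged = as.integer(n_averaged)
  )
}

#' Autocorrelation function of a time series
#'
#' Time-averaged estimator: lag-k value is (1/(n-k)) * sum over t0 of
#' x(t0+k) x(t0), with x mean-subtracted when `center` is TRUE.
#'
#' @param ts `idp_series` tibble or numeric vector.
#' @param center subtract the mean first (default TRUE).
#' @param dt sampling interval (taken from `ts` when absent).
#' @return `idp_series` tibble whose `time` column holds the lag.
#' @export
autocorrelation <- function(ts, center = TRUE, dt = NULL) {
  x <- series_values(ts)
  n <- length(x)
  if (n < 2) abort("autocorrelation needs length >= 2")
  dt <- series_dt(ts, dt)
  if (center) x <- x - mean(x)
  # FFT-based linear correlation (zero-padded), then unbiased normalization
  m <- 2^ceiling(log2(2 * n))
  X <- fft(c(x, rep(0, m - n)))
  raw <- Re(fft(Mod(X)^2, inverse = TRUE)) / m
  ac <- raw[1:n] / (n - 0:(n - 1))
  time_series(ac, dt = dt)
}

#' One-sided power spectrum (periodogram)
#'
#' Frequencies k/(n*dt) for k = 1..floor(n/2); the zero-frequency bin is
#' excluded (with centering it is identically zero, without it carries only
#' the squared mean). Optional Welch segmentation averages the periodograms
#' of `segments` non-overlapping pieces; OFF by default.
#'
#' @param ts `idp_series` tibble or numeric vector.
#' @param center subtract the mean (default TRUE; the DC offset of a distance
#'   series otherwise leaks across the low-frequency bins and corrupts the
#'   power-law fit).
#' @param dt sampling interval (taken from `ts` when absent).
#' @param segments number of Welch segments (default 1 = plain periodogram).
#' @return `power_spectrum` tibble with columns frequency, power.
#' @export
power_spectrum <- function(ts, center = TRUE, dt = NULL, segments = 1L) {
  x <- series_values(ts)
  if (length(x) < 4) abort("power spectrum needs length >= 4")
  if (!all(is.finite(x))) abort("values must be finite")
  dt <- series_dt(ts, dt)
  if (segments > 1) {
    len <- floor(length(x) / segments)
    specs <- lapply(seq_len(segments), function(s) {
      power_spectrum(x[((s - 1) * len + 1):(s * len)], center = center, dt = dt)
    })
    return(average_spectra(specs))
  }
  if (center) x <- x - mean(x)
  n <- length(x)
  X <- fft(x)
  k <- seq_len(floor(n / 2))
  new_power_spectrum(
    frequency = k / (n * dt),
    power = Mod(X[k + 1])^2 * dt / n
  )
}

#' Average power spectra over independent trajectories
#'
#' Bin-wise arithmetic mean over spectra sharing one frequency grid; this is
#' how the per-trajectory spectra of independent runs are pooled into the
#' final spectrum.
#'
#' @param spectra list of `power_spectrum` tibbles on identical grids.
#' @return `power_spectrum` tibble; its `n_averaged` attribute sums the inputs'.
#' @export
average_spectra <- function(spectra) {
  if (!is.list(spectra) || length(spectra) == 0) abort("need a non-empty list of spectra")
  f <- spectra[[1]]$frequency
  for (s in spectra) {
    if (length(s$frequency) != length(f) ||
        max(abs(s$frequency - f)) > 1e-9 * max(f)) {
      abort("spectra are on different frequency grids")
    }
  }
  pw <- rowMeans(do.call(cbind, lapply(spectra, function(s) s$power)))
  nav <- sum(vapply(spectra, function(s) {
    a <- attr(s, "n_averaged"); if (is.null(a)) 1L else a
  }, 1L))
  new_power_spectrum(f, pw, n_averaged = nav)
}

#' Logarithmic binning of a spectrum
#'
#' Geometric-mean frequency and arithmetic-mean power per log-spaced bin;
#' empty bins are dropped. Stabilizes log-log power-law fits over spectra
#' spanning several frequency decades.
#'
#' @param spec `power_spectrum` tibble.
#' @param bins_per_decade bins per factor of 10 (default 8).
#' @return `power_spectrum` tibble.
#' @export
log_bin <- function(spec, bins_per_decade = 8L) {
  if (bins_per_decade < 1) abort("bins_per_decade must be >= 1")
  lf <- log10(spec$frequency)
  idx <- floor((lf - min(lf)) * bins_per_decade + 1e-12)
  df <- tibble(idx = idx, lf = lf, power = spec$power) |>
    group_by(.data$idx) |>
    summarise(frequency = 10^mean(.data$lf), power = mean(.data$power),
              .groups = "drop") |>
    arrange(.data$frequency)
  nav <- attr(spec, "n_averaged")
  new_power_spectrum(df$frequency, df$power, n_averaged = if (is.null(nav)) 1L else nav)
}

default_fit_window <- function(spec) {
  # exclude the lowest 3 bins (poorly averaged) and the top half-decade
  # (saving-interval aliasing); overridable via f_min / f_max
  f <- spec$frequency
  list(f_min = f[min(4L, length(f))], f_max = max(f) / sqrt(10))
}

#' Fit the spectral power-law exponent beta
#'
#' Ordinary least squares of log10 S on log10 f over a frequency window;
#' beta is minus the slope, so S(f) ~ f^-beta. The default window drops the
#' lowest three frequency points and the top half-decade.
#'
#' @param spec `power_spectrum` tibble.
#' @param f_min,f_max fit window (defaults as above).
#' @return `spectral_fit` object with fields beta, intercept, r_squared,
#'   f_min, f_max, n_points; `tidy()` and `glance()` methods apply.
#' @export
fit_exponent <- function(spec, f_min = NULL, f_max = NULL) {
  w <- default_fit_window(spec)
  if (is.null(f_min)) f_min <- w$f_min
  if (is.null(f_max)) f_max <- w$f_max
  if (f_min >= f_max) abort("f_min must be below f_max")
  sel <- spec$frequency >= f_min & spec$frequency <= f_max & spec$power > 0
  if (sum(sel) < 5) abort("need at least 5 positive-power points inside the fit window")
  lf <- log10(spec$frequency[sel])
  lp <- log10(spec$power[sel])
  fit <- lm(lp ~ lf)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((lp - mean(lp))^2)
  structure(
    list(
      beta = -unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      r_squared = if (ss_tot == 0) 1 else max(0, min(1, 1 - ss_res / ss_tot)),
      f_min = f_min, f_max = f_max, n_points = sum(sel)
    ),
    class = "spectral_fit"
  )
}

#' @export
print.spectral_fit <- function(x, ...) {
  cat(sprintf(
    "Spectral power-law fit: beta = %.4f (r^2 = %.4f, %d points, f in [%.3g, %.3g])\n",
    x$beta, x$r_squared, x$n_points, x$f_min, x$f_max
  ))
  invisible(x)
}

#' @method tidy spectral_fit
#' @export
tidy.spectral_fit <- function(x, ...) {
  tibble(term = c("beta", "intercept"), estimate = c(x$beta, x$intercept))
}

#' @method glance spectral_fit
#' @export
glance.spectral_fit <- function(x, ...) {
  tibble(beta = x$beta, intercept = x$intercept, r.squared = x$r_squared,
         f.min = x$f_min, f.max = x$f_max, n.points = x$n_points)
}

#' Write a spectrum (TSV) with a key=value sidecar for an associated fit
#'
#' @param spec `power_spectrum` tibble.
#' @param path output TSV path; the sidecar is `<path>.info`.
#' @param fit optional `spectral_fit`.
#' @export
write_spectrum_tsv <- function(spec, path, fit = NULL) {
  utils::write.table(as.data.frame(spec[, c("frequency", "power")]),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  nav <- attr(spec, "n_averaged")
  info <- c(sprintf("n_averaged=%d", if (is.null(nav)) 1L else nav))
  if (!is.null(fit)) {
    info <- c(info, sprintf("beta=%.10g", fit$beta),
              sprintf("r_squared=%.10g", fit$r_squared),
              sprintf("f_min=%.10g", fit$f_min), sprintf("f_max=%.10g", fit$f_max))
  }
  writeLines(info, paste0(path, ".info"))
  invisible(path)
}
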