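#' Single-molecule FRET traces and their spectral analysis
#'
#' Energy-transfer efficiency between a donor/acceptor dye pair at distance
#' R follows E = 1 / (1 + (R/R0)^6), with Forster radius R0 (about 5 nm for
#' the Cy3 / Alexa-647 pair the experiments this pipeline targets use).
#' Efficiency trajectories are inverted to inter-dye distance series, which
#' then go through the same power-spectrum machinery as simulated
#' end-to-end distances.
#'
#' @name fret
NULL

#' FRET efficiency from donor/acceptor intensities
#'
#' E = I_A / (I_A + gamma I_D). Points with zero total intensity are masked
#' (NA) and counted in the `n_masked` attribute.
#'
#' @param donor,acceptor non-negative intensity vectors of equal length.
#' @param gamma detection-correction factor (default 1).
#' @return efficiency vector in \[0, 1\] with attribute n_masked.
#' @export
efficiency_from_intensities <- function(donor, acceptor, gamma = 1) {
  if (length(donor) != length(acceptor)) abort("donor and acceptor lengths differ")
  if (any(donor < 0, na.rm = TRUE) || any(acceptor < 0, na.rm = TRUE)) {
    abort("intensities must be non-negative")
  }
  tot <- acceptor + gamma * donor
  out <- ifelse(tot > 0, acceptor / tot, NA_real_)
  structure(out, n_masked = sum(tot <= 0))
}

#' Efficiency at a given inter-dye distance
#'
#' @param R distance in nm (> 0), vectorized.
#' @param R0 Forster radius in nm (default 5).
#' @return E = 1 / (1 + (R/R0)^6), strictly decreasing in R.
#' @export
efficiency_from_distance <- function(R, R0 = 5) {
  if (any(R <= 0) || R0 <= 0) abort("distances and R0 must be positive")
  1 / (1 + (R / R0)^6)
}

#' Inter-dye distance from efficiency
#'
#' E is clamped into (lo, hi) before inversion -- the transfer law is
#' non-invertible at 0 and 1 and shot noise routinely exceeds those bounds.
#' Clamped points are counted in the `n_clamped` attribute.
#'
#' @param E efficiency values (any real; clamped), vectorized.
#' @param R0 Forster radius, nm.
#' @param clamp length-2 bounds, default c(0.01, 0.99).
#' @return R = R0 ((1 - E) / E)^(1/6) in nm, attribute n_clamped.
#' @export
distance_from_efficiency <- function(E, R0 = 5, clamp = c(0.01, 0.99)) {
  if (R0 <= 0) abort("R0 must be positive")
  if (length(clamp) != 2 || clamp[1] <= 0 || clamp[2] >= 1 || clamp[1] >= clamp[2]) {
    abort("clamp must be (lo, hi) with 0 < lo < hi < 1")
  }
  n_clamped <- sum(E < clamp[1] | E > clamp[2])
  Ec <- pmin(pmax(E, clamp[1]), clamp[2])
  structure(R0 * ((1 - Ec) / Ec)^(1 / 6), n_clamped = n_clamped)
}

#' Build a FRET trace tibble
#'
#' @param time strictly increasing, uniformly spaced times (s).
#' @param efficiency efficiency values.
#' @param R0 Forster radius, nm (default 5).
#' @return `fret_trace` tibble (time, efficiency) with attributes R0 and dt.
#' @export
fret_trace <- function(time, efficiency, R0 = 5) {
  if (length(time) != length(efficiency)) abort("time and efficiency lengths differ")
  d <- diff(time)
  if (any(d <= 0) || max(abs(d - d[1])) > 0.01 * d[1]) {
    abort("time must be strictly increasing and uniform within 1%")
  }
  structure(tibble(time = time, efficiency = efficiency),
            class = c("fret_trace", class(tibble())),
            R0 = R0, dt = d[1])
}

#' Read a FRET trace from TSV
#'
#' Accepts two columns (time, efficiency) or three (time, donor, acceptor);
#' in the three-column form efficiencies are computed from intensities.
#'
#' @param path TSV file with a header line.
#' @param R0 Forster radius, nm.
#' @param gamma detection-correction factor for the intensity form.
#' @return `fret_trace` tibble.
#' @export
read_fret_tsv <- function(path, R0 = 5, gamma = 1) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (ncol(df) == 2) {
    eff <- df[[2]]
  } else if (ncol(df) >= 3) {
    eff <- efficiency_from_intensities(df[[2]], df[[3]], gamma = gamma)
  } else {
    abort("FRET TSV needs (time, efficiency) or (time, donor, acceptor) columns")
  }
  fret_trace(df[[1]], as.double(eff), R0 = R0)
}

#' Power spectrum and spectral fit of FRET-derived distance series
#'
#' Each trace's efficiency series is converted to an inter-dye distance
#' series and fed through [power_spectrum()] and [fit_exponent()]. Traces of
#' equal length are bin-averaged first and fitted once; unequal-length
#' traces cannot share a frequency grid, so each is fitted separately and
#' the pooled mean and SD of beta are reported instead (flagged in the
#' result).
#'
#' @param traces one `fret_trace` or a list of them.
#' @param clamp efficiency clamp bounds before inversion.
#' @param f_min,f_max spectral fit window (defaults as in [fit_exponent()]).
#' @return list(spectrum, fit, beta_mean, beta_sd, per_trace, pooled_only).
#' @export
fret_power_spectrum <- function(traces, clamp = c(0.01, 0.99),
                                f_min = NULL, f_max = NULL) {
  if (is.data.frame(traces)) traces <- list(traces)
  dist_series <- lapply(traces, function(tr) {
    R0 <- attr(tr, "R0"); dt <- attr(tr, "dt")
    if (is.null(R0) || is.null(dt)) abort("trace lacks R0/dt; build it with fret_trace()")
    R <- distance_from_efficiency(tr$efficiency, R0 = R0, clamp = clamp)
    if (sd(R) == 0) abort("fit refused: constant trace has no spectral content")
    time_series(as.double(R), dt = dt)
  })
  lens <- vapply(dist_series, nrow, 1L)
  per_trace <- lapply(dist_series, function(s) {
    sp <- power_spectrum(s)
    list(spectrum = sp, fit = fit_exponent(sp, f_min, f_max))
  })
  betas <- vapply(per_trace, function(p) p$fit$beta, 1)
  if (length(unique(lens)) == 1) {
    avg <- average_spectra(lapply(per_trace, function(p) p$spectrum))
    fit <- fit_exponent(avg, f_min, f_max)
    list(spectrum = avg, fit = fit,
         beta_mean = mean(betas), beta_sd = sd(betas),
         per_trace = per_trace, pooled_only = FALSE)
  } else {
    warn("traces differ in length; reporting pooled per-trace fits only")
    list(spectrum = NULL, fit = NULL,
         beta_mean = mean(betas), beta_sd = sd(betas),
         per_trace = per_trace, pooled_only = TRUE)
  }
}

#' Mean FRET efficiency predicted from a simulated trajectory
#'
#' Mean over frames of the transfer efficiency at the center-of-mass
#' distance between two labeled residues -- the simulation-side counterpart
#' of the experimental mean efficiency.
#'
#' @param traj trajectory tibble.
#' @param i,j labeled residue indices (defaults: termini).
#' @param R0 Forster radius, nm.
#' @return scalar mean efficiency.
#' @export
mean_efficiency_from_trajectory <- function(traj, i = 1L, j = n_residues(traj), R0 = 5) {
  R <- end_to_end_series(traj, i, j)$value
  mean(efficiency_from_distance(R, R0 = R0))
}
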