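# Waveform analytics: cycle segmentation, per-cycle heart rate and
# amplitude, normalized pulse waveforms, integer-cycle spectra, and
# spline-based baseline estimation.

#' Detect pulse-cycle onsets (feet)
#'
#' The foot of each cycle is the local minimum preceding the steepest
#' systolic upstroke. Upstroke candidates are local maxima of the slope
#' above 30% of the global maximum slope, thinned greedily (largest slope
#' first) under a refractory window of `0.6 / f0_hint`; from each accepted
#' upstroke the algorithm walks back to the nearest local minimum and
#' refines it by parabolic interpolation. Detection is invariant to a
#' constant offset of the series.
#'
#' @param x signal series.
#' @param t time vector (uniform grid, same length).
#' @param f0_hint expected fundamental frequency (Hz).
#' @return Numeric vector of onset times (s), strictly increasing.
#' @export
detect_cycles <- function(x, t, f0_hint) {
  if (length(x) != length(t)) stop("`x` and `t` lengths differ",
                                   call. = FALSE)
  if (!is.finite(f0_hint) || f0_hint <= 0) {
    stop("`f0_hint` must be positive", call. = FALSE)
  }
  dt <- t[2] - t[1]
  if (diff(range(t)) < 3 / f0_hint) {
    stop("series must span at least 3 expected cycles", call. = FALSE)
  }
  n <- length(x)
  v <- c(0, (x[3:n] - x[1:(n - 2)]) / (2 * dt), 0) # centered slope
  vmax <- max(v)
  if (vmax <= 0) stop("no rising segment found", call. = FALSE)
  cand <- which(v > 0.3 * vmax)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[v[cand] >= v[cand - 1] & v[cand] >= v[cand + 1]] # local max
  if (!length(cand)) stop("cycle detection failed: no upstrokes",
                          call. = FALSE)
  refr <- 0.6 / f0_hint
  cand <- cand[order(v[cand], decreasing = TRUE)]
  accepted <- integer()
  for (i in cand) {
    if (!length(accepted) || all(abs(t[i] - t[accepted]) >= refr)) {
      accepted <- c(accepted, i)
    }
  }
  accepted <- sort(accepted)
  onsets <- numeric(0)
  for (i in accepted) {
    j <- i
    while (j > 1 && x[j - 1] <= x[j]) j <- j - 1
    if (j <= 1 || j >= n) next # foot truncated by the window edge
    # parabolic refinement through (j-1, j, j+1)
    d2 <- x[j - 1] - 2 * x[j] + x[j + 1]
    delta <- if (d2 > 0) 0.5 * (x[j - 1] - x[j + 1]) / d2 else 0
    delta <- max(-0.5, min(0.5, delta))
    onsets <- c(onsets, t[j] + delta * dt)
  }
  onsets <- sort(unique(onsets))
  if (length(onsets) >= 2) onsets <- onsets[c(TRUE, diff(onsets) > refr)]
  if (length(onsets) < 2) {
    stop("cycle detection failed: fewer than 2 onsets", call. = FALSE)
  }
  onsets
}

#' Per-cycle heart rate, amplitude and normalized waveform
#'
#' For consecutive onset pairs, computes the per-cycle heart rate
#' `60 / period` (bpm) and the foot-to-peak amplitude (cycle maximum minus
#' the value at the onset). Each cycle is additionally mapped to the unit
#' square (time and amplitude normalized to `[0, 1]`) and resampled to 200
#' points, giving the normalized arterial pulse waveform (APW).
#'
#' @param x signal series.
#' @param t time vector.
#' @param onsets onset times from [detect_cycles()], strictly increasing.
#' @return Object of class `cycle_metrics`: list with `onset_times`,
#'   `hr_per_cycle` (bpm), `amplitude_per_cycle`, and `apw_normalized`
#'   (200 x n_cycles matrix).
#' @export
hr_and_amplitude <- function(x, t, onsets) {
  if (length(onsets) < 2) stop("need at least 2 onsets", call. = FALSE)
  if (any(diff(onsets) <= 0)) stop("onsets must be strictly increasing",
                                   call. = FALSE)
  ncyc <- length(onsets) - 1L
  hr <- 60 / diff(onsets)
  amp <- numeric(ncyc)
  apw <- matrix(NA_real_, nrow = 200L, ncol = ncyc)
  u <- seq(0, 1, length.out = 200L)
  for (i in seq_len(ncyc)) {
    sel <- t >= onsets[i] & t <= onsets[i + 1]
    if (sum(sel) < 4) stop("cycle ", i, " has too few samples",
                           call. = FALSE)
    xi <- x[sel]; ti <- t[sel]
    x_on <- stats::approx(t, x, xout = onsets[i])$y
    amp[i] <- max(xi) - x_on
    tau <- (ti - onsets[i]) / (onsets[i + 1] - onsets[i])
    span <- max(xi) - min(xi)
    xn <- if (span > 0) (xi - min(xi)) / span else xi * 0
    apw[, i] <- stats::approx(tau, xn, xout = u, rule = 2)$y
  }
  structure(list(onset_times = onsets, hr_per_cycle = hr,
                 amplitude_per_cycle = amp, apw_normalized = apw),
            class = "cycle_metrics")
}

#' Integer-cycle magnitude spectrum with harmonic-band energy
#'
#' Computes the discrete Fourier spectrum over a window trimmed internally
#' to an integer number of fundamental periods, with a rectangular window,
#' so that harmonics of `f_C` fall on exact DFT bins. Reports the fraction
#' of spectral energy (DC bin excluded) within `+/- delta_f` of the first
#' `n_harmonics` harmonics, and the largest spectral peak below `f_C / 2`
#' (the signature of low-frequency baseline drift).
#'
#' @param x signal series.
#' @param dt sample interval (s).
#' @param f_C fundamental (heart-rate) frequency (Hz).
#' @param n_harmonics number of harmonic bands.
#' @param delta_f half-width of each harmonic band (Hz); default scales as
#'   `0.3 * f_C`.
#' @return Object of class `spectrum_report`: list with `frequency_hz`,
#'   `magnitude`, `energy`, `harmonic_band_energy_fraction`,
#'   `low_freq_peak` (list `frequency_hz`, `magnitude`), `n_used`.
#' @export
spectrum_report <- function(x, dt, f_C, n_harmonics = 10,
                            delta_f = 0.3 * f_C) {
  if (!is.finite(f_C) || f_C <= 0) stop("`f_C` must be positive",
                                        call. = FALSE)
  nper <- round(1 / (f_C * dt))
  ncyc <- floor(length(x) / nper)
  if (ncyc < 2) stop("window shorter than 2 fundamental periods",
                     call. = FALSE)
  n <- ncyc * nper
  xw <- x[seq_len(n)]
  X <- stats::fft(xw)
  nh <- floor(n / 2)
  freq <- (0:nh) / (n * dt)
  scale <- rep(2 / n, nh + 1L)
  scale[1] <- 1 / n
  if (n %% 2 == 0) scale[nh + 1L] <- 1 / n
  mag <- Mod(X[1:(nh + 1L)]) * scale
  energy <- Mod(X[1:(nh + 1L)])^2
  # double interior one-sided bins so sum(energy) = n * sum(xw^2) holds
  if (nh >= 2) {
    interior <- 2:(if (n %% 2 == 0) nh else nh + 1L)
    energy[interior] <- 2 * energy[interior]
  }
  tot <- sum(energy[-1]) # DC excluded
  inband <- rep(FALSE, nh + 1L)
  for (k in seq_len(n_harmonics)) {
    inband <- inband | abs(freq - k * f_C) <= delta_f
  }
  inband[1] <- FALSE
  frac <- if (tot > 0) sum(energy[inband]) / tot else 0
  low <- which(freq > 0 & freq < f_C / 2)
  low_peak <- if (length(low)) {
    i <- low[which.max(mag[low])]
    list(frequency_hz = freq[i], magnitude = mag[i])
  } else {
    list(frequency_hz = NA_real_, magnitude = NA_real_)
  }
  structure(list(frequency_hz = freq, magnitude = mag, energy = energy,
                 harmonic_band_energy_fraction = frac,
                 low_freq_peak = low_peak, n_used = n),
            class = "spectrum_report")
}

#' Spline-estimated baseline through cycle onsets
#'
#' The classical baseline estimator for pulse-type biosignals: a natural
#' cubic spline through the signal values at the cycle onsets, evaluated on
#' the full grid, held constant beyond the first and last onset. Useful for
#' showing that spline estimation does not recover the model's true
#' measured drift once TVSP distortion shifts the cycle feet.
#'
#' @param x signal series.
#' @param t time vector.
#' @param onsets onset times (>= 4, the spline needs 4 knots).
#' @return Numeric baseline series on `t`.
#' @export
cse_baseline <- function(x, t, onsets) {
  if (length(onsets) < 4) stop("need at least 4 onsets for the spline",
                               call. = FALSE)
  knots_y <- stats::approx(t, x, xout = onsets)$y
  sf <- stats::splinefun(onsets, knots_y, method = "natural")
  tc <- pmin(pmax(t, onsets[1]), onsets[length(onsets)])
  sf(tc)
}

rms <- function(x) sqrt(mean(x^2))

#' Motion-artifact distortion summary metrics
#'
#' Condenses a run into the headline motion-artifact metrics:
#' \itemize{
#' \item `baseline_attenuation`: `max|drift_measured| / max|z_b|` - how much
#'   smaller the drift in the measured signal is than the actual artifact;
#' \item `drift_trend_correlation`: correlation between the measured drift
#'   and `z_b` (negative when the measured drift opposes the artifact);
#' \item `hr_max_rel_dev_pct`: maximum per-cycle relative deviation of the
#'   measured heart rate from the MA-free heart rate, in percent;
#' \item `amp_max_rel_change_pct`: maximum per-cycle relative change of
#'   foot-to-peak amplitude vs the MA-free signal, in percent;
#' \item `tvsp_rms_ratio`: RMS of the TVSP distortion over RMS of the
#'   MA-free signal.
#' }
#' Cycle sequences of unequal length are aligned on their overlap with a
#' warning.
#'
#' @param measured a [compose_measured()] object.
#' @param metrics_free [hr_and_amplitude()] of the MA-free signal.
#' @param metrics_meas [hr_and_amplitude()] of the distorted signal.
#' @return Named list of metrics; `correlation_defined` flags whether the
#'   trend correlation could be computed (zero-MA runs report 0).
#' @export
ma_metrics <- function(measured, metrics_free, metrics_meas) {
  stopifnot(inherits(measured, "measured_signals"),
            inherits(metrics_free, "cycle_metrics"),
            inherits(metrics_meas, "cycle_metrics"))
  mode <- attr(measured, "mode")
  drift <- measured$drift_measured
  z_b <- measured$z_b
  x_free <- if (mode == "1dof") measured$x_C else measured$x2C
  x_tvsp <- if (mode == "1dof") measured$x_TVSP else measured$x2TVSP
  zmax <- max(abs(z_b))
  if (zmax > 0) {
    atten <- max(abs(drift)) / zmax
    corr <- stats::cor(drift, z_b)
    corr_def <- is.finite(corr)
    if (!corr_def) corr <- 0
  } else {
    atten <- 0; corr <- 0; corr_def <- FALSE
  }
  nf <- length(metrics_free$hr_per_cycle)
  nm <- length(metrics_meas$hr_per_cycle)
  ncyc <- min(nf, nm)
  if (nf != nm) {
    warning("cycle-count mismatch (", nf, " vs ", nm,
            "); metrics aligned on the first ", ncyc, " cycles",
            call. = FALSE)
  }
  hr_f <- metrics_free$hr_per_cycle[seq_len(ncyc)]
  hr_m <- metrics_meas$hr_per_cycle[seq_len(ncyc)]
  amp_f <- metrics_free$amplitude_per_cycle[seq_len(ncyc)]
  amp_m <- metrics_meas$amplitude_per_cycle[seq_len(ncyc)]
  list(
    baseline_attenuation = atten,
    drift_trend_correlation = corr,
    correlation_defined = corr_def,
    hr_max_rel_dev_pct = 100 * max(abs(hr_m - hr_f) / hr_f),
    amp_max_rel_change_pct = 100 * max(abs(amp_m - amp_f) / amp_f),
    tvsp_rms_ratio = if (rms(x_free) > 0) rms(x_tvsp) / rms(x_free) else 0,
    n_cycles = ncyc
  )
}
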