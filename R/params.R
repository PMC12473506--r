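# Stack parameters and synthetic input signals.

#' Tissue-contact-sensor stack parameters from dimensionless ratios
#'
#' Builds the physical parameters of the tissue-contact-sensor (TCS) stack
#' and the tactile sensor from the dimensionless ratios in which the model
#' is usually stated. The arterial-wall stiffness `kA` sets the stiffness
#' scale; everything else is derived:
#' \deqn{k_0 = (k_0/k_A)\,k_A,\quad \omega_0 = r_0\,\omega_C,\quad
#'       m_0 = k_0/\omega_0^2,}
#' \deqn{c_0 = 2\zeta_0\sqrt{k_0 m_0},\quad k_s = (k_s/k_0)\,k_0,\quad
#'       c_s = 2\zeta_s\sqrt{k_s m_0},}
#' where \eqn{\omega_C = 2\pi f_C} is the heart-rate angular frequency.
#' The joined mass \eqn{m_0} (tissue plus sensor microstructure) normalizes
#' both damping factors, including the sensor's.
#'
#' @param kA arterial-wall stiffness (stiffness units; sets the scale).
#' @param k0_over_kA ratio of stack stiffness to wall stiffness.
#' @param r0 nominal frequency ratio \eqn{\omega_0/\omega_C}.
#' @param zeta0 nominal damping factor of the stack.
#' @param ks_over_k0 ratio of sensor stiffness to stack stiffness.
#' @param zeta_s damping factor of the sensor (normalized by \eqn{m_0}).
#' @param heart_rate_hz heart-rate fundamental frequency \eqn{f_C} (Hz).
#' @return An object of class `stack_params`: a list with elements
#'   `m0`, `k0`, `c0`, `ks`, `cs`, `kA`, `omega_C`, `heart_rate_hz` and the
#'   stored ratios `r0`, `zeta0`, `zeta_s`, `k0_over_kA`, `ks_over_k0`.
#' @examples
#' p <- build_params()
#' p$k0            # 1/6
#' p$ks            # 1
#' stack_ratios(p) # recovers the inputs
#' @export
build_params <- function(kA = 1, k0_over_kA = 1 / 6, r0 = 2, zeta0 = 1.5,
                         ks_over_k0 = 6, zeta_s = 1.5, heart_rate_hz = 1) {
  args <- list(kA = kA, k0_over_kA = k0_over_kA, r0 = r0, zeta0 = zeta0,
               ks_over_k0 = ks_over_k0, zeta_s = zeta_s,
               heart_rate_hz = heart_rate_hz)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("`", nm, "` must be a single positive finite number", call. = FALSE)
    }
  }
  omega_C <- 2 * pi * heart_rate_hz
  k0 <- k0_over_kA * kA
  omega0 <- r0 * omega_C
  m0 <- k0 / omega0^2
  c0 <- 2 * zeta0 * sqrt(k0 * m0)
  ks <- ks_over_k0 * k0
  cs <- 2 * zeta_s * sqrt(ks * m0)
  structure(
    list(m0 = m0, k0 = k0, c0 = c0, ks = ks, cs = cs, kA = kA,
         omega_C = omega_C, heart_rate_hz = heart_rate_hz,
         r0 = r0, zeta0 = zeta0, zeta_s = zeta_s,
         k0_over_kA = k0_over_kA, ks_over_k0 = ks_over_k0),
    class = "stack_params"
  )
}

#' Recover the dimensionless ratios from stored stack parameters
#'
#' Computes `r0`, `zeta0` and `zeta_s` back from the physical parameters
#' (not from the stored inputs), so that the ratio -> parameter -> ratio
#' round trip can be checked.
#'
#' @param params a `stack_params` object.
#' @return Named list with `r0`, `zeta0`, `zeta_s`, `k0_over_kA`,
#'   `ks_over_k0`.
#' @export
stack_ratios <- function(params) {
  stopifnot(inherits(params, "stack_params"))
  omega0 <- sqrt(params$k0 / params$m0)
  list(
    r0 = omega0 / params$omega_C,
    zeta0 = params$c0 / (2 * sqrt(params$k0 * params$m0)),
    zeta_s = params$cs / (2 * sqrt(params$ks * params$m0)),
    k0_over_kA = params$k0 / params$kA,
    ks_over_k0 = params$ks / params$k0
  )
}

#' @export
print.stack_params <- function(x, ...) {
  cat("TCS stack parameters\n")
  cat(sprintf("  m0 = %.6g  k0 = %.6g  c0 = %.6g\n", x$m0, x$k0, x$c0))
  cat(sprintf("  ks = %.6g  cs = %.6g  kA = %.6g\n", x$ks, x$cs, x$kA))
  cat(sprintf("  heart rate = %.4g Hz (omega_C = %.6g rad/s)\n",
              x$heart_rate_hz, x$omega_C))
  cat(sprintf("  r0 = %.4g  zeta0 = %.4g  zeta_s = %.4g\n",
              x$r0, x$zeta0, x$zeta_s))
  invisible(x)
}

#' True pulse signal as a harmonic series
#'
#' The true pulse signal is a periodic signal at the heart-rate fundamental
#' \eqn{f_C} with a decaying harmonic envelope:
#' \deqn{s(t) = \sum_k A_k \cos(2\pi k f_C t + \phi_k).}
#' In `wall_displacement` mode the signal is the arterial wall displacement
#' \eqn{y(t)} (base excitation of the one-degree-of-freedom stack); in
#' `pulsatile_pressure` mode it is the pulsatile pressure \eqn{\Delta p(t)},
#' which acts on the arterial wall as the force
#' \eqn{F(t) = \pi a\,\Delta p(t)} with effective-area coefficient
#' `force_scale` \eqn{= \pi a}.
#'
#' @param fundamental_hz heart-rate fundamental frequency \eqn{f_C} (Hz).
#' @param amplitudes harmonic amplitudes \eqn{A_k} (displacement or
#'   pressure units), harmonic k at frequency `k * fundamental_hz`.
#' @param phases harmonic phases (rad); default all zero.
#' @param mode `"wall_displacement"` or `"pulsatile_pressure"`.
#' @param force_scale effective-area coefficient mapping pressure to force
#'   (pressure mode only).
#' @return Object of class `harmonic_pulse`.
#' @examples
#' canonical_pulse()
#' harmonic_pulse(1.2, amplitudes = c(1, 0.5), phases = c(0, -0.4))
#' @export
harmonic_pulse <- function(fundamental_hz, amplitudes, phases = NULL,
                           mode = c("wall_displacement", "pulsatile_pressure"),
                           force_scale = 1) {
  mode <- match.arg(mode)
  if (!is.numeric(fundamental_hz) || length(fundamental_hz) != 1L ||
      !is.finite(fundamental_hz) || fundamental_hz <= 0) {
    stop("`fundamental_hz` must be a single positive number", call. = FALSE)
  }
  if (length(amplitudes) < 1L) {
    stop("at least one harmonic amplitude is required", call. = FALSE)
  }
  if (any(!is.finite(amplitudes)) || any(amplitudes < 0)) {
    stop("`amplitudes` must be finite and non-negative", call. = FALSE)
  }
  if (is.null(phases)) phases <- rep(0, length(amplitudes))
  if (length(phases) != length(amplitudes)) {
    stop("`phases` must match `amplitudes` in length", call. = FALSE)
  }
  if (mode == "pulsatile_pressure" &&
      (!is.finite(force_scale) || force_scale <= 0)) {
    stop("`force_scale` must be positive in pulsatile_pressure mode",
         call. = FALSE)
  }
  structure(
    list(fundamental_hz = fundamental_hz,
         amplitudes = as.numeric(amplitudes),
         phases = as.numeric(phases),
         mode = mode, force_scale = force_scale),
    class = "harmonic_pulse"
  )
}

#' Motion-artifact displacement at the sensor substrate
#'
#' The motion artifact (MA) is a low-frequency displacement \eqn{z_b(t)} of
#' the sensor substrate, modelled as a finite sum of sinusoids:
#' \deqn{z_b(t) = \sum_i B_i \cos(2\pi f_i t + \phi_i).}
#' An empty component list describes an MA-free measurement.
#'
#' @param amplitudes component amplitudes \eqn{B_i} (displacement units).
#' @param frequencies_hz component frequencies (Hz), all positive.
#' @param phases component phases (rad); default zero.
#' @return Object of class `ma_signal`.
#' @examples
#' ma_signal()                                   # MA-free
#' ma_signal(c(2, 0.8), c(0.10, 0.23), c(0, 0.8)) # canonical drift
#' @export
ma_signal <- function(amplitudes = numeric(), frequencies_hz = numeric(),
                      phases = NULL) {
  if (length(amplitudes) != length(frequencies_hz)) {
    stop("`amplitudes` and `frequencies_hz` must have equal length",
         call. = FALSE)
  }
  if (is.null(phases)) phases <- rep(0, length(amplitudes))
  if (length(phases) != length(amplitudes)) {
    stop("`phases` must match `amplitudes` in length", call. = FALSE)
  }
  if (length(frequencies_hz) && (any(!is.finite(frequencies_hz)) ||
                                 any(frequencies_hz <= 0))) {
    stop("`frequencies_hz` must be positive", call. = FALSE)
  }
  if (length(amplitudes) && (any(!is.finite(amplitudes)) ||
                             any(amplitudes < 0))) {
    stop("`amplitudes` must be finite and non-negative", call. = FALSE)
  }
  structure(
    list(amplitudes = as.numeric(amplitudes),
         frequencies_hz = as.numeric(frequencies_hz),
         phases = as.numeric(phases)),
    class = "ma_signal"
  )
}

#' Uniform time grid
#'
#' @param t0 start time (s).
#' @param t_end end time (s).
#' @param dt sample interval (s).
#' @return Object of class `time_grid` with the sample vector `t`.
#' @export
time_grid <- function(t0 = 0, t_end = 12, dt = 1e-3) {
  if (!is.finite(dt) || dt <= 0) stop("`dt` must be positive", call. = FALSE)
  if (!is.finite(t_end) || t_end <= t0) {
    stop("`t_end` must exceed `t0`", call. = FALSE)
  }
  n <- round((t_end - t0) / dt) + 1L
  structure(list(t0 = t0, t_end = t_end, dt = dt,
                 t = t0 + dt * (seq_len(n) - 1L)),
            class = "time_grid")
}

# Evaluate sum_k A_k cos(w_k t + phi_k) or its time derivatives (closed
# form, no numerical differentiation). deriv 0, 1 or 2.
harmonic_sum <- function(amplitudes, omegas, phases, t, deriv = 0L) {
  out <- numeric(length(t))
  for (i in seq_along(amplitudes)) {
    A <- amplitudes[i]; w <- omegas[i]; ph <- phases[i]
    out <- out + switch(as.character(deriv),
      "0" = A * cos(w * t + ph),
      "1" = -A * w * sin(w * t + ph),
      "2" = -A * w^2 * cos(w * t + ph),
      stop("`deriv` must be 0, 1 or 2", call. = FALSE))
  }
  out
}

check_nyquist <- function(max_freq_hz, grid, what) {
  if (max_freq_hz >= 1 / (2 * grid$dt)) {
    stop("highest ", what, " frequency (", max_freq_hz,
         " Hz) is not below the Nyquist frequency 1/(2 dt) = ",
         1 / (2 * grid$dt), " Hz", call. = FALSE)
  }
  invisible(TRUE)
}

#' Evaluate the true pulse signal on a time grid
#'
#' Synthesizes \eqn{s(t) = \sum_k A_k \cos(2\pi k f_C t + \phi_k)} (or its
#' exact time derivative) on a uniform grid. Sampling adequacy is enforced:
#' the highest harmonic frequency must lie below the Nyquist frequency.
#'
#' @param pulse a [harmonic_pulse()] object.
#' @param grid a [time_grid()] object.
#' @param deriv derivative order 0, 1 or 2 (closed form).
#' @return Numeric vector on `grid$t`.
#' @export
eval_pulse <- function(pulse, grid, deriv = 0L) {
  stopifnot(inherits(pulse, "harmonic_pulse"), inherits(grid, "time_grid"))
  k <- seq_along(pulse$amplitudes)
  check_nyquist(max(k) * pulse$fundamental_hz, grid, "pulse harmonic")
  harmonic_sum(pulse$amplitudes, 2 * pi * k * pulse$fundamental_hz,
               pulse$phases, grid$t, deriv)
}

#' Evaluate the pulse force on a time grid (pressure mode)
#'
#' In `pulsatile_pressure` mode the pressure translates to the force
#' \eqn{F(t) = \pi a\,\Delta p(t)} on the arterial wall; `force_scale`
#' holds \eqn{\pi a}.
#'
#' @inheritParams eval_pulse
#' @return Numeric force series on `grid$t`.
#' @export
eval_pulse_force <- function(pulse, grid, deriv = 0L) {
  stopifnot(inherits(pulse, "harmonic_pulse"))
  if (pulse$mode != "pulsatile_pressure") {
    stop("`eval_pulse_force` requires a pulsatile_pressure pulse",
         call. = FALSE)
  }
  pulse$force_scale * eval_pulse(pulse, grid, deriv)
}

#' Evaluate the motion-artifact displacement on a time grid
#'
#' @param ma a [ma_signal()] object.
#' @param grid a [time_grid()] object.
#' @param deriv derivative order 0, 1 or 2 (closed form).
#' @return Numeric vector on `grid$t`; identically zero if `ma` has no
#'   components.
#' @export
eval_ma <- function(ma, grid, deriv = 0L) {
  stopifnot(inherits(ma, "ma_signal"), inherits(grid, "time_grid"))
  if (!length(ma$amplitudes)) return(numeric(length(grid$t)))
  check_nyquist(max(ma$frequencies_hz), grid, "MA component")
  harmonic_sum(ma$amplitudes, 2 * pi * ma$frequencies_hz, ma$phases,
               grid$t, deriv)
}

#' Canonical true pulse signal
#'
#' A ten-harmonic pulse with a monotonically decaying harmonic envelope
#' typical of carotid arterial pulse waveforms: relative amplitudes
#' `c(1, 0.55, 0.32, 0.18, 0.10, 0.055, 0.03, 0.018, 0.01, 0.006)` scaled
#' by `a1`, phases \eqn{\phi_k = -0.4 (k-1)} rad, fundamental
#' `fundamental_hz` (default 1 Hz, i.e. 60 bpm).
#'
#' @param fundamental_hz heart rate (Hz).
#' @param a1 first-harmonic amplitude (sets the displacement/pressure unit).
#' @param mode signal mode, as in [harmonic_pulse()].
#' @param force_scale effective-area coefficient (pressure mode).
#' @return A [harmonic_pulse()] object.
#' @export
canonical_pulse <- function(fundamental_hz = 1, a1 = 1,
                            mode = c("wall_displacement",
                                     "pulsatile_pressure"),
                            force_scale = 1) {
  rel <- c(1, 0.55, 0.32, 0.18, 0.10, 0.055, 0.03, 0.018, 0.01, 0.006)
  harmonic_pulse(fundamental_hz, a1 * rel,
                 phases = -0.4 * (seq_along(rel) - 1),
                 mode = match.arg(mode), force_scale = force_scale)
}

#' Canonical motion-artifact scenario
#'
#' Two low-frequency components, larger than the pulse itself:
#' amplitudes `c(2, 0.8) * a1` at 0.10 and 0.23 Hz with phases 0 and
#' 0.8 rad. MA concentrated well below the heart rate and exceeding the
#' pulse amplitude reflects the premise that the artifact is larger than
#' the drift it leaves in the measured signal.
#'
#' @param a1 pulse first-harmonic amplitude the MA is scaled against.
#' @return An [ma_signal()] object.
#' @export
canonical_ma <- function(a1 = 1) {
  ma_signal(amplitudes = a1 * c(2, 0.8),
            frequencies_hz = c(0.10, 0.23),
            phases = c(0, 0.8))
}
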