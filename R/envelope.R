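# Instantaneous amplitude, phase and frequency via the analytic signal.

# Analytic signal by the FFT half-spectrum construction: doubles positive
# frequencies, zeroes negative ones (DC and Nyquist kept once). Equivalent
# to x + j*H[x] with H the Hilbert transform. Callers pad-and-taper first:
# the raw construction has O(1/(2 f T)) envelope ripple for finite tones.
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Instantaneous amplitude, phase and frequency of a signal
#'
#' Builds the analytic signal of a (near-)zero-mean series and returns its
#' modulus (instantaneous amplitude), unwrapped argument (instantaneous
#' phase) and the phase derivative (instantaneous angular frequency). The
#' series is detrended by its mean and mirror-padded by half its length on
#' each side, with a raised-cosine taper on the padded extensions so the
#' circular FFT wrap is smooth (this suppresses both edge effects and the
#' spectral-leakage envelope ripple of finite off-bin tones). The unwrapped
#' phase is smoothed with a 5-point Savitzky-Golay filter before centered
#' differencing. The first and last 5% of samples are flagged
#' edge-unreliable.
#'
#' @param x numeric series (length >= 16, not constant).
#' @param dt sample interval (s).
#' @return List with `amplitude`, `phase` (rad, unwrapped), `omega`
#'   (rad/s), and logical `edge` marking edge-unreliable samples.
#' @export
instantaneous_envelope <- function(x, dt) {
  if (length(x) < 16L) stop("series too short (need >= 16 samples)",
                            call. = FALSE)
  if (!is.finite(dt) || dt <= 0) stop("`dt` must be positive", call. = FALSE)
  xc <- x - mean(x)
  if (max(abs(xc)) == 0) {
    stop("constant series: instantaneous phase undefined", call. = FALSE)
  }
  n <- length(xc)
  p <- max(8L, floor(n / 2))
  p <- min(p, n - 1L)
  # even (mirror) reflection padding, tapered to zero at the array ends
  xp <- c(rev(xc[2:(p + 1L)]), xc, rev(xc[(n - p):(n - 1L)]))
  ramp <- 0.5 * (1 - cos(pi * seq_len(p) / (p + 1)))
  xp[seq_len(p)] <- xp[seq_len(p)] * ramp
  m <- length(xp)
  xp[(m - p + 1L):m] <- xp[(m - p + 1L):m] * rev(ramp)
  xa <- analytic_signal(xp)[(p + 1L):(p + n)]
  amp <- Mod(xa)
  phase <- signal::unwrap(Arg(xa))
  phs <- if (n >= 7L) signal::sgolayfilt(phase, p = 2, n = 5) else phase
  omega <- numeric(n)
  omega[2:(n - 1L)] <- (phs[3:n] - phs[1:(n - 2L)]) / (2 * dt)
  omega[1] <- (phs[2] - phs[1]) / dt
  omega[n] <- (phs[n] - phs[n - 1L]) / dt
  edge <- rep(FALSE, n)
  ne <- max(1L, floor(0.05 * n))
  edge[seq_len(ne)] <- TRUE
  edge[(n - ne + 1L):n] <- TRUE
  list(amplitude = amp, phase = phase, omega = omega, edge = edge)
}
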