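# Time-varying-system-parameter (TVSP) dynamics: baseline drift, coupling
# law, time-domain integration of the modified equations of motion, and
# composition of the measured signals.

#' Baseline drift induced by motion artifacts
#'
#' Substrate motion \eqn{z_b(t)} drives the stack through the sensor spring
#' and damper, producing the drift displacement \eqn{x_b(t)} at the mass
#' (1DOF) or the pair \eqn{x_{1b}, x_{2b}} at wall and mass (2DOF). Because
#' \eqn{z_b} is a finite sum of sinusoids, the steady-state response is
#' computed exactly by per-component harmonic gains (the default); an ODE
#' route is retained for cross-validation.
#'
#' The returned `drift` channel is the displacement that modulates the
#' stack parameters: \eqn{x_b} in 1DOF mode, \eqn{x_{2b} - x_{1b}} (the
#' stretch of the stack) in 2DOF mode.
#'
#' @param params a [build_params()] object.
#' @param ma a [ma_signal()] object.
#' @param grid a [time_grid()] object.
#' @param mode `"1dof"` or `"2dof"`.
#' @param method `"closed_form"` (exact steady state, default) or `"ode"`
#'   (numerical integration from the closed-form initial state).
#' @param solver solver options for the ODE route (`rtol`, `atol`).
#' @return 1DOF: list `x_b`, `dx_b`, `drift`, `ddrift`. 2DOF: list `x1b`,
#'   `dx1b`, `x2b`, `dx2b`, `drift`, `ddrift`.
#' @export
simulate_baseline <- function(params, ma, grid, mode = c("1dof", "2dof"),
                              method = c("closed_form", "ode"),
                              solver = list(rtol = 1e-8, atol = 1e-10)) {
  mode <- match.arg(mode); method <- match.arg(method)
  stopifnot(inherits(params, "stack_params"), inherits(ma, "ma_signal"),
            inherits(grid, "time_grid"))
  if (mode == "2dof") check_2dof(params)
  n <- length(grid$t)
  if (!length(ma$amplitudes)) {
    zero <- numeric(n)
    return(if (mode == "1dof") {
      list(x_b = zero, dx_b = zero, drift = zero, ddrift = zero)
    } else {
      list(x1b = zero, dx1b = zero, x2b = zero, dx2b = zero,
           drift = zero, ddrift = zero)
    })
  }
  omegas <- 2 * pi * ma$frequencies_hz
  check_nyquist(max(ma$frequencies_hz), grid, "MA component")
  res <- if (mode == "1dof") {
    g <- gain_baseline_1dof(params, omegas)
    x_b <- superpose(ma$amplitudes, omegas, ma$phases, g, grid$t, 0L)
    dx_b <- superpose(ma$amplitudes, omegas, ma$phases, g, grid$t, 1L)
    list(x_b = x_b, dx_b = dx_b, drift = x_b, ddrift = dx_b)
  } else {
    g <- gains_2dof_baseline(params, omegas)
    x1b <- superpose(ma$amplitudes, omegas, ma$phases, g$wall, grid$t, 0L)
    dx1b <- superpose(ma$amplitudes, omegas, ma$phases, g$wall, grid$t, 1L)
    x2b <- superpose(ma$amplitudes, omegas, ma$phases, g$mass, grid$t, 0L)
    dx2b <- superpose(ma$amplitudes, omegas, ma$phases, g$mass, grid$t, 1L)
    list(x1b = x1b, dx1b = dx1b, x2b = x2b, dx2b = dx2b,
         drift = x2b - x1b, ddrift = dx2b - dx1b)
  }
  if (method == "ode") res <- baseline_ode(params, ma, grid, mode, res, solver)
  res
}

# ODE cross-validation route for the baseline drift: integrates the same
# equations numerically, starting from the closed-form steady state so no
# transient is introduced. Replaces the displacement channels.
baseline_ode <- function(params, ma, grid, mode, cf, solver) {
  zf <- function(t, d = 0L) {
    harmonic_sum(ma$amplitudes, 2 * pi * ma$frequencies_hz, ma$phases, t, d)
  }
  p <- params
  if (mode == "1dof") {
    rhs <- function(t, y, parms) {
      a <- (p$ks * zf(t) + p$cs * zf(t, 1L) - (p$c0 + p$cs) * y[2] -
              (p$k0 + p$ks) * y[1]) / p$m0
      list(c(y[2], a))
    }
    out <- deSolve::ode(c(x = cf$x_b[1], v = cf$dx_b[1]), grid$t, rhs, NULL,
                        rtol = solver$rtol, atol = solver$atol)
    cf$x_b <- as.numeric(out[, "x"]); cf$dx_b <- as.numeric(out[, "v"])
    cf$drift <- cf$x_b; cf$ddrift <- cf$dx_b
  } else {
    # states: x1, x2, v2; dx1 from the (massless-wall) first equation
    rhs <- function(t, y, parms) {
      dx1 <- y[3] + (-(p$kA + p$k0) * y[1] + p$k0 * y[2]) / p$c0
      a2 <- (p$k0 * y[1] + p$c0 * dx1 - (p$k0 + p$ks) * y[2] -
               (p$c0 + p$cs) * y[3] + p$ks * zf(t) + p$cs * zf(t, 1L)) / p$m0
      list(c(dx1, y[3], a2), dx1 = unname(dx1))
    }
    out <- deSolve::ode(c(x1 = cf$x1b[1], x2 = cf$x2b[1], v2 = cf$dx2b[1]),
                        grid$t, rhs, NULL,
                        rtol = solver$rtol, atol = solver$atol)
    cf$x1b <- as.numeric(out[, "x1"]); cf$dx1b <- as.numeric(out[, "dx1"])
    cf$x2b <- as.numeric(out[, "x2"]); cf$dx2b <- as.numeric(out[, "v2"])
    cf$drift <- cf$x2b - cf$x1b; cf$ddrift <- cf$dx2b - cf$dx1b
  }
  cf
}

#' TVSP coupling law
#'
#' The stack parameters are modulated proportionally to the MA-induced
#' drift displacement. The law is linear with peak fractional modulations
#' `kappa_m`, `kappa_c`, `kappa_k` normalized by a reference displacement
#' `x_ref` (default: the peak absolute drift over the analyzed window), so
#' e.g. \eqn{k(t) = \kappa_k\,k_0\,d(t)/x_\mathrm{ref}} reaches a
#' \eqn{\kappa_k} fractional change of stiffness at peak drift.
#'
#' @param kappa_m,kappa_c,kappa_k peak fractional modulations (>= 0).
#' @param x_ref reference displacement; `NULL` means the peak absolute
#'   drift of the series the coupling is applied to.
#' @return Object of class `tvsp_coupling`.
#' @export
tvsp_coupling <- function(kappa_m = 0.05, kappa_c = 0.05, kappa_k = 0.05,
                          x_ref = NULL) {
  for (v in c(kappa_m, kappa_c, kappa_k)) {
    if (!is.finite(v) || v < 0) {
      stop("coupling fractions must be finite and non-negative",
           call. = FALSE)
    }
  }
  if (!is.null(x_ref) && (!is.finite(x_ref) || x_ref <= 0)) {
    stop("`x_ref` must be positive when given", call. = FALSE)
  }
  structure(list(kappa_m = kappa_m, kappa_c = kappa_c, kappa_k = kappa_k,
                 x_ref = x_ref), class = "tvsp_coupling")
}

#' Time-varying stack parameters from the drift displacement
#'
#' Applies the linear coupling law to a drift series and derives the
#' instantaneous frequency ratio \eqn{r(t)}, damping factor \eqn{\zeta(t)}
#' and total frequency ratio \eqn{r_\mathrm{total}(t)}:
#' \deqn{r(t) = \sqrt{(k_0+k(t))/(m_0+m(t))}/\omega_C,\qquad
#'   \zeta(t) = (c_0+c(t))/(2\sqrt{(k_0+k(t))(m_0+m(t))}).}
#' \eqn{r_\mathrm{total}} additionally accounts for the sensor stiffness
#' (1DOF: \eqn{k_0+k(t)+k_s} in the numerator) and, in 2DOF mode, for the
#' arterial wall: by default \eqn{k_A} is combined in series with the stack
#' spring (the load path wall-spring -> stack-spring seen from the mass),
#' switchable to the parallel variant.
#'
#' Modulations are clamped so each total parameter stays above 5% of its
#' nominal value; activation raises a warning.
#'
#' @param coupling a [tvsp_coupling()] object.
#' @param drift drift displacement series on the working grid (\eqn{x_b}
#'   in 1DOF mode, \eqn{x_{2b}-x_{1b}} in 2DOF mode).
#' @param params a [build_params()] object.
#' @param mode `"1dof"` or `"2dof"` (selects the `r_total` definition).
#' @param kA_total `"series"` or `"parallel"` combination of `kA` in the
#'   2DOF `r_total`.
#' @return Object of class `tvsp_series`: list with `m_t`, `c_t`, `k_t`,
#'   `r_t`, `zeta_t`, `r_total_t`, `x_ref`, `clamped`.
#' @export
tvsp_from_drift <- function(coupling, drift, params, mode = c("1dof", "2dof"),
                            kA_total = c("series", "parallel")) {
  mode <- match.arg(mode); kA_total <- match.arg(kA_total)
  stopifnot(inherits(coupling, "tvsp_coupling"),
            inherits(params, "stack_params"), is.numeric(drift))
  x_ref <- coupling$x_ref
  if (is.null(x_ref)) x_ref <- max(abs(drift))
  any_kappa <- coupling$kappa_m > 0 || coupling$kappa_c > 0 ||
    coupling$kappa_k > 0
  if (x_ref == 0) {
    if (any_kappa && any(drift != 0)) {
      stop("`x_ref` is zero but coupling is nonzero", call. = FALSE)
    }
    x_ref <- 1 # zero drift: modulations are identically zero
  }
  u <- drift / x_ref
  m_t <- coupling$kappa_m * params$m0 * u
  c_t <- coupling$kappa_c * params$c0 * u
  k_t <- coupling$kappa_k * params$k0 * u
  # hard floor: total parameters never drop below 5% of nominal
  clamped <- FALSE
  floor_clip <- function(total, nominal) {
    lo <- 0.05 * nominal
    if (any(total < lo)) {
      clamped <<- TRUE
      total <- pmax(total, lo)
    }
    total
  }
  m_tot <- floor_clip(params$m0 + m_t, params$m0)
  c_tot <- floor_clip(params$c0 + c_t, params$c0)
  k_tot <- floor_clip(params$k0 + k_t, params$k0)
  if (clamped) {
    warning("TVSP modulation clamped at 5% of nominal parameters",
            call. = FALSE)
  }
  m_t <- m_tot - params$m0; c_t <- c_tot - params$c0; k_t <- k_tot - params$k0
  r_t <- sqrt(k_tot / m_tot) / params$omega_C
  zeta_t <- c_tot / (2 * sqrt(k_tot * m_tot))
  k_total <- if (mode == "1dof") {
    k_tot + params$ks
  } else if (kA_total == "series") {
    params$ks + k_tot * params$kA / (k_tot + params$kA)
  } else {
    params$ks + k_tot + params$kA
  }
  r_total_t <- sqrt(k_total / m_tot) / params$omega_C
  structure(list(m_t = m_t, c_t = c_t, k_t = k_t,
                 r_t = r_t, zeta_t = zeta_t, r_total_t = r_total_t,
                 x_ref = x_ref, clamped = clamped, mode = mode),
            class = "tvsp_series")
}

#' Integrate the equations of motion with time-varying stack parameters
#'
#' Time-domain solution of the measured displacement under TVSP. In 1DOF
#' mode the state is \eqn{(x_M, \dot x_M)} with forcing
#' \eqn{(k_0+k(t))y + (c_0+c(t))\dot y}; in 2DOF mode the state is
#' \eqn{(x_1, x_2, \dot x_2)} and \eqn{\dot x_1} follows algebraically from
#' the massless wall equation. The TVSP series are interpolated with cubic
#' splines (their variation is slow relative to the heart rate); the pulse
#' forcing is evaluated in closed form inside the right-hand side. Initial
#' conditions are the MA-free closed-form steady state at `t0`, so startup
#' transients reflect only the TVSP perturbation.
#'
#' @param params a [build_params()] object.
#' @param pulse a [harmonic_pulse()] object; its mode must match the TVSP
#'   series' mode (`wall_displacement` with `"1dof"`).
#' @param tvsp a [tvsp_from_drift()] object on the same grid.
#' @param grid a [time_grid()] object.
#' @param solver list of solver options `rtol`, `atol` (adaptive lsoda,
#'   dense output sampled onto the grid).
#' @return 1DOF: list `x_M`, `dx_M`, `ddx_M`. 2DOF: list `x1M`, `dx1M`,
#'   `x2M`, `dx2M`, `ddx2M`.
#' @export
simulate_tvsp <- function(params, pulse, tvsp, grid,
                          solver = list(rtol = 1e-8, atol = 1e-10)) {
  stopifnot(inherits(params, "stack_params"),
            inherits(pulse, "harmonic_pulse"),
            inherits(tvsp, "tvsp_series"), inherits(grid, "time_grid"))
  if (!is.finite(solver$rtol) || solver$rtol <= 0 ||
      !is.finite(solver$atol) || solver$atol <= 0) {
    stop("solver tolerances must be positive", call. = FALSE)
  }
  n <- length(grid$t)
  if (length(tvsp$m_t) != n) {
    stop("TVSP series and grid lengths differ", call. = FALSE)
  }
  mode <- if (pulse$mode == "wall_displacement") "1dof" else "2dof"
  if (mode != tvsp$mode) {
    stop("pulse mode (", pulse$mode, ") does not match TVSP mode (",
         tvsp$mode, ")", call. = FALSE)
  }
  p <- params
  mf <- stats::splinefun(grid$t, tvsp$m_t, method = "fmm")
  cf <- stats::splinefun(grid$t, tvsp$c_t, method = "fmm")
  kf <- stats::splinefun(grid$t, tvsp$k_t, method = "fmm")
  kharm <- seq_along(pulse$amplitudes)
  omegas <- 2 * pi * kharm * pulse$fundamental_hz
  free <- measured_free(params, pulse, grid)
  if (mode == "1dof") {
    rhs <- function(t, y, parms) {
      kk <- p$k0 + kf(t); cc <- p$c0 + cf(t); mm <- p$m0 + mf(t)
      yt <- harmonic_sum(pulse$amplitudes, omegas, pulse$phases, t, 0L)
      dyt <- harmonic_sum(pulse$amplitudes, omegas, pulse$phases, t, 1L)
      a <- (kk * yt + cc * dyt - (cc + p$cs) * y[2] - (kk + p$ks) * y[1]) / mm
      list(c(y[2], a), acc = unname(a))
    }
    y0 <- c(x = free$x_C[1], v = free$dx_C[1])
    out <- run_ode(y0, grid$t, rhs, solver)
    list(x_M = as.numeric(out[, "x"]), dx_M = as.numeric(out[, "v"]),
         ddx_M = as.numeric(out[, "acc"]))
  } else {
    famp <- pulse$force_scale * pulse$amplitudes
    rhs <- function(t, y, parms) {
      kk <- p$k0 + kf(t); cc <- p$c0 + cf(t); mm <- p$m0 + mf(t)
      ft <- harmonic_sum(famp, omegas, pulse$phases, t, 0L)
      dx1 <- y[3] + (ft - (p$kA + kk) * y[1] + kk * y[2]) / cc
      a2 <- (kk * y[1] + cc * dx1 - (kk + p$ks) * y[2] -
               (cc + p$cs) * y[3]) / mm
      list(c(dx1, y[3], a2), dx1 = unname(dx1), acc = unname(a2))
    }
    y0 <- c(x1 = free$x1C[1], x2 = free$x2C[1], v2 = free$dx2C[1])
    out <- run_ode(y0, grid$t, rhs, solver)
    list(x1M = as.numeric(out[, "x1"]), dx1M = as.numeric(out[, "dx1"]),
         x2M = as.numeric(out[, "x2"]), dx2M = as.numeric(out[, "v2"]),
         ddx2M = as.numeric(out[, "acc"]))
  }
}

run_ode <- function(y0, times, rhs, solver) {
  out <- deSolve::ode(y0, times, rhs, NULL, method = "lsoda",
                      rtol = solver$rtol, atol = solver$atol)
  if (nrow(out) < length(times)) {
    stop("ODE solver failed at t = ", out[nrow(out), 1],
         "; see deSolve diagnostics", call. = FALSE)
  }
  out
}

#' Compose the measured signals and MA distortion terms
#'
#' Assembles all displacement channels of a run and forms the composition
#' identities of the model: the TVSP distortion is the difference between
#' the TVSP solution and the MA-free solution, the tactile output is the
#' TVSP solution plus the measured drift,
#' \deqn{x_\mathrm{TVSP} = x_M - x_C,\qquad
#'   x_\mathrm{tactile} = x_M + x_b - z_b,\qquad
#'   x_\mathrm{tactile,MA} = x_\mathrm{TVSP} + x_b - z_b,}
#' and in 2DOF mode additionally the wall channel
#' \eqn{x_\mathrm{wall} = x_{1M} + x_{1b}} with distortion
#' \eqn{x_\mathrm{wall,MA} = x_{1TVSP} + x_{1b}}. The identities are
#' asserted to 1e-10 after composition.
#'
#' @param params a [build_params()] object.
#' @param pulse a [harmonic_pulse()] object.
#' @param ma a [ma_signal()] object.
#' @param grid a [time_grid()] object.
#' @param baseline output of [simulate_baseline()].
#' @param tvsp_sim output of [simulate_tvsp()].
#' @param free output of [measured_free()].
#' @return Object of class `measured_signals` carrying all aligned series
#'   (including derivative channels needed by [force_tvsp()]), with
#'   attributes `mode` and `t`.
#' @export
compose_measured <- function(params, pulse, ma, grid, baseline, tvsp_sim,
                             free) {
  stopifnot(inherits(grid, "time_grid"))
  n <- length(grid$t)
  lens <- vapply(c(baseline, tvsp_sim, free), length, integer(1))
  if (any(lens != n)) stop("component series are not on one grid",
                           call. = FALSE)
  z_b <- eval_ma(ma, grid, 0L)
  dz_b <- eval_ma(ma, grid, 1L)
  mode <- if (pulse$mode == "wall_displacement") "1dof" else "2dof"
  sig <- if (mode == "1dof") {
    x_TVSP <- tvsp_sim$x_M - free$x_C
    list(
      t = grid$t,
      y = eval_pulse(pulse, grid, 0L), dy = eval_pulse(pulse, grid, 1L),
      z_b = z_b, dz_b = dz_b,
      x_C = free$x_C, dx_C = free$dx_C,
      x_b = baseline$x_b, dx_b = baseline$dx_b,
      x_M = tvsp_sim$x_M, dx_M = tvsp_sim$dx_M, ddx_M = tvsp_sim$ddx_M,
      x_TVSP = x_TVSP,
      drift_measured = baseline$x_b - z_b,
      x_tactile = tvsp_sim$x_M + baseline$x_b - z_b,
      x_tactile_MA = x_TVSP + baseline$x_b - z_b
    )
  } else {
    x1TVSP <- tvsp_sim$x1M - free$x1C
    x2TVSP <- tvsp_sim$x2M - free$x2C
    list(
      t = grid$t,
      force = free$force, dforce = free$dforce,
      z_b = z_b, dz_b = dz_b,
      x1C = free$x1C, dx1C = free$dx1C,
      x2C = free$x2C, dx2C = free$dx2C,
      x1b = baseline$x1b, dx1b = baseline$dx1b,
      x2b = baseline$x2b, dx2b = baseline$dx2b,
      x1M = tvsp_sim$x1M, dx1M = tvsp_sim$dx1M,
      x2M = tvsp_sim$x2M, dx2M = tvsp_sim$dx2M, ddx2M = tvsp_sim$ddx2M,
      x1TVSP = x1TVSP, x2TVSP = x2TVSP,
      drift_measured = baseline$x2b - z_b,
      drift_tvsp = baseline$x2b - baseline$x1b,
      x_tactile = tvsp_sim$x2M + baseline$x2b - z_b,
      x_wall = tvsp_sim$x1M + baseline$x1b,
      x_tactile_MA = x2TVSP + baseline$x2b - z_b,
      x_wall_MA = x1TVSP + baseline$x1b
    )
  }
  # composition identities (constructive; asserted as a guard)
  tol <- 1e-10 * max(1, max(abs(sig$x_tactile)))
  ok <- if (mode == "1dof") {
    max(abs(sig$x_TVSP - (sig$x_M - sig$x_C))) <= tol &&
      max(abs(sig$x_tactile - (sig$x_M + sig$x_b - sig$z_b))) <= tol &&
      max(abs(sig$x_tactile_MA - (sig$x_TVSP + sig$x_b - sig$z_b))) <= tol
  } else {
    max(abs(sig$x_tactile - (sig$x2M + sig$x2b - sig$z_b))) <= tol &&
      max(abs(sig$x_wall - (sig$x1M + sig$x1b))) <= tol &&
      max(abs(sig$x_tactile_MA - (sig$x2TVSP + sig$x2b - sig$z_b))) <= tol &&
      max(abs(sig$x_wall_MA - (sig$x1TVSP + sig$x1b))) <= tol
  }
  if (!ok) stop("internal error: composition identities violated",
                call. = FALSE)
  structure(sig, class = "measured_signals", mode = mode)
}

#' @export
print.measured_signals <- function(x, ...) {
  cat("measured_signals (", attr(x, "mode"), "), ",
      length(x$t), " samples on [", x$t[1], ", ", x$t[length(x$t)],
      "] s\n", sep = "")
  cat("channels:", paste(setdiff(names(x), "t"), collapse = ", "), "\n")
  invisible(x)
}
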