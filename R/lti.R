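# Closed-form frequency responses of the nominal (time-invariant) system
# and MA-free measured signals.
#
# 1DOF (wall-displacement input): the stack mass m0 sits between the
# arterial wall (k0, c0) and the sensor substrate (ks, cs); both walls can
# move (base excitation on either side).
# 2DOF (pulsatile-pressure input): the arterial wall is itself a spring kA
# driven by the pulse force F(t); x1 is the wall displacement, x2 the mass.

# Characteristic denominator of the 1DOF system at angular frequency w.
den_1dof <- function(params, w) {
  -params$m0 * w^2 + 1i * w * (params$c0 + params$cs) + params$k0 + params$ks
}

#' Harmonic gain from arterial-wall displacement to the stack mass (1DOF)
#'
#' The complex transmissibility
#' \deqn{G_0(\omega) = \frac{k_0 + j\omega c_0}
#'   {-m_0\omega^2 + j\omega(c_0+c_s) + k_0 + k_s}}
#' mapping a wall-displacement harmonic \eqn{y_0 e^{j\omega t}} to the mass
#' displacement. Applied per harmonic it gives the MA-free measured signal
#' \eqn{x_C(t)}. At \eqn{\omega = 0} the explicit real static limit
#' \eqn{k_0/(k_0+k_s)} is returned (no `0i` artifacts).
#'
#' @param params a [build_params()] object.
#' @param omega angular frequency (rad/s), vectorized, each `>= 0`.
#' @return Complex vector of gains.
#' @export
gain_pulse_1dof <- function(params, omega) {
  stopifnot(inherits(params, "stack_params"), all(omega >= 0))
  out <- complex(length(omega))
  z <- omega == 0
  out[z] <- params$k0 / (params$k0 + params$ks)
  w <- omega[!z]
  out[!z] <- (params$k0 + 1i * w * params$c0) / den_1dof(params, w)
  out
}

#' Harmonic gain from substrate motion to the stack mass (1DOF)
#'
#' The gain \eqn{(k_s + j\omega c_s)/(-m_0\omega^2 + j\omega(c_0+c_s) +
#' k_0 + k_s)} mapping a substrate-displacement harmonic \eqn{z_b} to the
#' mass displacement \eqn{x_b}. The sensor reads the relative displacement,
#' so the gain of the *measured* drift \eqn{x_b - z_b} is this minus one;
#' at low frequency that difference is negative (static value
#' \eqn{k_s/(k_0+k_s) - 1 = -k_0/(k_0+k_s)}), which is why measured
#' baseline drift is small and opposite in trend to the actual artifact.
#'
#' @inheritParams gain_pulse_1dof
#' @return Complex vector of gains.
#' @export
gain_baseline_1dof <- function(params, omega) {
  stopifnot(inherits(params, "stack_params"), all(omega >= 0))
  out <- complex(length(omega))
  z <- omega == 0
  out[z] <- params$ks / (params$k0 + params$ks)
  w <- omega[!z]
  out[!z] <- (params$ks + 1i * w * params$cs) / den_1dof(params, w)
  out
}

# Complex 2x2 dynamic-stiffness matrix of the 2DOF system at frequency w:
#   [ kA+k0+jwc0      -(k0+jwc0)            ] [x1]   [rhs1]
#   [ -(k0+jwc0)   -m0 w^2+k0+ks+jw(c0+cs)  ] [x2] = [rhs2]
solve_2dof <- function(params, w, rhs1, rhs2) {
  a11 <- params$kA + params$k0 + 1i * w * params$c0
  a12 <- -(params$k0 + 1i * w * params$c0)
  a22 <- -params$m0 * w^2 + params$k0 + params$ks +
    1i * w * (params$c0 + params$cs)
  det <- a11 * a22 - a12 * a12
  list(x1 = (rhs1 * a22 - a12 * rhs2) / det,
       x2 = (a11 * rhs2 - a12 * rhs1) / det)
}

# Real static (w = 0) solve, used as the explicit zero-frequency limit.
solve_2dof_static <- function(params, rhs1, rhs2) {
  a <- matrix(c(params$kA + params$k0, -params$k0,
                -params$k0, params$k0 + params$ks), 2, 2, byrow = TRUE)
  x <- solve(a, c(rhs1, rhs2))
  list(x1 = x[1], x2 = x[2])
}

check_2dof <- function(params) {
  if (is.null(params$kA) || !is.finite(params$kA) || params$kA <= 0) {
    stop("2DOF response requires a positive arterial-wall stiffness `kA`",
         call. = FALSE)
  }
}

#' Harmonic gains from pulse force to wall and mass displacements (2DOF)
#'
#' Solves the coupled wall/mass equations of motion (time-varying terms set
#' to zero) for a unit force harmonic \eqn{F e^{j\omega t}} on the arterial
#' wall, returning the pair \eqn{(H_1, H_2)} with \eqn{x_1 = H_1 F} (wall)
#' and \eqn{x_2 = H_2 F} (mass, i.e. the tactile measurement). The gains
#' are obtained by a direct complex 2x2 solve of the governing equations;
#' the zero-frequency limit is a real static equilibrium solve.
#'
#' @inheritParams gain_pulse_1dof
#' @return List with complex vectors `wall` and `mass`.
#' @export
gains_2dof_force <- function(params, omega) {
  stopifnot(inherits(params, "stack_params"), all(omega >= 0))
  check_2dof(params)
  wall <- complex(length(omega)); mass <- complex(length(omega))
  for (i in seq_along(omega)) {
    s <- if (omega[i] == 0) solve_2dof_static(params, 1, 0)
         else solve_2dof(params, omega[i], 1 + 0i, 0 + 0i)
    wall[i] <- s$x1; mass[i] <- s$x2
  }
  list(wall = wall, mass = mass)
}

#' Harmonic gains from substrate motion to wall and mass drift (2DOF)
#'
#' Gains \eqn{z_b \to (x_{1b}, x_{2b})} for substrate base excitation: the
#' substrate enters the mass equation through the sensor spring and damper,
#' with right-hand side \eqn{k_s z_b + c_s \dot z_b}. The measured-drift
#' gain (what the sensor reports) is `mass - 1`.
#'
#' @inheritParams gain_pulse_1dof
#' @return List with complex vectors `wall` and `mass`.
#' @export
gains_2dof_baseline <- function(params, omega) {
  stopifnot(inherits(params, "stack_params"), all(omega >= 0))
  check_2dof(params)
  wall <- complex(length(omega)); mass <- complex(length(omega))
  for (i in seq_along(omega)) {
    w <- omega[i]
    s <- if (w == 0) solve_2dof_static(params, 0, params$ks)
         else solve_2dof(params, w, 0 + 0i, params$ks + 1i * w * params$cs)
    wall[i] <- s$x1; mass[i] <- s$x2
  }
  list(wall = wall, mass = mass)
}

# Superpose per-harmonic complex gains into a real time series:
# sum_k Re[ A_k e^{j phi_k} G_k (j w_k)^deriv e^{j w_k t} ].
superpose <- function(amplitudes, omegas, phases, gains, t, deriv = 0L) {
  out <- numeric(length(t))
  for (i in seq_along(amplitudes)) {
    coefficient <- amplitudes[i] * exp(1i * phases[i]) * gains[i] *
      (1i * omegas[i])^deriv
    out <- out + Re(coefficient * exp(1i * omegas[i] * t))
  }
  out
}

#' MA-free measured signals in closed form
#'
#' Applies the per-harmonic complex gains to the true pulse signal and
#' superposes the real parts, giving the steady-state measured signal when
#' the measurement is free of motion artifacts. In wall-displacement mode
#' this is \eqn{x_C(t)} at the mass; in pulsatile-pressure mode the pair
#' \eqn{x_{1C}(t)} (wall) and \eqn{x_{2C}(t)} (mass). Exact closed-form
#' derivatives are returned alongside for initial conditions and force
#' reconstruction.
#'
#' @param params a [build_params()] object.
#' @param pulse a [harmonic_pulse()] object; its `mode` selects 1DOF vs
#'   2DOF.
#' @param grid a [time_grid()] object.
#' @return For wall-displacement mode, list `x_C`, `dx_C`, `ddx_C`. For
#'   pulsatile-pressure mode, list `x1C`, `dx1C`, `x2C`, `dx2C`, `ddx2C`,
#'   `force`, `dforce`.
#' @export
measured_free <- function(params, pulse, grid) {
  stopifnot(inherits(params, "stack_params"),
            inherits(pulse, "harmonic_pulse"),
            inherits(grid, "time_grid"))
  k <- seq_along(pulse$amplitudes)
  omegas <- 2 * pi * k * pulse$fundamental_hz
  check_nyquist(max(k) * pulse$fundamental_hz, grid, "pulse harmonic")
  if (pulse$mode == "wall_displacement") {
    g <- gain_pulse_1dof(params, omegas)
    list(
      x_C = superpose(pulse$amplitudes, omegas, pulse$phases, g, grid$t, 0L),
      dx_C = superpose(pulse$amplitudes, omegas, pulse$phases, g, grid$t, 1L),
      ddx_C = superpose(pulse$amplitudes, omegas, pulse$phases, g, grid$t, 2L)
    )
  } else {
    g <- gains_2dof_force(params, omegas)
    famp <- pulse$force_scale * pulse$amplitudes
    list(
      x1C = superpose(famp, omegas, pulse$phases, g$wall, grid$t, 0L),
      dx1C = superpose(famp, omegas, pulse$phases, g$wall, grid$t, 1L),
      x2C = superpose(famp, omegas, pulse$phases, g$mass, grid$t, 0L),
      dx2C = superpose(famp, omegas, pulse$phases, g$mass, grid$t, 1L),
      ddx2C = superpose(famp, omegas, pulse$phases, g$mass, grid$t, 2L),
      force = eval_pulse_force(pulse, grid, 0L),
      dforce = eval_pulse_force(pulse, grid, 1L)
    )
  }
}

#' Export a frequency response as a Bode-style table
#'
#' @param params a [build_params()] object.
#' @param omega angular frequencies (rad/s).
#' @param response one of `"pulse_1dof"`, `"baseline_1dof"`,
#'   `"force_2dof_wall"`, `"force_2dof_mass"`, `"baseline_2dof_wall"`,
#'   `"baseline_2dof_mass"`.
#' @return data.frame with columns `omega_rad_s`, `magnitude`, `phase_rad`.
#' @export
frequency_response <- function(params, omega,
                               response = c("pulse_1dof", "baseline_1dof",
                                            "force_2dof_wall",
                                            "force_2dof_mass",
                                            "baseline_2dof_wall",
                                            "baseline_2dof_mass")) {
  response <- match.arg(response)
  g <- switch(response,
    pulse_1dof = gain_pulse_1dof(params, omega),
    baseline_1dof = gain_baseline_1dof(params, omega),
    force_2dof_wall = gains_2dof_force(params, omega)$wall,
    force_2dof_mass = gains_2dof_force(params, omega)$mass,
    baseline_2dof_wall = gains_2dof_baseline(params, omega)$wall,
    baseline_2dof_mass = gains_2dof_baseline(params, omega)$mass)
  data.frame(omega_rad_s = omega, magnitude = Mod(g), phase_rad = Arg(g))
}
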