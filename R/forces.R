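# Equivalent-force decomposition: motion artifacts represented as forces
# acting on the nominal (time-invariant) system, verified by round-trip
# integration.

#' Equivalent force from the arterial wall (1DOF)
#'
#' \eqn{F_C(t) = k_0\,y(t) + c_0\,\dot y(t)}: the force the moving wall
#' exerts on the nominal stack mass. Derivatives must be the exact
#' closed-form harmonic derivatives, not numerical differences.
#'
#' @param y,dy wall displacement and its derivative on one grid.
#' @param params a [build_params()] object.
#' @return Numeric force series.
#' @export
force_from_wall <- function(y, dy, params) {
  stopifnot(inherits(params, "stack_params"))
  if (length(y) != length(dy)) stop("series are not on one grid",
                                    call. = FALSE)
  params$k0 * y + params$c0 * dy
}

#' Equivalent force from the sensor substrate
#'
#' \eqn{F_b(t) = k_s\,z_b(t) + c_s\,\dot z_b(t)}: the force the moving
#' substrate exerts on the mass through the sensor spring and damper. This
#' is the force-level representation of the actual motion artifact.
#'
#' @param z_b,dz_b substrate displacement and its derivative on one grid.
#' @param params a [build_params()] object.
#' @return Numeric force series.
#' @export
force_from_substrate <- function(z_b, dz_b, params) {
  stopifnot(inherits(params, "stack_params"))
  if (length(z_b) != length(dz_b)) stop("series are not on one grid",
                                        call. = FALSE)
  params$ks * z_b + params$cs * dz_b
}

#' Equivalent-force decomposition of a TVSP run
#'
#' Represents the TVSP-distorted displacements on the *nominal* system as
#' forces. In 1DOF mode,
#' \deqn{F_T = m_0\ddot x_M + (c_0+c_s)\dot x_M + (k_0+k_s)x_M,\qquad
#'   F_\mathrm{TVSP} = F_T - F_C;}
#' in 2DOF mode the wall and mass operators applied to
#' \eqn{(x_{1M}, x_{2M})} give \eqn{F_{1T}, F_{2T}}, and
#' \eqn{F_{1TVSP} = F_{1T} - F} (wall), \eqn{F_{2TVSP} = F_{2T}} (mass).
#' All derivatives are taken from the integrator state and the evaluated
#' right-hand side stored in the [compose_measured()] object; the 2DOF
#' wall velocity comes from the algebraic wall equation.
#'
#' @param measured a [compose_measured()] object carrying derivative
#'   channels.
#' @param params a [build_params()] object.
#' @return Object of class `force_set`. 1DOF: `F_C`, `F_b`, `F_T`,
#'   `F_TVSP`. 2DOF: `F`, `F_b`, `F1T`, `F2T`, `F1TVSP`, `F2TVSP`.
#' @export
force_tvsp <- function(measured, params) {
  stopifnot(inherits(measured, "measured_signals"),
            inherits(params, "stack_params"))
  mode <- attr(measured, "mode")
  p <- params
  fs <- if (mode == "1dof") {
    need <- c("x_M", "dx_M", "ddx_M", "y", "dy", "z_b", "dz_b")
    if (!all(need %in% names(measured))) {
      stop("derivative channels missing; rerun the simulation with state ",
           "export (compose_measured keeps them)", call. = FALSE)
    }
    F_C <- force_from_wall(measured$y, measured$dy, p)
    F_T <- p$m0 * measured$ddx_M + (p$c0 + p$cs) * measured$dx_M +
      (p$k0 + p$ks) * measured$x_M
    list(t = measured$t,
         F_C = F_C,
         F_b = force_from_substrate(measured$z_b, measured$dz_b, p),
         F_T = F_T,
         F_TVSP = F_T - F_C)
  } else {
    need <- c("x1M", "dx1M", "x2M", "dx2M", "ddx2M", "force", "z_b", "dz_b")
    if (!all(need %in% names(measured))) {
      stop("derivative channels missing; rerun the simulation with state ",
           "export (compose_measured keeps them)", call. = FALSE)
    }
    F1T <- (p$kA + p$k0) * measured$x1M + p$c0 * measured$dx1M -
      p$k0 * measured$x2M - p$c0 * measured$dx2M
    F2T <- -p$k0 * measured$x1M - p$c0 * measured$dx1M +
      p$m0 * measured$ddx2M + (p$k0 + p$ks) * measured$x2M +
      (p$c0 + p$cs) * measured$dx2M
    list(t = measured$t,
         F = measured$force,
         F_b = force_from_substrate(measured$z_b, measured$dz_b, p),
         F1T = F1T, F2T = F2T,
         F1TVSP = F1T - measured$force,
         F2TVSP = F2T)
  }
  structure(fs, class = "force_set", mode = mode)
}

#' Round-trip consistency check of the equivalent-force representation
#'
#' Integrates the *nominal* (time-invariant) system driven by the
#' equivalent forces and compares against the displacements they are
#' supposed to reproduce. 1DOF: the mass is driven by
#' \eqn{F_C + F_b + F_\mathrm{TVSP}} and must reproduce \eqn{x_M + x_b}.
#' 2DOF: \eqn{F_{1TVSP}} acts on the wall, \eqn{F_{2TVSP}} on the mass,
#' and the substrate motion \eqn{z_b} is kept as base excitation (a
#' displacement sensor reads relative motion, so the substrate input
#' cannot be replaced by a mass force); the response must reproduce
#' \eqn{(x_{1M}-x_{1C}+x_{1b},\; x_{2M}-x_{2C}+x_{2b})}.
#'
#' @param forces a [force_tvsp()] object.
#' @param measured the matching [compose_measured()] object.
#' @param params a [build_params()] object.
#' @param grid the [time_grid()] of the run.
#' @param threshold relative L2 residual above which `pass` is `FALSE`.
#' @param solver solver options (`rtol`, `atol`).
#' @return List `{mode, residual_rel_l2, threshold, pass}` (2DOF adds
#'   per-channel residuals `residual_wall`, `residual_mass`).
#' @export
roundtrip_check <- function(forces, measured, params, grid,
                            threshold = 1e-3,
                            solver = list(rtol = 1e-8, atol = 1e-10)) {
  stopifnot(inherits(forces, "force_set"),
            inherits(measured, "measured_signals"),
            inherits(params, "stack_params"), inherits(grid, "time_grid"))
  mode <- attr(forces, "mode")
  p <- params
  tt <- grid$t
  rel_l2 <- function(xhat, target) {
    sqrt(sum((xhat - target)^2) / max(sum(target^2),
                                      .Machine$double.xmin))
  }
  if (mode == "1dof") {
    ftot <- stats::splinefun(tt, forces$F_C + forces$F_b + forces$F_TVSP,
                             method = "fmm")
    rhs <- function(t, y, parms) {
      a <- (ftot(t) - (p$c0 + p$cs) * y[2] - (p$k0 + p$ks) * y[1]) / p$m0
      list(c(y[2], a))
    }
    y0 <- c(x = measured$x_M[1] + measured$x_b[1],
            v = measured$dx_M[1] + measured$dx_b[1])
    out <- run_ode(y0, tt, rhs, solver)
    target <- measured$x_M + measured$x_b
    res <- rel_l2(as.numeric(out[, "x"]), target)
    list(mode = mode, residual_rel_l2 = res, threshold = threshold,
         pass = res < threshold)
  } else {
    f1 <- stats::splinefun(tt, forces$F1TVSP, method = "fmm")
    f2 <- stats::splinefun(tt, forces$F2TVSP, method = "fmm")
    zsp <- stats::splinefun(tt, p$ks * measured$z_b + p$cs * measured$dz_b,
                            method = "fmm")
    rhs <- function(t, y, parms) {
      dx1 <- y[3] + (f1(t) - (p$kA + p$k0) * y[1] + p$k0 * y[2]) / p$c0
      a2 <- (p$k0 * y[1] + p$c0 * dx1 - (p$k0 + p$ks) * y[2] -
               (p$c0 + p$cs) * y[3] + f2(t) + zsp(t)) / p$m0
      list(c(dx1, y[3], a2))
    }
    t1 <- measured$x1M - measured$x1C + measured$x1b
    t2 <- measured$x2M - measured$x2C + measured$x2b
    y0 <- c(x1 = t1[1], x2 = t2[1],
            v2 = measured$dx2M[1] - measured$dx2C[1] + measured$dx2b[1])
    out <- run_ode(y0, tt, rhs, solver)
    r1 <- rel_l2(as.numeric(out[, "x1"]), t1)
    r2 <- rel_l2(as.numeric(out[, "x2"]), t2)
    res <- max(r1, r2)
    list(mode = mode, residual_rel_l2 = res,
         residual_wall = r1, residual_mass = r2,
         threshold = threshold, pass = res < threshold)
  }
}
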