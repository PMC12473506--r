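# Baseline drift, the TVSP coupling law, time-domain integration and
# signal composition.

test_that("baseline drift matches the frequency-response gain per
           component", {
  p <- nominal_params()
  g <- short_grid()
  ma <- ma_signal(1, 0.1, 0)
  bl <- simulate_baseline(p, ma, g, "1dof")
  expect_equal(max(abs(bl$x_b)), Mod(gain_baseline_1dof(p, 2 * pi * 0.1)),
               tolerance = 0.01)
  # empty MA gives zero drift
  bl0 <- simulate_baseline(p, ma_signal(), g, "1dof")
  expect_true(all(bl0$x_b == 0) && all(bl0$drift == 0))
})

test_that("baseline drift is linear in the MA amplitude", {
  p <- nominal_params()
  g <- short_grid()
  b1 <- simulate_baseline(p, canonical_ma(), g, "1dof")
  b3 <- simulate_baseline(p, canonical_ma(a1 = 3), g, "1dof")
  expect_equal(b3$x_b, 3 * b1$x_b, tolerance = 1e-10)
})

test_that("2DOF drift has a comparable mass response and a small wall
           response", {
  p <- nominal_params()
  g <- short_grid()
  bl <- simulate_baseline(p, canonical_ma(), g, "2dof")
  expect_lt(max(abs(bl$x1b)), max(abs(bl$x2b)))
  expect_equal(bl$drift, bl$x2b - bl$x1b, tolerance = 1e-14)
})

test_that("ODE route reproduces the closed-form baseline drift", {
  p <- nominal_params()
  g <- short_grid()
  for (mode in c("1dof", "2dof")) {
    cf <- simulate_baseline(p, canonical_ma(), g, mode)
    od <- simulate_baseline(p, canonical_ma(), g, mode, method = "ode")
    expect_lt(rel_l2(od$drift, cf$drift), 1e-6)
  }
})

test_that("TVSP coupling law follows its definition and keeps nominal
           values when off", {
  p <- nominal_params()
  drift <- rep(0.4, 100)
  off <- tvsp_from_drift(tvsp_coupling(0, 0, 0), drift, p, "1dof")
  expect_true(all(off$m_t == 0) && all(off$c_t == 0) && all(off$k_t == 0))
  expect_equal(off$r_t, rep(2, 100), tolerance = 1e-12)
  expect_equal(off$zeta_t, rep(1.5, 100), tolerance = 1e-12)
  # drift pinned at +x_ref: k(t) = kappa_k * k0 exactly
  on <- tvsp_from_drift(tvsp_coupling(0, 0, 0.05, x_ref = 0.4), drift, p,
                        "1dof")
  expect_equal(on$k_t, rep(0.05 * p$k0, 100), tolerance = 1e-14)
  # the sensor raises the total frequency ratio above the stack's
  any_drift <- 0.4 * sin(seq(0, 2 * pi, length.out = 100))
  tv <- tvsp_from_drift(tvsp_coupling(), any_drift, p, "1dof")
  expect_true(all(tv$r_total_t > tv$r_t))
})

test_that("coupling guards: zero reference and parameter floor", {
  p <- nominal_params()
  expect_error(
    tvsp_from_drift(tvsp_coupling(x_ref = NULL), rep(0, 10), p, "1dof"),
    NA) # zero drift with default coupling is fine (zero modulation)
  expect_error(
    tvsp_from_drift(tvsp_coupling(kappa_k = 0.05, x_ref = NULL),
                    c(0, 0, 0), p, "1dof"),
    NA)
  # clamp activates when modulation would exceed the 5% floor
  expect_warning(
    tv <- tvsp_from_drift(tvsp_coupling(2, 2, 2, x_ref = 1), rep(-1, 10),
                          p, "1dof"),
    "clamped")
  expect_true(all(p$k0 + tv$k_t >= 0.05 * p$k0 - 1e-15))
  expect_true(tv$clamped)
})

test_that("2DOF r_total accounts for the arterial wall in both variants", {
  p <- nominal_params()
  drift <- 0.3 * sin(seq(0, 2 * pi, length.out = 50))
  ser <- tvsp_from_drift(tvsp_coupling(), drift, p, "2dof", "series")
  par <- tvsp_from_drift(tvsp_coupling(), drift, p, "2dof", "parallel")
  expect_true(all(ser$r_total_t > ser$r_t))
  expect_true(all(par$r_total_t > ser$r_total_t)) # parallel stiffer
})

test_that("with coupling off the integrator reproduces the closed form
           (both modes)", {
  p <- nominal_params()
  g <- short_grid()
  post <- g$t >= 2
  ma <- canonical_ma()
  # 1DOF
  pulse <- canonical_pulse()
  bl <- simulate_baseline(p, ma, g, "1dof")
  tv <- tvsp_from_drift(tvsp_coupling(0, 0, 0), bl$drift, p, "1dof")
  sim <- simulate_tvsp(p, pulse, tv, g)
  free <- measured_free(p, pulse, g)
  expect_lt(rel_l2(sim$x_M[post], free$x_C[post]), 1e-4)
  # 2DOF
  pp <- canonical_pulse(mode = "pulsatile_pressure")
  bl2 <- simulate_baseline(p, ma, g, "2dof")
  tv2 <- tvsp_from_drift(tvsp_coupling(0, 0, 0), bl2$drift, p, "2dof")
  sim2 <- simulate_tvsp(p, pp, tv2, g)
  free2 <- measured_free(p, pp, g)
  expect_lt(rel_l2(sim2$x1M[post], free2$x1C[post]), 1e-4)
  expect_lt(rel_l2(sim2$x2M[post], free2$x2C[post]), 1e-4)
})

test_that("pulse mode and TVSP mode must agree", {
  p <- nominal_params()
  g <- short_grid()
  bl <- simulate_baseline(p, canonical_ma(), g, "2dof")
  tv <- tvsp_from_drift(tvsp_coupling(), bl$drift, p, "2dof")
  expect_error(simulate_tvsp(p, canonical_pulse(), tv, g),
               "does not match")
})

test_that("composition identities hold and the TVSP distortion is a small
           perturbation", {
  res <- short_1dof()
  s <- res$signals
  expect_equal(s$x_TVSP, s$x_M - s$x_C, tolerance = 1e-10)
  expect_equal(s$x_tactile, s$x_M + s$x_b - s$z_b, tolerance = 1e-10)
  expect_equal(s$x_tactile_MA, s$x_TVSP + s$x_b - s$z_b, tolerance = 1e-10)
  idx <- res$analysis_idx
  expect_lt(max(abs(s$x_TVSP[idx])) / max(abs(s$x_C[idx])), 0.15)
  # measured drift is smaller than the artifact and opposes its trend
  expect_lt(max(abs(s$drift_measured)), max(abs(s$z_b)))
  expect_lt(stats::cor(s$drift_measured, s$z_b), 0)
})

test_that("2DOF composition identities hold", {
  res <- short_2dof()
  s <- res$signals
  expect_equal(s$x_tactile, s$x2M + s$x2b - s$z_b, tolerance = 1e-10)
  expect_equal(s$x_wall, s$x1M + s$x1b, tolerance = 1e-10)
  expect_equal(s$x_tactile_MA, s$x2TVSP + s$x2b - s$z_b, tolerance = 1e-10)
  expect_equal(s$x_wall_MA, s$x1TVSP + s$x1b, tolerance = 1e-10)
})
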