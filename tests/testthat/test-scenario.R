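# Scenario orchestration: presets, channel inventory, determinism, config
# round trip, artifact writing.

test_that("the 1DOF preset produces the full signal inventory", {
  res <- short_1dof()
  s <- res$signals
  for (nm in c("z_b", "x_b", "drift_measured", "x_C", "x_M", "x_TVSP",
               "x_tactile", "x_tactile_MA")) {
    expect_true(nm %in% names(s), info = nm)
  }
  expect_named(res$tvsp, c("m_t", "c_t", "k_t", "r_t", "zeta_t",
                           "r_total_t", "x_ref", "clamped", "mode"))
  for (nm in c("F_C", "F_b", "F_T", "F_TVSP")) {
    expect_true(nm %in% names(res$forces), info = nm)
  }
})

test_that("the 2DOF preset produces the full signal inventory", {
  res <- short_2dof()
  s <- res$signals
  for (nm in c("z_b", "x1b", "x2b", "drift_measured", "drift_tvsp",
               "x1C", "x2C", "x1M", "x2M", "x1TVSP", "x2TVSP",
               "x_tactile", "x_wall", "x_tactile_MA", "x_wall_MA")) {
    expect_true(nm %in% names(s), info = nm)
  }
  for (nm in c("F", "F_b", "F1T", "F2T", "F1TVSP", "F2TVSP")) {
    expect_true(nm %in% names(res$forces), info = nm)
  }
})

test_that("zero MA and zero coupling collapse the measurement to the
           MA-free signal", {
  sc <- preset_scenario("wall_1dof", grid = short_grid(),
                        coupling = tvsp_coupling(0, 0, 0), ma = ma_signal())
  res <- run_scenario(sc)
  s <- res$signals
  expect_equal(s$x_tactile, s$x_C, tolerance = 1e-6)
  expect_true(all(s$z_b == 0) && all(s$x_b == 0))
  expect_true(all(s$drift_measured == 0))
})

test_that("identical configurations give identical metrics", {
  sc <- preset_scenario("wall_1dof", grid = short_grid())
  r1 <- run_scenario(sc)
  r2 <- run_scenario(sc)
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$signals$x_M, r2$signals$x_M)
})

test_that("scenario validation rejects inconsistent configurations", {
  expect_error(scenario(mode = "pressure_2dof", pulse = canonical_pulse()),
               "pulsatile_pressure")
  expect_error(scenario(transient_s = 20), "transient")
  expect_error(preset_scenario("nope"), "arg")
})

test_that("YAML configs load onto canonical defaults", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c(
    "name: custom",
    "mode: wall_1dof",
    "pulse:",
    "  fundamental_hz: 1.2",
    "  amplitudes: [1.0, 0.4]",
    "  phases: [0.0, -0.4]",
    "ma:",
    "  amplitudes: [1.5]",
    "  frequencies_hz: [0.12]",
    "coupling:",
    "  kappa_k: 0.03",
    "grid: {t0: 0.0, t_end: 6.0, dt: 0.001}",
    "transient_s: 2.0"
  ), cfg)
  sc <- load_scenario(cfg)
  expect_s3_class(sc, "pulse_scenario")
  expect_equal(sc$pulse$fundamental_hz, 1.2)
  expect_equal(length(sc$pulse$amplitudes), 2L)
  expect_equal(sc$ma$frequencies_hz, 0.12)
  expect_equal(sc$coupling$kappa_k, 0.03)
  expect_equal(sc$coupling$kappa_m, 0.05) # default retained
  expect_equal(sc$grid$t_end, 6)
  unlink(cfg)
})

test_that("run artifacts are written and the manifest echoes the config", {
  out <- file.path(tempdir(), "pulsema-test-run")
  on.exit(unlink(out, recursive = TRUE), add = TRUE)
  sc <- preset_scenario("wall_1dof", grid = short_grid())
  run_scenario(sc, output_dir = out)
  files <- list.files(out)
  for (f in c("timeseries.csv", "metrics.json", "roundtrip.json",
              "manifest.txt", "cycles_tactile.csv")) {
    expect_true(f %in% files, info = f)
  }
  ts <- utils::read.csv(file.path(out, "timeseries.csv"))
  expect_true(all(c("t", "x_C", "x_M", "x_tactile", "F_TVSP", "r_t")
                  %in% names(ts)))
  man <- readLines(file.path(out, "manifest.txt"))
  expect_true(any(grepl("kappa_k: 0.05", man)))
  expect_true(any(grepl("dt: 0.001", man)))
  rt <- jsonlite::read_json(file.path(out, "roundtrip.json"))
  expect_true(rt$pass)
})

test_that("stiffness sweep reproduces the sensor-design orderings", {
  sw <- run_cached("sweep_short", function() {
    stiffness_sweep(preset_scenario("pressure_2dof", grid = short_grid()),
                    c(6, 2))
  })
  s <- sw$summary
  i6 <- which(s$ks_over_k0 == 6); i2 <- which(s$ks_over_k0 == 2)
  expect_gt(s$pulse_amplitude[i2], s$pulse_amplitude[i6])
  expect_lt(s$apw_l2_deviation[i2], s$apw_l2_deviation[i6])
  expect_gt(s$tvsp_rms[i2], s$tvsp_rms[i6])
  expect_error(stiffness_sweep(preset_scenario("pressure_2dof"), 6),
               "at least 2")
})
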