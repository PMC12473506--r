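# Cycle segmentation, per-cycle metrics, spectra, spline baseline.

test_that("onsets of a strictly periodic pulse are evenly spaced", {
  p <- nominal_params()
  g <- time_grid(0, 10, 1e-3)
  x_C <- measured_free(p, canonical_pulse(), g)$x_C
  onsets <- detect_cycles(x_C, g$t, 1)
  expect_gte(length(onsets), 9)
  expect_lt(max(abs(diff(onsets) - 1)), 1e-3)
  # offset invariance
  onsets_shifted <- detect_cycles(x_C + 5, g$t, 1)
  expect_equal(onsets_shifted, onsets, tolerance = 1e-9)
  # idempotence: re-detecting on a cycle-aligned restriction returns the
  # interior onsets within one sample
  sel <- g$t >= onsets[2] - 0.2 & g$t <= onsets[length(onsets) - 1] + 0.2
  onsets2 <- detect_cycles(x_C[sel], g$t[sel], 1)
  common <- onsets[onsets >= min(onsets2) - 5e-4 &
                   onsets <= max(onsets2) + 5e-4]
  expect_equal(length(onsets2), length(common))
  expect_lt(max(abs(onsets2 - common)), 1e-3)
})

test_that("per-cycle heart rate of a periodic signal is 60 bpm", {
  p <- nominal_params()
  g <- time_grid(0, 10, 1e-3)
  x_C <- measured_free(p, canonical_pulse(), g)$x_C
  m <- hr_and_amplitude(x_C, g$t, detect_cycles(x_C, g$t, 1))
  expect_lt(max(abs(m$hr_per_cycle - 60)), 0.06)
  expect_true(all(m$amplitude_per_cycle > 0))
  expect_error(hr_and_amplitude(x_C, g$t, c(2, 1.5)), "increasing")
  expect_error(hr_and_amplitude(x_C, g$t, 2), "at least 2")
})

test_that("normalized waveform is invariant to amplitude scaling", {
  p <- nominal_params()
  g <- time_grid(0, 8, 1e-3)
  x <- measured_free(p, canonical_pulse(), g)$x_C
  on <- detect_cycles(x, g$t, 1)
  m1 <- hr_and_amplitude(x, g$t, on)
  m2 <- hr_and_amplitude(3.7 * x, g$t, detect_cycles(3.7 * x, g$t, 1))
  expect_equal(m2$apw_normalized, m1$apw_normalized, tolerance = 1e-12)
  expect_equal(m2$amplitude_per_cycle, 3.7 * m1$amplitude_per_cycle,
               tolerance = 1e-9)
})

test_that("integer-cycle spectrum puts harmonics on exact bins and obeys
           Parseval", {
  p <- nominal_params()
  g <- time_grid(0, 10, 1e-3)
  x_C <- measured_free(p, canonical_pulse(), g)$x_C
  sp <- spectrum_report(x_C, g$dt, 1, n_harmonics = 10, delta_f = 1e-6)
  # with a near-zero band width the harmonic bins still carry ~all energy
  expect_gt(sp$harmonic_band_energy_fraction, 1 - 1e-6)
  # Parseval: sum |X_k|^2 = n * sum x^2 over the trimmed window
  n <- sp$n_used
  expect_equal(sum(sp$energy), n * sum(x_C[seq_len(n)]^2), tolerance = 1e-9)
  expect_error(spectrum_report(x_C[1:500], g$dt, 1), "2 fundamental")
})

test_that("measured drift spectrum peaks at the dominant MA frequency", {
  p <- nominal_params()
  g <- time_grid(0, 20, 1e-3) # 0.05 Hz bins resolve the 0.10 Hz component
  z_b <- eval_ma(canonical_ma(), g)
  drift <- simulate_baseline(p, canonical_ma(), g, "1dof")$x_b - z_b
  sp <- spectrum_report(drift, g$dt, 1)
  expect_equal(sp$low_freq_peak$frequency_hz, 0.10, tolerance = 1e-9)
  expect_lt(sp$low_freq_peak$frequency_hz, 0.5)
})

test_that("spline baseline interpolates its knots and flattens a
           drift-free signal", {
  p <- nominal_params()
  g <- time_grid(0, 10, 1e-3)
  x_C <- measured_free(p, canonical_pulse(), g)$x_C
  on <- detect_cycles(x_C, g$t, 1)
  base <- cse_baseline(x_C, g$t, on)
  at_knots <- stats::approx(g$t, base, xout = on)$y
  val_knots <- stats::approx(g$t, x_C, xout = on)$y
  expect_lt(max(abs(at_knots - val_knots)), 1e-10)
  # periodic signal: onset values all equal, baseline constant at them
  expect_lt(diff(range(base)), 1e-4 * diff(range(x_C)))
  expect_error(cse_baseline(x_C, g$t, on[1:3]), "4 onsets")
})

test_that("spline baseline differs from the true measured drift under MA", {
  res <- short_1dof()
  idx <- res$analysis_idx
  truth <- res$signals$drift_measured[idx]
  expect_gt(rel_l2(res$cse, truth), 0.05)
})

test_that("summary metrics degenerate gracefully without MA", {
  sc <- preset_scenario("wall_1dof", grid = short_grid(),
                        coupling = tvsp_coupling(0, 0, 0), ma = ma_signal())
  res <- run_scenario(sc)
  m <- res$metrics
  expect_equal(m$baseline_attenuation, 0)
  expect_equal(m$drift_trend_correlation, 0)
  expect_false(m$correlation_defined)
  expect_lt(m$hr_max_rel_dev_pct, 1e-6)
  expect_lt(m$amp_max_rel_change_pct, 1e-4)
  expect_equal(m$tvsp_rms_ratio, 0, tolerance = 1e-7)
})

test_that("MA shifts cycle onsets relative to the MA-free signal", {
  res <- short_1dof()
  on_free <- res$cycles$free$onset_times
  on_meas <- res$cycles$tactile$onset_times
  k <- min(length(on_free), length(on_meas))
  expect_gt(max(abs(on_free[seq_len(k)] - on_meas[seq_len(k)])), 1e-3)
})
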