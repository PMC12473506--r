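# Stack parameter construction and input-signal synthesis.

test_that("nominal ratios produce the expected physical parameters", {
  p <- build_params(kA = 1, k0_over_kA = 1 / 6, r0 = 2, zeta0 = 1.5,
                    ks_over_k0 = 6, zeta_s = 1.5, heart_rate_hz = 1)
  expect_equal(p$k0, 1 / 6, tolerance = 1e-14)
  expect_equal(p$ks, 1, tolerance = 1e-14)
  # independent arithmetic: m0 = k0 / (r0 * 2 pi f)^2, c = 2 zeta sqrt(k m)
  m0 <- (1 / 6) / (2 * 2 * pi)^2
  expect_equal(p$m0, m0, tolerance = 1e-12)
  expect_equal(p$c0, 2 * 1.5 * sqrt((1 / 6) * m0), tolerance = 1e-12)
  expect_equal(p$cs, 2 * 1.5 * sqrt(1 * m0), tolerance = 1e-12)
  # frozen magnitudes
  expect_equal(p$m0, 1.0554297e-3, tolerance = 1e-6)
  expect_equal(p$c0, 3.9788736e-2, tolerance = 1e-6)
  expect_equal(p$cs, 9.7462140e-2, tolerance = 1e-6)
})

test_that("ratio -> params -> ratio round trip is identity", {
  p <- build_params(kA = 3.7, k0_over_kA = 0.21, r0 = 1.4, zeta0 = 0.8,
                    ks_over_k0 = 4.2, zeta_s = 2.1, heart_rate_hz = 1.25)
  r <- stack_ratios(p)
  expect_equal(r$r0, 1.4, tolerance = 1e-12)
  expect_equal(r$zeta0, 0.8, tolerance = 1e-12)
  expect_equal(r$zeta_s, 2.1, tolerance = 1e-12)
  expect_equal(r$k0_over_kA, 0.21, tolerance = 1e-12)
  expect_equal(r$ks_over_k0, 4.2, tolerance = 1e-12)
})

test_that("doubling the heart rate scales mass by 1/4 and damping by 1/2", {
  p1 <- build_params(heart_rate_hz = 1)
  p2 <- build_params(heart_rate_hz = 2)
  expect_equal(p2$m0, p1$m0 / 4, tolerance = 1e-12)
  expect_equal(p2$c0, p1$c0 / 2, tolerance = 1e-12)
  expect_equal(p2$cs, p1$cs / 2, tolerance = 1e-12)
  expect_equal(p2$k0, p1$k0, tolerance = 1e-14) # stiffness untouched
})

test_that("non-positive arguments are rejected by name", {
  expect_error(build_params(r0 = 0), "`r0`")
  expect_error(build_params(zeta_s = -1), "`zeta_s`")
  expect_error(build_params(heart_rate_hz = 0), "`heart_rate_hz`")
})

test_that("pulse synthesis matches the cosine closed form", {
  g <- time_grid(0, 2, 1e-3)
  pulse <- harmonic_pulse(1, amplitudes = 1, phases = 0)
  s <- eval_pulse(pulse, g)
  expect_equal(s[g$t == 0.25], 0, tolerance = 1e-12) # cos(pi/2)
  expect_equal(s[g$t == 0], 1, tolerance = 1e-12)
  # zero amplitudes give an identically zero series
  z <- eval_pulse(harmonic_pulse(1, amplitudes = c(0, 0)), g)
  expect_true(all(z == 0))
  expect_error(harmonic_pulse(1, amplitudes = numeric()), "at least one")
})

test_that("mean square of the canonical pulse obeys Parseval", {
  pulse <- canonical_pulse()
  g <- time_grid(0, 4, 1e-3)
  s <- eval_pulse(pulse, g)
  s <- s[-length(s)] # drop duplicated cycle endpoint: mean over [0, 4)
  expect_equal(mean(s^2), sum(pulse$amplitudes^2) / 2,
               tolerance = 1e-9)
})

test_that("signal synthesis is linear in the harmonic list", {
  g <- time_grid(0, 3, 1e-3)
  p1 <- harmonic_pulse(1, c(1, 0.5), c(0, -0.4))
  p2 <- harmonic_pulse(1, c(0.3, 0.2, 0.7), c(0.1, 0.2, 0.3))
  joint <- harmonic_pulse(1, c(p1$amplitudes + p2$amplitudes[1:2], p2$amplitudes[3]),
                          phases = c(0, 0, p2$phases[3]))
  # generic linearity: scaling amplitudes scales the series
  s1 <- eval_pulse(p1, g)
  s1x3 <- eval_pulse(harmonic_pulse(1, 3 * p1$amplitudes, p1$phases), g)
  expect_equal(s1x3, 3 * s1, tolerance = 1e-12)
  # additivity across MA components
  ma_a <- ma_signal(2, 0.1, 0)
  ma_b <- ma_signal(0.8, 0.23, 0.8)
  ma_ab <- ma_signal(c(2, 0.8), c(0.1, 0.23), c(0, 0.8))
  expect_equal(eval_ma(ma_ab, g), eval_ma(ma_a, g) + eval_ma(ma_b, g),
               tolerance = 1e-12)
})

test_that("MA evaluation handles empty lists and matches the closed form", {
  g <- time_grid(0, 5, 1e-3)
  expect_true(all(eval_ma(ma_signal(), g) == 0))
  ma <- ma_signal(1, 0.1, 0)
  z <- eval_ma(ma, g)
  expect_equal(z[g$t == 2.5], 0, tolerance = 1e-12) # cos(pi/2)
  # canonical MA peak agrees with a 10x denser grid search within 2%
  zc <- eval_ma(canonical_ma(), time_grid(0, 12, 1e-3))
  zf <- eval_ma(canonical_ma(), time_grid(0, 12, 1e-4))
  expect_equal(max(abs(zc)), max(abs(zf)), tolerance = 0.02)
})

test_that("sampling adequacy is enforced against the Nyquist frequency", {
  g <- time_grid(0, 2, 0.1) # Nyquist 5 Hz
  expect_error(eval_pulse(canonical_pulse(), g), "Nyquist")
  expect_error(eval_ma(ma_signal(1, 6, 0), g), "Nyquist")
  expect_silent(eval_ma(ma_signal(1, 0.1, 0), g))
})

test_that("pressure mode maps pressure to force through the area scale", {
  g <- time_grid(0, 2, 1e-3)
  pulse <- canonical_pulse(mode = "pulsatile_pressure", force_scale = 2.5)
  expect_equal(eval_pulse_force(pulse, g), 2.5 * eval_pulse(pulse, g),
               tolerance = 1e-14)
  wall <- canonical_pulse()
  expect_error(eval_pulse_force(wall, g), "pulsatile_pressure")
})
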