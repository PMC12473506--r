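# Configuration-driven orchestration of a full simulation run.

#' Scenario definition
#'
#' Bundles every input of a run: signal mode, true-pulse harmonics, stack
#' ratios, motion-artifact components, TVSP coupling, time grid, solver
#' tolerances and analysis options. Defaults are the canonical study
#' conditions: nominal stack ratios (`k0 = kA/6`, `r0 = 2`,
#' `zeta0 = zeta_s = 1.5`, `ks = 6 k0`), the canonical ten-harmonic pulse
#' at 60 bpm, the canonical two-component MA, 5% peak TVSP modulation, and
#' a 12 s grid at 1 kHz with the first 2 s discarded as startup transient.
#'
#' @param name scenario name (used in output files).
#' @param mode `"wall_1dof"` (arterial wall displacement as the true pulse
#'   signal, 1DOF) or `"pressure_2dof"` (pulsatile pressure, 2DOF).
#' @param pulse a [harmonic_pulse()]; `NULL` for the canonical pulse in the
#'   mode-appropriate flavour.
#' @param stack named list of [build_params()] arguments to override.
#' @param ma a [ma_signal()]; `NULL` for the canonical MA.
#' @param coupling a [tvsp_coupling()].
#' @param grid a [time_grid()].
#' @param transient_s startup interval discarded from all metrics (s).
#' @param n_harmonics,delta_f spectral analysis options, see
#'   [spectrum_report()]; `delta_f = NULL` scales as `0.3 * f_C`.
#' @param kA_total `r_total` variant for 2DOF runs, see
#'   [tvsp_from_drift()].
#' @param solver solver options (`rtol`, `atol`).
#' @return Object of class `pulse_scenario`.
#' @export
scenario <- function(name = "scenario",
                     mode = c("wall_1dof", "pressure_2dof"),
                     pulse = NULL, stack = list(), ma = NULL,
                     coupling = tvsp_coupling(),
                     grid = time_grid(0, 12, 1e-3),
                     transient_s = 2,
                     n_harmonics = 10, delta_f = NULL,
                     kA_total = c("series", "parallel"),
                     solver = list(rtol = 1e-8, atol = 1e-10)) {
  mode <- match.arg(mode)
  kA_total <- match.arg(kA_total)
  params <- do.call(build_params, stack)
  if (is.null(pulse)) {
    pulse <- canonical_pulse(
      fundamental_hz = params$heart_rate_hz,
      mode = if (mode == "wall_1dof") "wall_displacement"
             else "pulsatile_pressure")
  }
  want <- if (mode == "wall_1dof") "wall_displacement" else "pulsatile_pressure"
  if (pulse$mode != want) {
    stop("scenario mode ", mode, " requires a ", want, " pulse",
         call. = FALSE)
  }
  if (is.null(ma)) ma <- canonical_ma()
  if (is.null(delta_f)) delta_f <- 0.3 * pulse$fundamental_hz
  if (transient_s < 0 || transient_s >= grid$t_end - grid$t0) {
    stop("`transient_s` must lie inside the grid span", call. = FALSE)
  }
  structure(list(name = name, mode = mode, pulse = pulse, params = params,
                 stack = stack, ma = ma, coupling = coupling, grid = grid,
                 transient_s = transient_s, n_harmonics = n_harmonics,
                 delta_f = delta_f, kA_total = kA_total, solver = solver),
            class = "pulse_scenario")
}

#' Named scenario presets
#'
#' `"wall_1dof"`: canonical 1DOF run with arterial wall displacement as the
#' true pulse signal. `"pressure_2dof"`: canonical 2DOF run with pulsatile
#' pressure as the true pulse signal.
#'
#' @param name preset name; see [list_presets()].
#' @param ... overrides passed to [scenario()].
#' @return A [scenario()] object.
#' @export
preset_scenario <- function(name = c("wall_1dof", "pressure_2dof"), ...) {
  name <- match.arg(name)
  scenario(name = name, mode = name, ...)
}

#' @rdname preset_scenario
#' @export
list_presets <- function() c("wall_1dof", "pressure_2dof")

#' Load a scenario from a YAML or JSON config file
#'
#' Recognized blocks: `name`, `mode`, `pulse` (`fundamental_hz`,
#' `amplitudes`, `phases`, `force_scale`), `stack` ([build_params()]
#' arguments), `ma` (`amplitudes`, `frequencies_hz`, `phases`), `coupling`
#' (`kappa_m`, `kappa_c`, `kappa_k`, `x_ref`), `grid` (`t0`, `t_end`,
#' `dt`), `solver` (`rtol`, `atol`), and scalar options `transient_s`,
#' `n_harmonics`, `delta_f`, `kA_total`. Missing blocks fall back to the
#' canonical defaults.
#'
#' @param path config file path (`.yaml`/`.yml`/`.json`).
#' @return A [scenario()] object.
#' @export
load_scenario <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  mode <- cfg$mode %||% "wall_1dof"
  pulse <- if (!is.null(cfg$pulse)) {
    harmonic_pulse(
      fundamental_hz = cfg$pulse$fundamental_hz %||% 1,
      amplitudes = cfg$pulse$amplitudes,
      phases = cfg$pulse$phases,
      mode = if (mode == "wall_1dof") "wall_displacement"
             else "pulsatile_pressure",
      force_scale = cfg$pulse$force_scale %||% 1)
  }
  ma <- if (!is.null(cfg$ma)) {
    ma_signal(amplitudes = cfg$ma$amplitudes %||% numeric(),
              frequencies_hz = cfg$ma$frequencies_hz %||% numeric(),
              phases = cfg$ma$phases)
  }
  coupling <- if (!is.null(cfg$coupling)) {
    tvsp_coupling(kappa_m = cfg$coupling$kappa_m %||% 0.05,
                  kappa_c = cfg$coupling$kappa_c %||% 0.05,
                  kappa_k = cfg$coupling$kappa_k %||% 0.05,
                  x_ref = cfg$coupling$x_ref)
  } else {
    tvsp_coupling()
  }
  grid <- if (!is.null(cfg$grid)) {
    time_grid(cfg$grid$t0 %||% 0, cfg$grid$t_end %||% 12,
              cfg$grid$dt %||% 1e-3)
  } else {
    time_grid()
  }
  args <- list(name = cfg$name %||% "scenario", mode = mode, pulse = pulse,
               stack = cfg$stack %||% list(), ma = ma, coupling = coupling,
               grid = grid)
  for (opt in c("transient_s", "n_harmonics", "delta_f", "kA_total")) {
    if (!is.null(cfg[[opt]])) args[[opt]] <- cfg[[opt]]
  }
  if (!is.null(cfg$solver)) {
    args$solver <- list(rtol = cfg$solver$rtol %||% 1e-8,
                        atol = cfg$solver$atol %||% 1e-10)
  }
  do.call(scenario, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a scenario end to end
#'
#' Executes the full pipeline: baseline drift, TVSP coupling, time-domain
#' integration of the time-varying equations of motion, signal composition,
#' equivalent forces with round-trip check, and waveform analytics (cycle
#' onsets, per-cycle heart rate and amplitude, spectra, spline baseline,
#' summary metrics). Analytics use the post-transient window. If
#' `output_dir` is given, writes the time series and spectra as CSV, the
#' metrics and round-trip report as JSON, and a plain-text manifest echoing
#' the full configuration.
#'
#' @param sc a [scenario()] object.
#' @param output_dir optional output directory (created if needed).
#' @return Invisible list with `scenario`, `signals`
#'   ([compose_measured()]), `tvsp` ([tvsp_from_drift()]), `forces`,
#'   `roundtrip`, `cycles` (per-signal [hr_and_amplitude()]), `spectra`,
#'   `cse`, `metrics`, and the analysis window index `analysis_idx`.
#' @export
run_scenario <- function(sc, output_dir = NULL) {
  stopifnot(inherits(sc, "pulse_scenario"))
  params <- sc$params; grid <- sc$grid
  mode <- if (sc$mode == "wall_1dof") "1dof" else "2dof"
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop("scenario stage `", what, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  baseline <- stage("simulate_baseline",
                    simulate_baseline(params, sc$ma, grid, mode,
                                      solver = sc$solver))
  idx <- grid$t >= grid$t0 + sc$transient_s
  # reference displacement: peak |drift| over the analyzed window
  x_ref <- max(abs(baseline$drift[idx]))
  coupling <- sc$coupling
  if (is.null(coupling$x_ref) && x_ref > 0) coupling$x_ref <- x_ref
  tvsp <- stage("tvsp_from_drift",
                tvsp_from_drift(coupling, baseline$drift, params, mode,
                                kA_total = sc$kA_total))
  tvsp_sim <- stage("simulate_tvsp",
                    simulate_tvsp(params, sc$pulse, tvsp, grid,
                                  solver = sc$solver))
  free <- stage("measured_free", measured_free(params, sc$pulse, grid))
  signals <- stage("compose_measured",
                   compose_measured(params, sc$pulse, sc$ma, grid,
                                    baseline, tvsp_sim, free))
  forces <- stage("force_tvsp", force_tvsp(signals, params))
  roundtrip <- stage("roundtrip_check",
                     roundtrip_check(forces, signals, params, grid,
                                     solver = sc$solver))
  # ---- analytics on the post-transient window ----
  tt <- grid$t[idx]
  f0 <- sc$pulse$fundamental_hz
  ch_free <- if (mode == "1dof") "x_C" else "x2C"
  ch_tvsp_sig <- if (mode == "1dof") "x_M" else "x2M"
  ch_dist <- if (mode == "1dof") "x_TVSP" else "x2TVSP"
  cyc <- function(series) {
    hr_and_amplitude(series[idx], tt, detect_cycles(series[idx], tt, f0))
  }
  cycles <- stage("cycle_metrics", list(
    free = cyc(signals[[ch_free]]),
    tvsp = cyc(signals[[ch_tvsp_sig]]),
    tactile = cyc(signals$x_tactile)
  ))
  spectra <- stage("spectra", list(
    free = spectrum_report(signals[[ch_free]][idx], grid$dt, f0,
                           sc$n_harmonics, sc$delta_f),
    tvsp_distortion = spectrum_report(signals[[ch_dist]][idx], grid$dt, f0,
                                      sc$n_harmonics, sc$delta_f),
    drift_measured = spectrum_report(signals$drift_measured[idx], grid$dt,
                                     f0, sc$n_harmonics, sc$delta_f)
  ))
  cse <- stage("cse_baseline",
               cse_baseline(signals$x_tactile[idx], tt,
                            cycles$tactile$onset_times))
  metrics <- stage("ma_metrics",
                   ma_metrics_window(signals, idx, cycles$free, cycles$tvsp))
  result <- list(scenario = sc, signals = signals, tvsp = tvsp,
                 forces = forces, roundtrip = roundtrip, cycles = cycles,
                 spectra = spectra, cse = cse, metrics = metrics,
                 analysis_idx = which(idx))
  if (!is.null(output_dir)) write_run(result, output_dir)
  invisible(result)
}

# ma_metrics on the analyzed window only (drift/z_b restricted to idx).
ma_metrics_window <- function(signals, idx, metrics_free, metrics_meas) {
  win <- signals
  for (nm in setdiff(names(win), "t")) win[[nm]] <- win[[nm]][idx]
  win$t <- signals$t[idx]
  attr(win, "mode") <- attr(signals, "mode")
  class(win) <- "measured_signals"
  ma_metrics(win, metrics_free, metrics_meas)
}

fmt9 <- function(x) sprintf("%.9g", x)

write_series_csv <- function(df, path) {
  out <- as.data.frame(lapply(df, fmt9), stringsAsFactors = FALSE)
  names(out) <- names(df)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

# Write CSV time series, CSV spectra, JSON metrics/round-trip and a
# manifest for a finished run.
write_run <- function(result, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  sig <- result$signals
  series <- data.frame(t = sig$t)
  for (nm in setdiff(names(sig), "t")) series[[nm]] <- sig[[nm]]
  tv <- result$tvsp
  series$r_t <- tv$r_t; series$zeta_t <- tv$zeta_t
  series$r_total_t <- tv$r_total_t
  fr <- result$forces
  for (nm in setdiff(names(fr), "t")) series[[nm]] <- fr[[nm]]
  write_series_csv(series, file.path(output_dir, "timeseries.csv"))
  for (nm in names(result$spectra)) {
    sp <- result$spectra[[nm]]
    write_series_csv(
      data.frame(frequency_hz = sp$frequency_hz, magnitude = sp$magnitude),
      file.path(output_dir, paste0("spectrum_", nm, ".csv")))
  }
  cyc <- result$cycles$tactile
  ncyc <- length(cyc$hr_per_cycle)
  write_series_csv(
    data.frame(cycle_index = seq_len(ncyc),
               onset_s = cyc$onset_times[seq_len(ncyc)],
               hr_bpm = cyc$hr_per_cycle,
               amplitude = cyc$amplitude_per_cycle),
    file.path(output_dir, "cycles_tactile.csv"))
  jsonlite::write_json(
    c(result$metrics,
      list(harmonic_band_energy_fraction =
             result$spectra$tvsp_distortion$harmonic_band_energy_fraction,
           drift_low_freq_peak_hz =
             result$spectra$drift_measured$low_freq_peak$frequency_hz)),
    file.path(output_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(result$roundtrip,
                       file.path(output_dir, "roundtrip.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(run_manifest(result), file.path(output_dir, "manifest.txt"))
  invisible(output_dir)
}

run_manifest <- function(result) {
  sc <- result$scenario
  c(paste0("pulsema ", as.character(utils::packageVersion("pulsema")),
           " run manifest"),
    paste0("R ", R.version.string),
    paste0("scenario: ", sc$name, " (", sc$mode, ")"),
    "",
    "config:",
    yaml::as.yaml(list(
      mode = sc$mode,
      pulse = sc$pulse[c("fundamental_hz", "amplitudes", "phases", "mode",
                         "force_scale")],
      stack = stack_ratios(sc$params),
      kA = sc$params$kA,
      heart_rate_hz = sc$params$heart_rate_hz,
      ma = unclass(sc$ma),
      coupling = unclass(sc$coupling),
      grid = sc$grid[c("t0", "t_end", "dt")],
      transient_s = sc$transient_s,
      n_harmonics = sc$n_harmonics,
      delta_f = sc$delta_f,
      kA_total = sc$kA_total,
      solver = sc$solver)))
}

#' Sensor-stiffness sweep
#'
#' Reruns a scenario for each sensor-to-stack stiffness ratio and reports
#' how the sensor design changes the measurement: pulse amplitude of the
#' MA-free measured signal, L2 deviation of its normalized waveform from
#' the normalized true pulse, TVSP distortion level, and baseline
#' attenuation.
#'
#' @param base a [scenario()] object.
#' @param ks_over_k0_values numeric vector of stiffness ratios (>= 2
#'   values).
#' @return List with `summary` (one row per ratio) and `runs` (the full
#'   [run_scenario()] results).
#' @export
stiffness_sweep <- function(base, ks_over_k0_values) {
  stopifnot(inherits(base, "pulse_scenario"))
  if (length(ks_over_k0_values) < 2) {
    stop("need at least 2 stiffness ratios", call. = FALSE)
  }
  # The coupling reference displacement is a property of the tissue, not of
  # the sensor: resolve it once from the base design and hold it fixed, so
  # that across designs the parameter modulation stays proportional to the
  # drift each design actually experiences under the same artifact.
  coupling <- base$coupling
  if (is.null(coupling$x_ref)) {
    mode <- if (base$mode == "wall_1dof") "1dof" else "2dof"
    bl <- simulate_baseline(base$params, base$ma, base$grid, mode,
                            solver = base$solver)
    idx <- base$grid$t >= base$grid$t0 + base$transient_s
    x_ref <- max(abs(bl$drift[idx]))
    if (x_ref > 0) coupling$x_ref <- x_ref
  }
  runs <- lapply(ks_over_k0_values, function(r) {
    stack <- base$stack
    stack$ks_over_k0 <- r
    sc <- scenario(name = paste0(base$name, "_ks", r), mode = base$mode,
                   pulse = base$pulse, stack = stack, ma = base$ma,
                   coupling = coupling, grid = base$grid,
                   transient_s = base$transient_s,
                   n_harmonics = base$n_harmonics, delta_f = base$delta_f,
                   kA_total = base$kA_total, solver = base$solver)
    run_scenario(sc)
  })
  # normalized true pulse over the analyzed window (mode-appropriate)
  true_apw <- function(run) {
    sc <- run$scenario
    tt <- sc$grid$t[run$analysis_idx]
    y <- if (sc$mode == "wall_1dof") {
      eval_pulse(sc$pulse, sc$grid)[run$analysis_idx]
    } else {
      run$signals$force[run$analysis_idx] / sc$params$kA
    }
    m <- hr_and_amplitude(y, tt, detect_cycles(y, tt, sc$pulse$fundamental_hz))
    rowMeans(m$apw_normalized)
  }
  summary <- do.call(rbind, lapply(seq_along(runs), function(i) {
    run <- runs[[i]]
    mean_apw <- rowMeans(run$cycles$free$apw_normalized)
    dev <- sqrt(mean((mean_apw - true_apw(run))^2))
    sc <- run$scenario
    ch_dist <- if (sc$mode == "wall_1dof") "x_TVSP" else "x2TVSP"
    data.frame(
      ks_over_k0 = ks_over_k0_values[i],
      pulse_amplitude = mean(run$cycles$free$amplitude_per_cycle),
      apw_l2_deviation = dev,
      tvsp_rms = rms(run$signals[[ch_dist]][run$analysis_idx]),
      tvsp_rms_ratio = run$metrics$tvsp_rms_ratio,
      baseline_attenuation = run$metrics$baseline_attenuation
    )
  }))
  list(summary = summary, runs = runs)
}
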