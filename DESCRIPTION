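Package: pulsema
Title: Motion-Artifact Modelling for Tactile-Sensor Arterial Pulse Measurement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Forward simulation of arterial pulse measurement through a
    tissue-contact-sensor (TCS) stack subject to motion artifacts (MA).
    The stack and a deformable tactile sensor form a base-excited
    mass-spring-damper system (one degree of freedom for wall-displacement
    input, two degrees of freedom for pulsatile-pressure input) whose
    mass, damping and stiffness are modulated in time by MA-induced
    baseline drift. Provides closed-form frequency responses, time-domain
    integration of the time-varying-parameter equations of motion, the
    equivalent-force decomposition of the artifact with a round-trip
    consistency check, and waveform analytics: cycle segmentation,
    per-cycle heart rate and amplitude, normalized pulse waveforms,
    integer-cycle spectra with harmonic-band energy fractions,
    analytic-signal envelopes, and spline-based baseline estimation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
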