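# Example scenario config for pulsema::load_scenario() / the CLI script.
# Omitted blocks fall back to the canonical defaults.
name: example_wall_1dof
mode: wall_1dof
pulse:
  fundamental_hz: 1.0
  amplitudes: [1.0, 0.55, 0.32, 0.18, 0.10, 0.055, 0.03, 0.018, 0.01, 0.006]
  phases: [0.0, -0.4, -0.8, -1.2, -1.6, -2.0, -2.4, -2.8, -3.2, -3.6]
stack:
  kA: 1.0
  k0_over_kA: 0.16666666666666666
  r0: 2.0
  zeta0: 1.5
  ks_over_k0: 6.0
  zeta_s: 1.5
  heart_rate_hz: 1.0
ma:
  amplitudes: [2.0, 0.8]
  frequencies_hz: [0.10, 0.23]
  phases: [0.0, 0.8]
coupling:
  kappa_m: 0.05
  kappa_c: 0.05
  kappa_k: 0.05
grid: {t0: 0.0, t_end: 12.0, dt: 0.001}
transient_s: 2.0
n_harmonics: 10
delta_f: 0.3
solver: {rtol: 1.0e-8, atol: 1.0e-10}
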