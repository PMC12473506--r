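# Shared fixtures. Unit tests run on a short 6 s grid (4 analyzed cycles
# after the 2 s transient); the acceptance suite uses the full canonical
# 12 s grid.

nominal_params <- function(...) build_params(...)

short_grid <- function() time_grid(0, 6, 1e-3)

canonical_grid <- function() time_grid(0, 12, 1e-3)

rel_l2 <- function(x, ref) sqrt(sum((x - ref)^2) / sum(ref^2))

# Run the full pipeline for a scenario on a short grid; shared across tests
# via lazy memoization to keep the suite fast.
.run_cache <- new.env(parent = emptyenv())
run_cached <- function(key, maker) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- maker()
  .run_cache[[key]]
}

short_1dof <- function() {
  run_cached("short_1dof", function() {
    run_scenario(preset_scenario("wall_1dof", grid = short_grid()))
  })
}

short_2dof <- function() {
  run_cached("short_2dof", function() {
    run_scenario(preset_scenario("pressure_2dof", grid = short_grid()))
  })
}
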