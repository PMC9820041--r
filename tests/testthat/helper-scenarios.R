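# Small scenario configurations shared across test files.

tiny_config <- function(seed = 1, ...) {
  scenario_config(n_rows = 6, n_cols = 8, seed = seed, ...)
}

# scenario sized for recovery statistics (1,000 cells; the default size)
recovery_config <- function(seed = 1, ...) {
  scenario_config(n_rows = 25, n_cols = 40, seed = seed, ...)
}

# classification labels for a scenario, via the real pipeline path
classify_scenario <- function(scn) {
  classify_grid(bin_points_to_cells(scn$pois, scn$grid))
}
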