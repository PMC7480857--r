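# shared fixtures, built in code

default_model <- spike_mean_model()

# small experiment used by several structural tests
small_experiment <- function(df = 5, n_trials = 40, seed = 101, ...) {
  run_experiment(df, n_trials = n_trials, seed = seed, ...)
}

# summarise completed durations per percept cell
cell_means <- function(ex) {
  percept_durations(ex) |>
    dplyr::group_by(label, ordinal) |>
    dplyr::summarise(mu = mean(duration_s), n = dplyr::n(), .groups = "drop")
}
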