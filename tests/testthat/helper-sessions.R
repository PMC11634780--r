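# Shared fixtures: small synthetic sessions built once per test run.

# a small standard session (On/Off states, tuning in On, ensembles)
small_session <- local({
  s <- NULL
  function() {
    if (is.null(s)) s <<- simulate_session(
      sim_config(n_units = 12, n_trials_per_condition = 8, seed = 42))
    s
  }
})

# Poisson-like stationary session: no tuning, no evoked, no ensembles
flat_session <- local({
  s <- NULL
  function() {
    if (is.null(s)) s <<- simulate_session(
      sim_config(n_units = 6, n_trials_per_condition = 25,
                 baseline_rate_hz = 5, tuning_gain = 0, evoked_gain = 0,
                 ensemble_mode = "none", seed = 7))
    s
  }
})

# independent Poisson bin lists for CCG tests
poisson_bins <- function(n_trials, N, p, seed) {
  set.seed(seed)
  lapply(seq_len(n_trials), function(i) which(runif(N) < p) - 1L)
}

# ground-truth state intervals as a segments-like data.frame for masking
truth_segments <- function(session) {
  st <- session$truth$states
  structure(st[, c("trial_id", "label", "t_start_ms", "t_end_ms")],
            time_ms = rate_time_axis(0, 1400),
            trial_ids = session$trials$trial_id,
            class = c("state_segments", "data.frame"))
}
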