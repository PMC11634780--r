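# Generator: reproducibility, closed-form rate checks, state-duration
# statistics, coincidence budget, and the auxiliary trace simulators.

test_that("identical seed and config give identical sessions", {
  cfg <- sim_config(n_units = 4, n_trials_per_condition = 3, seed = 9)
  a <- simulate_session(cfg)
  b <- simulate_session(cfg)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$trials, b$trials)
  expect_identical(a$truth$states, b$truth$states)
})

test_that("config validation rejects invalid rates and jitters", {
  expect_error(sim_config(sync_jitter_ms = 12), "10")
  expect_error(sim_config(baseline_rate_hz = 300, evoked_gain = 3,
                          tuning_gain = 3), "Bernoulli")
  expect_error(sim_config(on_mean_ms = 30), "state_min_ms")
})

test_that("unmodulated spiking matches the Poisson mean", {
  # 5 Hz baseline, no evoked/tuning/ensembles: in a 1,000-ms window the
  # expected count is 5 per unit per trial
  s <- flat_session()  # 200 trials x 6 units at 5 Hz
  sel <- s$spikes$t_ms >= 0 & s$spikes$t_ms < 1000
  n_cells <- 6 * nrow(s$trials)
  mean_count <- sum(sel) / n_cells
  expect_lt(abs(mean_count - 5), 3 * sqrt(5 / n_cells))
})

test_that("state-duration means match the configured 192/146 ms", {
  cfg <- sim_config(n_units = 1, n_trials_per_condition = 80, seed = 3)
  s <- simulate_session(cfg)  # 640 trials of state sequences
  st <- s$truth$states
  # drop the final, boundary-truncated interval of every trial
  t_end <- s$trials$go_time_ms[match(st$trial_id, s$trials$trial_id)]
  full <- st$t_end_ms < t_end
  on_mean <- mean(st$t_end_ms[full & st$label == "on"] -
                    st$t_start_ms[full & st$label == "on"])
  off_mean <- mean(st$t_end_ms[full & st$label == "off"] -
                     st$t_start_ms[full & st$label == "off"])
  expect_lt(abs(on_mean - 192) / 192, 0.05)
  expect_lt(abs(off_mean - 146) / 146, 0.05)
  # intervals tile the trial without overlap
  one <- st[st$trial_id == 1, ]
  expect_equal(one$t_start_ms[-1], one$t_end_ms[-nrow(one)])
  expect_equal(one$t_start_ms[1], 0)
})

test_that("injected coincidences respect the configured budget", {
  cfg <- sim_config(n_units = 8, n_trials_per_condition = 20,
                    ensemble_pairs_per_condition = 1, sync_rate_hz = 4,
                    seed = 5)
  s <- simulate_session(cfg)
  cc <- s$truth$coincidences
  expect_true(!is.null(cc))
  # per trial with an active pair: Poisson(sync_rate * window)
  win_s <- vapply(s$trials$trial_id, function(tr)
    (s$trials$go_time_ms[tr] - 500 - 2 * cfg$sync_jitter_ms) / 1000,
    numeric(1))
  expected <- 4 * mean(win_s)
  observed <- nrow(cc) / nrow(s$trials)
  expect_lt(abs(observed - expected),
            4 * sqrt(expected / nrow(s$trials)))
  # ensemble pairs reference valid unit ids
  ens <- do.call(rbind, s$truth$ensembles)
  expect_true(all(ens$unit_a %in% 1:8 & ens$unit_b %in% 1:8))
})

test_that("eye-trace generator books events and rejects bad amplitudes", {
  expect_error(simulate_eye_traces(2, amplitude_deg = c(-1, 0)), "positive")
  ey <- simulate_eye_traces(20, msacc_rate_hz = 0, seed = 2)
  expect_true(all(lengths(ey$events) == 0))
  ey2 <- simulate_eye_traces(50, msacc_rate_hz = 1, seed = 3)
  expect_gt(sum(lengths(ey2$events)), 0)
  # all injected events respect the minimum separation
  seps <- unlist(lapply(ey2$events, function(e) diff(e)))
  expect_true(all(seps >= 150))
})

test_that("phase generator is uniform at kappa 0 and rejects kappa < 0", {
  expect_error(simulate_phases(2, 10, 4, kappa = -1), "non-negative")
  ph <- simulate_phases(2, c(10, 20), 5, kappa = 0, seed = 4)
  expect_equal(dim(ph), c(2, 2, 5, 140))
  expect_true(all(ph > -pi & ph <= pi))
  # Rayleigh-style check of uniformity
  r <- sqrt(mean(sin(ph))^2 + mean(cos(ph))^2)
  expect_lt(r, 0.01)
  expect_warning(simulate_phases(1, 80, 2, kappa = 0, seed = 1), "4-60")
})
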