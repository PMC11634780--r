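# Leave-one-trial-out decoder: chance behaviour, separability, leakage,
# subsampling stability, state restriction, cross-temporal generalisation.

sep_session <- local({
  s <- NULL
  function() {
    if (is.null(s)) s <<- simulate_session(
      sim_config(n_units = 12, n_trials_per_condition = 8, tuning_gain = 8,
                 tuning_width_deg = 40, tuning_during = "all",
                 ensemble_mode = "none", seed = 13))
    s
  }
})

test_that("linearly separable sessions decode almost perfectly", {
  s <- sep_session()
  r <- smooth_and_zscore_rates(s$spikes, s$trials)
  cs <- loo_confidence(r, s$trials, seed = 1)
  expect_gt(delay_accuracy(cs), 0.95)
  # confidence well above chance (ridge tempers it below 1 by design)
  sel <- cs$time_ms >= 500
  expect_gt(mean(cs$conf[, sel]), 0.6)
})

test_that("label-shuffled decoding sits at chance", {
  s <- sep_session()
  r <- smooth_and_zscore_rates(s$spikes, s$trials)
  tr <- s$trials
  set.seed(2)
  tr$cue_location <- sample(tr$cue_location)
  cs <- loo_confidence(r, tr, seed = 1)
  acc <- delay_accuracy(cs)
  expect_lt(abs(acc - 0.5), 1.96 * 0.5 / sqrt(nrow(tr)))
})

test_that("the held-out trial never influences its own training fold", {
  # marker construction: every condition-1 trial sits at +1, every
  # condition-5 trial at -1 on all features, except a marker condition-1
  # trial placed deep on the opposite side.  A leaky decoder that trained
  # on the marker would pull the boundary over and classify it correctly;
  # a clean leave-one-out fit must classify it confidently wrong.
  set.seed(5)
  n_per <- 8
  nu <- 6
  tp <- rate_time_axis(0, 1400)
  vals <- array(0, c(nu, 2 * n_per, length(tp)))
  vals[, 1:n_per, ] <- 1 + rnorm(nu * n_per * length(tp), 0, 0.05)
  vals[, n_per + 1:n_per, ] <- -1 + rnorm(nu * n_per * length(tp), 0, 0.05)
  marker <- 3
  vals[, marker, ] <- -5
  r <- structure(vals, time_ms = tp, zscored = TRUE,
                 class = c("rate_tensor", "array"))
  trials <- data.frame(trial_id = 1:(2 * n_per),
                       cue_location = rep(c(1, 5), each = n_per))
  cs <- loo_confidence(r, trials, timepoints = c(600, 800), seed = 6)
  expect_lt(max(cs$conf[marker, ]), 0.1)
  # the marker does sit in other trials' training folds, so their
  # confidence is dented but stays on the correct side
  expect_gt(min(cs$conf[-marker, ]), 0.5)
})

test_that("equalised subsampling keeps accuracy stable across seeds", {
  s <- sep_session()
  r <- smooth_and_zscore_rates(s$spikes, s$trials)
  a1 <- delay_accuracy(loo_confidence(r, s$trials, seed = 1))
  a2 <- delay_accuracy(loo_confidence(r, s$trials, seed = 99))
  expect_lt(abs(a1 - a2), 0.02)
})

test_that("state-restricted decoding fails loudly without the state", {
  s <- small_session()
  r <- smooth_and_zscore_rates(s$spikes, s$trials)
  seg <- data.frame(trial_id = s$trials$trial_id, label = "off",
                    t_start_ms = 0, t_end_ms = 1400)
  seg <- structure(seg, time_ms = rate_time_axis(0, 1400),
                   trial_ids = s$trials$trial_id,
                   class = c("state_segments", "data.frame"))
  expect_error(state_restricted_accuracy(r, s$trials, seg, "on"),
               "no timepoints")
})

test_that("decoding restricted to true On beats true Off", {
  # no injected synchrony: cue-specific coincidences would add a rate
  # signal that persists through Off states and confound the contrast
  s <- simulate_session(
    sim_config(n_units = 24, n_trials_per_condition = 10,
               ensemble_mode = "none", seed = 17))
  r <- smooth_and_zscore_rates(s$spikes, s$trials)
  seg <- truth_segments(s)
  on <- state_restricted_accuracy(r, s$trials, seg, "on", seed = 2)
  off <- state_restricted_accuracy(r, s$trials, seg, "off", seed = 2)
  expect_gt(on$accuracy, 0.7)
  expect_lt(abs(off$accuracy - 0.5), 0.1)
  expect_gt(on$accuracy, off$accuracy + 0.1)
})

test_that("a stable code generalises across the delay; a rotated one not", {
  s <- sep_session()  # time-invariant tuning
  r <- smooth_and_zscore_rates(s$spikes, s$trials)
  tp <- seq(200, 1300, by = 100)
  ct <- cross_temporal_accuracy(r, s$trials, timepoints = tp, n_perm = 20,
                                seed = 3)
  off_diag <- ct$accuracy[row(ct$accuracy) != col(ct$accuracy)]
  expect_gt(mean(off_diag), 0.85)  # block structure: good generalisation
  expect_true(all(dim(ct$accuracy) == length(tp)))

  # rotate the tuning halfway through the delay: train-early/test-late
  # cells drop to chance
  s2 <- s
  flip <- s2$spikes$t_ms >= 900
  # relabel units by shifting identity: unit u's late spikes come from the
  # unit preferring the orthogonal location
  nu <- 12
  s2$spikes$unit_id <- ifelse(flip, (s2$spikes$unit_id %% nu) + 1,
                              s2$spikes$unit_id)
  r2 <- smooth_and_zscore_rates(s2$spikes, s2$trials)
  ct2 <- cross_temporal_accuracy(r2, s2$trials,
                                 timepoints = c(600, 700, 1200, 1300),
                                 n_perm = 10, seed = 3)
  early_late <- ct2$accuracy[1:2, 3:4]
  within <- c(diag(ct2$accuracy)[1:2], diag(ct2$accuracy)[3:4])
  expect_gt(mean(within), mean(early_late))
})
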