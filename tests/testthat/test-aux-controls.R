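# Microsaccade detection and the phase vs state-onset association.

test_that("quiet traces yield no events; threshold is respected", {
  set.seed(11)
  eyes <- list(x = matrix(rnorm(2 * 1000, 0, 0.002), 2),
               y = matrix(rnorm(2 * 1000, 0, 0.002), 2))
  ev <- detect_microsaccades(eyes)
  expect_true(all(lengths(ev) == 0))
  # sub-threshold events (peak ~5 deg/s) are not detected
  slow <- simulate_eye_traces(10, msacc_rate_hz = 1,
                              amplitude_deg = c(0.11, 0.13), seed = 4)
  expect_gt(sum(lengths(slow$events)), 0)  # events were injected...
  expect_equal(sum(lengths(detect_microsaccades(slow))), 0)  # ...not seen
})

test_that("two peaks 30 ms apart merge under the 50-ms interpeak rule", {
  # two strong saccades injected 30 ms apart
  nt <- 600
  vx <- rep(0, nt)
  prof <- dnorm(seq(-30, 30), 0, 10)
  for (t0 in c(300, 330)) {
    idx <- t0 + seq(-30, 30)
    vx[idx] <- vx[idx] + 0.8 * prof
  }
  eyes <- list(x = matrix(cumsum(vx), 1), y = matrix(0, 1, nt))
  ev <- detect_microsaccades(eyes)
  expect_equal(length(ev[[1]]), 1)
})

test_that("injected microsaccades are recovered with few false alarms", {
  eyes <- simulate_eye_traces(60, msacc_rate_hz = 1, seed = 6)
  det <- detect_microsaccades(eyes)
  hits <- 0; n_true <- 0; n_extra <- 0
  for (i in seq_along(det)) {
    tr <- eyes$events[[i]]
    n_true <- n_true + length(tr)
    matched <- vapply(tr, function(t) any(abs(det[[i]] - t) <= 15),
                      logical(1))
    hits <- hits + sum(matched)
    n_extra <- n_extra + sum(vapply(det[[i]], function(d)
      all(abs(tr - d) > 15), logical(1)))
  }
  expect_gte(hits / n_true, 0.95)
  expect_lte(n_extra / (60 * 1.8), 0.2)  # false alarms per second
  # NaN traces are skipped
  eyes$x[3, 10] <- NaN
  det2 <- detect_microsaccades(eyes)
  expect_null(det2[[3]])
})

test_that("raising the speed threshold never adds events", {
  eyes <- simulate_eye_traces(20, msacc_rate_hz = 1.2, seed = 8)
  n10 <- sum(lengths(detect_microsaccades(eyes, peak_deg_s = 10)))
  n15 <- sum(lengths(detect_microsaccades(eyes, peak_deg_s = 15)))
  n30 <- sum(lengths(detect_microsaccades(eyes, peak_deg_s = 30)))
  expect_true(n10 >= n15 && n15 >= n30)
})

test_that("circular difference is rotation invariant", {
  set.seed(12)
  a <- runif(50, -pi, pi)
  b <- runif(60, -pi, pi)
  d0 <- ang_diff(circ_mean(a), circ_mean(b))
  for (rot in c(0.5, 2, -3)) {
    d1 <- ang_diff(circ_mean(wmstates:::wrap_angle(a + rot)),
                   circ_mean(wmstates:::wrap_angle(b + rot)))
    expect_equal(d1, d0, tolerance = 1e-10)
  }
  expect_true(all(ang_diff(c(0, 1, 3), c(3, -1, -3)) >= 0))
  expect_lte(max(ang_diff(runif(100, -pi, pi), runif(100, -pi, pi))), pi)
})

fake_segments <- function(n_trials, seed = 1) {
  set.seed(seed)
  rows <- do.call(rbind, lapply(seq_len(n_trials), function(i) {
    starts <- sort(sample(seq(500, 1300, by = 10), 4))
    data.frame(trial_id = i, label = c("on", "off", "on", "off"),
               t_start_ms = starts, t_end_ms = starts + 50)
  }))
  structure(rows, time_ms = rate_time_axis(0, 1400),
            trial_ids = seq_len(n_trials),
            class = c("state_segments", "data.frame"))
}

test_that("phase-state z is null-calibrated and finds localized locking", {
  seg <- fake_segments(30)
  ons <- state_onsets(seg)
  freqs <- c(8, 10, 12)
  # kappa = 0: z approximately standard normal
  ph0 <- simulate_phases(3, freqs, 30, kappa = 0, seed = 2)
  r0 <- phase_state_association(ph0, seg, n_perm = 300, seed = 3)
  expect_true(all(abs(r0$z) < 3))
  # strong locking at 10 Hz only
  ph1 <- simulate_phases(3, freqs, 30, kappa = 5, locked = TRUE,
                         onsets = ons, lock_freqs = 10, seed = 4)
  r1 <- phase_state_association(ph1, seg, n_perm = 300, seed = 5)
  expect_gt(r1$z[2], 3)
  expect_lt(max(abs(r1$z[c(1, 3)])), 3)
  # cohort-level cluster test flags the locked frequency
  zmat <- rbind(r1$z, r1$z * 0.8 + rnorm(3, 0, 0.2), r1$z * 1.2)
  ct <- phase_state_cluster_test(zmat, n_perm = 200, seed = 6)
  expect_true(nrow(ct$clusters) >= 1)
  hit <- any(ct$clusters$start <= 2 & ct$clusters$end >= 2)
  expect_true(hit)
})

test_that("too few onsets abort the phase association", {
  seg <- fake_segments(1)
  ph <- simulate_phases(1, 10, 1, kappa = 0, seed = 7)
  expect_error(phase_state_association(ph, seg, n_perm = 10),
               "too few|onsets")
})
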