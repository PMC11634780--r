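# Cross-correlograms: brute-force equivalence, shift/self properties,
# jitter expectation vs Monte-Carlo, significance rule, state masking.

# O(N^2) brute-force CCG oracle straight from the definition
brute_ccg <- function(ras, L) {
  N <- dim(ras)[3]
  ntr <- dim(ras)[2]
  counts <- numeric(2 * L + 1)
  den <- numeric(2 * L + 1)
  for (tau in -L:L) {
    num <- 0; nj <- 0; nk <- 0
    for (i in seq_len(ntr)) {
      xj <- ras[1, i, ]; xk <- ras[2, i, ]
      for (t in seq_len(N)) {
        tp <- t - tau
        if (tp >= 1 && tp <= N) num <- num + xj[tp] * xk[t]
      }
      if (tau >= 0) {
        nj <- nj + sum(xj[seq_len(N - tau)])
        nk <- nk + sum(xk[(tau + 1):N])
      } else {
        nj <- nj + sum(xj[(1 - tau):N])
        nk <- nk + sum(xk[seq_len(N + tau)])
      }
    }
    counts[tau + L + 1] <- num
    den[tau + L + 1] <- sqrt(nj * nk)
  }
  list(counts = counts, denom = den)
}

rand_raster <- function(ntr, N, p, seed) {
  set.seed(seed)
  ras <- array(as.integer(runif(2 * ntr * N) < p), c(2, ntr, N))
  structure(ras, window = c(0, N), unit_ids = 1:2, trial_ids = seq_len(ntr),
            class = c("binary_raster", "array"))
}

test_that("coincidence counts and denominators match brute force exactly", {
  ras <- rand_raster(6, 180, 0.03, 31)
  cc <- compute_ccg(ras, c(1, 2), max_lag = 25)
  or <- brute_ccg(ras, 25)
  expect_identical(as.numeric(cc$counts), or$counts)
  expect_equal(cc$denom, or$denom)
})

test_that("shift and self-correlation behave as the definition demands", {
  ras <- rand_raster(5, 150, 0.04, 32)
  # k = j shifted by +3 bins
  ras2 <- ras
  ras2[2, , ] <- 0L
  ras2[2, , 4:150] <- ras[1, , 1:147]
  cc <- compute_ccg(ras2, c(1, 2), max_lag = 20)
  expect_equal(cc$lag[which.max(cc$raw)], 3)
  # identical trains: raw CCG(0) = 1
  ras3 <- ras
  ras3[2, , ] <- ras3[1, , ]
  cc0 <- compute_ccg(ras3, c(1, 2), max_lag = 20)
  expect_equal(cc0$raw[21], 1)
})

test_that("raw CCG is symmetric under pair exchange and lag reversal", {
  ras <- rand_raster(5, 160, 0.03, 33)
  a <- compute_ccg(ras, c(1, 2), max_lag = 30)
  b <- compute_ccg(ras, c(2, 1), max_lag = 30)
  expect_equal(a$raw, rev(b$raw))
  expect_identical(as.numeric(a$counts), rev(as.numeric(b$counts)))
})

test_that("closed-form jitter expectation matches Monte-Carlo resampling", {
  ras <- rand_raster(8, 200, 0.03, 34)
  jexp <- jitter_expectation(ras, c(1, 2), max_lag = 30)
  mc <- ccg_jitter_mc(ras, c(1, 2), max_lag = 30, n_resamples = 1000,
                      seed = 7)
  se <- apply(mc, 2, sd) / sqrt(nrow(mc))
  dev <- abs(colMeans(mc) - jexp) / pmax(se, 1e-12)
  expect_lt(max(dev, na.rm = TRUE), 3)
})

test_that("jitter correction removes slow co-modulation, keeps fast peaks", {
  set.seed(35)
  ntr <- 30; N <- 900
  ras <- array(0L, c(2, ntr, N))
  for (i in seq_len(ntr)) {
    # shared slow (150-ms period) envelope: conditionally independent
    env <- 0.006 * (1 + 0.9 * sin(2 * pi * (seq_len(N) + runif(1, 0, N)) /
                                    150))
    ras[1, i, ] <- as.integer(runif(N) < env)
    ras[2, i, ] <- as.integer(runif(N) < env)
    # injected fast coincidences at +2 ms
    ev <- which(runif(N - 2) < 0.003)
    ras[1, i, ev] <- 1L
    ras[2, i, ev + 2] <- 1L
  }
  ras <- structure(ras, window = c(0, N), unit_ids = 1:2,
                   trial_ids = seq_len(ntr),
                   class = c("binary_raster", "array"))
  cc <- compute_ccg(ras, c(1, 2))
  # raw pedestal present away from the peak (slow co-modulation)
  base_idx <- c(52:100, 102:150)  # |tau| in 51..99 wrt index 101 = 0
  raw_base <- mean(cc$raw[c(101 - 99:51, 101 + 51:99)])
  chance <- mean(cc$raw[c(101 - 40:20, 101 + 20:40)])
  corr_base <- cc$corrected[c(101 - 99:51, 101 + 51:99)]
  expect_gt(raw_base, 0)
  expect_lt(abs(mean(corr_base)), 3 * sd(corr_base) / sqrt(98))
  # injected +2-ms peak survives the correction
  fl <- flag_significant_ccg(cc)
  expect_true(fl$significant)
  expect_equal(fl$peak_lag, 2)
})

test_that("the significance rule excludes zero lag and needs 7 SDs", {
  corr <- rep(0, 201)
  corr[-101] <- rnorm(200, 0, 0.001)
  corr[101] <- 1  # peak only at tau = 0
  fl <- flag_significant_ccg(corr)
  expect_false(fl$significant)
  corr2 <- corr
  corr2[101] <- 0
  corr2[103] <- 1  # tau = +2
  fl2 <- flag_significant_ccg(corr2)
  expect_true(fl2$significant)
  expect_equal(fl2$peak_lag, 2)
  # zero baseline SD -> insignificant with flag
  fl3 <- flag_significant_ccg(rep(0, 201))
  expect_false(fl3$significant)
  expect_equal(fl3$base_sd, 0)
})

test_that("peak ties break toward smaller |lag|, then negative", {
  corr <- rep(0, 201)
  corr[101 + 5] <- 0.5
  corr[101 - 5] <- 0.5
  corr[101 + 8] <- 0.5
  corr[c(101 - 99:51, 101 + 51:99)] <- rnorm(98, 0, 1e-4)
  fl <- flag_significant_ccg(corr)
  expect_equal(fl$peak_lag, -5)
})

test_that("an identity state mask reproduces the unrestricted census", {
  s <- small_session()
  ras <- bin_raster(s$spikes, c(500, 1400), unit_ids = 1:12,
                    trial_ids = s$trials$trial_id)
  all_seg <- data.frame(trial_id = s$trials$trial_id, label = "on",
                        t_start_ms = 0, t_end_ms = 1700)
  all_seg <- structure(all_seg, time_ms = rate_time_axis(0, 1400),
                       trial_ids = s$trials$trial_id,
                       class = c("state_segments", "data.frame"))
  cen_full <- significant_ccg_census(ras, s$trials)
  cen_mask <- state_restricted_ccg(ras, s$trials, all_seg, "on")
  expect_identical(cen_full$sig, cen_mask$sig)
  expect_identical(cen_full$peak_lag, cen_mask$peak_lag)
  # empty mask -> warning and empty census
  none_seg <- all_seg[0, ]
  none_seg <- structure(none_seg, time_ms = rate_time_axis(0, 1400),
                        trial_ids = s$trials$trial_id,
                        class = c("state_segments", "data.frame"))
  expect_warning(cen0 <- state_restricted_ccg(ras, s$trials, none_seg,
                                              "on"), "no time")
  expect_equal(nrow(cen0$edge_table), 0)
})

test_that("connection probability falls with distance for proximal wiring", {
  cfg <- sim_config(n_units = 14, n_trials_per_condition = 12,
                    ensemble_pairs_per_condition = 4,
                    ensemble_bias = "proximal", sync_rate_hz = 4, seed = 19)
  s <- simulate_session(cfg)
  ras <- bin_raster(s$spikes, c(500, 1400), unit_ids = 1:14,
                    trial_ids = s$trials$trial_id)
  cen <- significant_ccg_census(ras, s$trials)
  dd <- distance_dependence(cen, s$truth$units$depth_um, n_bins = 4)
  expect_true(is.data.frame(dd$table))
  expect_lt(dd$r, 0)
  expect_error(distance_dependence(cen, NULL), "missing")
})
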