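# Rate smoothing, binarisation, unit filters, subtype ANOVA, noise SD.

test_that("a single spike spreads as a 100-ms boxcar of height 10 sp/s", {
  spikes <- data.frame(unit_id = 1, trial_id = 1, t_ms = 0)
  trials <- data.frame(trial_id = 1, cue_location = 1, delay_ms = 1500,
                       go_time_ms = 1550)
  r <- smooth_and_zscore_rates(spikes, trials, zscore = FALSE)
  tax <- attr(r, "time_ms")
  hot <- tax > -50 & tax <= 50
  expect_equal(as.vector(r[1, 1, hot]), rep(10, 10))
  expect_true(all(r[1, 1, !hot] == 0))
  # mass conservation: sum(rate) * dt = 1 spike
  expect_equal(sum(r) * 0.01, 1)
})

test_that("smoothing conserves spike mass away from window edges", {
  s <- small_session()
  r <- smooth_and_zscore_rates(s$spikes, s$trials, zscore = FALSE)
  # spikes within the interior of the rate window (edge effects bounded by
  # the boxcar half-width)
  interior <- s$spikes$t_ms >= -350 & s$spikes$t_ms < 1340
  n_interior <- sum(interior)
  total_mass <- sum(r) * 0.01
  n_window <- sum(s$spikes$t_ms >= -450 & s$spikes$t_ms < 1450)
  expect_gte(total_mass, n_interior * 0.999)
  expect_lte(total_mass, n_window * 1.001)
})

test_that("homogeneous 5-Hz trains smooth to ~5 sp/s everywhere", {
  s <- flat_session()
  r <- smooth_and_zscore_rates(s$spikes, s$trials, zscore = FALSE,
                               t_start = 0, t_end = 1400)
  per_tp <- apply(r, 3, mean)
  expect_true(all(abs(per_tp - 5) < 0.5))
})

test_that("z-scored tensors have per-(unit, timepoint) mean 0 and SD 1", {
  s <- small_session()
  r <- smooth_and_zscore_rates(s$spikes, s$trials)
  mu <- apply(r, c(1, 3), mean)
  sg <- apply(r, c(1, 3), sd)
  expect_lt(max(abs(mu)), 1e-10)
  expect_true(all(abs(sg - 1) < 1e-10 | sg == 0))
})

test_that("binarisation clips multiple spikes and is idempotent", {
  spikes <- data.frame(unit_id = 1, trial_id = 1, t_ms = c(500.2, 500.7))
  ras <- bin_raster(spikes, window = c(500, 510))
  expect_equal(sum(ras), 1)
  expect_equal(ras[1, 1, 1], 1L)
  # empty train -> all-zero raster
  ras0 <- bin_raster(data.frame(unit_id = integer(0), trial_id = integer(0),
                                t_ms = numeric(0)),
                     window = c(0, 100), unit_ids = 1, trial_ids = 1)
  expect_true(all(ras0 == 0))
  expect_error(bin_raster(spikes, window = c(510, 500)), "inverted")
  # total <= spike count, equality iff no bin receives two spikes
  s <- small_session()
  ras2 <- bin_raster(s$spikes, window = c(500, 1400))
  n_in <- sum(s$spikes$t_ms >= 500 & s$spikes$t_ms < 1400)
  expect_lte(sum(ras2), n_in)
})

test_that("unit filters are nested and monotone", {
  meta <- data.frame(unit_id = 1:4,
                     total_spikes = c(999, 10000, 1500, 20000),
                     mean_rate_hz = c(2, 0.5, 1.5, 3))
  f <- filter_units(meta)
  expect_false(1 %in% f$analysis_units)  # 999 spikes: excluded everywhere
  expect_true(2 %in% f$analysis_units)   # 10k spikes but 0.5 Hz
  expect_false(2 %in% f$ccg_units)
  expect_true(all(f$ccg_units %in% f$analysis_units))
  # raising thresholds never adds units
  f2 <- filter_units(meta, min_total_spikes = 2000, min_rate_hz = 2)
  expect_true(all(f2$analysis_units %in% f$analysis_units))
  expect_true(all(f2$ccg_units %in% f$ccg_units))
  # all units above both thresholds -> both subsets equal input
  f3 <- filter_units(meta, min_total_spikes = 0, min_rate_hz = 0.1)
  expect_equal(f3$analysis_units, meta$unit_id)
  expect_equal(f3$ccg_units, meta$unit_id)
})

test_that("functional subtyping recovers epoch-specific selectivity", {
  set.seed(21)
  n_tr <- 64
  trials <- data.frame(trial_id = 1:n_tr,
                       cue_location = rep(1:8, each = n_tr / 8),
                       delay_ms = 1400, go_time_ms = 1450)
  mk_unit <- function(uid, vis_gain, mem_gain) {
    do.call(rbind, lapply(seq_len(n_tr), function(i) {
      g <- if (trials$cue_location[i] == 1) 1 else 0
      r_vis <- 8 * (1 + vis_gain * g)
      r_mem <- 8 * (1 + mem_gain * g)
      t1 <- runif(rpois(1, r_vis * 0.3), 0, 300)
      t2 <- runif(rpois(1, r_mem * 0.9), 500, 1400)
      t3 <- runif(rpois(1, 8 * 0.2), 1450, 1650)
      data.frame(unit_id = uid, trial_id = i, t_ms = c(t1, t2, t3))
    }))
  }
  spikes <- rbind(mk_unit(1, 0, 4),   # delay-only tuning
                  mk_unit(2, 4, 4),   # evoked + delay tuning
                  mk_unit(3, 0, 0))   # untuned
  out <- classify_functional_subtype(spikes, trials)
  expect_equal(out$subtype[out$unit_id == 1], "memory")
  expect_equal(out$subtype[out$unit_id == 2], "visual+memory")
  expect_false(out$memory[out$unit_id == 3])
})

test_that("noise SD estimator is calibrated, equivariant and robust", {
  set.seed(2)
  x <- rnorm(1e6)
  expect_lt(abs(estimate_noise_sd(x) - 1), 0.01)
  expect_equal(estimate_noise_sd(3.7 * x), 3.7 * estimate_noise_sd(x))
  expect_warning(estimate_noise_sd(numeric(10)), "all-zero")
  expect_error(estimate_noise_sd(numeric(0)), "empty")
  # heavy tails: robust estimate below the sample SD
  xt <- rt(1e5, df = 3)
  expect_lt(estimate_noise_sd(xt), sd(xt))
})

test_that("csv round trip preserves spike and trial tables", {
  s <- small_session()
  tf <- tempfile(fileext = ".csv")
  write.csv(s$spikes, tf, row.names = FALSE)
  sp <- read_spike_table(tf)
  expect_equal(nrow(sp), nrow(s$spikes))
  tf2 <- tempfile(fileext = ".csv")
  write.csv(s$trials, tf2, row.names = FALSE)
  tr <- read_trial_table(tf2)
  expect_equal(tr$cue_location, s$trials$cue_location)
  # incorrect trials are dropped on ingest
  t2 <- s$trials
  t2$correct[1:3] <- FALSE
  write.csv(t2, tf2, row.names = FALSE)
  expect_equal(nrow(read_trial_table(tf2)), nrow(t2) - 3)
})
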