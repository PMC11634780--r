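# Confidence z-scoring and On/Off segmentation, including the brute-force
# cluster-mass oracle.

# build a synthetic null_confidence object directly
fake_null <- function(conf, null_array, time_ms = NULL) {
  if (is.null(time_ms)) time_ms <- seq(0, by = 10,
                                       length.out = ncol(conf))
  structure(list(conf = conf, null = null_array,
                 mean = apply(null_array, c(1, 2), mean),
                 sd = apply(null_array, c(1, 2), sd),
                 time_ms = time_ms, trial_ids = seq_len(nrow(conf))),
            class = "null_confidence")
}

test_that("z-scoring reproduces (conf - mean) / sd cell by cell", {
  set.seed(3)
  nul <- array(runif(2 * 10 * 20, 0.3, 0.7), c(2, 10, 20))
  nc <- fake_null(matrix(0.5, 2, 10), nul)
  z <- zscore_confidence(nc$conf, nc)
  expect_equal(z, (0.5 - nc$mean) / nc$sd)
  # conf equal to null mean -> z = 0; mean + 2 sd -> z = 2
  nc2 <- fake_null(nc$mean, nul)
  expect_true(all(abs(zscore_confidence(nc2$conf, nc2)) < 1e-12))
  nc3 <- fake_null(nc$mean + 2 * nc$sd, nul)
  expect_true(all(abs(zscore_confidence(nc3$conf, nc3) - 2) < 1e-12))
})

test_that("flat z yields no On states and one spanning Off state", {
  set.seed(4)
  nul <- array(runif(1 * 140 * 20, 0.4, 0.6), c(1, 140, 20))
  nc <- fake_null(matrix(0.5, 1, 140), nul)
  z <- matrix(0, 1, 140)
  seg <- label_states(z, nc)
  expect_equal(sum(seg$label == "on"), 0)
  off <- seg[seg$label == "off", ]
  expect_equal(nrow(off), 1)
  expect_equal(off$t_start_ms, 0)
  expect_equal(off$t_end_ms, 1400)
})

test_that("cluster retention matches a brute-force enumeration oracle", {
  # tiny series: 20 timepoints, 12 shuffles, 3 trials; the oracle
  # recomputes every shuffle's leave-one-out z-series, enumerates cluster
  # masses by hand, and rebuilds the retention decisions independently
  set.seed(5)
  n_tr <- 3; n_tp <- 20; n_sh <- 12
  nul <- array(rbeta(n_tr * n_tp * n_sh, 2, 2), c(n_tr, n_tp, n_sh))
  conf <- matrix(rbeta(n_tr * n_tp, 2, 2), n_tr, n_tp)
  conf[1, 5:7] <- 0.999   # one strong 3-point run in trial 1
  nc <- fake_null(conf, nul)
  z <- zscore_confidence(conf, nc)
  seg <- label_states(z, nc)

  # --- oracle ---
  masses <- c()
  for (i in 1:n_tr) for (s in 1:n_sh) {
    rest <- nul[i, , -s, drop = FALSE]
    mu <- apply(rest, 2, mean)
    sg <- apply(rest, 2, sd)
    zs <- (nul[i, , s] - mu) / sg
    above <- zs > 1.96
    best <- 0
    run <- 0
    for (q in seq_len(n_tp)) {
      run <- if (isTRUE(above[q])) run + zs[q] else 0
      best <- max(best, run)
    }
    masses <- c(masses, best)
  }
  thr <- quantile(masses, 0.95, names = FALSE)
  expect_equal(attr(seg, "mass_threshold"), thr)
  # per-trial decisions
  for (i in 1:n_tr) {
    above <- z[i, ] > 1.96
    r <- rle(as.vector(above))
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    expected_on <- rep(FALSE, n_tp)
    for (q in which(r$values)) {
      idx <- starts[q]:ends[q]
      if (sum(z[i, idx]) > thr) expected_on[idx] <- TRUE
    }
    got_on <- rep(FALSE, n_tp)
    si <- seg[seg$trial_id == i & seg$label == "on", ]
    for (rr in seq_len(nrow(si))) {
      got_on[(si$t_start_ms[rr] / 10 + 1):(si$t_end_ms[rr] / 10)] <- TRUE
    }
    expect_equal(got_on, expected_on)
  }
})

test_that("raising the On entry threshold never increases On coverage", {
  set.seed(6)
  n_tr <- 4; n_tp <- 60; n_sh <- 15
  nul <- array(rbeta(n_tr * n_tp * n_sh, 2, 2), c(n_tr, n_tp, n_sh))
  conf <- matrix(rbeta(n_tr * n_tp, 4, 2), n_tr, n_tp)
  nc <- fake_null(conf, nul)
  z <- zscore_confidence(conf, nc)
  on_total <- function(z_on) {
    seg <- label_states(z, nc, z_on = z_on)
    sum(seg$t_end_ms[seg$label == "on"] -
          seg$t_start_ms[seg$label == "on"])
  }
  tot <- vapply(c(1.5, 1.96, 2.5, 3.2), on_total, numeric(1))
  expect_true(all(diff(tot) <= 0))
})

test_that("state summaries count intervals and report the end state", {
  seg <- data.frame(trial_id = c(1, 1, 2),
                    label = c("on", "off", "on"),
                    t_start_ms = c(0, 200, 100),
                    t_end_ms = c(200, 1400, 1400))
  seg <- structure(seg, time_ms = seq(0, 1390, 10), trial_ids = 1:2,
                   class = c("state_segments", "data.frame"))
  st <- summarize_states(seg)
  expect_equal(st$n_on, c(1, 1))
  expect_equal(st$n_off, c(1, 0))
  expect_equal(st$mean_on_ms, mean(c(200, 1300)))
  expect_equal(unname(st$state_at_end), c("off", "on"))
})

test_that("off threshold is one-sided by default with a two-sided option", {
  set.seed(8)
  n_tp <- 40
  nul <- array(rbeta(1 * n_tp * 15, 2, 2), c(1, n_tp, 15))
  nc <- fake_null(matrix(0.5, 1, n_tp), nul)
  z <- matrix(-1.5, 1, n_tp)  # strongly negative but not "incorrect"
  seg1 <- label_states(z, nc)
  expect_true(any(seg1$label == "off"))
  seg2 <- label_states(z, nc, two_sided_off = TRUE)
  # |z| = 1.5 exceeds the two-sided 1.2816 bound: not Off under that rule
  expect_false(any(seg2$label == "off"))
})
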