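# Synthetic session generator.
#
# Spikes are inhomogeneous Bernoulli trains at 1-ms resolution.  A single
# population-shared sequence of alternating On/Off epochs is drawn per trial;
# von Mises cue tuning multiplies the baseline rate only inside On epochs
# (optionally throughout the delay), and a cue transient multiplies it inside
# the evoked window.  Designated "ensemble" pairs additionally receive
# synchronous spike pairs at a configurable rate, irrespective of state, so
# that cue information persists in pairwise correlations even when rate
# tuning is absent.  Every generated quantity is recorded as ground truth.

#' Configuration for a synthetic working-memory session
#'
#' Defaults reproduce the headline session statistics of the motivating
#' recordings: 8 cue locations at 45 degree spacing, a 50-ms cue, a
#' 1,400-1,600-ms delay, ~5.8 Hz baseline rates, and population-coordinated
#' On/Off epochs with mean durations 192 ms and 146 ms.
#'
#' @param n_units number of simultaneously recorded units
#' @param n_trials_per_condition trials per cue location
#' @param n_conditions number of cue locations (8 for the standard protocol)
#' @param baseline_rate_hz spontaneous firing rate (Hz)
#' @param tuning_gain peak multiplicative rate gain at the preferred location
#'   during On states (0 disables cue information in rates)
#' @param tuning_width_deg angular width (deg) of the von Mises tuning profile
#' @param evoked_gain multiplicative gain of the cue transient
#' @param evoked_window_ms two-vector, window of the cue transient (ms)
#' @param on_mean_ms,off_mean_ms mean durations of On and Off epochs (ms)
#' @param state_shape gamma shape of the duration distribution
#' @param state_min_ms minimum epoch duration (ms); durations are
#'   `state_min_ms + gamma(state_shape)` with the configured mean preserved
#' @param ensemble_pairs_per_condition number of synchronous pairs per cue
#' @param sync_rate_hz rate (Hz) of injected coincidences per ensemble pair
#' @param sync_jitter_ms lag spread of injected coincidences (must be <= 10 so
#'   the injected structure falls inside the CCG peak-search window)
#' @param sync_window_ms window (ms, cue-aligned) in which coincidences are
#'   injected; the default covers the analysed memory delay while leaving the
#'   evoked window free of synchrony
#' @param delay_range_ms range of delay durations (ms after cue offset)
#' @param cue_ms cue duration (ms)
#' @param time_step_ms simulation step (1 ms)
#' @param state_mode `"population"` for one shared state sequence per trial,
#'   `"per_unit"` for independent sequences (detector-specificity control)
#' @param tuning_during `"on"` restricts tuning to On epochs, `"all"` applies
#'   it throughout cue and delay (state-blind control)
#' @param ensemble_mode `"condition_specific"` draws a distinct pair set per
#'   cue, `"shared"` uses one set active in every condition (null for the
#'   graph-distance test), `"none"` disables synchrony
#' @param ensemble_bias `"same_pref"` (pairs among units preferring the
#'   condition; co-tuned pairs are the reported structure of delay
#'   ensembles), `"uniform"` (independence control) or `"proximal"`
#'   (nearby units favoured)
#' @param seed integer RNG seed
#' @return an object of class `sim_config`
#' @export
sim_config <- function(n_units = 64L, n_trials_per_condition = 20L,
                       n_conditions = 8L, baseline_rate_hz = 5.8,
                       tuning_gain = 4, tuning_width_deg = 60,
                       evoked_gain = 2, evoked_window_ms = c(30, 300),
                       on_mean_ms = 192, off_mean_ms = 146,
                       state_shape = 2, state_min_ms = 50,
                       ensemble_pairs_per_condition = 2L, sync_rate_hz = 3,
                       sync_jitter_ms = 2, sync_window_ms = NULL,
                       delay_range_ms = c(1400, 1600), cue_ms = 50,
                       time_step_ms = 1, state_mode = "population",
                       tuning_during = "on",
                       ensemble_mode = "condition_specific",
                       ensemble_bias = "same_pref", seed = 1L) {
  cfg <- list(
    n_units = as.integer(n_units),
    n_trials_per_condition = as.integer(n_trials_per_condition),
    n_conditions = as.integer(n_conditions),
    baseline_rate_hz = baseline_rate_hz, tuning_gain = tuning_gain,
    tuning_width_deg = tuning_width_deg, evoked_gain = evoked_gain,
    evoked_window_ms = evoked_window_ms, on_mean_ms = on_mean_ms,
    off_mean_ms = off_mean_ms, state_shape = state_shape,
    state_min_ms = state_min_ms,
    ensemble_pairs_per_condition = as.integer(ensemble_pairs_per_condition),
    sync_rate_hz = sync_rate_hz, sync_jitter_ms = sync_jitter_ms,
    sync_window_ms = sync_window_ms, delay_range_ms = delay_range_ms,
    cue_ms = cue_ms, time_step_ms = time_step_ms,
    state_mode = match.arg(state_mode, c("population", "per_unit")),
    tuning_during = match.arg(tuning_during, c("on", "all")),
    ensemble_mode = match.arg(ensemble_mode,
                              c("condition_specific", "shared", "none")),
    ensemble_bias = match.arg(ensemble_bias,
                              c("uniform", "same_pref", "proximal")),
    seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_units >= 1, cfg$n_trials_per_condition >= 1,
            cfg$baseline_rate_hz >= 0, cfg$tuning_gain >= 0,
            cfg$on_mean_ms > 0, cfg$off_mean_ms > 0,
            cfg$sync_rate_hz >= 0, cfg$state_min_ms >= 0)
  if (cfg$sync_jitter_ms > 10)
    stop("sync_jitter_ms must be <= 10 (injected structure must fall ",
         "inside the <=10-ms CCG peak window)")
  if (cfg$on_mean_ms <= cfg$state_min_ms || cfg$off_mean_ms <= cfg$state_min_ms)
    stop("state mean durations must exceed state_min_ms")
  peak_rate <- cfg$baseline_rate_hz * (1 + cfg$evoked_gain) *
    (1 + cfg$tuning_gain)
  if (peak_rate * cfg$time_step_ms / 1000 >= 1)
    stop("rate x dt >= 1 per bin: Bernoulli approximation invalid; ",
         "reduce rates or gains")
  invisible(cfg)
}

# one alternating On/Off sequence tiling [0, t_end); durations are
# state_min + gamma(shape, mean - state_min) so configured means are exact
draw_state_sequence <- function(t_end, cfg, first = "on") {
  labels <- character(0)
  starts <- numeric(0)
  t <- 0
  lab <- first
  while (t < t_end) {
    m <- if (lab == "on") cfg$on_mean_ms else cfg$off_mean_ms
    d <- cfg$state_min_ms +
      rgamma(1, shape = cfg$state_shape,
             scale = (m - cfg$state_min_ms) / cfg$state_shape)
    labels <- c(labels, lab)
    starts <- c(starts, t)
    t <- t + d
    lab <- if (lab == "on") "off" else "on"
  }
  ends <- c(starts[-1], t_end)
  data.frame(label = labels, t_start_ms = starts, t_end_ms = pmin(ends, t_end))
}

# von Mises tuning shape in [0, 1] over conditions, peak 1 at preferred
tuning_shape <- function(pref, n_cond, width_deg) {
  ang <- (seq_len(n_cond) - pref) * (360 / n_cond) * pi / 180
  kappa <- 1 / (width_deg * pi / 180)^2
  exp(kappa * (cos(ang) - 1))
}

draw_ensemble_pairs <- function(cfg, pref, depth) {
  all_pairs <- which(upper.tri(matrix(0, cfg$n_units, cfg$n_units)),
                     arr.ind = TRUE)
  pick <- function(cond, k) {
    if (k == 0 || cfg$n_units < 2) {
      return(data.frame(unit_a = integer(0), unit_b = integer(0)))
    }
    idx <- seq_len(nrow(all_pairs))
    w <- rep(1, nrow(all_pairs))
    if (cfg$ensemble_bias == "same_pref" && !is.null(cond)) {
      ok <- pref[all_pairs[, 1]] == cond & pref[all_pairs[, 2]] == cond
      if (sum(ok) >= k) idx <- which(ok)
    } else if (cfg$ensemble_bias == "proximal") {
      d <- abs(depth[all_pairs[, 1]] - depth[all_pairs[, 2]])
      w <- exp(-d / 400)
    }
    w <- w[idx] / sum(w[idx])
    sel <- if (length(idx) == 1) idx else
      sample(idx, min(k, length(idx)), prob = w)
    data.frame(unit_a = all_pairs[sel, 1], unit_b = all_pairs[sel, 2])
  }
  if (cfg$ensemble_mode == "none") {
    lapply(seq_len(cfg$n_conditions), function(c)
      data.frame(unit_a = integer(0), unit_b = integer(0)))
  } else if (cfg$ensemble_mode == "shared") {
    shared <- pick(NULL, cfg$ensemble_pairs_per_condition)
    lapply(seq_len(cfg$n_conditions), function(c) shared)
  } else {
    lapply(seq_len(cfg$n_conditions), function(c)
      pick(c, cfg$ensemble_pairs_per_condition))
  }
}

#' Simulate one synthetic working-memory session
#'
#' @param config a [sim_config()]
#' @return a list of class `wm_session` with elements `spikes`
#'   (data.frame: unit_id, trial_id, t_ms relative to cue onset), `trials`
#'   (trial metadata), and `truth` (ground truth: per-trial state intervals,
#'   unit preferences and depths, ensemble pairs per condition, injected
#'   coincidence times)
#' @export
simulate_session <- function(config) {
  cfg <- validate_sim_config(config)
  set.seed(cfg$seed)
  n_trials <- cfg$n_trials_per_condition * cfg$n_conditions
  cond <- sample(rep(seq_len(cfg$n_conditions), cfg$n_trials_per_condition))
  delay <- sample(seq(cfg$delay_range_ms[1], cfg$delay_range_ms[2]),
                  n_trials, replace = TRUE)
  trials <- data.frame(
    trial_id = seq_len(n_trials), cue_location = cond,
    cue_angle_deg = (cond - 1) * (360 / cfg$n_conditions), delay_ms = delay,
    task_type = rep_len(c("MTS", "MGS"), n_trials), correct = TRUE,
    go_time_ms = cfg$cue_ms + delay)

  pref <- sample(rep_len(seq_len(cfg$n_conditions), cfg$n_units))
  depth <- seq(0, 3840, length.out = cfg$n_units)
  shapes <- vapply(pref, tuning_shape, numeric(cfg$n_conditions),
                   n_cond = cfg$n_conditions,
                   width_deg = cfg$tuning_width_deg)  # cond x unit

  ens <- draw_ensemble_pairs(cfg, pref, depth)

  t0 <- WM_RATE_START
  base_p <- cfg$baseline_rate_hz * cfg$time_step_ms / 1000
  ev <- cfg$evoked_window_ms
  sync_win <- cfg$sync_window_ms

  spk_unit <- vector("list", n_trials)
  spk_time <- vector("list", n_trials)
  states <- vector("list", n_trials)
  coinc <- vector("list", n_trials)

  for (i in seq_len(n_trials)) {
    t_end <- cfg$cue_ms + delay[i]
    bins <- seq(t0, t_end - 1)  # 1-ms bin left edges
    nb <- length(bins)
    seq_states <- draw_state_sequence(t_end, cfg)
    seq_states$trial_id <- trials$trial_id[i]
    states[[i]] <- seq_states

    on_mask <- rep(FALSE, nb)
    for (r in which(seq_states$label == "on")) {
      sel <- bins >= seq_states$t_start_ms[r] & bins < seq_states$t_end_ms[r]
      on_mask[sel] <- TRUE
    }
    tun_mask <- if (cfg$tuning_during == "all") bins >= 0 else on_mask
    ev_mask <- bins >= ev[1] & bins < ev[2]

    sh <- shapes[cond[i], ]  # per-unit tuning shape for this trial's cue
    rate <- base_p *
      (1 + cfg$evoked_gain * outer(sh, ev_mask)) *
      (1 + cfg$tuning_gain * outer(sh, tun_mask))
    fired <- matrix(runif(cfg$n_units * nb), cfg$n_units, nb) < rate
    hit <- which(fired, arr.ind = TRUE)
    u <- hit[, 1]
    tm <- bins[hit[, 2]]

    pairs <- ens[[cond[i]]]
    if (cfg$ensemble_mode == "shared") pairs <- ens[[1]]
    cc <- NULL
    if (cfg$ensemble_mode != "none" && nrow(pairs) > 0 &&
        cfg$sync_rate_hz > 0) {
      win <- if (is.null(sync_win)) c(WM_DELAY[1], t_end) else sync_win
      win[2] <- min(win[2], t_end)
      dur_s <- (win[2] - win[1] - 2 * cfg$sync_jitter_ms) / 1000
      out <- vector("list", nrow(pairs))
      for (p in seq_len(nrow(pairs))) {
        n_ev <- rpois(1, cfg$sync_rate_hz * dur_s)
        if (n_ev == 0) next
        ta <- runif(n_ev, win[1] + cfg$sync_jitter_ms,
                    win[2] - cfg$sync_jitter_ms)
        # synaptic-style latency: |lag| in [0.5, jitter] ms, random sign,
        # so the injected mass avoids the zero-lag bin that the
        # significance rule excludes
        lag <- sample(c(-1, 1), n_ev, replace = TRUE) *
          runif(n_ev, 0.5, max(cfg$sync_jitter_ms, 0.6))
        tb <- ta + lag
        out[[p]] <- data.frame(trial_id = trials$trial_id[i],
                               unit_a = pairs$unit_a[p],
                               unit_b = pairs$unit_b[p],
                               t_a_ms = floor(ta), t_b_ms = floor(tb))
      }
      cc <- do.call(rbind, out)
      if (!is.null(cc) && nrow(cc) > 0) {
        u <- c(u, cc$unit_a, cc$unit_b)
        tm <- c(tm, cc$t_a_ms, cc$t_b_ms)
      }
    }
    coinc[[i]] <- cc
    dup <- duplicated(cbind(u, tm))
    spk_unit[[i]] <- u[!dup]
    spk_time[[i]] <- tm[!dup]
  }

  n_per <- vapply(spk_unit, length, integer(1))
  spikes <- data.frame(
    unit_id = unlist(spk_unit),
    trial_id = rep(trials$trial_id, n_per),
    t_ms = unlist(spk_time))
  spikes <- spikes[order(spikes$unit_id, spikes$trial_id, spikes$t_ms), ]
  rownames(spikes) <- NULL

  truth <- list(
    states = do.call(rbind, states),
    units = data.frame(unit_id = seq_len(cfg$n_units), preferred = pref,
                       gain = cfg$tuning_gain, depth_um = depth),
    ensembles = ens,
    coincidences = if (length(coinc)) do.call(rbind, coinc) else NULL,
    config = cfg)

  structure(list(spikes = spikes, trials = trials, truth = truth),
            class = "wm_session")
}

#' @export
print.wm_session <- function(x, ...) {
  cfg <- x$truth$config
  cat("<wm_session> ", cfg$n_units, " units, ", nrow(x$trials), " trials, ",
      nrow(x$spikes), " spikes\n", sep = "")
  invisible(x)
}

#' Simulate fixational eye traces with injected microsaccades
#'
#' Horizontal/vertical position at 1 kHz: random-walk drift plus white
#' measurement noise, with injected microsaccades whose velocity profile is a
#' symmetric Gaussian (sigma 10 ms).  An event of amplitude `a` degrees has
#' peak speed `a / (0.010 * sqrt(2*pi))` deg/s (~40 deg/s per degree).
#'
#' @param n_trials number of trials
#' @param msacc_rate_hz mean microsaccade rate (Hz); events closer than
#'   `min_sep_ms` to an accepted event are thinned
#' @param amplitude_deg two-vector amplitude range (deg); must be positive
#' @param duration_ms trace duration per trial
#' @param drift_sd random-walk step SD (deg per sqrt ms)
#' @param noise_sd white position noise SD (deg)
#' @param min_sep_ms minimum separation between injected events
#' @param seed RNG seed
#' @return list with `x`, `y` (trials x time matrices, deg, 1 kHz) and
#'   `events` (list of injected event times, ms, per trial)
#' @export
simulate_eye_traces <- function(n_trials, msacc_rate_hz = 0.8,
                                amplitude_deg = c(0.3, 1.2),
                                duration_ms = 1800, drift_sd = 0.002,
                                noise_sd = 0.002, min_sep_ms = 150,
                                seed = 1L) {
  if (any(amplitude_deg <= 0)) stop("amplitude range must be positive")
  set.seed(as.integer(seed))
  nt <- as.integer(duration_ms)
  x <- matrix(0, n_trials, nt)
  y <- matrix(0, n_trials, nt)
  events <- vector("list", n_trials)
  prof_t <- seq(-30, 30)
  prof <- dnorm(prof_t, 0, 10)  # deg/ms per unit amplitude
  for (i in seq_len(n_trials)) {
    vx <- rnorm(nt, 0, drift_sd)
    vy <- rnorm(nt, 0, drift_sd)
    n_ev <- rpois(1, msacc_rate_hz * duration_ms / 1000)
    tt <- sort(runif(n_ev, 50, duration_ms - 50))
    keep <- numeric(0)
    for (t in tt) {
      if (!length(keep) || t - keep[length(keep)] >= min_sep_ms)
        keep <- c(keep, t)
    }
    for (t in keep) {
      a <- runif(1, amplitude_deg[1], amplitude_deg[2])
      th <- runif(1, 0, 2 * pi)
      idx <- round(t) + prof_t
      ok <- idx >= 1 & idx <= nt
      vx[idx[ok]] <- vx[idx[ok]] + a * cos(th) * prof[ok]
      vy[idx[ok]] <- vy[idx[ok]] + a * sin(th) * prof[ok]
    }
    x[i, ] <- cumsum(vx) + rnorm(nt, 0, noise_sd)
    y[i, ] <- cumsum(vy) + rnorm(nt, 0, noise_sd)
    events[[i]] <- keep
  }
  list(x = x, y = y, events = events, sampling_hz = 1000)
}

#' Simulate LFP phase arrays, optionally locked to state onsets
#'
#' Phases are i.i.d. uniform on (-pi, pi] except that, when `locked = TRUE`
#' and `kappa > 0`, the samples at On-state onsets are drawn from a von Mises
#' distribution around a channel-specific mean and those at Off-state onsets
#' around a mean rotated by `mean_separation`.  The default separation is a
#' quarter turn: with means a full half-turn apart, label permutations of a
#' balanced sample produce mean directions pinned to the locking axis, the
#' null difference distribution becomes bimodal at 0 and pi, and the
#' permutation z-score saturates near 1.5 however strong the locking — so a
#' half-turn fixture cannot demonstrate detector power.
#'
#' @param n_channels,n_trials array dimensions
#' @param freqs_hz frequencies of interest (4-60 Hz analysis range)
#' @param kappa von Mises concentration (>= 0) of the state locking
#' @param locked lock phases at state onsets?
#' @param onsets list per trial with elements `on` and `off`: onset times (ms)
#'   on the 10-ms grid; required when `locked = TRUE`
#' @param lock_freqs frequencies (subset of `freqs_hz`) that carry the
#'   locking; default all
#' @param time_axis_ms phase sample times (100 Hz grid)
#' @param seed RNG seed
#' @return array channels x freqs x trials x time with attribute `time_ms`
#' @export
simulate_phases <- function(n_channels, freqs_hz, n_trials, kappa = 0,
                            locked = FALSE, onsets = NULL, lock_freqs = NULL,
                            mean_separation = pi / 2,
                            time_axis_ms = rate_time_axis(0, 1400), seed = 1L) {
  if (kappa < 0) stop("kappa must be non-negative")
  if (any(freqs_hz < 4 | freqs_hz > 60))
    warning("frequencies outside the 4-60 Hz analysis range")
  set.seed(as.integer(seed))
  nf <- length(freqs_hz)
  nt <- length(time_axis_ms)
  ph <- array(runif(n_channels * nf * n_trials * nt, -pi, pi),
              dim = c(n_channels, nf, n_trials, nt))
  if (locked && kappa > 0) {
    if (is.null(onsets)) stop("onsets required when locked = TRUE")
    if (is.null(lock_freqs)) lock_freqs <- freqs_hz
    mu <- runif(n_channels, -pi, pi)
    fidx <- which(freqs_hz %in% lock_freqs)
    for (i in seq_len(n_trials)) {
      for (what in c("on", "off")) {
        ts <- onsets[[i]][[what]]
        ts <- ts[ts >= min(time_axis_ms) & ts <= max(time_axis_ms)]
        if (!length(ts)) next
        sidx <- vapply(ts, function(t) which.min(abs(time_axis_ms - t)),
                       integer(1))
        shift <- if (what == "on") 0 else mean_separation
        for (ch in seq_len(n_channels)) {
          for (f in fidx) {
            ph[ch, f, i, sidx] <-
              rvonmises(length(sidx), mu[ch] + shift, kappa)
          }
        }
      }
    }
  }
  attr(ph, "time_ms") <- time_axis_ms
  attr(ph, "freqs_hz") <- freqs_hz
  ph
}
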