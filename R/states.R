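# On/Off state segmentation of decoder-confidence time series.
#
# The true confidence series is z-scored against a 50-replicate shuffled-
# label null; runs of z > 1.96 are cluster-corrected by comparing their mass
# (sum of z) with the 95th percentile of the null cluster-mass distribution,
# itself built by z-scoring each shuffle series against the remaining
# shuffles and collecting the maximal cluster mass, pooled across trials.
# Runs of at least five consecutive points below the P > 0.20 threshold
# (z < 0.8416, one-sided) are Off states; retained clusters of z < -1.96 by
# the mirrored procedure are "incorrect" states; other points stay
# unlabelled.

#' Shuffled-label null confidence ensemble
#'
#' Repeats the leave-one-trial-out decoding `n_shuffles` times with the
#' training labels permuted for every test trial, yielding a per-trial null
#' distribution of confidence time series.
#'
#' @inheritParams loo_confidence
#' @param n_shuffles number of shuffled replicates (default 50)
#' @return list of class `null_confidence`: `conf` (true series), `null`
#'   (trials x timepoints x shuffles), `mean`, `sd` (per cell), `time_ms`
#' @export
build_null_confidence <- function(rates, trials, n_shuffles = 50,
                                  timepoints = NULL, lambda = 50, seed = 1L) {
  if (n_shuffles < 10)
    warning("fewer than 10 shuffles gives an unstable null")
  cs <- loo_confidence(rates, trials, timepoints = timepoints,
                       lambda = lambda, n_shuffles = n_shuffles, seed = seed)
  out <- list(conf = cs$conf, null = cs$null,
              mean = apply(cs$null, c(1, 2), mean),
              sd = apply(cs$null, c(1, 2), sd),
              time_ms = cs$time_ms,
              trial_ids = trials$trial_id)
  class(out) <- "null_confidence"
  out
}

#' Z-score confidence against its shuffled-label null
#'
#' @param conf trials x timepoints confidence matrix (or a
#'   `confidence_series`)
#' @param null a `null_confidence` object
#' @return matrix of z-values (NA where the null SD is zero)
#' @export
zscore_confidence <- function(conf, null) {
  if (inherits(conf, "confidence_series")) conf <- conf$conf
  stopifnot(all(dim(conf) == dim(null$mean)))
  z <- (conf - null$mean) / null$sd
  z[null$sd == 0] <- NA
  z
}

# cluster masses of runs of z > thr within one series; returns numeric(0)
# when no run exists
cluster_masses <- function(z, thr) {
  runs <- true_runs(z > thr)
  if (!nrow(runs)) return(numeric(0))
  vapply(seq_len(nrow(runs)), function(r)
    sum(z[runs$start[r]:runs$end[r]]), numeric(1))
}

# pooled null distribution of maximal cluster masses: each shuffle series is
# z-scored against the remaining shuffles; sign = -1 gives the mirrored
# (below-null) distribution
null_cluster_masses <- function(null, z_thr, sign = 1) {
  ns <- dim(null$null)[3]
  out <- matrix(0, nrow(null$conf), ns)
  for (s in seq_len(ns)) {
    rest <- null$null[, , -s, drop = FALSE]
    mu <- apply(rest, c(1, 2), mean)
    sg <- apply(rest, c(1, 2), sd)
    zs <- sign * (null$null[, , s] - mu) / sg
    zs[sg == 0] <- NA
    for (i in seq_len(nrow(zs))) {
      m <- cluster_masses(zs[i, ], z_thr)
      out[i, s] <- if (length(m)) max(m) else 0
    }
  }
  as.vector(out)
}

#' Label On, Off and incorrect states from a confidence z-series
#'
#' @param z trials x timepoints z matrix from [zscore_confidence()]
#' @param null the `null_confidence` the z was computed from (source of the
#'   cluster-mass null)
#' @param z_on entry threshold for On clusters (1.96)
#' @param off_p one-sided Off threshold as a P-value (0.20; points with
#'   z < qnorm(1 - off_p) count as "no information")
#' @param min_off_pts minimum Off run length in timepoints (5 = 50 ms)
#' @param two_sided_off use |z| < qnorm(1 - off_p/2) instead of the one-sided
#'   rule
#' @param null_pool `"pooled"` builds one cluster-mass null across all trials
#'   of the session; `"per_trial"` thresholds each trial against its own
#' @return data.frame of class `state_segments` (trial_id, label, t_start_ms,
#'   t_end_ms) with attributes `time_ms`, `trial_ids`, `mass_threshold`
#' @export
label_states <- function(z, null, z_on = 1.96, off_p = 0.20,
                         min_off_pts = 5, two_sided_off = FALSE,
                         null_pool = c("pooled", "per_trial")) {
  null_pool <- match.arg(null_pool)
  time_ms <- null$time_ms
  step <- diff(time_ms[1:2])
  masses_pos <- null_cluster_masses(null, z_on, sign = 1)
  masses_neg <- null_cluster_masses(null, z_on, sign = -1)
  if (null_pool == "pooled") {
    thr_pos <- quantile(masses_pos, 0.95, names = FALSE, na.rm = TRUE)
    thr_neg <- quantile(masses_neg, 0.95, names = FALSE, na.rm = TRUE)
  }
  ns <- dim(null$null)[3]
  off_thr <- if (two_sided_off) qnorm(1 - off_p / 2) else qnorm(1 - off_p)

  rows <- list()
  for (i in seq_len(nrow(z))) {
    zi <- z[i, ]
    if (null_pool == "per_trial") {
      mp <- matrix(masses_pos, ncol = ns)[i, ]
      mn <- matrix(masses_neg, ncol = ns)[i, ]
      thr_pos <- quantile(mp, 0.95, names = FALSE, na.rm = TRUE)
      thr_neg <- quantile(mn, 0.95, names = FALSE, na.rm = TRUE)
    }
    lab <- rep(NA_character_, length(zi))
    on_runs <- true_runs(zi > z_on)
    for (r in seq_len(nrow(on_runs))) {
      idx <- on_runs$start[r]:on_runs$end[r]
      if (sum(zi[idx]) > thr_pos) lab[idx] <- "on"
    }
    inc_runs <- true_runs(-zi > z_on)
    for (r in seq_len(nrow(inc_runs))) {
      idx <- inc_runs$start[r]:inc_runs$end[r]
      if (sum(-zi[idx]) > thr_neg) lab[idx] <- "incorrect"
    }
    off_ok <- (if (two_sided_off) abs(zi) < off_thr else zi < off_thr) &
      is.na(lab)
    off_runs <- true_runs(off_ok)
    for (r in seq_len(nrow(off_runs))) {
      idx <- off_runs$start[r]:off_runs$end[r]
      if (length(idx) >= min_off_pts) lab[idx] <- "off"
    }
    runs <- rle(ifelse(is.na(lab), "unlabeled", lab))
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    keep <- runs$values != "unlabeled"
    if (any(keep)) {
      rows[[length(rows) + 1]] <- data.frame(
        trial_id = null$trial_ids[i], label = runs$values[keep],
        t_start_ms = time_ms[starts[keep]],
        t_end_ms = time_ms[ends[keep]] + step)
    }
  }
  seg <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trial_id = integer(0), label = character(0),
               t_start_ms = numeric(0), t_end_ms = numeric(0))
  structure(seg, time_ms = time_ms, trial_ids = null$trial_ids,
            mass_threshold = if (null_pool == "pooled") thr_pos else NA,
            class = c("state_segments", "data.frame"))
}

#' Summary statistics of a state segmentation
#'
#' @param segments a `state_segments` object
#' @param window restrict to intervals overlapping this window (NULL = all)
#' @return list: per-trial counts of On/Off/incorrect states, duration
#'   vectors, means and medians, and the state at the end of the labelling
#'   span per trial
#' @export
summarize_states <- function(segments, window = NULL) {
  seg <- as.data.frame(segments)
  if (!is.null(window))
    seg <- seg[seg$t_end_ms > window[1] & seg$t_start_ms < window[2], ,
               drop = FALSE]
  trial_ids <- attr(segments, "trial_ids")
  if (is.null(trial_ids)) trial_ids <- sort(unique(seg$trial_id))
  cnt <- function(lab) {
    tab <- table(factor(seg$trial_id[seg$label == lab], levels = trial_ids))
    as.vector(tab)
  }
  dur <- function(lab) {
    s <- seg[seg$label == lab, , drop = FALSE]
    s$t_end_ms - s$t_start_ms
  }
  time_ms <- attr(segments, "time_ms")
  state_at_end <- vapply(trial_ids, function(tr) {
    s <- seg[seg$trial_id == tr, , drop = FALSE]
    if (!nrow(s)) return(NA_character_)
    last <- max(time_ms)
    hit <- s$label[s$t_start_ms <= last & s$t_end_ms > last]
    if (length(hit)) hit[1] else s$label[which.max(s$t_end_ms)]
  }, character(1))
  list(n_on = cnt("on"), n_off = cnt("off"), n_incorrect = cnt("incorrect"),
       on_durations_ms = dur("on"), off_durations_ms = dur("off"),
       mean_on_ms = mean(dur("on")), mean_off_ms = mean(dur("off")),
       median_on_ms = median(dur("on")), median_off_ms = median(dur("off")),
       mean_n_on = mean(cnt("on")), mean_n_off = mean(cnt("off")),
       mean_n_incorrect = mean(cnt("incorrect")),
       state_at_end = setNames(state_at_end, trial_ids))
}

#' Timepoint-level balanced accuracy of a segmentation against ground truth
#'
#' Compares predicted On/Off labels with ground-truth state intervals on the
#' 10-ms grid (midpoint rule); predicted unlabelled or incorrect points are
#' excluded.
#'
#' @param segments a `state_segments` object
#' @param truth_states ground-truth intervals (trial_id, label, t_start_ms,
#'   t_end_ms) from the generator
#' @param window evaluation window (default the memory delay)
#' @return list: balanced accuracy, On sensitivity, Off sensitivity
#' @export
segments_balanced_accuracy <- function(segments, truth_states,
                                       window = WM_DELAY) {
  time_ms <- attr(segments, "time_ms")
  time_ms <- time_ms[time_ms >= window[1] & time_ms < window[2]]
  trial_ids <- attr(segments, "trial_ids")
  mid <- time_ms + diff(time_ms[1:2]) / 2
  lab_at <- function(df, tr, t) {
    s <- df[df$trial_id == tr & df$t_start_ms <= t & df$t_end_ms > t, ]
    if (nrow(s)) s$label[1] else NA_character_
  }
  pred <- truth <- character(0)
  for (tr in trial_ids) {
    p <- vapply(mid, function(t) lab_at(as.data.frame(segments), tr, t),
                character(1))
    g <- vapply(mid, function(t) lab_at(truth_states, tr, t), character(1))
    pred <- c(pred, p)
    truth <- c(truth, g)
  }
  ok <- pred %in% c("on", "off") & truth %in% c("on", "off")
  sens_on <- mean(pred[ok & truth == "on"] == "on")
  sens_off <- mean(pred[ok & truth == "off"] == "off")
  list(balanced_accuracy = mean(c(sens_on, sens_off)),
       on_sensitivity = sens_on, off_sensitivity = sens_off,
       n_points = sum(ok))
}
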