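# Control analyses: velocity-threshold microsaccade detection and the LFP
# phase vs state-onset association test.

gaussian_kernel <- function(sigma_ms, dt = 1) {
  r <- ceiling(4 * sigma_ms / dt)
  t <- seq(-r, r, by = dt)
  k <- exp(-t^2 / (2 * sigma_ms^2))
  k / sum(k)
}

smooth_conv <- function(x, k) {
  r <- (length(k) - 1) / 2
  xp <- c(rep(x[1], r), x, rep(x[length(x)], r))
  as.numeric(stats::filter(xp, k, sides = 2))[(r + 1):(r + length(x))]
}

#' Detect microsaccades from 1-kHz eye traces
#'
#' Positions are smoothed with a Gaussian kernel (sigma 4.75 ms, truncated
#' at 4 sigma), differentiated (central differences) to velocity, and
#' combined to speed (root sum of squares).  Speed peaks above 10 deg/s with
#' at least 50 ms separation are events; trials containing non-finite
#' samples are skipped.
#'
#' @param eyes list with `x`, `y` trials x time matrices (deg, 1 kHz), as
#'   from [simulate_eye_traces()]
#' @param sigma_ms smoothing kernel SD
#' @param peak_deg_s minimum peak speed
#' @param min_sep_ms minimum interpeak distance
#' @return list per trial of event times (ms); skipped trials give NULL
#' @export
detect_microsaccades <- function(eyes, sigma_ms = 4.75, peak_deg_s = 10,
                                 min_sep_ms = 50) {
  k <- gaussian_kernel(sigma_ms)
  out <- vector("list", nrow(eyes$x))
  for (i in seq_len(nrow(eyes$x))) {
    xi <- eyes$x[i, ]
    yi <- eyes$y[i, ]
    if (any(!is.finite(xi)) || any(!is.finite(yi))) next
    xs <- smooth_conv(xi, k)
    ys <- smooth_conv(yi, k)
    n <- length(xs)
    vx <- c(0, (xs[3:n] - xs[1:(n - 2)]) / 2, 0) * 1000  # deg/s
    vy <- c(0, (ys[3:n] - ys[1:(n - 2)]) / 2, 0) * 1000
    speed <- sqrt(vx^2 + vy^2)
    out[[i]] <- find_speed_peaks(speed, peak_deg_s, min_sep_ms)
  }
  out
}

find_speed_peaks <- function(speed, height, min_sep) {
  n <- length(speed)
  is_peak <- c(FALSE, speed[2:(n - 1)] > speed[1:(n - 2)] &
                 speed[2:(n - 1)] >= speed[3:n], FALSE) & speed >= height
  cand <- which(is_peak)
  if (!length(cand)) return(numeric(0))
  cand <- cand[order(speed[cand], decreasing = TRUE)]
  kept <- numeric(0)
  for (p in cand) {
    if (!length(kept) || all(abs(kept - p) >= min_sep)) kept <- c(kept, p)
  }
  sort(kept) - 1  # times in ms (0-based sample index at 1 kHz)
}

#' On/Off state onset times from a segmentation
#'
#' @param segments a `state_segments` object
#' @param window restrict onsets to this window (default the memory delay)
#' @return list per trial with elements `on` and `off` (onset times, ms)
#' @export
state_onsets <- function(segments, window = WM_DELAY) {
  trial_ids <- attr(segments, "trial_ids")
  seg <- as.data.frame(segments)
  lapply(trial_ids, function(tr) {
    s <- seg[seg$trial_id == tr & seg$t_start_ms >= window[1] &
               seg$t_start_ms < window[2], ]
    list(on = s$t_start_ms[s$label == "on"],
         off = s$t_start_ms[s$label == "off"])
  })
}

#' LFP phase vs state-onset association
#'
#' Per channel and frequency, the magnitude of the angular difference
#' between the circular mean phases at On-state and Off-state onsets is
#' compared with a null obtained by permuting the On/Off labels of the
#' pooled onsets; the resulting z-scores are averaged over channels,
#' yielding one phase-state score per frequency.
#'
#' @param phases array channels x freqs x trials x time from
#'   [simulate_phases()] (or any source with a `time_ms` attribute)
#' @param segments a `state_segments` object on the same trial order
#' @param n_perm label permutations (1000)
#' @param min_onsets minimum onsets per label (5)
#' @param seed RNG seed
#' @return list: `z` per frequency (channel-averaged), `z_by_channel`
#'   (channels x freqs), `freqs_hz`
#' @export
phase_state_association <- function(phases, segments, n_perm = 1000,
                                    min_onsets = 5, seed = 1L) {
  time_ms <- attr(phases, "time_ms")
  freqs <- attr(phases, "freqs_hz")
  ons <- state_onsets(segments)
  set.seed(as.integer(seed))
  n_ch <- dim(phases)[1]
  n_f <- dim(phases)[2]
  # pool (trial, sample index, label) across trials
  tri <- integer(0); sidx <- integer(0); lab <- integer(0)
  for (i in seq_along(ons)) {
    for (what in c("on", "off")) {
      ts <- ons[[i]][[what]]
      if (!length(ts)) next
      si <- vapply(ts, function(t) which.min(abs(time_ms - t)), integer(1))
      tri <- c(tri, rep(i, length(si)))
      sidx <- c(sidx, si)
      lab <- c(lab, rep(if (what == "on") 1L else 0L, length(si)))
    }
  }
  if (sum(lab == 1) < min_onsets || sum(lab == 0) < min_onsets)
    stop("too few state onsets for the phase association test")
  zs <- matrix(NA_real_, n_ch, n_f)
  perms <- replicate(n_perm, sample(lab), simplify = FALSE)
  for (ch in seq_len(n_ch)) {
    for (f in seq_len(n_f)) {
      ph <- phases[cbind(ch, f, tri, sidx)]
      stat <- function(l) ang_diff(circ_mean(ph[l == 1]),
                                   circ_mean(ph[l == 0]))
      obs <- stat(lab)
      nil <- vapply(perms, stat, numeric(1))
      sg <- sd(nil)
      zs[ch, f] <- if (sg > 0) (obs - mean(nil)) / sg else NA
    }
  }
  list(z = colMeans(zs, na.rm = TRUE), z_by_channel = zs, freqs_hz = freqs)
}

#' Across-session cluster test of phase-state scores over frequency
#'
#' One-sided test that the channel-averaged z-scores exceed zero at each
#' frequency, cluster-corrected along the frequency axis (nearest-neighbour
#' adjacency, entry threshold z 1.645) with a sign-flip permutation null.
#'
#' @param z_mat sessions x frequencies matrix of phase-state z-scores
#' @param entry_z cluster entry threshold on the across-session t-like
#'   statistic
#' @param n_perm sign-flip permutations
#' @param seed RNG seed
#' @return list: `t` per frequency, `clusters` (start, end, mass, p)
#' @export
phase_state_cluster_test <- function(z_mat, entry_z = 1.645, n_perm = 1000,
                                     seed = 1L) {
  set.seed(as.integer(seed))
  tstat <- function(m) {
    mu <- colMeans(m)
    se <- apply(m, 2, sd) / sqrt(nrow(m))
    ifelse(se > 0, mu / se, 0)
  }
  obs <- tstat(z_mat)
  obs_runs <- true_runs(obs > entry_z)
  null_max <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    flip <- sample(c(-1, 1), nrow(z_mat), replace = TRUE)
    tn <- tstat(z_mat * flip)
    m <- cluster_masses(tn, entry_z)
    null_max[p] <- if (length(m)) max(m) else 0
  }
  clusters <- data.frame(start = integer(0), end = integer(0),
                         mass = numeric(0), p = numeric(0))
  for (r in seq_len(nrow(obs_runs))) {
    mass <- sum(obs[obs_runs$start[r]:obs_runs$end[r]])
    pval <- (1 + sum(null_max >= mass)) / (1 + n_perm)
    clusters <- rbind(clusters,
                      data.frame(start = obs_runs$start[r],
                                 end = obs_runs$end[r], mass = mass,
                                 p = pval))
  }
  list(t = obs, clusters = clusters)
}
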