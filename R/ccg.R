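# Jitter-corrected cross-correlograms and the significant-connection rule.
#
# CCG(tau) for a pair (j, k) in condition c counts coincidences
# x_j(t - tau) * x_k(t) over trials, normalised by the geometric mean of the
# two units' spike counts over the bins entering the sum.  The jitter null
# redistributes unit k's spikes within 25-ms windows (anchored at the window
# start), preserving the across-trial PSTH and each trial's window counts;
# its closed-form expectation is subtracted from the raw CCG.  A pair is a
# putative functional connection if the corrected CCG peaks within 10 ms of
# zero (zero lag excluded) at more than seven SDs above the mean of the
# high-lag baseline (50 < |tau| < 100 ms).

ccg_defaults <- list(max_lag = 100L, jitter_window = 25L, z_thresh = 7,
                     peak_max = 10L, base_lo = 51L, base_hi = 99L)

raster_pair_bins <- function(raster, pair, trial_sel) {
  lapply(pair, function(u)
    lapply(trial_sel, function(i) which(raster[u, i, ] == 1L) - 1L))
}

#' Raw normalised cross-correlogram for one pair
#'
#' @param raster 0/1 array from [bin_raster()] over the analysis window
#' @param pair two unit indices (j, k); positive lags mean k fires after j
#' @param trial_sel trial indices defining the condition (default: all)
#' @param max_lag lag range in bins (ms)
#' @param jitter_window jitter window (ms) used for the correction fields
#' @return list of class `ccg_result`: `lag`, `counts`, `raw`, `jitter`,
#'   `corrected`, `denom`
#' @export
compute_ccg <- function(raster, pair, trial_sel = NULL,
                        max_lag = ccg_defaults$max_lag,
                        jitter_window = ccg_defaults$jitter_window) {
  if (is.null(trial_sel)) trial_sel <- seq_len(dim(raster)[2])
  if (jitter_window <= 1) stop("jitter window must exceed 1 ms")
  bins <- raster_pair_bins(raster, pair, trial_sel)
  nsp <- vapply(bins, function(u) sum(lengths(u)), numeric(1))
  if (any(nsp == 0))
    stop("zero spikes for a unit in this condition: pair excluded")
  res <- ccg_pair_core(bins[[1]], bins[[2]], dim(raster)[3],
                       as.integer(max_lag), as.integer(jitter_window))
  structure(res, pair = pair, class = "ccg_result")
}

#' Closed-form jitter expectation of a CCG
#'
#' Convenience accessor: the `jitter` component of [compute_ccg()].
#' @inheritParams compute_ccg
#' @return numeric vector over lags -max_lag..max_lag
#' @export
jitter_expectation <- function(raster, pair, trial_sel = NULL,
                               max_lag = ccg_defaults$max_lag,
                               jitter_window = ccg_defaults$jitter_window) {
  compute_ccg(raster, pair, trial_sel, max_lag, jitter_window)$jitter
}

#' Monte-Carlo jitter resamples of a CCG
#'
#' Explicitly resamples the second train within jitter windows (spike counts
#' per trial-window preserved, positions drawn proportional to the
#' across-trial PSTH) and recomputes the normalised CCG; the mean over
#' resamples converges to the closed-form expectation.
#'
#' @inheritParams compute_ccg
#' @param n_resamples number of resampled CCGs
#' @param seed RNG seed
#' @return matrix n_resamples x lags
#' @export
ccg_jitter_mc <- function(raster, pair, trial_sel = NULL,
                          max_lag = ccg_defaults$max_lag,
                          jitter_window = ccg_defaults$jitter_window,
                          n_resamples = 1000, seed = 1L) {
  if (is.null(trial_sel)) trial_sel <- seq_len(dim(raster)[2])
  bins <- raster_pair_bins(raster, pair, trial_sel)
  set.seed(as.integer(seed))
  ccg_jitter_mc_core(bins[[1]], bins[[2]], dim(raster)[3],
                     as.integer(max_lag), as.integer(jitter_window),
                     as.integer(n_resamples))
}

#' Significance of a jitter-corrected CCG
#'
#' Baseline mean/SD from lags 51-99 ms (both signs); peak searched over
#' 1 <= |tau| <= 10 ms, zero lag excluded, ties broken toward smaller |tau|
#' then negative lag; significant iff peak > mean + 7 SD.
#'
#' @param ccg a `ccg_result` (or a corrected-CCG vector over -100..100)
#' @param z_thresh SD threshold (7)
#' @param peak_max peak-search lag bound (10 ms)
#' @param base baseline lag range (c(51, 99))
#' @return list: `significant`, `peak`, `peak_lag`, `peak_z`, `base_mean`,
#'   `base_sd`
#' @export
flag_significant_ccg <- function(ccg, z_thresh = ccg_defaults$z_thresh,
                                 peak_max = ccg_defaults$peak_max,
                                 base = c(ccg_defaults$base_lo,
                                          ccg_defaults$base_hi)) {
  corr <- if (is.list(ccg)) ccg$corrected else ccg
  L <- (length(corr) - 1) / 2
  at <- function(tau) corr[tau + L + 1]
  bvals <- c(at(-(base[1]:base[2])), at(base[1]:base[2]))
  bvals <- bvals[!is.na(bvals)]
  if (length(bvals) < 2)
    return(list(significant = FALSE, peak = NA, peak_lag = NA,
                peak_z = NA, base_mean = NA, base_sd = NA))
  mu <- mean(bvals)
  sg <- sd(bvals)
  best <- -Inf
  best_lag <- NA_integer_
  for (a in seq_len(peak_max)) {
    for (tau in c(-a, a)) {
      v <- at(tau)
      if (!is.na(v) && v > best) { best <- v; best_lag <- tau }
    }
  }
  if (sg == 0)
    return(list(significant = FALSE, peak = best, peak_lag = best_lag,
                peak_z = NA, base_mean = mu, base_sd = 0))
  list(significant = best > mu + z_thresh * sg, peak = best,
       peak_lag = best_lag, peak_z = (best - mu) / sg, base_mean = mu,
       base_sd = sg)
}

#' Significant-CCG census over all pairs and cue conditions
#'
#' Runs the corrected-CCG significance rule for every pair of eligible units
#' in every condition.  Pair-conditions where either unit has no spikes are
#' marked unevaluated.
#'
#' @param raster 0/1 array over the delay window (eligible units only)
#' @param trials trial table aligned with the raster's trial axis
#' @param conditions condition values to evaluate (default: all)
#' @param ... overrides of the CCG defaults (`max_lag`, `jitter_window`,
#'   `z_thresh`, `peak_max`)
#' @return list of class `ccg_census`: `sig` (pairs x conditions, NA =
#'   unevaluated), `peak_z`, `peak_lag`, `pairs` (unit index pairs),
#'   `conditions`, `edge_table` (tidy significant-edge list)
#' @export
significant_ccg_census <- function(raster, trials, conditions = NULL, ...) {
  opts <- utils::modifyList(ccg_defaults, list(...))
  cond <- as.integer(trials$cue_location)
  if (is.null(conditions)) conditions <- sort(unique(cond))
  trial_sets <- lapply(conditions, function(cc) which(cond == cc) - 1L)
  spk <- raster_to_bins(raster)
  res <- ccg_edges_core(spk, trial_sets, dim(raster)[3],
                        as.integer(opts$max_lag),
                        as.integer(opts$jitter_window), opts$z_thresh,
                        as.integer(opts$peak_max),
                        as.integer(opts$base_lo), as.integer(opts$base_hi))
  # evaluated mask: both units fired in the condition
  nsp <- vapply(seq_along(conditions), function(q) {
    ts <- trial_sets[[q]] + 1L
    vapply(spk, function(u) sum(lengths(u[ts])), numeric(1))
  }, numeric(length(spk)))  # units x conditions
  sig <- res$sig
  for (q in seq_along(conditions)) {
    bad <- nsp[res$unit_a, q] == 0 | nsp[res$unit_b, q] == 0
    sig[bad, q] <- NA
  }
  edges <- which(sig & !is.na(sig), arr.ind = TRUE)
  edge_table <- data.frame(
    unit_a = res$unit_a[edges[, 1]], unit_b = res$unit_b[edges[, 1]],
    condition = conditions[edges[, 2]],
    peak_lag = res$peak_lag[edges], peak_z = res$peak_z[edges])
  structure(list(sig = sig, peak_z = res$peak_z, peak_lag = res$peak_lag,
                 pairs = data.frame(unit_a = res$unit_a,
                                    unit_b = res$unit_b),
                 conditions = conditions, edge_table = edge_table),
            class = "ccg_census")
}

#' Mask a raster to one state and recompute the CCG census
#'
#' Sets x(t) to zero for all 1-ms bins not covered by an interval of the
#' requested state, then repeats the full pipeline (normalisation and
#' jitter fields included) on the masked data.  Conditions whose total state
#' coverage is below `min_coverage_ms` are dropped.
#'
#' @param raster 0/1 array over the delay window
#' @param trials trial table
#' @param segments a `state_segments` object
#' @param which `"on"` or `"off"`
#' @param min_coverage_ms minimum summed coverage per condition (50 ms)
#' @param ... CCG overrides, as in [significant_ccg_census()]
#' @return a `ccg_census` restricted to sufficiently covered conditions
#' @export
state_restricted_ccg <- function(raster, trials, segments,
                                 which = c("on", "off"),
                                 min_coverage_ms = 50, ...) {
  which <- match.arg(which)
  masked <- mask_raster_by_state(raster, segments, which)
  cov <- attr(masked, "coverage_ms")
  cond <- as.integer(trials$cue_location)
  conds <- sort(unique(cond))
  cov_by_cond <- vapply(conds, function(cc)
    sum(cov[cond == cc]), numeric(1))
  keep <- conds[cov_by_cond >= min_coverage_ms]
  if (!length(keep)) {
    warning("state mask covers no time: empty census")
    return(structure(list(sig = matrix(NA, 0, 0), conditions = integer(0),
                          edge_table = data.frame()),
                     class = "ccg_census"))
  }
  significant_ccg_census(masked, trials, conditions = keep, ...)
}

#' Zero out raster bins outside a state's intervals
#'
#' @inheritParams state_restricted_ccg
#' @return masked raster with attribute `coverage_ms` (per trial)
#' @export
mask_raster_by_state <- function(raster, segments, which) {
  win <- attr(raster, "window")
  nb <- dim(raster)[3]
  ntr <- dim(raster)[2]
  trial_ids <- attr(segments, "trial_ids")
  if (is.null(trial_ids)) trial_ids <- seq_len(ntr)
  seg <- segments[segments$label == which, , drop = FALSE]
  keep <- matrix(FALSE, ntr, nb)
  for (r in seq_len(nrow(seg))) {
    i <- match(seg$trial_id[r], trial_ids)
    if (is.na(i)) next
    lo <- max(1, seg$t_start_ms[r] - win[1] + 1)
    hi <- min(nb, seg$t_end_ms[r] - win[1])
    if (hi >= lo) keep[i, lo:hi] <- TRUE
  }
  out <- raster
  for (i in seq_len(ntr)) out[, i, !keep[i, ]] <- 0L
  attributes(out) <- attributes(raster)
  attr(out, "coverage_ms") <- rowSums(keep)
  out
}

#' Distance dependence of significant connections
#'
#' @param census a `ccg_census`
#' @param depth_um per-unit depth/position (raster unit order)
#' @param n_bins distance bins
#' @return list: `table` (distance bin, probability), `r`, `p` (Pearson
#'   correlation of binned probability with bin centre)
#' @export
distance_dependence <- function(census, depth_um, n_bins = 5) {
  if (is.null(depth_um)) stop("unit positions missing")
  d <- abs(depth_um[census$pairs$unit_a] - depth_um[census$pairs$unit_b])
  any_sig <- rowSums(census$sig == TRUE, na.rm = TRUE) > 0
  evaluated <- rowSums(!is.na(census$sig)) > 0
  br <- seq(0, max(d) + 1e-9, length.out = n_bins + 1)
  bin <- cut(d, br, include.lowest = TRUE)
  tab <- data.frame(
    distance_um = (head(br, -1) + br[-1]) / 2,
    probability = as.vector(tapply(any_sig[evaluated], bin[evaluated],
                                   mean)),
    n_pairs = as.vector(table(bin[evaluated])))
  ok <- !is.na(tab$probability)
  if (sum(ok) < 3) return(list(table = tab, r = NA, p = NA))
  ct <- cor.test(tab$distance_um[ok], tab$probability[ok])
  list(table = tab, r = unname(ct$estimate), p = ct$p.value)
}
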