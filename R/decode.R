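# Leave-one-trial-out binary decoding of cue location with a time-resolved
# classifier-confidence output; cross-temporal generalisation; state-
# restricted decoding.

#' Leave-one-trial-out decoding confidence
#'
#' For every held-out trial and timepoint, a ridge-penalised logistic
#' classifier is trained on the remaining trials of the test trial's cue
#' location versus the diametrically opposite location (class counts
#' equalised by random subsampling) and evaluated on the held-out population
#' vector.  Confidence is the posterior probability assigned to the correct
#' label; accuracy is confidence > 0.5.  Optional label-shuffled replicates
#' refit the classifier with permuted training labels and form the null
#' ensemble used for state labelling.
#'
#' @param rates z-scored rate tensor from [smooth_and_zscore_rates()]
#' @param trials trial table aligned with the tensor's trial axis
#' @param timepoints sample times (ms) to decode; default the labelling span
#'   0-1,400 ms
#' @param lambda ridge penalty; the default was calibrated on synthetic
#'   sessions so that label-shuffled classifiers stay near chance confidence
#'   (tightening the state-labelling null) without costing real accuracy
#' @param n_shuffles label-shuffled replicates (0 = none)
#' @param mask optional trials x timepoints logical matrix (full tensor time
#'   axis); FALSE cells are excluded from training and testing
#' @param n_conditions number of cue locations in the protocol (8)
#' @param seed RNG seed for subsampling and shuffles
#' @return list of class `confidence_series`: `conf`, `accuracy`
#'   (trials x timepoints), `null` (trials x timepoints x shuffles, when
#'   requested), `time_ms`, `skipped` (trials with no usable fold)
#' @export
loo_confidence <- function(rates, trials, timepoints = NULL, lambda = 50,
                           n_shuffles = 0, mask = NULL, n_conditions = 8L,
                           seed = 1L) {
  stopifnot(isTRUE(attr(rates, "zscored")))
  tax <- attr(rates, "time_ms")
  if (is.null(timepoints))
    timepoints <- tax[tax >= WM_LABEL_SPAN[1] & tax < WM_LABEL_SPAN[2]]
  tp <- match(timepoints, tax)
  if (anyNA(tp)) stop("timepoints not on the tensor's time axis")
  cond <- as.integer(trials$cue_location)
  n_cond <- max(n_conditions, max(cond))
  opp <- opposite_location(cond, n_cond)
  if (!all(opp %in% cond))
    message("some trials lack the opposite condition and will be skipped")
  m <- if (is.null(mask)) matrix(TRUE, 0, 0) else mask
  eps <- 1e-4
  set.seed(as.integer(seed))
  res <- loo_confidence_core(unclass(rates), cond, opp, tp - 1L, lambda,
                             as.integer(n_shuffles), m)
  conf <- pmin(pmax(res$conf, eps), 1 - eps)
  out <- list(conf = conf, accuracy = (conf > 0.5) * 1,
              time_ms = timepoints,
              skipped = which(rowSums(!is.na(conf)) == 0))
  if (n_shuffles > 0) out$null <- pmin(pmax(res$null, eps), 1 - eps)
  class(out) <- "confidence_series"
  out
}

#' Session-mean delay accuracy of a confidence series
#'
#' @param cs a `confidence_series`
#' @param window averaging window, default the memory delay 500-1,400 ms
#' @param by_condition optionally a condition vector (per trial) to split by
#' @return mean accuracy (or a per-condition vector)
#' @export
delay_accuracy <- function(cs, window = WM_DELAY, by_condition = NULL) {
  sel <- cs$time_ms >= window[1] & cs$time_ms < window[2]
  per_trial <- rowMeans(cs$accuracy[, sel, drop = FALSE], na.rm = TRUE)
  if (is.null(by_condition)) return(mean(per_trial, na.rm = TRUE))
  tapply(per_trial, by_condition, mean, na.rm = TRUE)
}

#' Cross-temporal generalisation of the cue code
#'
#' Classifiers for each timepoint are trained on a random half of the trials
#' and tested, cross-temporally, on the other half, for every
#' (cue, opposite-cue) pair.  Significance of above-chance cells uses a
#' cluster-mass permutation test over the train x test matrix (threshold on
#' the per-cell binomial z, clusters 4-connected, null from label-shuffled
#' reruns).
#'
#' @inheritParams loo_confidence
#' @param n_perm label permutations for the cluster-mass null
#' @param alpha cluster-level significance
#' @param z_entry per-cell entry threshold (binomial z)
#' @return list: `accuracy` (train x test), `n` (counts), `sig_mask`,
#'   `time_ms`
#' @export
cross_temporal_accuracy <- function(rates, trials, timepoints = NULL,
                                    lambda = 50, n_perm = 100, alpha = 0.05,
                                    z_entry = 1.96, n_conditions = 8L,
                                    seed = 1L) {
  stopifnot(isTRUE(attr(rates, "zscored")))
  tax <- attr(rates, "time_ms")
  if (is.null(timepoints))
    timepoints <- tax[tax >= WM_LABEL_SPAN[1] & tax < WM_LABEL_SPAN[2]]
  tp <- match(timepoints, tax)
  cond <- as.integer(trials$cue_location)
  n_cond <- max(n_conditions, max(cond))
  set.seed(as.integer(seed))
  n <- length(cond)
  half <- sample(n, floor(n / 2))
  other <- setdiff(seq_len(n), half)
  res <- cross_temporal_core(unclass(rates), cond, n_cond, half - 1L,
                             other - 1L, tp - 1L, lambda, FALSE)
  acc <- res$correct / pmax(res$total, 1)
  zmat <- function(a, ntot) (a - 0.5) / sqrt(0.25 / pmax(ntot, 1))
  obs_z <- zmat(acc, res$total)
  obs_mass <- max_cluster_mass_2d(obs_z, z_entry)
  null_mass <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    rp <- cross_temporal_core(unclass(rates), cond, n_cond, half - 1L,
                              other - 1L, tp - 1L, lambda, TRUE)
    null_mass[p] <- max_cluster_mass_2d(
      zmat(rp$correct / pmax(rp$total, 1), rp$total), z_entry)
  }
  thr <- quantile(null_mass, 1 - alpha, names = FALSE)
  sig <- cluster_mask_2d(obs_z, z_entry, thr)
  list(accuracy = acc, n = res$total, sig_mask = sig, time_ms = timepoints,
       null_mass = null_mass)
}

# connected components (4-neighbour) of z > thr; returns max mass
max_cluster_mass_2d <- function(z, thr) {
  cl <- label_components(z > thr)
  if (max(cl) == 0) return(0)
  max(tapply(z[cl > 0], cl[cl > 0], sum))
}

cluster_mask_2d <- function(z, thr, mass_thr) {
  cl <- label_components(z > thr)
  out <- matrix(FALSE, nrow(z), ncol(z))
  if (max(cl) == 0) return(out)
  masses <- tapply(z[cl > 0], cl[cl > 0], sum)
  keep <- as.integer(names(masses)[masses > mass_thr])
  out[cl %in% keep] <- TRUE
  out
}

label_components <- function(flag) {
  nr <- nrow(flag); nc <- ncol(flag)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!flag[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    stack <- list(c(i, j))
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      a <- p[1]; b <- p[2]
      if (a < 1 || a > nr || b < 1 || b > nc) next
      if (!flag[a, b] || lab[a, b] != 0L) next
      lab[a, b] <- cur
      stack <- c(stack, list(c(a - 1, b), c(a + 1, b), c(a, b - 1),
                             c(a, b + 1)))
    }
  }
  lab
}

#' State-restricted decoding accuracy
#'
#' Re-runs the leave-one-trial-out decoder using only timepoints labelled
#' with the requested state, both for training and testing, and averages
#' confidence and accuracy over the memory delay.
#'
#' @inheritParams loo_confidence
#' @param segments a `state_segments` object
#' @param which `"on"` or `"off"`
#' @return list: `accuracy`, `confidence` (delay means), `conf` matrix,
#'   `n_trials_used`
#' @export
state_restricted_accuracy <- function(rates, trials, segments,
                                      which = c("on", "off"), lambda = 50,
                                      seed = 1L) {
  which <- match.arg(which)
  tax <- attr(rates, "time_ms")
  mask <- segments_to_mask(segments, tax, which,
                           n_trials = dim(rates)[2])
  if (!any(mask)) stop("no timepoints carry the requested state label")
  cs <- loo_confidence(rates, trials, timepoints = tax[tax >= WM_DELAY[1] &
                                                         tax < WM_DELAY[2]],
                       lambda = lambda, mask = mask, seed = seed)
  used <- rowSums(!is.na(cs$conf)) > 0
  list(accuracy = mean(cs$accuracy, na.rm = TRUE),
       confidence = mean(cs$conf, na.rm = TRUE), conf = cs$conf,
       n_trials_used = sum(used))
}

# segments -> trials x timepoints logical mask on a given time axis
segments_to_mask <- function(segments, time_ms, which, n_trials) {
  mask <- matrix(FALSE, n_trials, length(time_ms))
  seg <- segments[segments$label == which, , drop = FALSE]
  trial_ids <- attr(segments, "trial_ids")
  if (is.null(trial_ids)) trial_ids <- sort(unique(segments$trial_id))
  ti <- match(seg$trial_id, trial_ids)
  for (r in seq_len(nrow(seg))) {
    sel <- time_ms >= seg$t_start_ms[r] & time_ms < seg$t_end_ms[r]
    mask[ti[r], sel] <- TRUE
  }
  mask
}
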