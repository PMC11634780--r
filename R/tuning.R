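# State-conditioned rate coding: split-half cross-validated tuning curves,
# baseline-normalised population rate profiles, and per-unit variance
# partitioning between cue, state and their interaction.

# mean z-rate per (unit, condition) over the (trial, timepoint) cells
# selected by a state mask; returns units x conditions (NA when no samples)
state_cond_means <- function(rates, cond, mask, tp_sel, units) {
  n_cond <- max(cond)
  sums <- matrix(0, length(units), n_cond)
  cnts <- matrix(0, length(units), n_cond)
  tp_idx <- which(tp_sel)
  for (i in seq_len(dim(rates)[2])) {
    sel <- tp_idx[mask[i, tp_idx]]
    if (!length(sel)) next
    v <- rates[units, i, sel, drop = FALSE]
    sums[, cond[i]] <- sums[, cond[i]] + rowSums(v, dims = 1)
    cnts[, cond[i]] <- cnts[, cond[i]] + length(sel)
  }
  out <- sums / cnts
  out[cnts == 0] <- NA
  out
}

align_to_pref <- function(curve_on, curve_off) {
  # preferred location = argmax of On + Off sum; ties -> lowest index.
  # Returns curves rotated so index 1 is the preferred location.
  tot <- curve_on + curve_off
  pref <- which.max(tot)  # which.max takes the first maximum
  idx <- ((seq_along(curve_on) - 1 + pref - 1) %% length(curve_on)) + 1
  list(on = curve_on[idx], off = curve_off[idx], pref = pref)
}

#' Split-half, state-conditioned tuning curves
#'
#' Units are split into random halves; each half's population labels On/Off
#' states (full decoding + shuffle null + cluster correction), and the
#' held-out half's delay tuning is computed separately within On and Off
#' timepoints.  Halves are then swapped so every unit receives curves.
#' Curves are aligned to each unit's preferred location (argmax of On + Off,
#' placed at index 1 = 0 deg).  Alignment to the maximum biases even
#' untuned units toward a spurious peak, so null curves from cue-label
#' shuffles (aligned to their own argmax) are subtracted.
#'
#' @param rates z-scored rate tensor
#' @param trials trial table
#' @param n_shuffles decoding shuffles for state labelling (50)
#' @param n_null_curves cue-label shuffles for the alignment-bias correction
#' @param lambda ridge penalty passed to the decoder
#' @param seed RNG seed
#' @param segments_by_half optional list(list(A=unit_idx, segments), ...) to
#'   reuse precomputed segmentations (mainly for tests)
#' @return list: `on`, `off` (units x 8 aligned, null-corrected), `raw_on`,
#'   `raw_off`, `pref`, `unit_order`, `segments` per half
#' @export
split_half_state_tuning <- function(rates, trials, n_shuffles = 50,
                                    n_null_curves = 20, lambda = 50,
                                    seed = 1L, segments_by_half = NULL) {
  nu <- dim(rates)[1]
  if (nu < 2) stop("need at least 2 units")
  set.seed(as.integer(seed))
  cond <- as.integer(trials$cue_location)
  tax <- attr(rates, "time_ms")
  tp_sel <- tax >= WM_DELAY[1] & tax < WM_DELAY[2]
  halves <- split(sample(nu), rep_len(1:2, nu))

  seg_of_half <- function(h, s) {
    if (!is.null(segments_by_half)) return(segments_by_half[[h]])
    sub <- rates[halves[[h]], , , drop = FALSE]
    attributes(sub)[c("time_ms", "zscored")] <-
      attributes(rates)[c("time_ms", "zscored")]
    nullc <- build_null_confidence(sub, trials, n_shuffles = n_shuffles,
                                   lambda = lambda, seed = s)
    label_states(zscore_confidence(nullc$conf, nullc), nullc)
  }
  seg1 <- seg_of_half(1, seed + 101L)
  seg2 <- seg_of_half(2, seed + 102L)

  curves <- function(units, segments, cond_vec) {
    on_mask <- segments_to_mask(segments, tax, "on", dim(rates)[2])
    off_mask <- segments_to_mask(segments, tax, "off", dim(rates)[2])
    list(on = state_cond_means(rates, cond_vec, on_mask, tp_sel, units),
         off = state_cond_means(rates, cond_vec, off_mask, tp_sel, units))
  }
  held <- list(halves[[2]], halves[[1]])
  segs <- list(seg1, seg2)
  n_cond <- max(cond)
  all_units <- c(held[[1]], held[[2]])
  raw_on <- matrix(NA, nu, n_cond)
  raw_off <- matrix(NA, nu, n_cond)
  null_on <- matrix(0, nu, n_cond)
  null_off <- matrix(0, nu, n_cond)
  pref <- integer(nu)

  for (h in 1:2) {
    tc <- curves(held[[h]], segs[[h]], cond)
    for (j in seq_along(held[[h]])) {
      u <- held[[h]][j]
      al <- align_to_pref(tc$on[j, ], tc$off[j, ])
      raw_on[u, ] <- al$on
      raw_off[u, ] <- al$off
      pref[u] <- al$pref
    }
    for (s in seq_len(n_null_curves)) {
      sh_cond <- sample(cond)
      ts <- curves(held[[h]], segs[[h]], sh_cond)
      for (j in seq_along(held[[h]])) {
        u <- held[[h]][j]
        al <- align_to_pref(ts$on[j, ], ts$off[j, ])
        null_on[u, ] <- null_on[u, ] + al$on / n_null_curves
        null_off[u, ] <- null_off[u, ] + al$off / n_null_curves
      }
    }
  }
  list(on = raw_on - null_on, off = raw_off - null_off, raw_on = raw_on,
       raw_off = raw_off, null_on = null_on, null_off = null_off,
       pref = pref, segments = segs, halves = halves)
}

#' Baseline-normalised population rate profile
#'
#' The session-mean firing rate (across units, across trials of the
#' preferred cue condition) is normalised by the mean and SD of the
#' pre-cue baseline, yielding population spiking in SD above spontaneous
#' levels; delay averages are additionally computed restricted to On and to
#' Off timepoints.
#'
#' @param rates non-z-scored rate tensor (spikes/s)
#' @param trials trial table
#' @param segments a `state_segments` object
#' @param pref_condition cue condition to average over; if NULL, derived as
#'   the condition with the greatest mean delay confidence in `conf`
#' @param conf optional `confidence_series` used to pick the preferred
#'   condition
#' @return list: `time_ms`, `profile` (SD units), `on_mean`, `off_mean`,
#'   `baseline_mean`, `baseline_sd`, `pref_condition`
#' @export
population_rate_profile <- function(rates, trials, segments,
                                    pref_condition = NULL, conf = NULL) {
  stopifnot(!isTRUE(attr(rates, "zscored")))
  tax <- attr(rates, "time_ms")
  cond <- as.integer(trials$cue_location)
  if (is.null(pref_condition)) {
    if (is.null(conf)) stop("give pref_condition or conf")
    sel <- conf$time_ms >= WM_DELAY[1] & conf$time_ms < WM_DELAY[2]
    per_trial <- rowMeans(conf$conf[, sel, drop = FALSE], na.rm = TRUE)
    pref_condition <-
      as.integer(names(which.max(tapply(per_trial, cond, mean,
                                        na.rm = TRUE))))
  }
  tr_sel <- which(cond == pref_condition)
  prof <- apply(rates[, tr_sel, , drop = FALSE], 3, mean)
  base <- tax >= WM_BASELINE[1] & tax < WM_BASELINE[2]
  mu <- mean(prof[base])
  sg <- sd(prof[base])
  if (sg == 0) stop("zero baseline SD: session flagged")
  zprof <- (prof - mu) / sg

  delay_idx <- which(tax >= WM_DELAY[1] & tax < WM_DELAY[2])
  state_mean <- function(which_state) {
    mask <- segments_to_mask(segments, tax, which_state, dim(rates)[2])
    vals <- c()
    for (i in tr_sel) {
      sel <- delay_idx[mask[i, delay_idx]]
      if (length(sel))
        vals <- c(vals, (apply(rates[, i, sel, drop = FALSE], 3, mean) -
                           mu) / sg)
    }
    if (length(vals)) mean(vals) else NA_real_
  }
  list(time_ms = tax, profile = zprof, on_mean = state_mean("on"),
       off_mean = state_mean("off"), baseline_mean = mu, baseline_sd = sg,
       pref_condition = pref_condition)
}

#' Partition delay firing-rate variance between cue, state and interaction
#'
#' Smoothed rates are downsampled to 100-ms steps over the memory delay;
#' each sample is labelled by its trial's cue location and by the On/Off
#' state covering the majority of the sample.  Per unit, the percent of
#' variance explained by cue location is computed separately within On and
#' within Off samples; the cue x state interaction is assessed per unit by a
#' linear model and at the population level by a sign-rank test on the
#' per-unit difference of cue variance between states.
#'
#' @param rates non-z-scored rate tensor (10-ms samples)
#' @param trials trial table
#' @param segments a `state_segments` object
#' @param step_ms downsampling step (100 ms)
#' @return list: `per_unit` data.frame (unit, var_cue_on, var_cue_off,
#'   p_interaction), `pop_p` (sign-rank on var_cue_on - var_cue_off),
#'   `mean_var_on`, `mean_var_off`
#' @export
partition_rate_variance <- function(rates, trials, segments, step_ms = 100) {
  tax <- attr(rates, "time_ms")
  fine_step <- diff(tax[1:2])
  k <- step_ms / fine_step
  delay_idx <- which(tax >= WM_DELAY[1] & tax < WM_DELAY[2])
  n_coarse <- floor(length(delay_idx) / k)
  cond <- as.integer(trials$cue_location)
  on_mask <- segments_to_mask(segments, tax, "on", dim(rates)[2])
  off_mask <- segments_to_mask(segments, tax, "off", dim(rates)[2])

  nu <- dim(rates)[1]
  ntr <- dim(rates)[2]
  samp_rate <- array(NA_real_, c(nu, ntr, n_coarse))
  samp_state <- matrix(NA_character_, ntr, n_coarse)
  for (q in seq_len(n_coarse)) {
    idx <- delay_idx[((q - 1) * k + 1):(q * k)]
    samp_rate[, , q] <- apply(rates[, , idx, drop = FALSE], c(1, 2), mean)
    for (i in seq_len(ntr)) {
      n_on <- sum(on_mask[i, idx])
      n_off <- sum(off_mask[i, idx])
      if (n_on > k / 2) samp_state[i, q] <- "on"
      else if (n_off > k / 2) samp_state[i, q] <- "off"
    }
  }

  var_frac <- function(y, g) {
    if (length(unique(g)) < 2 || var(y) == 0) return(NA_real_)
    a <- anova(lm(y ~ factor(g)))
    100 * a[["Sum Sq"]][1] / sum(a[["Sum Sq"]])
  }
  per_unit <- data.frame(unit = seq_len(nu), var_cue_on = NA_real_,
                         var_cue_off = NA_real_, p_interaction = NA_real_)
  cond_mat <- matrix(cond, ntr, n_coarse)
  for (u in seq_len(nu)) {
    y <- as.vector(samp_rate[u, , ])
    st <- as.vector(samp_state)
    cu <- as.vector(cond_mat)
    ok <- !is.na(st)
    if (!any(st[ok] == "on") || !any(st[ok] == "off")) next
    per_unit$var_cue_on[u] <- var_frac(y[ok & st == "on"],
                                       cu[ok & st == "on"])
    per_unit$var_cue_off[u] <- var_frac(y[ok & st == "off"],
                                        cu[ok & st == "off"])
    fit <- tryCatch(anova(lm(y[ok] ~ factor(cu[ok]) * factor(st[ok]))),
                    error = function(e) NULL)
    if (!is.null(fit) && "factor(cu[ok]):factor(st[ok])" %in% rownames(fit))
      per_unit$p_interaction[u] <-
        fit["factor(cu[ok]):factor(st[ok])", "Pr(>F)"]
  }
  d <- per_unit$var_cue_on - per_unit$var_cue_off
  pop_p <- if (sum(!is.na(d)) >= 2)
    wilcox.test(d, mu = 0)$p.value else NA_real_
  list(per_unit = per_unit, pop_p = pop_p,
       mean_var_on = mean(per_unit$var_cue_on, na.rm = TRUE),
       mean_var_off = mean(per_unit$var_cue_off, na.rm = TRUE))
}
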