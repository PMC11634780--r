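# Spike tables -> rate tensors and rasters; unit filters; functional
# subtyping; background-noise estimation; CSV/Parquet ingest.

#' Boxcar-smoothed, optionally z-scored firing-rate tensor
#'
#' Each spike is treated as a delta function and convolved with a 100-ms
#' boxcar, sampled every 10 ms.  The boxcar is centred by default (a sample
#' at time t covers `[t - 50, t + 50)` ms); `causal = TRUE` uses
#' `[t - 100, t)`.  Optionally z-scored across trials per (unit, timepoint);
#' zero-variance slices are imputed to z = 0 so the tensor stays rectangular.
#'
#' @param spikes spike table (unit_id, trial_id, t_ms)
#' @param trials trial table; all its trial_ids define the trial axis
#' @param t_start,t_end,step time grid (ms, cue-aligned, half-open bins)
#' @param boxcar_ms boxcar width (ms; must be a multiple of `step`)
#' @param zscore z-score across trials per (unit, timepoint)?
#' @param causal causal boxcar instead of centred
#' @param unit_ids units forming the unit axis (default: all in `spikes`)
#' @return array units x trials x timepoints (spikes/s, or z-units) with
#'   attributes `time_ms`, `zscored`, `unit_ids`, `trial_ids`
#' @export
smooth_and_zscore_rates <- function(spikes, trials,
                                    t_start = WM_RATE_START,
                                    t_end = WM_RATE_END,
                                    step = WM_RATE_STEP, boxcar_ms = 100,
                                    zscore = TRUE, causal = FALSE,
                                    unit_ids = NULL) {
  if (is.null(unit_ids)) unit_ids <- sort(unique(spikes$unit_id))
  if (!length(unit_ids)) stop("empty unit set")
  if (boxcar_ms %% step != 0)
    stop("boxcar_ms must be a multiple of the sample step")
  trial_ids <- trials$trial_id
  tp <- seq(t_start, t_end - step, by = step)
  half <- boxcar_ms / 2
  lo <- if (causal) t_start - boxcar_ms else t_start - half
  hi <- if (causal) t_end else t_end + half
  n_fine <- (hi - lo) / step
  k <- boxcar_ms / step

  ui <- match(spikes$unit_id, unit_ids)
  ti <- match(spikes$trial_id, trial_ids)
  bi <- floor((spikes$t_ms - lo) / step) + 1
  ok <- !is.na(ui) & !is.na(ti) & bi >= 1 & bi <= n_fine
  nu <- length(unit_ids)
  ntr <- length(trial_ids)
  lin <- ui[ok] + (ti[ok] - 1) * nu + (bi[ok] - 1) * nu * ntr
  counts <- array(tabulate(lin, nbins = nu * ntr * n_fine),
                  dim = c(nu, ntr, n_fine))
  # rolling sum of k fine bins: sample q covers fine bins q .. q+k-1
  cs <- apply(counts, c(1, 2), cumsum)  # n_fine x nu x ntr
  rate <- array(0, dim = c(nu, ntr, length(tp)))
  for (q in seq_along(tp)) {
    top <- matrix(cs[q + k - 1, , ], nu, ntr)
    bot <- if (q > 1) matrix(cs[q - 1, , ], nu, ntr) else 0
    rate[, , q] <- (top - bot) * (1000 / boxcar_ms)
  }
  if (zscore) {
    mu <- apply(rate, c(1, 3), mean)
    sg <- apply(rate, c(1, 3), sd)
    for (q in seq_along(tp)) {
      s <- sg[, q]
      s[s == 0 | is.na(s)] <- Inf  # zero-variance slices -> z = 0
      rate[, , q] <- (rate[, , q] - mu[, q]) / s
    }
  }
  structure(rate, time_ms = tp, zscored = zscore, unit_ids = unit_ids,
            trial_ids = trial_ids, class = c("rate_tensor", "array"))
}

#' Binarise spike times at 1 ms
#'
#' Bins with two or more spikes clip to 1 (the cross-correlogram treats the
#' train as an indicator).
#'
#' @param spikes spike table
#' @param window two-vector `(start, end)` ms, half-open
#' @param unit_ids,trial_ids axes (defaults: all present in `spikes`)
#' @param bin_ms bin width (1 ms)
#' @return 0/1 array units x trials x bins with attributes `window`,
#'   `unit_ids`, `trial_ids`
#' @export
bin_raster <- function(spikes, window = WM_DELAY, unit_ids = NULL,
                       trial_ids = NULL, bin_ms = 1) {
  if (window[2] <= window[1]) stop("inverted window")
  if (is.null(unit_ids)) unit_ids <- sort(unique(spikes$unit_id))
  if (is.null(trial_ids)) trial_ids <- sort(unique(spikes$trial_id))
  nb <- as.integer((window[2] - window[1]) / bin_ms)
  ui <- match(spikes$unit_id, unit_ids)
  ti <- match(spikes$trial_id, trial_ids)
  bi <- floor((spikes$t_ms - window[1]) / bin_ms) + 1
  ok <- !is.na(ui) & !is.na(ti) & bi >= 1 & bi <= nb
  ras <- array(0L, dim = c(length(unit_ids), length(trial_ids), nb))
  ras[cbind(ui[ok], ti[ok], bi[ok])] <- 1L  # >=2 spikes clip to 1
  structure(ras, window = window, unit_ids = unit_ids, trial_ids = trial_ids,
            class = c("binary_raster", "array"))
}

# raster -> list over units of lists over trials of 0-based bin indices
raster_to_bins <- function(raster) {
  nu <- dim(raster)[1]
  ntr <- dim(raster)[2]
  lapply(seq_len(nu), function(u) {
    lapply(seq_len(ntr), function(i) which(raster[u, i, ] == 1L) - 1L)
  })
}

#' Per-unit spike counts and mean rates
#'
#' Mean rate uses the total recorded span of each trial (fixation through go
#' cue).
#' @param spikes spike table
#' @param trials trial table
#' @return data.frame unit_id, total_spikes, mean_rate_hz
#' @export
unit_meta <- function(spikes, trials) {
  ids <- sort(unique(spikes$unit_id))
  tot <- as.vector(table(factor(spikes$unit_id, levels = ids)))
  span_s <- sum(trials$go_time_ms - WM_RATE_START) / 1000
  data.frame(unit_id = ids, total_spikes = tot, mean_rate_hz = tot / span_s)
}

#' Unit inclusion filters
#'
#' Returns two nested subsets: analysis units (at least `min_total_spikes`
#' spikes in the session) and CCG-eligible units (additionally a mean rate
#' above `min_rate_hz`).  Raising either threshold never adds units.
#'
#' @param meta data.frame from [unit_meta()]
#' @param min_total_spikes session spike-count threshold (default 1000)
#' @param min_rate_hz mean-rate threshold for CCG eligibility (default 1 Hz)
#' @return list(analysis_units, ccg_units)
#' @export
filter_units <- function(meta, min_total_spikes = 1000, min_rate_hz = 1) {
  analysis <- meta$unit_id[meta$total_spikes >= min_total_spikes]
  ccg <- meta$unit_id[meta$total_spikes >= min_total_spikes &
                        meta$mean_rate_hz > min_rate_hz]
  if (!length(analysis)) message("filter_units: no units pass the filters")
  list(analysis_units = analysis, ccg_units = ccg)
}

epoch_mean_rates <- function(spikes, trials, win, relative_to = "cue") {
  # per unit x trial mean rate (Hz) in a window; window may be go-aligned
  ids <- sort(unique(spikes$unit_id))
  lo <- if (relative_to == "go") trials$go_time_ms + win[1] else
    rep(win[1], nrow(trials))
  hi <- if (relative_to == "go") trials$go_time_ms + win[2] else
    rep(win[2], nrow(trials))
  ti <- match(spikes$trial_id, trials$trial_id)
  sel <- spikes$t_ms >= lo[ti] & spikes$t_ms < hi[ti]
  cnt <- table(factor(spikes$unit_id[sel], levels = ids),
               factor(spikes$trial_id[sel], levels = trials$trial_id))
  dur <- (hi - lo) / 1000
  sweep(unclass(cnt), 2, dur, "/")
}

#' Classify units into visual / memory / motor functional subtypes
#'
#' Firing rates in three epochs (visual: 0-300 ms after cue; memory:
#' 500-1,400 ms after cue; motor: 100-300 ms after fixation offset, i.e.
#' after the go cue) are tested for cue-location modulation by one-way ANOVA
#' at P < 0.05; the subtype is the set of selective epochs.
#'
#' @param spikes spike table
#' @param trials trial table (needs `go_time_ms`)
#' @param alpha significance criterion
#' @return data.frame unit_id, visual, memory, motor (logical), subtype
#' @export
classify_functional_subtype <- function(spikes, trials, alpha = 0.05) {
  cue <- factor(trials$cue_location)
  if (nlevels(cue) < 2 || min(table(cue)) < 2)
    stop("need >= 2 conditions with >= 2 trials each")
  wins <- list(visual = list(c(0, 300), "cue"),
               memory = list(c(500, 1400), "cue"),
               motor = list(c(100, 300), "go"))
  ids <- sort(unique(spikes$unit_id))
  flags <- sapply(wins, function(w) {
    rates <- epoch_mean_rates(spikes, trials, w[[1]], w[[2]])
    apply(rates, 1, function(r) {
      if (var(r) == 0) return(FALSE)
      summary(aov(r ~ cue))[[1]][["Pr(>F)"]][1] < alpha
    })
  })
  flags <- matrix(flags, nrow = length(ids),
                  dimnames = list(NULL, names(wins)))
  subtype <- apply(flags, 1, function(f)
    paste(names(wins)[f], collapse = "+"))
  subtype[subtype == ""] <- "none"
  data.frame(unit_id = ids, visual = flags[, "visual"],
             memory = flags[, "memory"], motor = flags[, "motor"],
             subtype = subtype)
}

#' Robust background-noise SD
#'
#' `sigma_n = median(|x|) / 0.6745`: for Gaussian noise this equals the SD,
#' and it is insensitive to spike-driven tails.
#' @param x raw wide-band sample vector
#' @return noise SD estimate
#' @export
estimate_noise_sd <- function(x) {
  if (!length(x)) stop("empty segment")
  s <- median(abs(x)) / 0.6745
  if (s == 0) warning("all-zero segment: sigma_n = 0")
  s
}

#' Read a spike or trial table from CSV or Parquet
#'
#' @param path file path; `.parquet` uses the arrow package
#' @return data.frame
#' @export
read_spike_table <- function(path) {
  tab <- read_table_any(path)
  need <- c("unit_id", "trial_id", "t_ms")
  if (!all(need %in% names(tab)))
    stop("spike table needs columns: ", paste(need, collapse = ", "))
  tab[order(tab$unit_id, tab$trial_id, tab$t_ms), need]
}

#' @rdname read_spike_table
#' @export
read_trial_table <- function(path) {
  tab <- read_table_any(path)
  need <- c("trial_id", "cue_location", "delay_ms")
  if (!all(need %in% names(tab)))
    stop("trial table needs columns: ", paste(need, collapse = ", "))
  if (!"go_time_ms" %in% names(tab)) tab$go_time_ms <- 50 + tab$delay_ms
  if (!"correct" %in% names(tab)) tab$correct <- TRUE
  tab[tab$correct, , drop = FALSE]  # only correct trials enter analyses
}

read_table_any <- function(path) {
  if (grepl("\\.parquet$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("reading parquet requires the arrow package")
    as.data.frame(arrow::read_parquet(path))
  } else {
    read.csv(path)
  }
}
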