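# Session-level runner wiring the stages end-to-end, and a cohort-level
# summary with across-session sign-rank tests.

stage_try <- function(report, name, expr) {
  res <- tryCatch(expr, error = function(e) {
    message("stage '", name, "' failed: ", conditionMessage(e))
    structure(list(error = conditionMessage(e)), class = "stage_error")
  })
  report$status[[name]] <- if (inherits(res, "stage_error")) "failed"
  else "ok"
  report[[name]] <- res
  report
}

#' Run the full analysis pipeline on one (synthetic) session
#'
#' Simulates a session from `config`, then runs preprocessing, decoding with
#' the 50-replicate shuffle null (cached and reused for state labelling),
#' state segmentation and statistics, the beta-mixture model comparison,
#' state-conditioned variance partitioning and population rates, the CCG
#' census and Manhattan-distance permutation tests (full and
#' state-restricted), and joint-selectivity enrichment.  Stage failures are
#' caught and recorded in `status`, so a partial report is still returned.
#'
#' All stage seeds derive from `config$seed` by fixed offsets.
#'
#' @param config a [sim_config()]
#' @param n_shuffles decoding shuffles (50)
#' @param n_perm Manhattan permutations for the full-delay test (50)
#' @param n_perm_state permutations for the state-restricted variants (25)
#' @param min_total_spikes,min_rate_hz unit filters
#' @param do_tuning run the split-half tuning stage (it repeats the decoding
#'   per unit half, the most expensive step)
#' @param do_state_ccg run On/Off-restricted Manhattan tests
#' @param lambda decoder ridge penalty
#' @return list of class `session_report`
#' @export
run_session <- function(config, n_shuffles = 50, n_perm = 50,
                        n_perm_state = 25, min_total_spikes = 1000,
                        min_rate_hz = 1, do_tuning = FALSE,
                        do_state_ccg = TRUE, lambda = 50) {
  seed <- config$seed
  report <- list(config = config, status = list())

  sim <- simulate_session(config)
  report$n_trials <- nrow(sim$trials)
  report$n_units <- config$n_units

  meta <- unit_meta(sim$spikes, sim$trials)
  flt <- filter_units(meta, min_total_spikes, min_rate_hz)
  report$filters <- flt
  rates_z <- smooth_and_zscore_rates(sim$spikes, sim$trials,
                                     unit_ids = flt$analysis_units)
  rates_raw <- smooth_and_zscore_rates(sim$spikes, sim$trials,
                                       zscore = FALSE,
                                       unit_ids = flt$analysis_units)

  nullc <- build_null_confidence(rates_z, sim$trials,
                                 n_shuffles = n_shuffles, lambda = lambda,
                                 seed = seed + 1L)
  z <- zscore_confidence(nullc$conf, nullc)
  segments <- label_states(z, nullc)
  stats <- summarize_states(segments)
  cond <- sim$trials$cue_location

  report$decoding <- list(
    delay_accuracy = delay_accuracy(
      structure(list(accuracy = (nullc$conf > 0.5) * 1,
                     time_ms = nullc$time_ms), class = "confidence_series")),
    per_condition = delay_accuracy(
      structure(list(accuracy = (nullc$conf > 0.5) * 1,
                     time_ms = nullc$time_ms), class = "confidence_series"),
      by_condition = cond))
  report$states <- stats
  report$segments <- segments
  report$status$decoding <- "ok"

  delay_sel <- nullc$time_ms >= WM_DELAY[1] & nullc$time_ms < WM_DELAY[2]
  conf_delay <- nullc$conf[, delay_sel, drop = FALSE]
  vals <- as.vector(conf_delay)
  tid <- rep(sim$trials$trial_id, times = sum(delay_sel))
  cvec <- rep(cond, times = sum(delay_sel))
  report <- stage_try(report, "betamix", {
    cv_model_comparison(vals, tid, conditions = cvec, seed = seed + 2L)
  })

  report <- stage_try(report, "variance_partition", {
    partition_rate_variance(rates_raw, sim$trials, segments)
  })
  report <- stage_try(report, "population_rate", {
    population_rate_profile(rates_raw, sim$trials, segments,
                            conf = structure(list(conf = nullc$conf,
                                                  time_ms = nullc$time_ms),
                                             class = "confidence_series"))
  })
  if (do_tuning) {
    report <- stage_try(report, "tuning", {
      split_half_state_tuning(rates_z, sim$trials, n_shuffles = n_shuffles,
                              lambda = lambda, seed = seed + 3L)
    })
  }

  raster <- bin_raster(sim$spikes, WM_DELAY, unit_ids = flt$ccg_units,
                       trial_ids = sim$trials$trial_id)
  report <- stage_try(report, "ccg_census", {
    significant_ccg_census(raster, sim$trials)
  })
  report <- stage_try(report, "manhattan", {
    manhattan_null_zscore(raster, sim$trials, n_perm = n_perm,
                          seed = seed + 4L)
  })
  if (do_state_ccg) {
    report <- stage_try(report, "manhattan_on", {
      ras_on <- mask_raster_by_state(raster, segments, "on")
      manhattan_null_zscore(ras_on, sim$trials, n_perm = n_perm_state,
                            seed = seed + 5L)
    })
    report <- stage_try(report, "manhattan_off", {
      ras_off <- mask_raster_by_state(raster, segments, "off")
      manhattan_null_zscore(ras_off, sim$trials, n_perm = n_perm_state,
                            seed = seed + 6L)
    })
  }
  report <- stage_try(report, "enrichment", {
    joint_selectivity_enrichment(sim$spikes, sim$trials,
                                 report$ccg_census, flt$ccg_units)
  })

  # QC: background-noise SD within detected states on a synthetic
  # unit-variance wide-band trace (the generator produces no raw voltage,
  # so this checks the estimator and the absence of On/Off bias)
  report <- stage_try(report, "qc", {
    set.seed(seed + 7L)
    seg <- as.data.frame(segments)
    sig_for <- function(lab) {
      durs <- seg$t_end_ms[seg$label == lab] - seg$t_start_ms[seg$label == lab]
      if (!length(durs)) return(NA_real_)
      mean(vapply(pmax(durs, 10), function(d)
        estimate_noise_sd(rnorm(d * 30)), numeric(1)))
    }
    eyes <- simulate_eye_traces(nrow(sim$trials), seed = seed + 8L)
    ms <- detect_microsaccades(eyes)
    list(sigma_n_on = sig_for("on"), sigma_n_off = sig_for("off"),
         msacc_per_trial = mean(lengths(ms)))
  })
  class(report) <- "session_report"
  report
}

#' @export
print.session_report <- function(x, ...) {
  cat("<session_report> ", x$n_units, " units, ", x$n_trials, " trials\n",
      "  delay accuracy: ",
      round(x$decoding$delay_accuracy, 3), "\n",
      "  On states/trial: ", round(x$states$mean_n_on, 2),
      ", Off states/trial: ", round(x$states$mean_n_off, 2), "\n", sep = "")
  if (!is.null(x$manhattan))
    cat("  Manhattan z (full delay): ", round(x$manhattan$z, 2), "\n",
        sep = "")
  invisible(x)
}

#' Run several sessions and summarise across them
#'
#' Applies two-sided sign-rank tests across sessions to the Manhattan
#' z-scores (against 0) and the enrichment ratios (against 1), and reports
#' the mean state statistics, the number of sessions where the two-state
#' confidence model wins, and per-session headline numbers.
#'
#' @param configs list of [sim_config()] objects (>= 6 sessions for the
#'   sign-rank to be able to reach P < 0.05)
#' @param ... passed to [run_session()]
#' @return list of class `cohort_summary`
#' @export
run_cohort <- function(configs, ...) {
  reports <- lapply(configs, run_session, ...)
  grab <- function(f) vapply(reports, function(r) {
    v <- tryCatch(f(r), error = function(e) NA_real_)
    if (is.null(v) || length(v) != 1 || !is.numeric(v)) NA_real_ else v
  }, numeric(1))
  mz <- grab(function(r) r$manhattan$z)
  mz_off <- grab(function(r) r$manhattan_off$z)
  enr <- grab(function(r) r$enrichment$enrichment)
  db <- grab(function(r) r$betamix$delta_bits)
  sr <- function(x, mu) {
    x <- x[!is.na(x)]
    if (length(x) < 2) return(NA_real_)
    wilcox.test(x, mu = mu)$p.value
  }
  structure(list(
    reports = reports,
    manhattan_z = mz, manhattan_z_off = mz_off, enrichment = enr,
    delta_bits = db,
    p_manhattan = sr(mz, 0), p_manhattan_off = sr(mz_off, 0),
    p_enrichment = sr(enr, 1), p_delta_bits = sr(db, 0),
    n_mixture_wins = sum(db > 0, na.rm = TRUE),
    n_sessions = length(reports)), class = "cohort_summary")
}
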