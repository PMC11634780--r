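# Condition-specific functional-connectivity graphs: Manhattan distance
# between per-cue graphs, label-permutation null and z-score, firing-rate-
# matched control, and joint-selectivity enrichment.

#' Manhattan distance between two binary connectivity graphs
#'
#' The number of edges whose presence differs, counted over the pairs
#' evaluated in both graphs (equivalently the Hamming distance of the
#' vectorised upper triangles on the common mask).
#'
#' @param g1,g2 logical edge vectors (NA = unevaluated) over the same pair
#'   enumeration, or `ccg_census` columns
#' @return integer distance
#' @export
graph_manhattan_distance <- function(g1, g2) {
  if (length(g1) != length(g2)) stop("graphs must share the node set")
  both <- !is.na(g1) & !is.na(g2)
  sum(g1[both] != g2[both])
}

edges_for_sets <- function(spk, trial_sets0, N, opts) {
  res <- ccg_edges_core(spk, trial_sets0, N, as.integer(opts$max_lag),
                        as.integer(opts$jitter_window), opts$z_thresh,
                        as.integer(opts$peak_max), as.integer(opts$base_lo),
                        as.integer(opts$base_hi))
  sig <- res$sig
  for (q in seq_along(trial_sets0)) {
    ts <- trial_sets0[[q]] + 1L
    nsp <- vapply(spk, function(u) sum(lengths(u[ts])), numeric(1))
    bad <- nsp[res$unit_a] == 0 | nsp[res$unit_b] == 0
    sig[bad, q] <- NA
  }
  sig
}

#' Graph-distance permutation test across cue conditions
#'
#' For every pair of cue conditions the Manhattan distance between their
#' significant-CCG graphs is computed; the session statistic is the mean
#' over condition pairs.  The null re-runs the entire pipeline (CCG, jitter
#' correction, significance, graph, distance) with cue labels shuffled
#' across the two conditions' trials, `n_perm` times, and the observed mean
#' distance is z-scored against it.
#'
#' @param raster 0/1 delay-window array over CCG-eligible units
#' @param trials trial table
#' @param n_perm permutations (50 for the full analysis; 25 is customary for
#'   state-restricted variants)
#' @param cond_pairs optional 2-column matrix of condition pairs (default:
#'   all pairs of observed conditions)
#' @param conditions conditions to include (default all observed)
#' @param perm_scope `"global"` draws one label permutation across all
#'   conditions per iteration and recomputes every graph, so the null mean
#'   distance inherits the same between-pair correlation as the observed
#'   one (the session z is then calibrated); `"pairwise"` re-shuffles each
#'   condition pair independently, which underestimates the variance of
#'   the 28-pair mean and overdisperses z when graphs share few edges
#' @param seed RNG seed
#' @param ... CCG parameter overrides
#' @return list of class `distance_result`: `observed` (per condition
#'   pair), `mean_observed`, `null` (per permutation means), `z`
#' @export
manhattan_null_zscore <- function(raster, trials, n_perm = 50,
                                  cond_pairs = NULL, conditions = NULL,
                                  perm_scope = c("global", "pairwise"),
                                  seed = 1L, ...) {
  perm_scope <- match.arg(perm_scope)
  opts <- utils::modifyList(ccg_defaults, list(...))
  cond <- as.integer(trials$cue_location)
  if (is.null(conditions)) conditions <- sort(unique(cond))
  if (is.null(cond_pairs))
    cond_pairs <- t(utils::combn(conditions, 2))
  spk <- raster_to_bins(raster)
  N <- dim(raster)[3]
  trial_sets0 <- lapply(conditions, function(cc) which(cond == cc) - 1L)
  sig <- edges_for_sets(spk, trial_sets0, N, opts)
  colnames(sig) <- as.character(conditions)

  dist_for <- function(smat, i1, i2)
    graph_manhattan_distance(smat[, i1], smat[, i2])
  obs <- vapply(seq_len(nrow(cond_pairs)), function(r)
    dist_for(sig, match(cond_pairs[r, 1], conditions),
             match(cond_pairs[r, 2], conditions)), numeric(1))

  set.seed(as.integer(seed))
  null_means <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    if (perm_scope == "global") {
      pool <- sample(unlist(trial_sets0))
      sizes <- lengths(trial_sets0)
      ends <- cumsum(sizes)
      sets_p <- lapply(seq_along(sizes), function(q)
        pool[(ends[q] - sizes[q] + 1):ends[q]])
      smat <- edges_for_sets(spk, sets_p, N, opts)
      dists <- vapply(seq_len(nrow(cond_pairs)), function(r)
        graph_manhattan_distance(
          smat[, match(cond_pairs[r, 1], conditions)],
          smat[, match(cond_pairs[r, 2], conditions)]), numeric(1))
    } else {
      dists <- numeric(nrow(cond_pairs))
      for (r in seq_len(nrow(cond_pairs))) {
        t1 <- trial_sets0[[match(cond_pairs[r, 1], conditions)]]
        t2 <- trial_sets0[[match(cond_pairs[r, 2], conditions)]]
        pool <- sample(c(t1, t2))
        s1 <- pool[seq_along(t1)]
        s2 <- pool[-seq_along(t1)]
        smat <- edges_for_sets(spk, list(s1, s2), N, opts)
        dists[r] <- graph_manhattan_distance(smat[, 1], smat[, 2])
      }
    }
    null_means[p] <- mean(dists)
  }
  mu <- mean(null_means)
  sg <- sd(null_means)
  z <- if (is.na(sg) || sg == 0) NA_real_ else (mean(obs) - mu) / sg
  if (is.na(z)) warning("null SD is zero: z undefined")
  structure(list(observed = data.frame(cond_a = cond_pairs[, 1],
                                       cond_b = cond_pairs[, 2],
                                       distance = obs),
                 mean_observed = mean(obs), null = null_means, z = z,
                 sig = sig),
            class = "distance_result")
}

#' Firing-rate-matched graph-distance control
#'
#' Repeats the Manhattan-distance permutation test using only condition
#' pairs within rate-homogeneous groups of cue locations (1-4 and 5-8),
#' removing rate differences across compared conditions.
#'
#' @inheritParams manhattan_null_zscore
#' @param groups list of condition groups
#' @return a `distance_result` over the within-group condition pairs
#' @export
rate_matched_distance <- function(raster, trials, n_perm = 50,
                                  groups = list(1:4, 5:8), seed = 1L, ...) {
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("each group needs >= 2 conditions")
  cp <- do.call(rbind, lapply(groups, function(g) t(utils::combn(g, 2))))
  manhattan_null_zscore(raster, trials, n_perm = n_perm, cond_pairs = cp,
                        conditions = sort(unique(unlist(groups))),
                        seed = seed, ...)
}

#' Joint selectivity-connectivity enrichment
#'
#' Units are deemed selective if their evoked (0-400 ms) mean rate depends
#' on cue location (one-way ANOVA, P < 0.05), with the argmax location as
#' preferred.  Per cue location c: P_sel(c) = fraction of pairs whose two
#' units are both selective with preferred location c; P_conn(c) = fraction
#' of pairs with a significant CCG in c; P_joint(c) = fraction satisfying
#' both.  If selectivity and connectivity were independent, P_joint would
#' equal P_sel * P_conn; the enrichment ratio is
#' mean_c P_joint / mean_c (P_sel * P_conn).
#'
#' @param spikes spike table
#' @param trials trial table
#' @param census a `ccg_census` over the same units/conditions
#' @param unit_ids unit ids in the census's unit order
#' @param alpha ANOVA criterion
#' @return list: `enrichment`, `per_condition` data.frame (p_sel, p_conn,
#'   p_joint, ratio), `selective`, `preferred`
#' @export
joint_selectivity_enrichment <- function(spikes, trials, census, unit_ids,
                                         alpha = 0.05) {
  rates <- epoch_mean_rates(spikes, trials, c(0, 400), "cue")
  rates <- rates[match(unit_ids, as.integer(rownames(rates))), ,
                 drop = FALSE]
  cue <- factor(trials$cue_location)
  sel <- logical(length(unit_ids))
  pref <- integer(length(unit_ids))
  for (u in seq_along(unit_ids)) {
    r <- rates[u, ]
    if (is.na(var(r)) || var(r) == 0) { sel[u] <- FALSE; next }
    p <- summary(aov(r ~ cue))[[1]][["Pr(>F)"]][1]
    sel[u] <- !is.na(p) && p < alpha
    pref[u] <- as.integer(names(which.max(tapply(r, cue, mean))))
  }
  pa <- census$pairs$unit_a
  pb <- census$pairs$unit_b
  conds <- census$conditions
  per <- data.frame(condition = conds, p_sel = NA_real_, p_conn = NA_real_,
                    p_joint = NA_real_)
  for (q in seq_along(conds)) {
    cc <- conds[q]
    ev <- !is.na(census$sig[, q])
    n <- sum(ev)
    if (n == 0) next
    both_sel <- sel[pa] & sel[pb] & pref[pa] == cc & pref[pb] == cc
    conn <- census$sig[, q] == TRUE
    per$p_sel[q] <- mean(both_sel[ev])
    per$p_conn[q] <- mean(conn[ev], na.rm = TRUE)
    per$p_joint[q] <- mean((both_sel & conn)[ev], na.rm = TRUE)
  }
  denom <- mean(per$p_sel * per$p_conn, na.rm = TRUE)
  if (is.na(denom) || denom == 0) {
    warning("independence expectation is zero: session excluded")
    enr <- NA_real_
  } else {
    enr <- mean(per$p_joint, na.rm = TRUE) / denom
  }
  per$ratio <- per$p_joint / (per$p_sel * per$p_conn)
  list(enrichment = enr, per_condition = per, selective = sel,
       preferred = pref)
}
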