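# One- vs two-state description of delay confidence: single-beta and
# two-component beta-mixture maximum likelihood, scored by cross-validated
# bits per trial.

dbetamix <- function(x, a, b, a2, b2, w, log = FALSE) {
  d <- w * dbeta(x, a, b) + (1 - w) * dbeta(x, a2, b2)
  if (log) log(pmax(d, .Machine$double.xmin)) else d
}

beta_mom <- function(x) {
  # method-of-moments init; guarded against degenerate variance
  m <- mean(x)
  v <- max(var(x), 1e-6)
  s <- max(m * (1 - m) / v - 1, 0.1)
  c(a = max(m * s, 0.05), b = max((1 - m) * s, 0.05))
}

fit_single_beta <- function(x) {
  # MLE on log-shape parameters with analytic gradients
  n <- length(x)
  slx <- sum(log(x))
  sl1x <- sum(log1p(-x))
  nll <- function(p) {
    p <- pmin(pmax(p, -8), 8)  # keep shapes in a numerically safe range
    -sum(dbeta(x, exp(p[1]), exp(p[2]), log = TRUE))
  }
  gr <- function(p) {
    p <- pmin(pmax(p, -8), 8)
    a <- exp(p[1]); b <- exp(p[2])
    da <- slx - n * (digamma(a) - digamma(a + b))
    db <- sl1x - n * (digamma(b) - digamma(a + b))
    -c(da * a, db * b)
  }
  init <- log(beta_mom(x))
  fit <- optim(init, nll, gr, method = "BFGS", control = list(maxit = 200))
  fit$par <- pmin(pmax(fit$par, -8), 8)
  list(alpha = exp(fit$par[1]), beta = exp(fit$par[2]),
       loglik = -fit$value, converged = fit$convergence == 0)
}

fit_mixture_beta <- function(x, n_restarts = 5, single = NULL) {
  lx <- log(x)
  l1x <- log1p(-x)
  nll <- function(p) {
    p[1:4] <- pmin(pmax(p[1:4], -8), 8)
    w <- 1 / (1 + exp(-p[5]))
    -sum(dbetamix(x, exp(p[1]), exp(p[2]), exp(p[3]), exp(p[4]), w,
                  log = TRUE))
  }
  gr <- function(p) {
    p[1:4] <- pmin(pmax(p[1:4], -8), 8)
    a <- exp(p[1]); b <- exp(p[2]); a2 <- exp(p[3]); b2 <- exp(p[4])
    w <- 1 / (1 + exp(-p[5]))
    f1 <- dbeta(x, a, b)
    f2 <- dbeta(x, a2, b2)
    mix <- pmax(w * f1 + (1 - w) * f2, .Machine$double.xmin)
    r1 <- w * f1 / mix          # responsibilities of component 1
    r2 <- 1 - r1
    g <- c(
      sum(r1 * (lx - digamma(a) + digamma(a + b))) * a,
      sum(r1 * (l1x - digamma(b) + digamma(a + b))) * b,
      sum(r2 * (lx - digamma(a2) + digamma(a2 + b2))) * a2,
      sum(r2 * (l1x - digamma(b2) + digamma(a2 + b2))) * b2,
      sum(r1 - w))
    -g
  }
  best <- NULL
  inits <- vector("list", n_restarts + 1)
  for (r in seq_len(n_restarts)) {
    # split at a random value quantile -> separated component inits
    cut <- runif(1, 0.25, 0.75)
    cv <- quantile(x, cut, names = FALSE)
    g1 <- x[x <= cv]
    g2 <- x[x > cv]
    if (length(g1) < 5 || length(g2) < 5) { g1 <- x; g2 <- x }
    m1 <- beta_mom(g1) * exp(runif(2, -0.3, 0.3))
    m2 <- beta_mom(g2) * exp(runif(2, -0.3, 0.3))
    inits[[r]] <- c(log(m1), log(m2), log(cut / (1 - cut)))
  }
  # include the single fit as a boundary init: guarantees the mixture train
  # likelihood can never fall below the nested single model
  if (!is.null(single)) {
    inits[[n_restarts + 1]] <- c(log(single$alpha), log(single$beta),
                                 log(single$alpha) + 0.2,
                                 log(single$beta) - 0.2, qlogis_safe(0.99))
  }
  for (init in inits) {
    if (is.null(init)) next
    fit <- tryCatch(optim(init, nll, gr, method = "BFGS",
                          control = list(maxit = 300)),
                    error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) return(NULL)
  p <- best$par
  p[1:4] <- pmin(pmax(p[1:4], -8), 8)
  w <- 1 / (1 + exp(-p[5]))
  comp <- list(a = exp(p[1]), b = exp(p[2]), a2 = exp(p[3]), b2 = exp(p[4]))
  # label switching: order components by mean
  m1 <- comp$a / (comp$a + comp$b)
  m2 <- comp$a2 / (comp$a2 + comp$b2)
  if (m1 > m2) {
    comp <- list(a = comp$a2, b = comp$b2, a2 = comp$a, b2 = comp$b)
    w <- 1 - w
  }
  list(alpha = comp$a, beta = comp$b, alpha2 = comp$a2, beta2 = comp$b2,
       w = w, loglik = -best$value, converged = best$convergence == 0)
}

qlogis_safe <- function(p) log(p / (1 - p))

#' Fit single-beta and two-component beta-mixture models to confidence values
#'
#' Values are clipped into `(eps, 1 - eps)` before likelihood evaluation (the
#' beta density diverges at the boundary).  The mixture is fitted with
#' multiple random restarts plus a boundary restart at the single-beta
#' solution, so its training likelihood never falls below the nested single
#' model; components are ordered by mean.
#'
#' @param x confidence values in (0, 1)
#' @param eps clipping bound (1e-4)
#' @param n_restarts random restarts for the mixture
#' @param min_n refuse fewer values than this (unstable fits)
#' @return list of class `beta_model_fit`: `single`, `mixture`, `n`
#' @export
fit_beta_models <- function(x, eps = 1e-4, n_restarts = 5, min_n = 50) {
  x <- x[!is.na(x)]
  if (length(x) < min_n)
    stop("need at least ", min_n, " confidence values")
  if (var(x) == 0) stop("degenerate input: all values equal")
  x <- pmin(pmax(x, eps), 1 - eps)
  single <- fit_single_beta(x)
  mixture <- fit_mixture_beta(x, n_restarts = n_restarts, single = single)
  structure(list(single = single, mixture = mixture, n = length(x)),
            class = "beta_model_fit")
}

#' Cross-validated model comparison in bits per trial
#'
#' Trial-level fourfold cross-validation: all timepoints of a trial stay in
#' the same fold.  Each model is fitted on the training trials and scored by
#' the held-out log2-likelihood normalised by the number of held-out trials;
#' the result is the mixture score minus the single score, averaged over
#' folds (and over conditions, when given).
#'
#' @param values confidence values (delay timepoints, pooled)
#' @param trial_ids trial id per value
#' @param conditions optional condition per value; the comparison is run per
#'   condition and averaged
#' @param k folds (4); folds with fewer than 10 trials trigger a re-fold
#'   with smaller k
#' @param eps clipping bound
#' @param n_restarts mixture restarts per fold (fewer than the final fit:
#'   each fold's fit is averaged over folds and conditions)
#' @param seed RNG seed for fold assignment and restarts
#' @return list: `delta_bits` (mixture - single, bits/trial), `per_fold`,
#'   `k_used`
#' @export
cv_model_comparison <- function(values, trial_ids, conditions = NULL, k = 4,
                                eps = 1e-4, n_restarts = 3, seed = 1L) {
  set.seed(as.integer(seed))
  if (!is.null(conditions)) {
    conds <- sort(unique(conditions))
    per <- lapply(conds, function(cc) {
      sel <- conditions == cc
      cv_one_group(values[sel], trial_ids[sel], k, eps, n_restarts)
    })
    db <- vapply(per, `[[`, numeric(1), "delta_bits")
    return(list(delta_bits = mean(db, na.rm = TRUE), per_condition = db,
                k_used = vapply(per, `[[`, numeric(1), "k_used")))
  }
  cv_one_group(values, trial_ids, k, eps, n_restarts)
}

cv_one_group <- function(values, trial_ids, k, eps, n_restarts = 3) {
  keep <- !is.na(values)
  values <- pmin(pmax(values[keep], eps), 1 - eps)
  trial_ids <- trial_ids[keep]
  trials <- unique(trial_ids)
  n <- length(trials)
  k_used <- k
  while (k_used > 2 && floor(n / k_used) < 10) k_used <- k_used - 1
  if (k_used < k)
    message("re-folded with k = ", k_used, " (folds need >= 10 trials)")
  fold <- sample(rep_len(seq_len(k_used), n))
  per_fold <- numeric(k_used)
  for (f in seq_len(k_used)) {
    tr_train <- trials[fold != f]
    tr_test <- trials[fold == f]
    xtr <- values[trial_ids %in% tr_train]
    xte <- values[trial_ids %in% tr_test]
    single <- fit_single_beta(xtr)
    mixture <- fit_mixture_beta(xtr, n_restarts = n_restarts,
                                single = single)
    s_bits <- sum(dbeta(xte, single$alpha, single$beta, log = TRUE)) /
      log(2) / length(tr_test)
    m_bits <- sum(dbetamix(xte, mixture$alpha, mixture$beta, mixture$alpha2,
                           mixture$beta2, mixture$w, log = TRUE)) /
      log(2) / length(tr_test)
    per_fold[f] <- m_bits - s_bits
  }
  list(delta_bits = mean(per_fold), per_fold = per_fold, k_used = k_used)
}
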