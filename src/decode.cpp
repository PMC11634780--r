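// Hot loops for leave-one-trial-out logistic decoding of cue location.
//
// The decoder discriminates, for every held-out trial, that trial's cue
// location from the diametrically opposite location, one classifier per
// timepoint, with class counts equalised by random subsampling.  Shuffle
// nulls permute the training labels.  All randomness draws from R's RNG so
// set.seed() in R makes results reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Ridge-penalised logistic regression via IRLS.  X: n x p (no intercept
// column), y in {0,1}.  The intercept is unpenalised.  Returns (p+1) vector,
// intercept first.  A weak fixed ridge keeps separable folds finite.
static arma::vec ridge_logit(const arma::mat& X, const arma::vec& y,
                             double lambda, int max_iter = 12,
                             double tol = 1e-5) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  arma::mat Xa(n, p + 1);
  Xa.col(0).ones();
  Xa.cols(1, p) = X;
  arma::vec beta(p + 1, arma::fill::zeros);
  arma::mat pen(p + 1, p + 1, arma::fill::eye);
  pen(0, 0) = 0.0;  // no penalty on intercept
  for (int it = 0; it < max_iter; ++it) {
    arma::vec eta = Xa * beta;
    arma::vec mu(n), w(n);
    for (arma::uword i = 0; i < n; ++i) {
      mu[i] = sigmoid(eta[i]);
      w[i] = std::max(mu[i] * (1.0 - mu[i]), 1e-6);
    }
    arma::vec z = eta + (y - mu) / w;
    arma::mat XtW = Xa.t();
    XtW.each_row() %= w.t();
    arma::mat H = XtW * Xa + lambda * pen;
    arma::vec rhs = XtW * z;
    arma::vec beta_new;
    if (!arma::solve(beta_new, H, rhs, arma::solve_opts::likely_sympd)) {
      // fall back to a heavier ridge if the system is ill conditioned
      beta_new = arma::solve(H + arma::eye(p + 1, p + 1), rhs);
    }
    double step = arma::norm(beta_new - beta, 2);
    beta = beta_new;
    if (step < tol) break;
  }
  return beta;
}

// Fisher-Yates partial shuffle using R's RNG; leaves a random subset of size
// m in the first m slots.
static void partial_shuffle(std::vector<int>& v, int m) {
  const int n = static_cast<int>(v.size());
  for (int i = 0; i < m; ++i) {
    int j = i + static_cast<int>(unif_rand() * (n - i));
    if (j >= n) j = n - 1;
    std::swap(v[i], v[j]);
  }
}

static void full_shuffle(arma::vec& y) {
  const int n = static_cast<int>(y.n_elem);
  for (int i = n - 1; i > 0; --i) {
    int j = static_cast<int>(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(y[i], y[j]);
  }
}

// X: units x trials x time cube of z-scored rates; cond: 1-based condition
// per trial; opp: 1-based opposite condition per trial; tp: 0-based time
// indices to decode; n_shuffles label-shuffled replicates (0 = none);
// mask: trials x time (full axis) inclusion mask, or empty for all-in.
// Returns conf (trials x length(tp)), null cube (trials x tp x shuffles).
// [[Rcpp::export]]
List loo_confidence_core(const arma::cube& X, const IntegerVector& cond,
                         const IntegerVector& opp, const IntegerVector& tp,
                         double lambda, int n_shuffles,
                         const LogicalMatrix& mask) {
  const int n_trials = X.n_cols;
  const int n_units = X.n_rows;
  const int n_tp = tp.size();
  const bool use_mask = mask.nrow() > 0;

  arma::mat conf(n_trials, n_tp);
  conf.fill(NA_REAL);
  arma::cube nul;
  if (n_shuffles > 0) {
    nul.set_size(n_trials, n_tp, n_shuffles);
    nul.fill(NA_REAL);
  }

  std::vector<int> same, oppv;
  same.reserve(n_trials);
  oppv.reserve(n_trials);

  for (int ti = 0; ti < n_tp; ++ti) {
    const int t = tp[ti];
    arma::mat Xt = X.slice(t);  // units x trials
    for (int i = 0; i < n_trials; ++i) {
      if (use_mask && !mask(i, t)) continue;
      same.clear();
      oppv.clear();
      for (int j = 0; j < n_trials; ++j) {
        if (j == i) continue;
        if (use_mask && !mask(j, t)) continue;
        if (cond[j] == cond[i]) same.push_back(j);
        else if (cond[j] == opp[i]) oppv.push_back(j);
      }
      int m = std::min(same.size(), oppv.size());
      if (m < 2) continue;
      partial_shuffle(same, m);
      partial_shuffle(oppv, m);
      arma::mat Xtr(2 * m, n_units);
      arma::vec y(2 * m);
      for (int r = 0; r < m; ++r) {
        Xtr.row(r) = Xt.col(same[r]).t();
        y[r] = 1.0;
        Xtr.row(m + r) = Xt.col(oppv[r]).t();
        y[m + r] = 0.0;
      }
      arma::rowvec xte = Xt.col(i).t();
      arma::vec beta = ridge_logit(Xtr, y, lambda);
      conf(i, ti) = sigmoid(beta[0] +
                            arma::dot(xte, beta.subvec(1, n_units)));
      for (int s = 0; s < n_shuffles; ++s) {
        arma::vec ys = y;
        full_shuffle(ys);
        arma::vec bs = ridge_logit(Xtr, ys, lambda);
        nul(i, ti, s) = sigmoid(bs[0] +
                                arma::dot(xte, bs.subvec(1, n_units)));
      }
    }
  }
  List out = List::create(Named("conf") = conf);
  if (n_shuffles > 0) out["null"] = nul;
  return out;
}

// Split-half cross-temporal decoding.  One classifier per (train timepoint,
// condition pair); each test trial scored at every test timepoint.  Returns
// summed correct counts and totals (T x T), to be averaged in R.
// [[Rcpp::export]]
List cross_temporal_core(const arma::cube& X, const IntegerVector& cond,
                         int n_cond, const IntegerVector& train_trials,
                         const IntegerVector& test_trials,
                         const IntegerVector& tp, double lambda,
                         bool shuffle_labels) {
  const int n_units = X.n_rows;
  const int n_tp = tp.size();
  const int half = n_cond / 2;
  arma::mat correct(n_tp, n_tp, arma::fill::zeros);
  arma::mat total(n_tp, n_tp, arma::fill::zeros);

  for (int ti = 0; ti < n_tp; ++ti) {
    const int t = tp[ti];
    arma::mat Xt = X.slice(t);
    for (int q = 1; q <= half; ++q) {
      const int c1 = q, c2 = q + half;
      std::vector<int> g1, g2;
      for (int idx = 0; idx < train_trials.size(); ++idx) {
        int j = train_trials[idx];
        if (cond[j] == c1) g1.push_back(j);
        else if (cond[j] == c2) g2.push_back(j);
      }
      int m = std::min(g1.size(), g2.size());
      if (m < 2) continue;
      partial_shuffle(g1, m);
      partial_shuffle(g2, m);
      arma::mat Xtr(2 * m, n_units);
      arma::vec y(2 * m);
      for (int r = 0; r < m; ++r) {
        Xtr.row(r) = Xt.col(g1[r]).t();
        y[r] = 1.0;
        Xtr.row(m + r) = Xt.col(g2[r]).t();
        y[m + r] = 0.0;
      }
      if (shuffle_labels) full_shuffle(y);
      arma::vec beta = ridge_logit(Xtr, y, lambda);
      for (int idx = 0; idx < test_trials.size(); ++idx) {
        int i = test_trials[idx];
        if (cond[i] != c1 && cond[i] != c2) continue;
        double y_true = (cond[i] == c1) ? 1.0 : 0.0;
        for (int tj = 0; tj < n_tp; ++tj) {
          arma::vec xte = X.slice(tp[tj]).col(i);
          double p = sigmoid(beta[0] +
                             arma::dot(xte, beta.subvec(1, n_units)));
          bool ok = (p > 0.5) == (y_true > 0.5);
          correct(ti, tj) += ok ? 1.0 : 0.0;
          total(ti, tj) += 1.0;
        }
      }
    }
  }
  return List::create(Named("correct") = correct, Named("total") = total);
}
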