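// Spike-train cross-correlogram (CCG) machinery.
//
// Spike trains arrive as 0-based 1-ms bin indices per trial (already
// binarised, so at most one spike per bin).  The CCG numerator at lag tau
// counts coincidences x_j(t - tau) * x_k(t) summed over trials; the
// denominator is the geometric mean of the two units' spike counts over the
// bins that enter the sum at that lag.  The jitter null redistributes the
// second train within fixed windows, preserving the across-trial PSTH and
// the per-trial count in each window; its expectation has the closed form
// E[x_k(t)] = n_k(win(t)) * PSTH_k(t) / sum_{t' in win} PSTH_k(t').

#include <Rcpp.h>
using namespace Rcpp;

// prefix[t] = pooled spike count of the unit in bins 0..t
static std::vector<double> prefix_counts(const List& trains, int N) {
  std::vector<double> cnt(N, 0.0);
  for (int i = 0; i < trains.size(); ++i) {
    IntegerVector s = trains[i];
    for (int a = 0; a < s.size(); ++a)
      if (s[a] >= 0 && s[a] < N) cnt[s[a]] += 1.0;
  }
  for (int t = 1; t < N; ++t) cnt[t] += cnt[t - 1];
  return cnt;
}

static inline double range_count(const std::vector<double>& pre, int lo,
                                 int hi) {
  if (hi < lo) return 0.0;
  double c = pre[hi];
  if (lo > 0) c -= pre[lo - 1];
  return c;
}

// Geometric-mean denominator at lag tau: for tau >= 0 unit j is counted in
// bins [0, N-1-tau] and unit k in [tau, N-1]; mirrored for tau < 0.
static double denom_at(const std::vector<double>& pre_j,
                       const std::vector<double>& pre_k, int N, int tau) {
  double nj, nk;
  if (tau >= 0) {
    nj = range_count(pre_j, 0, N - 1 - tau);
    nk = range_count(pre_k, tau, N - 1);
  } else {
    nj = range_count(pre_j, -tau, N - 1);
    nk = range_count(pre_k, 0, N - 1 + tau);
  }
  return std::sqrt(nj * nk);
}

// Raw coincidence counts at lags -L..L (index tau + L).
static std::vector<double> raw_counts(const List& tj, const List& tk, int N,
                                      int L) {
  std::vector<double> cnt(2 * L + 1, 0.0);
  for (int i = 0; i < tj.size(); ++i) {
    IntegerVector sj = tj[i], sk = tk[i];
    for (int a = 0; a < sj.size(); ++a)
      for (int b = 0; b < sk.size(); ++b) {
        int d = sk[b] - sj[a];
        if (d >= -L && d <= L) cnt[d + L] += 1.0;
      }
  }
  return cnt;
}

struct JitterField {
  // per unit/trial-set: PSTH, per-trial window counts, window PSTH sums
  std::vector<double> psth;           // length N
  std::vector<std::vector<double>> wc;  // n_trials x n_win
  std::vector<double> wps;            // n_win
  int jw, n_win, N;
  void build(const List& trains, int N_, int jw_) {
    N = N_;
    jw = jw_;
    n_win = (N + jw - 1) / jw;
    psth.assign(N, 0.0);
    wps.assign(n_win, 0.0);
    wc.assign(trains.size(), std::vector<double>(n_win, 0.0));
    for (int i = 0; i < trains.size(); ++i) {
      IntegerVector s = trains[i];
      for (int a = 0; a < s.size(); ++a) {
        int t = s[a];
        if (t < 0 || t >= N) continue;
        psth[t] += 1.0;
        wc[i][t / jw] += 1.0;
      }
    }
    for (int t = 0; t < N; ++t) wps[t / jw] += psth[t];
  }
  inline double expect(int trial, int t) const {
    int w = t / jw;
    if (wps[w] <= 0.0) return 0.0;
    return wc[trial][w] * psth[t] / wps[w];
  }
};

// Expected coincidence count under the jitter null at the requested lags
// (second train jittered).
static void jitter_counts(const List& tj, const JitterField& fk, int N,
                          const std::vector<int>& taus,
                          std::vector<double>& out) {
  out.assign(taus.size(), 0.0);
  for (int i = 0; i < tj.size(); ++i) {
    IntegerVector sj = tj[i];
    for (int a = 0; a < sj.size(); ++a) {
      int base = sj[a];
      for (size_t q = 0; q < taus.size(); ++q) {
        int t = base + taus[q];
        if (t >= 0 && t < N) out[q] += fk.expect(i, t);
      }
    }
  }
}

// Full-resolution raw, jitter-expected and corrected CCG for one pair over
// one set of trials.  trains_* : list over trials of 0-based bin indices.
// [[Rcpp::export]]
List ccg_pair_core(const List& trains_j, const List& trains_k, int N, int L,
                   int jitter_window) {
  std::vector<double> cnt = raw_counts(trains_j, trains_k, N, L);
  std::vector<double> pre_j = prefix_counts(trains_j, N);
  std::vector<double> pre_k = prefix_counts(trains_k, N);
  JitterField fk;
  fk.build(trains_k, N, jitter_window);
  std::vector<int> taus(2 * L + 1);
  for (int d = -L; d <= L; ++d) taus[d + L] = d;
  std::vector<double> jit;
  jitter_counts(trains_j, fk, N, taus, jit);

  NumericVector raw(2 * L + 1), jexp(2 * L + 1), corr(2 * L + 1),
      den(2 * L + 1), counts(2 * L + 1), jcounts(2 * L + 1);
  for (int q = 0; q <= 2 * L; ++q) {
    double d = denom_at(pre_j, pre_k, N, q - L);
    den[q] = d;
    counts[q] = cnt[q];
    jcounts[q] = jit[q];
    raw[q] = d > 0 ? cnt[q] / d : NA_REAL;
    jexp[q] = d > 0 ? jit[q] / d : NA_REAL;
    corr[q] = d > 0 ? (cnt[q] - jit[q]) / d : NA_REAL;
  }
  return List::create(Named("lag") = seq(-L, L), Named("counts") = counts,
                      Named("jitter_counts") = jcounts, Named("raw") = raw,
                      Named("jitter") = jexp, Named("corrected") = corr,
                      Named("denom") = den);
}

// Monte-Carlo jitter resamples of the second train: each spike count in a
// (trial, window) cell is redistributed over the window's bins with
// probability proportional to the across-trial PSTH (independent draws, so
// resampled trains are count trains).  Returns n_resamples x (2L+1)
// normalised CCGs using the original-data denominators.
// [[Rcpp::export]]
NumericMatrix ccg_jitter_mc_core(const List& trains_j, const List& trains_k,
                                 int N, int L, int jitter_window,
                                 int n_resamples) {
  std::vector<double> pre_j = prefix_counts(trains_j, N);
  std::vector<double> pre_k = prefix_counts(trains_k, N);
  JitterField fk;
  fk.build(trains_k, N, jitter_window);
  const int n_tr = trains_j.size();
  NumericMatrix out(n_resamples, 2 * L + 1);
  std::vector<double> den(2 * L + 1);
  for (int d = -L; d <= L; ++d) den[d + L] = denom_at(pre_j, pre_k, N, d);

  // per-window cumulative PSTH for categorical sampling
  for (int r = 0; r < n_resamples; ++r) {
    std::vector<double> cnt(2 * L + 1, 0.0);
    for (int i = 0; i < n_tr; ++i) {
      IntegerVector sj = trains_j[i];
      if (sj.size() == 0) continue;
      for (int w = 0; w < fk.n_win; ++w) {
        int m = static_cast<int>(fk.wc[i][w]);
        if (m == 0) continue;
        int lo = w * fk.jw;
        int hi = std::min(N - 1, lo + fk.jw - 1);
        double tot = fk.wps[w];
        for (int s = 0; s < m; ++s) {
          int b = hi;
          if (tot > 0) {
            double u = unif_rand() * tot, acc = 0.0;
            for (int t = lo; t <= hi; ++t) {
              acc += fk.psth[t];
              if (u <= acc) { b = t; break; }
            }
          } else {
            b = lo + static_cast<int>(unif_rand() * (hi - lo + 1));
            if (b > hi) b = hi;
          }
          for (int a = 0; a < sj.size(); ++a) {
            int d = b - sj[a];
            if (d >= -L && d <= L) cnt[d + L] += 1.0;
          }
        }
      }
    }
    for (int q = 0; q <= 2 * L; ++q)
      out(r, q) = den[q] > 0 ? cnt[q] / den[q] : NA_REAL;
  }
  return out;
}

struct PeakResult {
  double peak, base_mean, base_sd, z;
  int lag;
  bool sig, ok;
};

// Peak search over 1 <= |tau| <= peak_max (zero lag excluded; ties go to
// smaller |tau|, then negative lag); baseline over base_lo <= |tau| <= base_hi.
static PeakResult peak_stats(const std::vector<double>& corr, int L,
                             int peak_max, int base_lo, int base_hi,
                             double z_thresh) {
  PeakResult res;
  res.ok = true;
  double s = 0.0, s2 = 0.0;
  int nb = 0;
  for (int a = base_lo; a <= base_hi; ++a) {
    for (int sign = -1; sign <= 1; sign += 2) {
      double v = corr[sign * a + L];
      if (!ISNAN(v)) { s += v; s2 += v * v; ++nb; }
    }
  }
  if (nb < 2) { res.ok = false; res.sig = false; res.z = NA_REAL;
    res.peak = NA_REAL; res.lag = NA_INTEGER; res.base_mean = NA_REAL;
    res.base_sd = NA_REAL; return res; }
  double mean = s / nb;
  double var = (s2 - nb * mean * mean) / (nb - 1);
  double sd = var > 0 ? std::sqrt(var) : 0.0;
  double best = -std::numeric_limits<double>::infinity();
  int best_lag = NA_INTEGER;
  for (int a = 1; a <= peak_max; ++a) {
    for (int sign = -1; sign <= 1; sign += 2) {
      double v = corr[sign * a + L];
      if (!ISNAN(v) && v > best) { best = v; best_lag = sign * a; }
    }
  }
  res.peak = best;
  res.lag = best_lag;
  res.base_mean = mean;
  res.base_sd = sd;
  res.z = sd > 0 ? (best - mean) / sd : NA_REAL;
  res.sig = sd > 0 && best > mean + z_thresh * sd;
  return res;
}

// Significance census over all unit pairs and several trial sets
// (conditions).  spk: list over units of lists over trials of bin indices;
// trial_sets: list of 0-based trial index vectors.  Returns per pair x set
// significance, peak z and peak lag.
// [[Rcpp::export]]
List ccg_edges_core(const List& spk, const List& trial_sets, int N, int L,
                    int jitter_window, double z_thresh, int peak_max,
                    int base_lo, int base_hi) {
  const int n_units = spk.size();
  const int n_pairs = n_units * (n_units - 1) / 2;
  const int n_sets = trial_sets.size();
  LogicalMatrix sig(n_pairs, n_sets);
  NumericMatrix pz(n_pairs, n_sets);
  IntegerMatrix plag(n_pairs, n_sets);
  IntegerVector pa(n_pairs), pb(n_pairs);

  // lags actually needed
  std::vector<int> taus;
  for (int a = 1; a <= peak_max; ++a) { taus.push_back(-a); taus.push_back(a); }
  for (int a = base_lo; a <= base_hi; ++a) {
    taus.push_back(-a); taus.push_back(a);
  }

  for (int cs = 0; cs < n_sets; ++cs) {
    IntegerVector tridx = trial_sets[cs];
    const int n_tr = tridx.size();
    // flat spike times per unit (with trial offsets) for this trial set,
    // plus prefix counts and a dense jitter-expectation field per unit
    std::vector<std::vector<int>> spikes(n_units);   // t + trial * N
    std::vector<std::vector<double>> pre(n_units);
    std::vector<std::vector<double>> efield(n_units);  // trial * N + t
    for (int u = 0; u < n_units; ++u) {
      List all = spk[u];
      List s(n_tr);
      for (int i = 0; i < n_tr; ++i) s[i] = all[tridx[i]];
      pre[u] = prefix_counts(s, N);
      JitterField f;
      f.build(s, N, jitter_window);
      std::vector<double>& E = efield[u];
      E.assign(static_cast<size_t>(n_tr) * N, 0.0);
      for (int i = 0; i < n_tr; ++i)
        for (int t = 0; t < N; ++t)
          E[static_cast<size_t>(i) * N + t] = f.expect(i, t);
      std::vector<int>& sv = spikes[u];
      for (int i = 0; i < n_tr; ++i) {
        IntegerVector tr = s[i];
        for (int a = 0; a < tr.size(); ++a)
          if (tr[a] >= 0 && tr[a] < N) sv.push_back(i * N + tr[a]);
      }
    }
    int p = 0;
    std::vector<double> cnt(2 * L + 1), jit(taus.size());
    std::vector<double> corr(2 * L + 1);
    for (int j = 0; j < n_units; ++j) {
      for (int k = j + 1; k < n_units; ++k, ++p) {
        if (cs == 0) { pa[p] = j + 1; pb[p] = k + 1; }
        // raw coincidences: spikes share the trial iff same block of N
        std::fill(cnt.begin(), cnt.end(), 0.0);
        {
          const std::vector<int>& sj = spikes[j];
          const std::vector<int>& sk = spikes[k];
          size_t b0 = 0;
          for (size_t a = 0; a < sj.size(); ++a) {
            int trial = sj[a] / N;
            while (b0 < sk.size() && sk[b0] < trial * N) ++b0;
            for (size_t b = b0; b < sk.size() && sk[b] < (trial + 1) * N;
                 ++b) {
              int d = sk[b] - sj[a];
              if (d >= -L && d <= L) cnt[d + L] += 1.0;
            }
          }
        }
        // jitter expectation at the needed lags from the dense field
        std::fill(jit.begin(), jit.end(), 0.0);
        {
          const std::vector<int>& sj = spikes[j];
          const std::vector<double>& Ek = efield[k];
          for (size_t a = 0; a < sj.size(); ++a) {
            int base = sj[a];
            int t0 = (base / N) * N;
            for (size_t q = 0; q < taus.size(); ++q) {
              int t = base + taus[q];
              if (t >= t0 && t < t0 + N) jit[q] += Ek[t];
            }
          }
        }
        std::fill(corr.begin(), corr.end(),
                  std::numeric_limits<double>::quiet_NaN());
        bool any = false;
        for (size_t q = 0; q < taus.size(); ++q) {
          int tau = taus[q];
          double d = denom_at(pre[j], pre[k], N, tau);
          if (d > 0) { corr[tau + L] = (cnt[tau + L] - jit[q]) / d; any = true; }
        }
        if (!any) { sig(p, cs) = false; pz(p, cs) = NA_REAL;
          plag(p, cs) = NA_INTEGER; continue; }
        PeakResult res =
            peak_stats(corr, L, peak_max, base_lo, base_hi, z_thresh);
        sig(p, cs) = res.sig;
        pz(p, cs) = res.z;
        plag(p, cs) = res.lag;
      }
    }
  }
  return List::create(Named("sig") = sig, Named("peak_z") = pz,
                      Named("peak_lag") = plag, Named("unit_a") = pa,
                      Named("unit_b") = pb);
}
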