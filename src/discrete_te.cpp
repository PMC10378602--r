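#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Plug-in Shannon transfer entropy on integer-coded (binned or symbolised)
// phase series, pooled over repetition trials:
//   TE = H(b,c) - H(a,b,c) + H(a,b) - H(b)   [nats]
// with a = target present code, b = target past code, c = lagged source code.

namespace {

class Counter {
  std::vector<int> cnt;
  std::vector<int> used;
public:
  void reset(size_t K) {
    if (cnt.size() < K) cnt.resize(K, 0);
    for (size_t i = 0; i < used.size(); ++i) cnt[used[i]] = 0;
    used.clear();
  }
  inline void add(int code) {
    if (cnt[code]++ == 0) used.push_back(code);
  }
  double entropy(double n) const {
    double s = 0.0;
    for (size_t i = 0; i < used.size(); ++i) {
      const double c = cnt[used[i]];
      s += c * std::log(c);
    }
    return std::log(n) - s / n;
  }
};

// TE for one direction at one lag under one trial pairing.
// codeT/codeS are T x R column-major; target trial permT[r] is paired with
// source trial permS[r]; samples run t0..T-1; KT/KS are the target and
// source alphabet sizes of this direction.
double te_pair(const int* codeT, const int* codeS, int T, int R,
               const int* permT, const int* permS,
               int u, int t0, int KT, int KS,
               Counter& c_abc, Counter& c_bc, Counter& c_ab, Counter& c_b) {
  c_abc.reset((size_t)KT * KT * KS);
  c_bc.reset((size_t)KT * KS);
  c_ab.reset((size_t)KT * KT);
  c_b.reset((size_t)KT);
  long n = 0;
  for (int r = 0; r < R; ++r) {
    const int* tt = codeT + (size_t)permT[r] * T;
    const int* ss = codeS + (size_t)permS[r] * T;
    for (int t = t0; t < T; ++t) {
      const int a = tt[t], b = tt[t - 1], c = ss[t - u];
      c_abc.add(a + KT * (b + KT * c));
      c_bc.add(b + KT * c);
      c_ab.add(a + KT * b);
      c_b.add(b);
      ++n;
    }
  }
  const double dn = (double)n;
  return c_bc.entropy(dn) - c_abc.entropy(dn) + c_ab.entropy(dn) - c_b.entropy(dn);
}

} // namespace

// Single evaluation from already-gathered code vectors (used by te_bin/te_sym
// with the exact per-lag sample support of the embedding row-count formula).
// [[Rcpp::export(name = ".te_discrete_cpp")]]
double te_discrete_cpp(IntegerVector a, IntegerVector b, IntegerVector c,
                       int Ka, int Kc) {
  const int n = a.size();
  if (b.size() != n || c.size() != n) stop("code vectors must have equal length");
  if (n < 1) stop("no samples");
  Counter c_abc, c_bc, c_ab, c_b;
  c_abc.reset((size_t)Ka * Ka * Kc);
  c_bc.reset((size_t)Ka * Kc);
  c_ab.reset((size_t)Ka * Ka);
  c_b.reset((size_t)Ka);
  for (int i = 0; i < n; ++i) {
    c_abc.add(a[i] + Ka * (b[i] + Ka * c[i]));
    c_bc.add(b[i] + Ka * c[i]);
    c_ab.add(a[i] + Ka * b[i]);
    c_b.add(b[i]);
  }
  const double dn = n;
  return c_bc.entropy(dn) - c_abc.entropy(dn) + c_ab.entropy(dn) - c_b.entropy(dn);
}

// Full differential-TE pipeline (lag scan in both directions) for the
// observed pairing plus n_surr trial-shuffle surrogates.  All lags share the
// common valid support t >= t0 so TE values are comparable along the scan.
//
// Direction 1 (X -> Y): target codes codeT1 (Y, alphabet KT1), source codes
// codeS1 (X, alphabet KS1); trial pairing: target trial r with source trial
// perm[r].  Direction 2 (Y -> X): target codeT2 (X, trial perm[r]) with
// source codeS2 (Y, trial r), alphabets KT2/KS2.
// o* give the first valid sample index of each coded series.
// [[Rcpp::export(name = ".dte_scan_surr_disc_cpp")]]
List dte_scan_surr_disc_cpp(IntegerMatrix codeT1, IntegerMatrix codeS1,
                            int KT1, int KS1,
                            IntegerMatrix codeT2, IntegerMatrix codeS2,
                            int KT2, int KS2,
                            IntegerVector lags, IntegerMatrix perms,
                            int oT1, int oS1, int oT2, int oS2) {
  const int T = codeT1.nrow(), R = codeT1.ncol();
  if (codeS1.nrow() != T || codeS1.ncol() != R ||
      codeT2.nrow() != T || codeT2.ncol() != R ||
      codeS2.nrow() != T || codeS2.ncol() != R)
    stop("code matrices must have identical shape");
  const int L = lags.size(), S = perms.nrow();
  int umax = 1;
  for (int l = 0; l < L; ++l) if (lags[l] > umax) umax = lags[l];
  const int t0_1 = std::max(oT1 + 1, oS1 + umax);
  const int t0_2 = std::max(oT2 + 1, oS2 + umax);
  if (t0_1 >= T || t0_2 >= T) stop("insufficient samples for requested lags/embedding");

  std::vector<int> ident(R);
  for (int r = 0; r < R; ++r) ident[r] = r;

  Counter c1, c2, c3, c4;
  NumericVector te_xy(L), te_yx(L), dte_surr(S);
  double dte_obs = 0.0;

  for (int s = 0; s <= S; ++s) {
    const int* perm = ident.data();
    std::vector<int> prow;
    if (s > 0) {
      prow.resize(R);
      for (int r = 0; r < R; ++r) prow[r] = perms(s - 1, r);
      perm = prow.data();
    }
    double best_xy = R_NegInf, best_yx = R_NegInf;
    for (int l = 0; l < L; ++l) {
      const double txy = te_pair(codeT1.begin(), codeS1.begin(), T, R,
                                 ident.data(), perm, lags[l], t0_1, KT1, KS1,
                                 c1, c2, c3, c4);
      const double tyx = te_pair(codeT2.begin(), codeS2.begin(), T, R,
                                 perm, ident.data(), lags[l], t0_2, KT2, KS2,
                                 c1, c2, c3, c4);
      if (s == 0) { te_xy[l] = txy; te_yx[l] = tyx; }
      if (txy > best_xy) best_xy = txy;
      if (tyx > best_yx) best_yx = tyx;
    }
    if (s == 0) dte_obs = best_xy - best_yx;
    else dte_surr[s - 1] = best_xy - best_yx;
  }

  const double n_xy = (double)(T - t0_1) * R;
  return List::create(_["te_xy"] = te_xy, _["te_yx"] = te_yx,
                      _["dte_obs"] = dte_obs, _["dte_surr"] = dte_surr,
                      _["n_samples"] = n_xy);
}
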