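#include <Rcpp.h>
#include <Rmath.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include "circdist.h"
using namespace Rcpp;

// Kraskov-Stoegbauer-Grassberger (algorithm 1) transfer entropy on phases,
// max-norm with the wrapped per-coordinate distance, plus the Ragwitz
// local-predictor embedding criterion and the correlation sums used by the
// C-C embedding method.

namespace {

// KSG core on flat point arrays (n points):
//   ynow (n), ypast (n x dy, row-major per point), xpast (n x dx).
// TE = psi(k) + < psi(n_yp + 1) - psi(n_yn_yp + 1) - psi(n_yp_xp + 1) >
double ksg_core(const double* ynow, const double* ypast, const double* xpast,
                int n, int dy, int dx, int k, const double* psi_tab) {
  std::vector<double> d_yp(n), d_yn(n), d_xp(n), joint(n);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    const double yni = ynow[i];
    const double* ypi = ypast + (size_t)i * dy;
    const double* xpi = xpast + (size_t)i * dx;
    for (int j = 0; j < n; ++j) {
      double dyp = 0.0;
      const double* ypj = ypast + (size_t)j * dy;
      for (int m = 0; m < dy; ++m) {
        const double d = circ_adiff(ypi[m], ypj[m]);
        if (d > dyp) dyp = d;
      }
      double dxp = 0.0;
      const double* xpj = xpast + (size_t)j * dx;
      for (int m = 0; m < dx; ++m) {
        const double d = circ_adiff(xpi[m], xpj[m]);
        if (d > dxp) dxp = d;
      }
      const double dyn = circ_adiff(yni, ynow[j]);
      d_yp[j] = dyp; d_yn[j] = dyn; d_xp[j] = dxp;
      joint[j] = std::max(dyp, std::max(dyn, dxp));
    }
    joint[i] = R_PosInf; // exclude self
    // k-th smallest joint distance
    std::vector<double> tmp(joint);
    std::nth_element(tmp.begin(), tmp.begin() + (k - 1), tmp.end());
    const double eps = tmp[k - 1];
    int n_yp = 0, n_yn_yp = 0, n_yp_xp = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (d_yp[j] < eps) {
        ++n_yp;
        if (d_yn[j] < eps) ++n_yn_yp;
        if (d_xp[j] < eps) ++n_yp_xp;
      }
    }
    acc += psi_tab[n_yp + 1] - psi_tab[n_yn_yp + 1] - psi_tab[n_yp_xp + 1];
  }
  return psi_tab[k] + acc / n;
}

std::vector<double> psi_table(int nmax) {
  std::vector<double> tab(nmax + 2);
  for (int i = 1; i <= nmax + 1; ++i) tab[i] = R::digamma((double)i);
  tab[0] = R_NegInf; // never used
  return tab;
}

// gather embedded point coordinates from a T x R phase matrix
// point p: trial tr[p], time tp[p]; coords theta[t - off - m*tau], m=0..d-1
inline void gather(const double* ph, int T, const int* tr, const int* tp, int n,
                   int off, int d, int tau, double* out) {
  for (int p = 0; p < n; ++p) {
    const double* col = ph + (size_t)tr[p] * T;
    const int t = tp[p] - off;
    for (int m = 0; m < d; ++m) out[(size_t)p * d + m] = col[t - m * tau];
  }
}

} // namespace

// Single KSG evaluation from pre-embedded points.
// [[Rcpp::export(name = ".te_ksg_cpp")]]
double te_ksg_cpp(NumericVector ynow, NumericMatrix ypast, NumericMatrix xpast,
                  int k) {
  const int n = ynow.size(), dy = ypast.ncol(), dx = xpast.ncol();
  if (ypast.nrow() != n || xpast.nrow() != n) stop("point counts differ");
  if (n < k + 1) stop("need at least k + 1 pooled samples");
  // row-major copies
  std::vector<double> yp((size_t)n * dy), xp((size_t)n * dx);
  for (int i = 0; i < n; ++i) {
    for (int m = 0; m < dy; ++m) yp[(size_t)i * dy + m] = ypast(i, m);
    for (int m = 0; m < dx; ++m) xp[(size_t)i * dx + m] = xpast(i, m);
  }
  std::vector<double> psi = psi_table(n);
  return ksg_core(REAL(ynow), yp.data(), xp.data(), n, dy, dx, k, psi.data());
}

// Differential-TE surrogate scan for the KSG backend.
// phX, phY: T x R phase matrices. sub_tr/sub_t: 0-based pooled point list
// (valid for every lag and both directions). perms: 0-based permutations.
// [[Rcpp::export(name = ".dte_scan_surr_ksg_cpp")]]
List dte_scan_surr_ksg_cpp(NumericMatrix phX, NumericMatrix phY,
                           int dX, int tauX, int dY, int tauY,
                           IntegerVector lags, IntegerMatrix perms,
                           IntegerVector sub_tr, IntegerVector sub_t, int k) {
  const int T = phX.nrow();
  const int n = sub_tr.size(), L = lags.size(), S = perms.nrow();
  if (n < k + 1) stop("need at least k + 1 pooled samples");
  std::vector<double> psi = psi_table(n);

  std::vector<int> tr(n), tp(n);
  for (int p = 0; p < n; ++p) { tr[p] = sub_tr[p]; tp[p] = sub_t[p]; }

  // target-side structures never change with the surrogate pairing
  std::vector<double> ynowY(n), ypY((size_t)n * dY), ynowX(n), ypX((size_t)n * dX);
  for (int p = 0; p < n; ++p) {
    ynowY[p] = phY(tp[p], tr[p]);
    ynowX[p] = phX(tp[p], tr[p]);
  }
  gather(REAL(phY), T, tr.data(), tp.data(), n, 1, dY, tauY, ypY.data());
  gather(REAL(phX), T, tr.data(), tp.data(), n, 1, dX, tauX, ypX.data());

  NumericVector te_xy(L), te_yx(L), dte_surr(S);
  double dte_obs = 0.0;
  std::vector<double> src((size_t)n * std::max(dX, dY));
  std::vector<int> ptr(n);

  for (int s = 0; s <= S; ++s) {
    for (int p = 0; p < n; ++p)
      ptr[p] = (s == 0) ? tr[p] : perms(s - 1, tr[p]);
    double best_xy = R_NegInf, best_yx = R_NegInf;
    for (int l = 0; l < L; ++l) {
      const int u = lags[l];
      // X -> Y: source X from paired trial
      gather(REAL(phX), T, ptr.data(), tp.data(), n, u, dX, tauX, src.data());
      const double txy = ksg_core(ynowY.data(), ypY.data(), src.data(),
                                  n, dY, dX, k, psi.data());
      // Y -> X: target X from paired trial, source Y from original trial.
      // Pairing is what matters; gather target-X "now"/"past" from ptr.
      std::vector<double> ynowXp(n), ypXp((size_t)n * dX);
      for (int p = 0; p < n; ++p) ynowXp[p] = phX(tp[p], ptr[p]);
      gather(REAL(phX), T, ptr.data(), tp.data(), n, 1, dX, tauX, ypXp.data());
      gather(REAL(phY), T, tr.data(), tp.data(), n, u, dY, tauY, src.data());
      const double tyx = ksg_core(ynowXp.data(), ypXp.data(), src.data(),
                                  n, dX, dY, k, psi.data());
      if (s == 0) { te_xy[l] = txy; te_yx[l] = tyx; }
      if (txy > best_xy) best_xy = txy;
      if (tyx > best_yx) best_yx = tyx;
    }
    if (s == 0) dte_obs = best_xy - best_yx;
    else dte_surr[s - 1] = best_xy - best_yx;
    Rcpp::checkUserInterrupt();
  }

  return List::create(_["te_xy"] = te_xy, _["te_yx"] = te_yx,
                      _["dte_obs"] = dte_obs, _["dte_surr"] = dte_surr,
                      _["n_samples"] = (double)n);
}

// Ragwitz criterion: leave-one-out locally-constant one-step prediction of
// the phase series with k nearest embedded neighbours (circular max-norm);
// returns the mean squared wrapped prediction error over the pooled points.
// [[Rcpp::export(name = ".ragwitz_error_cpp")]]
double ragwitz_error_cpp(NumericMatrix ph, int d, int tau, int k,
                         IntegerVector sub_tr, IntegerVector sub_t) {
  const int T = ph.nrow();
  const int n = sub_tr.size();
  if (n < k + 2) stop("too few points for the Ragwitz criterion");
  std::vector<double> emb((size_t)n * d), succ(n);
  for (int p = 0; p < n; ++p) {
    const double* col = REAL(ph) + (size_t)sub_tr[p] * T;
    const int t = sub_t[p];
    for (int m = 0; m < d; ++m) emb[(size_t)p * d + m] = col[t - m * tau];
    succ[p] = col[t + 1];
  }
  std::vector<std::pair<double,int> > dist(n);
  double err = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double dm = 0.0;
      for (int m = 0; m < d; ++m) {
        const double dd = circ_adiff(emb[(size_t)i * d + m], emb[(size_t)j * d + m]);
        if (dd > dm) dm = dd;
      }
      dist[j] = std::make_pair(j == i ? R_PosInf : dm, j);
    }
    std::partial_sort(dist.begin(), dist.begin() + k, dist.end());
    double cs = 0.0, sn = 0.0;
    for (int m = 0; m < k; ++m) {
      cs += std::cos(succ[dist[m].second]);
      sn += std::sin(succ[dist[m].second]);
    }
    const double pred = std::atan2(sn, cs);
    const double e = circ_adiff(pred, succ[i]);
    err += e * e;
  }
  return err / n;
}

// Correlation sums for the C-C embedding method: the series is split into
// tau disjoint subseries; within each, embedding with internal delay 1
// corresponds to delay tau in the original series.  Returns, per radius r,
// the average of C(d, r) - C(1, r)^d over the subseries.
// [[Rcpp::export(name = ".cc_stat_cpp")]]
NumericVector cc_stat_cpp(NumericVector x, int d, int tau, NumericVector rvals) {
  const int T = x.size(), nr = rvals.size();
  NumericVector out(nr);
  int n_used = 0;
  for (int s = 0; s < tau; ++s) {
    // subseries x[s], x[s+tau], ...
    std::vector<double> sub;
    for (int t = s; t < T; t += tau) sub.push_back(x[t]);
    const int M = (int)sub.size() - (d - 1);
    if (M < 2) continue;
    ++n_used;
    std::vector<double> c_d(nr, 0.0), c_1(nr, 0.0);
    const long npairs_d = (long)M * (M - 1) / 2;
    const int M1 = (int)sub.size();
    const long npairs_1 = (long)M1 * (M1 - 1) / 2;
    for (int i = 0; i < M1; ++i)
      for (int j = i + 1; j < M1; ++j) {
        const double dd = circ_adiff(sub[i], sub[j]);
        for (int q = 0; q < nr; ++q) if (dd < rvals[q]) c_1[q] += 1.0;
      }
    for (int i = 0; i < M; ++i)
      for (int j = i + 1; j < M; ++j) {
        double dm = 0.0;
        for (int m = 0; m < d; ++m) {
          const double dd = circ_adiff(sub[i + m], sub[j + m]);
          if (dd > dm) dm = dd;
        }
        for (int q = 0; q < nr; ++q) if (dm < rvals[q]) c_d[q] += 1.0;
      }
    for (int q = 0; q < nr; ++q)
      out[q] += c_d[q] / npairs_d - std::pow(c_1[q] / npairs_1, (double)d);
  }
  if (n_used == 0) stop("series too short for C-C statistic");
  for (int q = 0; q < nr; ++q) out[q] /= n_used;
  return out;
}
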