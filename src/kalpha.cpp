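// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include "circdist.h"
using namespace Rcpp;

// Matrix-based Renyi alpha-order entropy transfer entropy on phases.
// Angles are mapped to the unit circle (cos, sin) per embedding coordinate so
// the Gaussian kernel's Euclidean distance respects phase periodicity; the
// kernel bandwidth is the median pairwise distance of each space's points.

namespace {

// Gram matrix with median-distance bandwidth from an n x d coordinate matrix
arma::mat gram_gauss(const arma::mat& pts) {
  const arma::uword n = pts.n_rows;
  arma::mat D2(n, n, arma::fill::zeros);
  for (arma::uword i = 0; i < n; ++i)
    for (arma::uword j = i + 1; j < n; ++j) {
      const double d2 = arma::accu(arma::square(pts.row(i) - pts.row(j)));
      D2(i, j) = d2; D2(j, i) = d2;
    }
  std::vector<double> dd;
  dd.reserve(n * (n - 1) / 2);
  for (arma::uword i = 0; i < n; ++i)
    for (arma::uword j = i + 1; j < n; ++j) dd.push_back(std::sqrt(D2(i, j)));
  double sigma = 1.0;
  if (!dd.empty()) {
    std::nth_element(dd.begin(), dd.begin() + dd.size() / 2, dd.end());
    sigma = dd[dd.size() / 2];
  }
  if (!(sigma > 0)) sigma = 1.0; // all-identical points: kernel is all ones
  return arma::exp(-D2 / (2.0 * sigma * sigma));
}

// H_alpha of a trace-normalised PSD matrix: log(tr(M^alpha)) / (1 - alpha)
double renyi_H(const arma::mat& C, double alpha) {
  const arma::mat M = C / arma::trace(C);
  double tr_a;
  const double ralpha = std::floor(alpha + 0.5);
  if (std::fabs(alpha - ralpha) < 1e-12 && ralpha >= 2) {
    arma::mat P = M;
    for (int i = 2; i < (int)ralpha; ++i) P = P * M;
    tr_a = arma::accu(P % M); // tr(M^alpha), M symmetric
  } else {
    arma::vec ev;
    if (!arma::eig_sym(ev, M)) stop("eigendecomposition failed");
    ev.clamp(0.0, arma::datum::inf);
    tr_a = arma::accu(arma::pow(ev, alpha));
  }
  if (!R_finite(tr_a) || tr_a <= 0) stop("non-finite Renyi entropy term");
  return std::log(tr_a) / (1.0 - alpha);
}

arma::mat angles_to_circle(const arma::mat& ang) {
  arma::mat out(ang.n_rows, 2 * ang.n_cols);
  for (arma::uword j = 0; j < ang.n_cols; ++j) {
    out.col(2 * j)     = arma::cos(ang.col(j));
    out.col(2 * j + 1) = arma::sin(ang.col(j));
  }
  return out;
}

arma::mat gather_emb(const NumericMatrix& ph, const std::vector<int>& tr,
                     const std::vector<int>& tp, int off, int d, int tau) {
  const int T = ph.nrow(), n = (int)tr.size();
  arma::mat ang(n, d);
  for (int p = 0; p < n; ++p) {
    const double* col = REAL(ph) + (size_t)tr[p] * T;
    for (int m = 0; m < d; ++m) ang(p, m) = col[tp[p] - off - m * tau];
  }
  return ang;
}

// the four-term combination with the Shannon-decomposition sign pattern
double te_terms(const arma::mat& K_yn, const arma::mat& K_yp,
                const arma::mat& K_xp, double alpha,
                double H_yn_yp, double H_yp) {
  const double H_yp_xp    = renyi_H(K_yp % K_xp, alpha);
  const double H_yn_yp_xp = renyi_H((K_yn % K_yp) % K_xp, alpha);
  return H_yp_xp - H_yn_yp_xp + H_yn_yp - H_yp;
}

} // namespace

// Single evaluation from pre-embedded angle matrices.
// [[Rcpp::export(name = ".te_kalpha_cpp")]]
double te_kalpha_cpp(NumericVector ynow, NumericMatrix ypast,
                     NumericMatrix xpast, double alpha) {
  const int n = ynow.size();
  if (ypast.nrow() != n || xpast.nrow() != n) stop("point counts differ");
  arma::mat yn = angles_to_circle(arma::mat(REAL(ynow), n, 1));
  arma::mat yp = angles_to_circle(arma::mat(REAL(ypast), n, ypast.ncol()));
  arma::mat xp = angles_to_circle(arma::mat(REAL(xpast), n, xpast.ncol()));
  const arma::mat K_yn = gram_gauss(yn), K_yp = gram_gauss(yp), K_xp = gram_gauss(xp);
  const double H_yn_yp = renyi_H(K_yn % K_yp, alpha);
  const double H_yp    = renyi_H(K_yp, alpha);
  return te_terms(K_yn, K_yp, K_xp, alpha, H_yn_yp, H_yp);
}

// Differential-TE surrogate scan for the kernel Renyi backend; the
// target-side Gram matrices and entropies of each direction are cached and
// only the lagged-source Gram is rebuilt per surrogate and lag.
// [[Rcpp::export(name = ".dte_scan_surr_kalpha_cpp")]]
List dte_scan_surr_kalpha_cpp(NumericMatrix phX, NumericMatrix phY,
                              int dX, int tauX, int dY, int tauY,
                              IntegerVector lags, IntegerMatrix perms,
                              IntegerVector sub_tr, IntegerVector sub_t,
                              double alpha) {
  const int n = sub_tr.size(), L = lags.size(), S = perms.nrow();
  std::vector<int> tr(n), tp(n);
  for (int p = 0; p < n; ++p) { tr[p] = sub_tr[p]; tp[p] = sub_t[p]; }

  // fixed target-side structures for X -> Y (target Y)
  const arma::mat K_ynY = gram_gauss(angles_to_circle(gather_emb(phY, tr, tp, 0, 1, 1)));
  const arma::mat K_ypY = gram_gauss(angles_to_circle(gather_emb(phY, tr, tp, 1, dY, tauY)));
  const double H_yn_ypY = renyi_H(K_ynY % K_ypY, alpha);
  const double H_ypY    = renyi_H(K_ypY, alpha);

  NumericVector te_xy(L), te_yx(L), dte_surr(S);
  double dte_obs = 0.0;
  std::vector<int> ptr(n);

  for (int s = 0; s <= S; ++s) {
    for (int p = 0; p < n; ++p)
      ptr[p] = (s == 0) ? tr[p] : perms(s - 1, tr[p]);
    // target-side structures for Y -> X (target X under the pairing)
    const arma::mat K_ynX = gram_gauss(angles_to_circle(gather_emb(phX, ptr, tp, 0, 1, 1)));
    const arma::mat K_ypX = gram_gauss(angles_to_circle(gather_emb(phX, ptr, tp, 1, dX, tauX)));
    const double H_yn_ypX = renyi_H(K_ynX % K_ypX, alpha);
    const double H_ypX    = renyi_H(K_ypX, alpha);

    double best_xy = R_NegInf, best_yx = R_NegInf;
    for (int l = 0; l < L; ++l) {
      const int u = lags[l];
      const arma::mat K_xp = gram_gauss(angles_to_circle(gather_emb(phX, ptr, tp, u, dX, tauX)));
      const double txy = te_terms(K_ynY, K_ypY, K_xp, alpha, H_yn_ypY, H_ypY);
      const arma::mat K_yp_src = gram_gauss(angles_to_circle(gather_emb(phY, tr, tp, u, dY, tauY)));
      const double tyx = te_terms(K_ynX, K_ypX, K_yp_src, alpha, H_yn_ypX, H_ypX);
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
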