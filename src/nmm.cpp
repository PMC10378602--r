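#include <Rcpp.h>
using namespace Rcpp;

// Coupled two-region Jansen-Rit-type neural mass model.
//
// Each region holds three populations (pyramidal, excitatory and inhibitory
// interneurons) with second-order synaptic kinetics and a sigmoidal
// rate function.  The presynaptic pyramidal pulse density, delayed by
// `delay_steps` and scaled by gain * omega, enters the other region's
// excitatory input together with the stochastic drive (the v = omega *
// Z(t - delta) + n(t) coupling form).
//
// Integration: fixed-step Euler at dt; the noise matrix is pre-generated on
// the R side so that all randomness flows through R's RNG.

static inline double sigm(double v, double e0, double r, double v0) {
  return 2.0 * e0 / (1.0 + std::exp(r * (v0 - v)));
}

// [[Rcpp::export(name = ".nmm_simulate_cpp")]]
NumericMatrix nmm_simulate_cpp(int n_keep, int n_burn, double dt,
                               double wxy, double wyx, int delay_steps,
                               NumericMatrix noise, List pars) {
  const double A  = as<double>(pars["A"]);
  const double B  = as<double>(pars["B"]);
  const double a  = as<double>(pars["a"]);
  const double b  = as<double>(pars["b"]);
  const double C1 = as<double>(pars["C1"]);
  const double C2 = as<double>(pars["C2"]);
  const double C3 = as<double>(pars["C3"]);
  const double C4 = as<double>(pars["C4"]);
  const double e0 = as<double>(pars["e0"]);
  const double r  = as<double>(pars["r"]);
  const double v0 = as<double>(pars["v0"]);
  const double p_mean = as<double>(pars["p_mean"]);
  const double p_sd   = as<double>(pars["p_sd"]);
  const double gain   = as<double>(pars["gain"]);

  const int n_tot = n_keep + n_burn;
  if (noise.nrow() < n_tot || noise.ncol() < 2)
    stop("noise matrix must be (n_keep + n_burn) x 2");

  // state: per region y0,y1,y2 and derivatives z0,z1,z2
  double y[2][3] = {{0, 0, 0}, {0, 0, 0}};
  double z[2][3] = {{0, 0, 0}, {0, 0, 0}};

  // history of pyramidal pulse densities for the delayed coupling
  const int nd = delay_steps > 0 ? delay_steps : 1;
  std::vector<double> hx(nd, 0.0), hy(nd, 0.0);
  int hpos = 0;

  NumericMatrix out(n_keep, 2);
  const double a2 = a * a, b2 = b * b;

  for (int t = 0; t < n_tot; ++t) {
    const double zx_del = (delay_steps > 0) ? hx[hpos] : sigm(y[0][1] - y[0][2], e0, r, v0);
    const double zy_del = (delay_steps > 0) ? hy[hpos] : sigm(y[1][1] - y[1][2], e0, r, v0);

    for (int i = 0; i < 2; ++i) {
      const double pyr = sigm(y[i][1] - y[i][2], e0, r, v0);
      const double coupling = (i == 0) ? gain * wyx * zy_del
                                       : gain * wxy * zx_del;
      const double p_in = p_mean + p_sd * noise(t, i) + coupling;

      const double d0 = A * a * pyr                          - 2.0 * a * z[i][0] - a2 * y[i][0];
      const double d1 = A * a * (p_in + C2 * sigm(C1 * y[i][0], e0, r, v0))
                                                             - 2.0 * a * z[i][1] - a2 * y[i][1];
      const double d2 = B * b * C4 * sigm(C3 * y[i][0], e0, r, v0)
                                                             - 2.0 * b * z[i][2] - b2 * y[i][2];
      y[i][0] += dt * z[i][0]; z[i][0] += dt * d0;
      y[i][1] += dt * z[i][1]; z[i][1] += dt * d1;
      y[i][2] += dt * z[i][2]; z[i][2] += dt * d2;
    }

    // push current pulse densities into the delay line
    hx[hpos] = sigm(y[0][1] - y[0][2], e0, r, v0);
    hy[hpos] = sigm(y[1][1] - y[1][2], e0, r, v0);
    hpos = (hpos + 1) % nd;

    if (t >= n_burn) {
      out(t - n_burn, 0) = y[0][1] - y[0][2];
      out(t - n_burn, 1) = y[1][1] - y[1][2];
    }
  }

  for (int j = 0; j < 2; ++j)
    for (int i = 0; i < n_keep; ++i)
      if (!R_finite(out(i, j))) stop("neural mass integration diverged (non-finite state)");

  return out;
}
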