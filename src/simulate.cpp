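#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Euler-Maruyama integration of dx = A x dt + sigma dW on n coupled nodes.
// Draws use R's RNG so set.seed() governs reproducibility.
// [[Rcpp::export(name = ".sim_slm_cpp")]]
NumericMatrix sim_slm_cpp(NumericMatrix A, double sigma, double dt,
                          int n_steps, NumericVector x0) {
  const int n = A.nrow();
  NumericMatrix out(n_steps, n);
  double* o = REAL(out);
  std::vector<double> Af(A.begin(), A.end());
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> dx(n);
  const double sq = sigma * std::sqrt(dt);
  for (int t = 0; t < n_steps; ++t) {
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      const double* ai = &Af[(size_t)i * n];
      for (int j = 0; j < n; ++j) acc += ai[j] * x[j];
      dx[i] = acc;
    }
    for (int i = 0; i < n; ++i) {
      x[i] += dt * dx[i] + sq * norm_rand();
      o[(size_t)i * n_steps + t] = x[i];
    }
  }
  return out;
}

static inline double ww_rate(double xi, double a, double b, double d) {
  const double u = a * xi - b;
  if (std::fabs(u) < 1e-9) return 1.0 / d;  // removable singularity
  return u / (1.0 - std::exp(-d * u));
}

// Reduced Wong-Wang mean-field network: synaptic gating S per region,
// dS = (-S/tau_s + (1 - S) * gamma * R(x)) dt + sigma dW, S clipped to [0,1].
// x_i = w*Jn*S_i + Jn*G*sum_j C_ij S_j + I0. Time in ms.
// [[Rcpp::export(name = ".sim_mfm_cpp")]]
NumericMatrix sim_mfm_cpp(NumericMatrix C, double G, double tau_s, double w,
                          double I0, double Jn, double gamma_k, double a,
                          double b, double d, double sigma, double dt_ms,
                          int n_steps, NumericVector S0) {
  const int n = C.nrow();
  NumericMatrix out(n_steps, n);
  double* o = REAL(out);
  // flat column-major copy of the coupling matrix (symmetric, so the
  // column walk below is also a row walk)
  std::vector<double> Cf(C.begin(), C.end());
  std::vector<double> S(S0.begin(), S0.end());
  std::vector<double> input(n);
  const double sq = sigma * std::sqrt(dt_ms);
  for (int t = 0; t < n_steps; ++t) {
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      const double* ci = &Cf[(size_t)i * n];
      for (int j = 0; j < n; ++j) acc += ci[j] * S[j];
      input[i] = w * Jn * S[i] + Jn * G * acc + I0;
    }
    bool ok = true;
    for (int i = 0; i < n; ++i) {
      const double R = ww_rate(input[i], a, b, d);
      // R is in Hz while time steps are in ms: gating term scaled by 1e-3
      const double drift = -S[i] / tau_s +
                           (1.0 - S[i]) * gamma_k * R * 1e-3;
      S[i] += dt_ms * drift + sq * norm_rand();
      if (S[i] < 0.0) S[i] = 0.0;
      if (S[i] > 1.0) S[i] = 1.0;
      ok = ok && std::isfinite(S[i]);
      o[(size_t)i * n_steps + t] = S[i];
    }
    if (!ok) stop("mean-field simulation blew up at step %d", t + 1);
  }
  return out;
}

// Balloon-Windkessel hemodynamics per region, driven by neural input u(t)
// sampled at dt_ms, decimated to one BOLD sample per TR. States start at
// the fixed point for the first drive value, removing the onset transient.
// [[Rcpp::export(name = ".bold_bw_cpp")]]
NumericMatrix bold_bw_cpp(NumericMatrix U, double dt_ms, double kappa,
                          double gamma_f, double tau, double alpha,
                          double rho, double v0, double tr_s) {
  const int n_steps = U.nrow();
  const int n = U.ncol();
  const double dt = dt_ms / 1000.0;
  const int per_tr = (int)std::floor(tr_s / dt + 0.5);
  const int n_out = n_steps / per_tr;
  if (n_out < 1) stop("trajectory shorter than one TR");
  NumericMatrix out(n_out, n);
  const double k1 = 7.0 * rho, k2 = 2.0, k3 = 2.0 * rho - 0.2;
  const double ialpha = 1.0 / alpha;
  for (int r = 0; r < n; ++r) {
    // fixed point for constant drive u0
    const double u0 = U(0, r);
    double s = 0.0;
    double f = 1.0 + u0 / gamma_f;
    double v = std::pow(f, alpha);
    double Ef0 = 1.0 - std::pow(1.0 - rho, 1.0 / f);
    double q = v * Ef0 * f / (rho * std::pow(v, ialpha));
    int k = 0;
    for (int t = 0; t < n_steps; ++t) {
      const double u = U(t, r);
      const double fout = std::pow(v, ialpha);
      const double Ef = 1.0 - std::pow(1.0 - rho, 1.0 / f);
      const double ds = u - kappa * s - gamma_f * (f - 1.0);
      const double df = s;
      const double dv = (f - fout) / tau;
      const double dq = (f * Ef / rho - fout * q / v) / tau;
      s += dt * ds;
      f += dt * df;
      v += dt * dv;
      q += dt * dq;
      if (f < 1e-6) f = 1e-6;
      if (v < 1e-6) v = 1e-6;
      if (q < 1e-6) q = 1e-6;
      if ((t + 1) % per_tr == 0 && k < n_out) {
        out(k, r) = v0 * (k1 * (1.0 - q) + k2 * (1.0 - q / v) +
                          k3 * (1.0 - v));
        ++k;
      }
    }
  }
  return out;
}
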