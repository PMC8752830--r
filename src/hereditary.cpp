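#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trapezoid-rule evaluation of I(t_i) = int_0^{t_i} exp(-(t_i - z)/tau) g(z) dz
// on a uniform grid, via the O(n) recursion
//   I_i = a * I_{i-1} + (dt/2) * (g_i + a * g_{i-1}),   a = exp(-dt/tau).
// Each step is exactly the trapezoid increment, so the recursion reproduces the
// full trapezoid sum (endpoint weights 1/2) up to floating-point roundoff.
// [[Rcpp::export]]
NumericVector exp_trapz_rec(NumericVector g, double dt, double tau) {
  R_xlen_t n = g.size();
  NumericVector out(n);
  if (n == 0) return out;
  double a = std::exp(-dt / tau);
  out[0] = 0.0;
  for (R_xlen_t i = 1; i < n; ++i)
    out[i] = a * out[i - 1] + 0.5 * dt * (g[i] + a * g[i - 1]);
  return out;
}

// Same integral by a direct O(n^2) trapezoidal double loop. Kept as the
// independent oracle route for the production recursion above.
// [[Rcpp::export]]
NumericVector exp_trapz_direct(NumericVector g, double dt, double tau) {
  R_xlen_t n = g.size();
  NumericVector out(n);
  if (n == 0) return out;
  out[0] = 0.0;
  for (R_xlen_t i = 1; i < n; ++i) {
    double ti = (double)i * dt;
    double s = 0.5 * (std::exp(-ti / tau) * g[0] + g[i]);
    for (R_xlen_t j = 1; j < i; ++j)
      s += std::exp(-(ti - (double)j * dt) / tau) * g[j];
    out[i] = s * dt;
  }
  return out;
}

// Residual vector and Jacobian for the bounded Levenberg-Marquardt fit.
// The exponential-kernel recursions (I_n and its tau-sensitivity companion
// K_n, dI/dtau = K/tau^2) run over the FULL acquisition grid, so the model
// operator is identical to the one that generates synthetic data; the
// residual r_i = y_i - scl * conv_i and the Jacobian rows
// J = d r / d (Ge, G_n, tau_n) are evaluated only at the decimated cost
// points `idx` (1-based, strictly increasing). This decouples decimation
// (an SSE weighting / cost-control choice) from quadrature accuracy.
// [[Rcpp::export]]
List gm_resid_jac(NumericVector g, NumericVector y, double scl, double dt,
                  IntegerVector idx, double Ge, NumericVector G,
                  NumericVector tau) {
  R_xlen_t n = g.size(), m = idx.size();
  int N = G.size();
  NumericVector r(m);
  NumericMatrix J(m, 1 + 2 * N);
  double G0 = Ge;
  for (int k = 0; k < N; ++k) G0 += G[k];
  std::vector<double> a(N), I(N, 0.0), K(N, 0.0);
  for (int k = 0; k < N; ++k) a[k] = std::exp(-dt / tau[k]);
  R_xlen_t j = 0;
  for (R_xlen_t i = 0; i < n && j < m; ++i) {
    if (i > 0)
      for (int k = 0; k < N; ++k) {
        K[k] = a[k] * (K[k] + dt * I[k]) + 0.5 * dt * dt * a[k] * g[i - 1];
        I[k] = a[k] * I[k] + 0.5 * dt * (g[i] + a[k] * g[i - 1]);
      }
    if (idx[j] - 1 == i) {
      double conv = G0 * g[i];
      J(j, 0) = -scl * g[i];
      for (int k = 0; k < N; ++k) {
        double tk = tau[k];
        conv -= (G[k] / tk) * I[k];
        J(j, 1 + k) = -scl * (g[i] - I[k] / tk);
        J(j, 1 + N + k) =
            -scl * G[k] * (I[k] / (tk * tk) - K[k] / (tk * tk * tk));
      }
      r[j] = y[j] - scl * conv;
      ++j;
    }
  }
  return List::create(_["r"] = r, _["jac"] = J);
}

// Kelvin-Voigt counterpart: conv_i = Jg F_i + sum (Jn/tau_n) I_n(F); the
// caller folds the 3(1-nu)/(8 sqrt R) normalization into scl.
// [[Rcpp::export]]
List gkv_resid_jac(NumericVector F, NumericVector y, double scl, double dt,
                   IntegerVector idx, double Jg, NumericVector Jn,
                   NumericVector tau) {
  R_xlen_t n = F.size(), m = idx.size();
  int N = Jn.size();
  NumericVector r(m);
  NumericMatrix J(m, 1 + 2 * N);
  std::vector<double> a(N), I(N, 0.0), K(N, 0.0);
  for (int k = 0; k < N; ++k) a[k] = std::exp(-dt / tau[k]);
  R_xlen_t j = 0;
  for (R_xlen_t i = 0; i < n && j < m; ++i) {
    if (i > 0)
      for (int k = 0; k < N; ++k) {
        K[k] = a[k] * (K[k] + dt * I[k]) + 0.5 * dt * dt * a[k] * F[i - 1];
        I[k] = a[k] * I[k] + 0.5 * dt * (F[i] + a[k] * F[i - 1]);
      }
    if (idx[j] - 1 == i) {
      double conv = Jg * F[i];
      J(j, 0) = -scl * F[i];
      for (int k = 0; k < N; ++k) {
        double tk = tau[k];
        conv += (Jn[k] / tk) * I[k];
        J(j, 1 + k) = -scl * I[k] / tk;
        J(j, 1 + N + k) =
            -scl * Jn[k] * (K[k] / (tk * tk * tk) - I[k] / (tk * tk));
      }
      r[j] = y[j] - scl * conv;
      ++j;
    }
  }
  return List::create(_["r"] = r, _["jac"] = J);
}
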