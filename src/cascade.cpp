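#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fixed-step integration of the phototransduction cascade
//
//   dR/dt = gamma * Stim - sigma * R
//   dP/dt = R - phi * P + eta
//   dG/dt = S - P * G,  S = smax / (1 + (C/kgc)^m)
//   dC/dt = q * I - beta * C,  I = k * G^n
//
// The stimulus is a per-sample vector; forward Euler treats it as
// piecewise constant over each step (the reference scheme, and the one the
// analytic inversion mirrors sample-by-sample).

struct CascadePars {
  double gamma, sigma, phi, eta, k, n, m, beta, kgc, smax, q;
};

static inline double synth_rate(double c, const CascadePars &p) {
  return p.smax / (1.0 + std::pow(c / p.kgc, p.m));
}

static inline double current_of(double g, const CascadePars &p) {
  return p.k * std::pow(g, p.n);
}

// [[Rcpp::export(name = ".cascade_euler_cpp")]]
List cascade_euler_cpp(NumericVector stim, double dt,
                       double gamma, double sigma, double phi, double eta,
                       double k, double n, double m, double beta,
                       double kgc, double smax, double q,
                       double r0, double p0, double g0, double c0) {
  CascadePars pp = {gamma, sigma, phi, eta, k, n, m, beta, kgc, smax, q};
  const int N = stim.size();
  NumericVector R(N), P(N), G(N), S(N), C(N), I(N);
  double r = r0, p = p0, g = g0, c = c0;
  for (int i = 0; i < N; ++i) {
    if (!(std::isfinite(r) && std::isfinite(p) &&
          std::isfinite(g) && std::isfinite(c)))
      stop("cascade integration became non-finite at t = %g s (sample %d)",
           i * dt, i + 1);
    R[i] = r; P[i] = p; G[i] = g; C[i] = c;
    double s = synth_rate(c, pp);
    double cur = current_of(g, pp);
    S[i] = s; I[i] = cur;
    double rn = r + dt * (gamma * stim[i] - sigma * r);
    double pn = p + dt * (r - phi * p + eta);
    double gn = g + dt * (s - p * g);
    double cn = c + dt * (q * cur - beta * c);
    r = rn; p = pn; g = gn; c = cn;
  }
  return List::create(_["R"] = R, _["P"] = P, _["G"] = G,
                      _["S"] = S, _["C"] = C, _["I"] = I);
}

// Classical RK4 with the stimulus linearly interpolated between samples.
// [[Rcpp::export(name = ".cascade_rk4_cpp")]]
List cascade_rk4_cpp(NumericVector stim, double dt,
                     double gamma, double sigma, double phi, double eta,
                     double k, double n, double m, double beta,
                     double kgc, double smax, double q,
                     double r0, double p0, double g0, double c0) {
  CascadePars pp = {gamma, sigma, phi, eta, k, n, m, beta, kgc, smax, q};
  const int N = stim.size();
  NumericVector R(N), P(N), G(N), S(N), C(N), I(N);
  double y[4] = {r0, p0, g0, c0};

  auto deriv = [&](const double *u, double s_in, double *du) {
    double syn = synth_rate(u[3], pp);
    double cur = current_of(u[2], pp);
    du[0] = pp.gamma * s_in - pp.sigma * u[0];
    du[1] = u[0] - pp.phi * u[1] + pp.eta;
    du[2] = syn - u[1] * u[2];
    du[3] = pp.q * cur - pp.beta * u[3];
  };

  for (int i = 0; i < N; ++i) {
    if (!(std::isfinite(y[0]) && std::isfinite(y[1]) &&
          std::isfinite(y[2]) && std::isfinite(y[3])))
      stop("cascade integration became non-finite at t = %g s (sample %d)",
           i * dt, i + 1);
    R[i] = y[0]; P[i] = y[1]; G[i] = y[2]; C[i] = y[3];
    S[i] = synth_rate(y[3], pp);
    I[i] = current_of(y[2], pp);
    if (i == N - 1) break;
    double s0 = stim[i];
    double s1 = stim[i + 1];
    double sh = 0.5 * (s0 + s1);
    double k1[4], k2[4], k3[4], k4[4], tmp[4];
    deriv(y, s0, k1);
    for (int j = 0; j < 4; ++j) tmp[j] = y[j] + 0.5 * dt * k1[j];
    deriv(tmp, sh, k2);
    for (int j = 0; j < 4; ++j) tmp[j] = y[j] + 0.5 * dt * k2[j];
    deriv(tmp, sh, k3);
    for (int j = 0; j < 4; ++j) tmp[j] = y[j] + dt * k3[j];
    deriv(tmp, s1, k4);
    for (int j = 0; j < 4; ++j)
      y[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
  }
  return List::create(_["R"] = R, _["P"] = P, _["G"] = G,
                      _["S"] = S, _["C"] = C, _["I"] = I);
}
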