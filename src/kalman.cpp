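#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Exact discretization of dx = A x dt + b u dt + noise(cov Q) over one step.
// Phi = expm(A dt); gam = int_0^dt expm(A s) ds * b  (zero-order-hold input);
// Qd from the Van Loan augmented exponential.
static bool discretize_region(const mat& A, const vec& b, const mat& Q,
                              double dt, mat& Phi, vec& gam, mat& Qd) {
  const uword m = A.n_rows;
  mat Ab(m + 1, m + 1, fill::zeros);
  Ab.submat(0, 0, m - 1, m - 1) = A;
  Ab.submat(0, m, m - 1, m) = b;
  mat E1;
  if (!expmat(E1, Ab * dt)) return false;
  Phi = E1.submat(0, 0, m - 1, m - 1);
  gam = E1.submat(0, m, m - 1, m);

  mat VL(2 * m, 2 * m, fill::zeros);
  VL.submat(0, 0, m - 1, m - 1) = -A;
  VL.submat(0, m, m - 1, 2 * m - 1) = Q;
  VL.submat(m, m, 2 * m - 1, 2 * m - 1) = A.t();
  mat E2;
  if (!expmat(E2, VL * dt)) return false;
  Qd = Phi * E2.submat(0, m, m - 1, 2 * m - 1);
  Qd = 0.5 * (Qd + Qd.t());
  return true;
}

// Marginal log-likelihood of observed series y (T x n) under the discretized
// linear-Gaussian state-space model with diagonal (per-region) dynamics.
// Regions are coupled only to themselves, so the filter factorizes over
// regions: each region runs an independent scalar-observation Kalman filter
// with state dimension 1 (order 1) or 2 (order 2, position + velocity).
// The initial state is the parameter (x0[, xdot0]) with zero covariance.
// Returns -1e12 when the prediction-error decomposition degenerates or
// overflows (e.g. explosive dynamics), so optimizers treat it as very bad
// rather than NaN.
// [[Rcpp::export]]
double ll_lingauss_cpp(int order, const arma::vec& a, const arma::vec& c,
                       const arma::vec& x0, const arma::vec& xdot0,
                       double log_prec_state, double log_prec_obs,
                       double dt, const arma::mat& y, const arma::mat& v) {
  const int n = a.n_elem;
  const int T = y.n_rows;
  const double sig2s = std::exp(-log_prec_state);
  const double R = std::exp(-log_prec_obs);
  const int m = (order == 1) ? 1 : 2;

  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    mat A(m, m, fill::zeros);
    vec b(m, fill::zeros);
    mat Q(m, m, fill::zeros);
    if (order == 1) {
      A(0, 0) = a(i);
      b(0) = c(i);
      Q(0, 0) = sig2s;
    } else {
      A(0, 1) = 1.0;
      A(1, 0) = a(i);
      b(1) = c(i);
      Q(1, 1) = sig2s;
    }
    mat Phi;
    vec gam;
    mat Qd;
    if (!discretize_region(A, b, Q, dt, Phi, gam, Qd)) return -1e12;
    if (!Phi.is_finite() || !Qd.is_finite() || !gam.is_finite()) return -1e12;

    vec xp(m, fill::zeros);
    xp(0) = x0(i);
    if (order == 2) xp(1) = xdot0(i);
    mat P(m, m, fill::zeros);

    for (int t = 0; t < T; ++t) {
      const double S = P(0, 0) + R;
      if (!(S > 0.0) || !std::isfinite(S)) return -1e12;
      const double resid = y(t, i) - xp(0);
      ll += -0.5 * (std::log(2.0 * M_PI * S) + resid * resid / S);
      vec K = P.col(0) / S;
      vec xf = xp + K * resid;
      mat Pf = P - K * trans(P.col(0));
      Pf = 0.5 * (Pf + Pf.t());
      xp = Phi * xf + gam * v(t, i);
      P = Phi * Pf * Phi.t() + Qd;
      if (!xp.is_finite() || !P.is_finite()) return -1e12;
    }
    if (!std::isfinite(ll)) return -1e12;
  }
  return ll;
}
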