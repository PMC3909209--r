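// Linear-Gaussian state-space core for the structural decomposition:
//   y_t = Z_t alpha_t + eps_t,   eps_t ~ N(0, H)
//   alpha_{t+1} = T alpha_t + eta_t,  eta_t ~ N(0, Q)
//   alpha_1 = A delta + b,  delta diffuse (flat prior), b ~ N(a1, P1)
//
// The diffuse vector delta (trend initial value and the constant seasonal
// coefficients) is handled by state augmentation: the filter is run once with
// delta = 0 while propagating, in parallel, the linear impact of each delta
// component on the innovations. The GLS estimate of delta and the diffuse
// (marginal) likelihood fall out of the accumulated cross-products. Missing
// observations (NA) skip the measurement update.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// [[Rcpp::export]]
Rcpp::List ssm_diffuse_filter(const arma::vec& y,
                              const arma::mat& Z,
                              const arma::mat& Tm,
                              const arma::mat& Q,
                              const double H,
                              const arma::mat& A,
                              const arma::mat& P1) {
  const uword n = y.n_elem;
  const uword m = Tm.n_rows;
  const uword d = A.n_cols;

  // M = [a0 | B]: predicted state mean is a0 + B * delta
  mat M(m, d + 1, fill::zeros);
  M.cols(1, d) = A;
  mat P = P1;

  double sumlogF = 0.0, q = 0.0;
  vec s(d, fill::zeros);
  mat S(d, d, fill::zeros);
  uword nobs = 0;
  bool ok = true;

  for (uword t = 0; t < n; ++t) {
    if (std::isfinite(y(t))) {
      rowvec Zt = Z.row(t);
      double F = as_scalar(Zt * P * Zt.t()) + H;
      if (!(F > 0.0) || !std::isfinite(F)) { ok = false; break; }
      rowvec ZM = Zt * M;                 // 1 x (d+1)
      double v0 = y(t) - ZM(0);           // innovation at delta = 0
      rowvec V = ZM.cols(1, d);           // impact of delta on the innovation
      sumlogF += std::log(F);
      q += v0 * v0 / F;
      s += V.t() * (v0 / F);
      S += V.t() * V / F;
      nobs++;
      vec K = Tm * P * Zt.t() / F;        // Kalman gain (one-step form)
      M = Tm * M;
      M.col(0) += K * v0;
      M.cols(1, d) -= K * V;
      P = Tm * P * Tm.t() + Q - K * (F * K.t());
    } else {
      M = Tm * M;
      P = Tm * P * Tm.t() + Q;
    }
    P = 0.5 * (P + P.t());
  }

  double loglik = -datum::inf;
  vec delta(d, fill::zeros);
  bool spd = false;
  if (ok && nobs > d) {
    mat Schol;
    spd = chol(Schol, S);
    if (spd) {
      vec u = solve(trimatl(Schol.t()), s);
      delta = solve(trimatu(Schol), u);
      double logdetS = 2.0 * sum(log(Schol.diag()));
      double rss = q - dot(s, delta);
      loglik = -0.5 * ((double)(nobs - d) * std::log(2.0 * datum::pi)
                       + sumlogF + logdetS + rss);
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("loglik") = loglik,
    Rcpp::Named("delta") = delta,
    Rcpp::Named("S") = S,
    Rcpp::Named("nobs") = (int)nobs,
    Rcpp::Named("ok") = (ok && spd && nobs > d));
}

// Fixed-interval (RTS) smoother with proper initial conditions a1, P1.
// Used after the diffuse pass with a1 = A * delta_hat, P1 = 0.
// [[Rcpp::export]]
Rcpp::List ssm_smooth(const arma::vec& y,
                      const arma::mat& Z,
                      const arma::mat& Tm,
                      const arma::mat& Q,
                      const double H,
                      const arma::vec& a1,
                      const arma::mat& P1) {
  const uword n = y.n_elem;
  const uword m = Tm.n_rows;

  mat a_pred(m, n), a_filt(m, n);
  cube P_pred(m, m, n), P_filt(m, m, n);

  vec a = a1;
  mat P = P1;
  for (uword t = 0; t < n; ++t) {
    a_pred.col(t) = a;
    P_pred.slice(t) = P;
    if (std::isfinite(y(t))) {
      rowvec Zt = Z.row(t);
      double F = as_scalar(Zt * P * Zt.t()) + H;
      if (F > 0.0) {
        double v = y(t) - as_scalar(Zt * a);
        vec PZ = P * Zt.t();
        a = a + PZ * (v / F);
        P = P - PZ * PZ.t() / F;
      }
    }
    a_filt.col(t) = a;
    P_filt.slice(t) = 0.5 * (P + P.t());
    a = Tm * a;
    P = Tm * P * Tm.t() + Q;
    P = 0.5 * (P + P.t());
  }

  // backward recursion
  mat alphahat(m, n);
  alphahat.col(n - 1) = a_filt.col(n - 1);
  for (uword t = n - 1; t-- > 0; ) {
    // J = P_filt T' Ppred_next^+ ; pseudo-inverse keeps deterministic
    // (zero-variance) state directions fixed at their filtered values
    mat J = P_filt.slice(t) * Tm.t() * pinv(P_pred.slice(t + 1));
    alphahat.col(t) = a_filt.col(t)
      + J * (alphahat.col(t + 1) - a_pred.col(t + 1));
  }

  return Rcpp::List::create(
    Rcpp::Named("alphahat") = alphahat.t(),
    Rcpp::Named("a_filt") = a_filt.t());
}
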