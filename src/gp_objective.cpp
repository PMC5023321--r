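// Marginal-likelihood objective for GP hyperparameter optimisation.
// Hot path of mass-univariate fitting: called once per optimiser step per
// location per fold, so the elementwise kernel algebra lives here.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static const double kJitterLadder[] = {1e-10, 1e-9, 1e-8, 1e-7,
                                       1e-6, 1e-5, 1e-4};

// par = c(log lengthScales, log signalVariance, log noiseVariance
//         [, log linearVariance]); D = n x n x d cube of per-covariate
// squared differences; XXt used only when useLinear. Returns the negative
// log marginal likelihood and its gradient in log-parameter space.
// [[Rcpp::export(name = ".gpObjectiveCpp")]]
Rcpp::List gpObjectiveCpp(const arma::vec& par, const arma::cube& D,
                          const arma::mat& XXt, bool useLinear,
                          const arma::vec& y) {
  const uword d = D.n_slices;
  const uword n = y.n_elem;
  const uword npar = par.n_elem;
  vec ell = exp(par.subvec(0, d - 1));
  const double sv = std::exp(par(d));
  const double nv = std::exp(par(d + 1));
  const double lv = useLinear ? std::exp(par(d + 2)) : 0.0;

  mat S(n, n, fill::zeros);
  for (uword k = 0; k < d; ++k) S += D.slice(k) / (ell(k) * ell(k));
  mat Kse = sv * exp(-0.5 * S);
  mat K = Kse;
  if (useLinear) K += lv * XXt;
  K.diag() += nv;

  mat R;
  bool ok = chol(R, K);
  if (!ok) {
    for (double j : kJitterLadder) {
      mat Kj = K;
      Kj.diag() += j;
      if (chol(R, Kj)) { ok = true; break; }
    }
  }
  if (!ok) {
    return Rcpp::List::create(Rcpp::Named("value") = 1e10,
                              Rcpp::Named("gradient") = Rcpp::NumericVector(npar));
  }

  vec alpha = solve(trimatu(R), solve(trimatl(R.t()), y));
  const double lml = -0.5 * dot(y, alpha) - accu(log(R.diag())) -
                     0.5 * n * std::log(2.0 * M_PI);

  mat Rinv = inv(trimatu(R));
  mat Kinv = Rinv * Rinv.t();
  mat A = alpha * alpha.t() - Kinv;

  vec grad(npar, fill::zeros);
  mat AKse = A % Kse;
  for (uword k = 0; k < d; ++k)
    grad(k) = 0.5 * accu(AKse % D.slice(k)) / (ell(k) * ell(k));
  grad(d) = 0.5 * accu(AKse);
  grad(d + 1) = 0.5 * nv * trace(A);
  if (useLinear) grad(d + 2) = 0.5 * lv * accu(A % XXt);

  return Rcpp::List::create(Rcpp::Named("value") = -lml,
                            Rcpp::Named("gradient") = Rcpp::wrap(-grad));
}
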