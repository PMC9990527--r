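// Block-tridiagonal Gaussian inference for the continuous latent chain.
//
// The structured variational posterior over latents x_{1:T} is a Gaussian
// Markov chain with precision blocks J_tt (diagonal) and J_{t,t+1}
// (off-diagonal) and linear term h_t.  This routine computes posterior
// means, marginal covariances, lag-one cross-covariances and log det J
// by block forward elimination / back substitution.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export(name = ".bt_smoother")]]
Rcpp::List bt_smoother(const arma::cube& Jdiag,   // D x D x T
                       const arma::cube& Joff,    // D x D x (T-1), block (t, t+1)
                       const arma::mat& h) {      // D x T
  const uword D = Jdiag.n_rows;
  const uword T = Jdiag.n_slices;

  cube S(D, D, T);        // Schur complements of the forward pass
  mat  g(D, T);           // transformed linear terms
  cube U(D, D, T > 1 ? T - 1 : 1);  // S_t^{-1} J_off_t
  double logdet = 0.0;

  S.slice(0) = Jdiag.slice(0);
  g.col(0) = h.col(0);
  for (uword t = 0; t + 1 < T; ++t) {
    mat St = symmatu(S.slice(t));
    mat L;
    if (!chol(L, St, "lower"))
      Rcpp::stop("latent precision matrix not positive definite at frame %d", (int)(t + 1));
    logdet += 2.0 * accu(log(L.diag()));
    // solve S_t X = [J_off_t, g_t]
    mat rhs = join_rows(Joff.slice(t), g.col(t));
    mat sol = solve(trimatu(L.t()), solve(trimatl(L), rhs));
    U.slice(t) = sol.cols(0, D - 1);
    vec gt = sol.col(D);
    S.slice(t + 1) = Jdiag.slice(t + 1) - Joff.slice(t).t() * U.slice(t);
    g.col(t + 1) = h.col(t + 1) - Joff.slice(t).t() * gt;
  }
  {
    mat L;
    if (!chol(L, symmatu(S.slice(T - 1)), "lower"))
      Rcpp::stop("latent precision matrix not positive definite at frame %d", (int)T);
    logdet += 2.0 * accu(log(L.diag()));
  }

  mat mu(D, T);
  cube Sigma(D, D, T);
  cube Cross(D, D, T > 1 ? T - 1 : 1, fill::zeros);

  Sigma.slice(T - 1) = inv_sympd(symmatu(S.slice(T - 1)));
  mu.col(T - 1) = Sigma.slice(T - 1) * g.col(T - 1);
  for (uword tt = T - 1; tt > 0; --tt) {
    uword t = tt - 1;
    mat Sinv = inv_sympd(symmatu(S.slice(t)));
    mu.col(t) = Sinv * (g.col(t) - Joff.slice(t) * mu.col(t + 1));
    Cross.slice(t) = -U.slice(t) * Sigma.slice(t + 1);   // Cov(x_t, x_{t+1})
    Sigma.slice(t) = symmatu(Sinv + U.slice(t) * Sigma.slice(t + 1) * U.slice(t).t());
  }

  return Rcpp::List::create(Rcpp::Named("mu") = mu,
                            Rcpp::Named("Sigma") = Sigma,
                            Rcpp::Named("Cross") = Cross,
                            Rcpp::Named("logdetJ") = logdet);
}
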