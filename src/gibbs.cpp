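#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// All randomness goes through R's RNG (norm_rand / R::rchisq / R::rgamma),
// so set.seed() on the R side makes every chain exactly reproducible.

static double rnorm_std() { return norm_rand(); }

// Draw from N(Q^{-1} b, Q^{-1}) given precision Q and linear term b.
static arma::vec rmvnorm_prec(const arma::vec& b, const arma::mat& Q,
                              const char* block, const int iter) {
  arma::mat U;
  if (!arma::chol(U, arma::symmatu(Q)))
    stop("Cholesky factorisation failed in the %s update at iteration %d",
         block, iter);
  arma::vec mu = arma::solve(arma::trimatu(U),
                             arma::solve(arma::trimatl(U.t()), b));
  arma::vec z(b.n_elem);
  for (arma::uword k = 0; k < z.n_elem; ++k) z(k) = rnorm_std();
  return mu + arma::solve(arma::trimatu(U), z);
}

// Inverse-Wishart draw with scale S and degrees of freedom df, in the
// parameterisation with prior mean S / (df - m - 1) for df > m + 1.
// Bartlett decomposition of W ~ Wishart(df, S^{-1}); the draw is W^{-1}.
static arma::mat riwish_one(const arma::mat& S, const double df) {
  const int m = S.n_rows;
  if (df <= m - 1)
    stop("inverse-Wishart degrees of freedom must exceed dim - 1");
  arma::mat Sinv = arma::inv_sympd(arma::symmatu(S));
  arma::mat L = arma::chol(Sinv, "lower");
  arma::mat A(m, m, arma::fill::zeros);
  for (int i = 0; i < m; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) A(i, j) = rnorm_std();
  }
  arma::mat LA = L * A;
  return arma::inv_sympd(arma::symmatu(LA * LA.t()));
}

//' @noRd
// [[Rcpp::export(rng = true)]]
arma::mat riwish_cpp(const arma::mat& S, const double df) {
  return riwish_one(S, df);
}

// Gibbs chain for the univariate random-intercept model
//   y_it = x_it' beta + u_i + e_it,  u_i ~ N(0, s2u),  e ~ N(0, s2e)
// with beta ~ N(beta0, diag(B_diag)) and inverse-gamma (shape, rate)
// priors on both variance components.
// [[Rcpp::export(rng = true)]]
List uni_gibbs_chain(const arma::vec& y, const arma::mat& X,
                     const arma::uvec& id, const int n_ind,
                     const arma::vec& beta0, const arma::vec& B_diag,
                     const double a_u, const double b_u,
                     const double a_e, const double b_e,
                     const int n_iter, const int burn_in, const int thin,
                     const arma::vec& beta_init, const double s2u_init,
                     const double s2e_init,
                     const bool fix_s2u, const double s2u_fix,
                     const bool fix_s2e, const double s2e_fix) {
  const int n = y.n_elem, P = X.n_cols;
  const int S = (n_iter - burn_in) / thin;
  arma::vec beta = beta_init;
  arma::vec u(n_ind, arma::fill::zeros);
  double s2u = fix_s2u ? s2u_fix : s2u_init;
  double s2e = fix_s2e ? s2e_fix : s2e_init;

  arma::vec Tcount(n_ind, arma::fill::zeros);
  for (int r = 0; r < n; ++r) Tcount(id(r)) += 1.0;
  const arma::mat Sxx = X.t() * X;

  arma::mat beta_draws(S, P), u_draws(S, n_ind);
  arma::vec s2u_draws(S), s2e_draws(S);

  int kept = 0;
  for (int it = 1; it <= n_iter; ++it) {
    // beta | u, s2e
    arma::mat Q = Sxx / s2e;
    Q.diag() += 1.0 / B_diag;
    arma::vec b = beta0 / B_diag + X.t() * (y - u.elem(id)) / s2e;
    beta = rmvnorm_prec(b, Q, "fixed-effect", it);

    // u_i | beta, s2u, s2e
    arma::vec resid = y - X * beta;
    arma::vec rsum(n_ind, arma::fill::zeros);
    for (int r = 0; r < n; ++r) rsum(id(r)) += resid(r);
    for (int i = 0; i < n_ind; ++i) {
      double prec = 1.0 / s2u + Tcount(i) / s2e;
      double mean = (rsum(i) / s2e) / prec;
      u(i) = mean + rnorm_std() / std::sqrt(prec);
    }

    // s2u | u  ~  IG(a_u + N/2, b_u + sum(u^2)/2)
    if (!fix_s2u) {
      double rate = b_u + 0.5 * arma::dot(u, u);
      s2u = rate / R::rgamma(a_u + 0.5 * n_ind, 1.0);
      if (!std::isfinite(s2u) || s2u <= 0.0)
        stop("divergent random-intercept variance draw at iteration %d; "
             "consider rescaling the response", it);
    }

    // s2e | beta, u  ~  IG(a_e + n/2, b_e + sum(e^2)/2)
    arma::vec e = resid - u.elem(id);
    if (!fix_s2e) {
      double rate = b_e + 0.5 * arma::dot(e, e);
      s2e = rate / R::rgamma(a_e + 0.5 * n, 1.0);
      if (!std::isfinite(s2e) || s2e <= 0.0)
        stop("divergent residual variance draw at iteration %d; "
             "consider rescaling the response", it);
    }

    if (it > burn_in && (it - burn_in) % thin == 0) {
      beta_draws.row(kept) = beta.t();
      u_draws.row(kept) = u.t();
      s2u_draws(kept) = s2u;
      s2e_draws(kept) = s2e;
      ++kept;
    }
  }

  return List::create(_["beta"] = beta_draws, _["u"] = u_draws,
                      _["sigma2_u"] = s2u_draws, _["sigma2_e"] = s2e_draws);
}

// Gibbs chain for the multivariate model
//   y_it = beta' x_it + u_i + e_it,  u_i ~ N_M(0, G),  e_it ~ N_M(0, R)
// with vec(beta) ~ N(vec(beta0), diag(B_diag)) (column-stacked vec: the
// coefficients of metabolite 1 first), G ~ IW(Sigma2, nu),
// R ~ IW(SigmaEps2, nu).  The fix_* switches clamp a block at its initial
// value, which turns individual conditionals into testable exact draws.
// [[Rcpp::export(rng = true)]]
List mv_gibbs_chain(const arma::mat& Y, const arma::mat& X,
                    const arma::uvec& id, const int n_ind,
                    const arma::mat& beta0, const arma::vec& B_diag,
                    const arma::mat& Sigma2, const arma::mat& SigmaEps2,
                    const double nu,
                    const int n_iter, const int burn_in, const int thin,
                    const arma::mat& beta_init, const arma::mat& u_init,
                    const arma::mat& G_init, const arma::mat& R_init,
                    const bool fix_beta, const bool fix_u,
                    const bool fix_G, const bool fix_R) {
  const int n = Y.n_rows, M = Y.n_cols, P = X.n_cols;
  const int S = (n_iter - burn_in) / thin;
  if (!Y.is_finite()) stop("non-finite response values reached the sampler; "
                           "filter incomplete rows upstream");

  arma::mat beta = beta_init, u = u_init, G = G_init, Rm = R_init;
  arma::vec Tcount(n_ind, arma::fill::zeros);
  for (int r = 0; r < n; ++r) Tcount(id(r)) += 1.0;
  const arma::mat Sxx = X.t() * X;
  const arma::vec b0vec = arma::vectorise(beta0);

  arma::cube beta_draws(P, M, S), u_draws(n_ind, M, S);
  arma::cube G_draws(M, M, S), R_draws(M, M, S);

  int kept = 0;
  for (int it = 1; it <= n_iter; ++it) {
    arma::mat Rinv;
    if (!arma::inv_sympd(Rinv, arma::symmatu(Rm)))
      stop("Cholesky factorisation failed in the residual-covariance "
           "inverse at iteration %d", it);

    // vec(beta) | u, R: precision B^-1 + R^-1 (x) X'X
    if (!fix_beta) {
      arma::mat Q = arma::kron(Rinv, Sxx);
      Q.diag() += 1.0 / B_diag;
      arma::mat bmat = X.t() * (Y - u.rows(id)) * Rinv;
      arma::vec b = b0vec / B_diag + arma::vectorise(bmat);
      arma::vec v = rmvnorm_prec(b, Q, "fixed-effect", it);
      beta = arma::reshape(v, P, M);
    }

    // u_i | beta, G, R: precision G^-1 + T_i R^-1
    if (!fix_u) {
      arma::mat Ginv;
      if (!arma::inv_sympd(Ginv, arma::symmatu(G)))
        stop("Cholesky factorisation failed in the random-effect "
             "covariance inverse at iteration %d", it);
      arma::mat E0 = Y - X * beta;
      arma::mat rsum(n_ind, M, arma::fill::zeros);
      for (int r = 0; r < n; ++r) rsum.row(id(r)) += E0.row(r);
      for (int i = 0; i < n_ind; ++i) {
        arma::mat Qi = Ginv + Tcount(i) * Rinv;
        arma::vec bi = Rinv * rsum.row(i).t();
        u.row(i) = rmvnorm_prec(bi, Qi, "random-effect", it).t();
      }
    }

    // G | u: IW(Sigma2 + sum_i u_i u_i', nu + N)
    if (!fix_G) G = riwish_one(Sigma2 + u.t() * u, nu + n_ind);

    // R | beta, u: IW(SigmaEps2 + sum_rows e e', nu + n)
    if (!fix_R) {
      arma::mat E = Y - X * beta - u.rows(id);
      Rm = riwish_one(SigmaEps2 + E.t() * E, nu + n);
    }

    if (it > burn_in && (it - burn_in) % thin == 0) {
      beta_draws.slice(kept) = beta;
      u_draws.slice(kept) = u;
      G_draws.slice(kept) = G;
      R_draws.slice(kept) = Rm;
      ++kept;
    }
  }

  return List::create(_["beta"] = beta_draws, _["u"] = u_draws,
                      _["G"] = G_draws, _["R"] = R_draws);
}
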