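// Gibbs sampler for the Bayesian multi-trait GBLUP model
//
//   y_t = 1 b_t + g_t + e_t,  g ~ N(0, Sigma_g (x) G),  e ~ N(0, Sigma_e (x) I)
//
// The sampler works in the eigenbasis of G (G = U D U').  Writing starred
// quantities for U'-transformed vectors, the model decouples over eigen
// index i: y*_i = u1_i b + g*_i + e*_i with g*_i ~ N(0, d_i Sigma_g) and
// e*_i ~ N(0, Sigma_e), so the full conditional of g* factorises into n
// independent t-dimensional normals.  Full conditionals:
//   b      ~ N( colMeans over i of u1_i (y*_i - g*_i) / c, Sigma_e / c ),
//            c = sum u1_i^2 = n, flat prior
//   g*_i   ~ N( P_i^{-1} Sigma_e^{-1} r_i, P_i^{-1} ),
//            P_i = Sigma_e^{-1} + Sigma_g^{-1} / d_i, r_i = y*_i - u1_i b
//   Sigma_g ~ IW( nu_g + n, S_g + sum_i g*_i g*_i' / d_i )
//   Sigma_e ~ IW( nu_e + n, S_e + sum_i e*_i e*_i' )
//
// All randomness is drawn from R's RNG so runs are reproducible via set.seed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat rnorm_mat(int r, int c) {
  mat out(r, c);
  for (int j = 0; j < c; ++j)
    for (int i = 0; i < r; ++i) out(i, j) = R::norm_rand();
  return out;
}

// Draw from Wishart(df, V) via the Bartlett decomposition (V = LL').
static mat rwishart(double df, const mat& V) {
  const int t = V.n_rows;
  mat L = chol(V, "lower");
  mat A(t, t, fill::zeros);
  for (int i = 0; i < t; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  }
  mat LA = L * A;
  return LA * LA.t();
}

// Sigma ~ IW(df, S)  <=>  Sigma^{-1} ~ Wishart(df, S^{-1})
static mat riwishart(double df, const mat& S) {
  mat W = rwishart(df, inv_sympd(symmatu(S)));
  return inv_sympd(symmatu(W));
}

// [[Rcpp::export(name = ".gibbs_mtgblup")]]
Rcpp::List gibbs_mtgblup(const arma::mat& ystar,   // n x t, U'y
                         const arma::vec& u1,      // n, U'1
                         const arma::vec& d,       // n eigenvalues (jittered)
                         const arma::mat& Sg0,     // t x t IW scale, genetic
                         const arma::mat& Se0,     // residual
                         double nu_g, double nu_e,
                         int n_burnin, int n_iter, int thin) {
  const int n = ystar.n_rows, t = ystar.n_cols;
  const int n_keep = n_iter / thin;
  const double c_b = accu(square(u1));

  // state
  mat Sg = Sg0 / std::max(nu_g - t - 1.0, 1.0);  // prior-mean-ish start
  mat Se = Se0 / std::max(nu_e - t - 1.0, 1.0);
  Sg = symmatu(Sg) + 1e-8 * eye(t, t);
  Se = symmatu(Se) + 1e-8 * eye(t, t);
  rowvec b(t, fill::zeros);
  mat gstar(n, t, fill::zeros);

  // accumulators
  mat gstar_sum(n, t, fill::zeros);
  rowvec b_sum(t, fill::zeros);
  cube Sg_draws(t, t, n_keep), Se_draws(t, t, n_keep);

  const int total = n_burnin + n_iter;
  int kept = 0;
  vec invd = 1.0 / d;

  for (int it = 1; it <= total; ++it) {
    mat Se_inv = inv_sympd(symmatu(Se));
    mat Sg_inv = inv_sympd(symmatu(Sg));

    // --- b | rest (flat prior)
    rowvec num(t, fill::zeros);
    for (int i = 0; i < n; ++i) num += u1(i) * (ystar.row(i) - gstar.row(i));
    rowvec b_mean = num / c_b;
    mat Lb = chol(symmatu(Se) / c_b, "lower");
    b = b_mean + (Lb * rnorm_mat(t, 1)).t();

    // --- g* | rest, independent across eigen index
    mat scat_g(t, t, fill::zeros);
    for (int i = 0; i < n; ++i) {
      mat P = Se_inv + Sg_inv * invd(i);
      mat Pinv = inv_sympd(symmatu(P));
      vec r = (ystar.row(i) - u1(i) * b).t();
      vec mu = Pinv * (Se_inv * r);
      mat Lg = chol(symmatu(Pinv), "lower");
      vec gi = mu + Lg * rnorm_mat(t, 1);
      gstar.row(i) = gi.t();
      scat_g += (gi * gi.t()) * invd(i);
    }

    // --- Sigma_g | g*
    Sg = riwishart(nu_g + n, symmatu(Sg0 + scat_g));

    // --- Sigma_e | residuals
    mat resid = ystar - u1 * b - gstar;
    Se = riwishart(nu_e + n, symmatu(Se0 + resid.t() * resid));

    if (!Sg.is_finite() || !Se.is_finite() || !gstar.is_finite())
      Rcpp::stop("divergent draw (non-finite state) at iteration %d", it);

    if (it > n_burnin && (it - n_burnin) % thin == 0) {
      Sg_draws.slice(kept) = Sg;
      Se_draws.slice(kept) = Se;
      gstar_sum += gstar;
      b_sum += b;
      ++kept;
    }
    if (it % 5000 == 0) Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(
    Rcpp::Named("gstar_mean") = gstar_sum / std::max(kept, 1),
    Rcpp::Named("b_mean") = b_sum / std::max(kept, 1),
    Rcpp::Named("sigma_g_draws") = Sg_draws,
    Rcpp::Named("sigma_e_draws") = Se_draws,
    Rcpp::Named("n_kept") = kept);
}
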