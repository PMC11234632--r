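// Gibbs sampler for the BayesGC model:
//   y = mu + g + sum_j I_j X_j b_j + e
//   g ~ N(0, G sigma2_g) via its spectral basis, e ~ N(0, diag(1/w) sigma2_e),
//   P(I_j = 1) = pi, b_j ~ N(0, effect_var).
// Variance components are fixed; (I_j, b_j) are sampled jointly with b
// integrated out of the inclusion odds. Uses R's RNG stream so chains are
// reproducible under set.seed().
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export(name = ".bayesgc_chain")]]
Rcpp::List bayesgc_chain(const arma::vec& y,
                         const arma::mat& X,        // train x m, centred
                         const arma::vec& w,        // residual weights
                         const arma::mat& U,        // train x k spectral basis of G_tt
                         const arma::vec& S,        // k positive eigenvalues
                         const arma::mat& Ra,       // upper chol of Prec_a (k x k)
                         const arma::mat& Bv,       // pred x k: G_vt U S^-1
                         const arma::mat& Xpred,    // pred x m, centred
                         double sigma2_g, double sigma2_e,
                         double effect_var, double pi,
                         int cycles, int burnin)
{
  const uword n = y.n_elem, m = X.n_cols, k = S.n_elem, np = Xpred.n_rows;
  (void)sigma2_g; // enters through Ra and effect_var, kept for the interface

  mat Xw = X.each_col() % w;          // column j = w .* X_j
  vec cxx = sum(X % Xw, 0).t();       // sum w X_j^2
  const double log_prior_odds = std::log(pi) - std::log1p(-pi);
  const double sum_w = accu(w);

  vec b(m, fill::zeros);
  uvec incl(m, fill::zeros);
  vec a(k, fill::zeros);
  vec g = U * a;
  double mu = 0.0;
  vec r = y;                           // y - mu - g - X b

  vec sum_gebv_t(n, fill::zeros), sum_gebv_p(np, fill::zeros);
  vec sum_pip(m, fill::zeros), sum_b(m, fill::zeros);
  vec n_incl_trace(cycles, fill::zeros);
  double sum_mu = 0.0;
  int n_save = 0;

  uvec order = regspace<uvec>(0, m - 1);

  for (int cyc = 0; cyc < cycles; ++cyc) {
    // --- overall mean ---
    r += mu;
    double mu_mean = dot(w, r) / sum_w;
    mu = mu_mean + std::sqrt(sigma2_e / sum_w) * norm_rand();
    r -= mu;

    // --- SNP effects, random order (Fisher-Yates on R's stream) ---
    for (uword i = m - 1; i > 0; --i) {
      uword jj = (uword)(unif_rand() * (i + 1));
      if (jj > i) jj = i;
      std::swap(order[i], order[jj]);
    }
    for (uword t = 0; t < m; ++t) {
      const uword j = order[t];
      if (incl[j]) r += X.col(j) * b[j];
      const double rhs = dot(Xw.col(j), r);
      const double post_var = 1.0 / (cxx[j] / sigma2_e + 1.0 / effect_var);
      const double post_mean = post_var * rhs / sigma2_e;
      const double log_bf = 0.5 * std::log(post_var / effect_var) +
        0.5 * post_mean * post_mean / post_var;
      const double logit = log_bf + log_prior_odds;
      const double p_incl = 1.0 / (1.0 + std::exp(-logit));
      if (unif_rand() < p_incl) {
        incl[j] = 1;
        b[j] = post_mean + std::sqrt(post_var) * norm_rand();
        r -= X.col(j) * b[j];
      } else {
        incl[j] = 0;
        b[j] = 0.0;
      }
    }

    // --- polygenic term in its spectral basis ---
    r += g;
    vec rhs_a = U.t() * (w % r) / sigma2_e;
    vec mean_a = solve(trimatu(Ra), solve(trimatl(Ra.t()), rhs_a));
    vec z(k);
    for (uword i = 0; i < k; ++i) z[i] = norm_rand();
    a = mean_a + solve(trimatu(Ra), z);
    g = U * a;
    r -= g;

    if (!r.is_finite()) Rcpp::stop("divergent chain state at cycle %d", cyc + 1);

    n_incl_trace[cyc] = (double)accu(incl);

    if (cyc >= burnin) {
      // genetic value = g + X b = y - mu - r on the training animals
      sum_gebv_t += (y - mu - r);
      if (np > 0) {
        vec gp = Bv * a;
        uvec on = find(incl == 1);
        if (on.n_elem > 0) gp += Xpred.cols(on) * b.elem(on);
        sum_gebv_p += gp;
      }
      sum_pip += conv_to<vec>::from(incl);
      sum_b += b;
      sum_mu += mu;
      ++n_save;
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("gebv_train") = sum_gebv_t / n_save,
    Rcpp::Named("gebv_pred") = sum_gebv_p / std::max(n_save, 1),
    Rcpp::Named("pip") = sum_pip / n_save,
    Rcpp::Named("effects") = sum_b / n_save,
    Rcpp::Named("mu") = sum_mu / n_save,
    Rcpp::Named("n_incl_trace") = n_incl_trace);
}
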