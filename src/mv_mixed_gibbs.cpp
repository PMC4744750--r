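#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Symmetric inverse with a ridge fallback for numerically non-PD matrices.
// Jitter events are counted so the caller can log them.
static arma::mat safe_inv_sympd(const arma::mat &S, int &n_jitter) {
  arma::mat Si;
  arma::mat Ssym = arma::symmatu(S);
  if (arma::inv_sympd(Si, Ssym)) return Si;
  double eps = 1e-8 * (arma::trace(Ssym) / Ssym.n_rows + 1.0);
  arma::mat J = Ssym + eps * arma::eye(Ssym.n_rows, Ssym.n_cols);
  ++n_jitter;
  if (arma::inv_sympd(Si, J)) return Si;
  return arma::pinv(J);
}

// Draw from an inverse-Wishart with df degrees of freedom and scale matrix S
// (density \propto |Sigma|^{-(df+p+1)/2} exp(-tr(S Sigma^{-1})/2)), via the
// Bartlett decomposition of a Wishart(df, S^{-1}) draw. Uses R's RNG so
// results are reproducible under set.seed().
static arma::mat rinvwishart(double df, const arma::mat &S, int &n_jitter) {
  const unsigned int p = S.n_rows;
  arma::mat Sinv = safe_inv_sympd(S, n_jitter);
  arma::mat L;
  if (!arma::chol(L, arma::symmatu(Sinv), "lower")) {
    double eps = 1e-8 * (arma::trace(Sinv) / p + 1.0);
    ++n_jitter;
    L = arma::chol(arma::symmatu(Sinv) + eps * arma::eye(p, p), "lower");
  }
  arma::mat A(p, p, arma::fill::zeros);
  for (unsigned int i = 0; i < p; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (unsigned int j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  }
  arma::mat LA = L * A;
  arma::mat W = LA * LA.t();
  return safe_inv_sympd(W, n_jitter);
}

// Gibbs sampler for a p-variate Gaussian mixed model with intercept-only
// fixed effects and J crossed random grouping factors:
//   y_i = mu + sum_j u_{j, f_j(i)} + e_i,
//   u_{j,g} ~ N_p(0, Sigma_j),  e_i ~ N_p(0, Sigma_res),
// flat prior on mu, inverse-Wishart(scale = nu*V, df = nu) on every Sigma.
// All full conditionals are conjugate; no Metropolis steps.
//
// Y:       n x p response matrix
// groups:  list of J integer vectors (0-based level codes, length n)
// V, nu:   prior scale matrix (p x p) and degree of belief
// n_iter, burn_in, thin: chain control; retained draws are those after
//   burn_in at stride thin.
// [[Rcpp::export]]
List mv_mixed_gibbs_cpp(const arma::mat &Y, const List &groups,
                        const arma::mat &V, double nu,
                        int n_iter, int burn_in, int thin) {
  const unsigned int n = Y.n_rows, p = Y.n_cols;
  const int J = groups.size();
  if (thin < 1) stop("thin must be >= 1");
  if (burn_in < 0 || burn_in >= n_iter) stop("burn_in must be in [0, n_iter)");

  std::vector<arma::uvec> fac(J);
  std::vector<unsigned int> G(J);
  std::vector<std::vector<arma::uvec>> level_rows(J);
  for (int j = 0; j < J; ++j) {
    IntegerVector f = groups[j];
    if ((unsigned int)f.size() != n) stop("grouping factor length mismatch");
    arma::uvec fj(n);
    for (unsigned int i = 0; i < n; ++i) fj(i) = (unsigned int)f[i];
    fac[j] = fj;
    G[j] = fj.max() + 1;
    level_rows[j].resize(G[j]);
    for (unsigned int g = 0; g < G[j]; ++g)
      level_rows[j][g] = arma::find(fj == g);
  }

  arma::rowvec mu = arma::mean(Y, 0);
  std::vector<arma::mat> U(J);
  std::vector<arma::mat> Sig(J);
  for (int j = 0; j < J; ++j) {
    U[j] = arma::mat(G[j], p, arma::fill::zeros);
    Sig[j] = arma::eye(p, p);
  }
  arma::mat SigR = arma::eye(p, p);
  arma::mat Vp = nu * V;
  int n_jitter = 0;

  const int n_keep = (n_iter - burn_in) / thin;
  arma::mat mu_draws(n_keep, p);
  std::vector<arma::cube> sig_draws(J);
  for (int j = 0; j < J; ++j) sig_draws[j] = arma::cube(p, p, n_keep);
  arma::cube sigres_draws(p, p, n_keep);

  int keep = 0;
  for (int it = 1; it <= n_iter; ++it) {
    // random-effect rows summed over all terms
    arma::mat RE(n, p, arma::fill::zeros);
    for (int j = 0; j < J; ++j) RE += U[j].rows(fac[j]);

    arma::mat Wres = safe_inv_sympd(SigR, n_jitter);

    // update each random-effect term
    for (int j = 0; j < J; ++j) {
      arma::mat Wj = safe_inv_sympd(Sig[j], n_jitter);
      for (unsigned int g = 0; g < G[j]; ++g) {
        const arma::uvec &rg = level_rows[j][g];
        const unsigned int ng = rg.n_elem;
        if (ng == 0) {
          // unobserved level: draw from the prior for that term
          arma::vec z(p);
          for (unsigned int k = 0; k < p; ++k) z(k) = R::norm_rand();
          arma::mat Lj = arma::chol(arma::symmatu(Sig[j]), "lower");
          U[j].row(g) = (Lj * z).t();
          continue;
        }
        arma::rowvec s(p, arma::fill::zeros);
        for (unsigned int r = 0; r < ng; ++r) {
          const unsigned int i = rg(r);
          s += Y.row(i) - mu - (RE.row(i) - U[j].row(g));
        }
        arma::mat P = (double)ng * Wres + Wj;       // full-conditional precision
        arma::vec m = arma::solve(arma::symmatu(P), (Wres * s.t()));
        arma::mat Ru;
        if (!arma::chol(Ru, arma::symmatu(P), "upper")) {
          double eps = 1e-8 * (arma::trace(P) / p + 1.0);
          ++n_jitter;
          Ru = arma::chol(arma::symmatu(P) + eps * arma::eye(p, p), "upper");
        }
        arma::vec z(p);
        for (unsigned int k = 0; k < p; ++k) z(k) = R::norm_rand();
        arma::vec unew = m + arma::solve(arma::trimatu(Ru), z);
        arma::rowvec delta = unew.t() - U[j].row(g);
        for (unsigned int r = 0; r < ng; ++r) RE.row(rg(r)) += delta;
        U[j].row(g) = unew.t();
      }
    }

    // fixed means (flat prior)
    arma::mat Rmu = Y - RE;
    arma::rowvec rbar = arma::mean(Rmu, 0);
    arma::mat Lr = arma::chol(arma::symmatu(SigR) / (double)n, "lower");
    arma::vec z(p);
    for (unsigned int k = 0; k < p; ++k) z(k) = R::norm_rand();
    mu = rbar + (Lr * z).t();

    // covariance matrices
    for (int j = 0; j < J; ++j)
      Sig[j] = rinvwishart(nu + (double)G[j], Vp + U[j].t() * U[j], n_jitter);
    arma::mat E = Y - arma::repmat(mu, n, 1) - RE;
    SigR = rinvwishart(nu + (double)n, Vp + E.t() * E, n_jitter);

    if (it > burn_in && (it - burn_in) % thin == 0 && keep < n_keep) {
      mu_draws.row(keep) = mu;
      for (int j = 0; j < J; ++j) sig_draws[j].slice(keep) = Sig[j];
      sigres_draws.slice(keep) = SigR;
      ++keep;
    }
  }

  List sigs(J);
  for (int j = 0; j < J; ++j) sigs[j] = sig_draws[j];
  return List::create(_["mu"] = mu_draws,
                      _["sigma_terms"] = sigs,
                      _["sigma_res"] = sigres_draws,
                      _["n_jitter"] = n_jitter,
                      _["n_keep"] = keep);
}
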