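#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Coordinate-descent graphical lasso (block coordinate descent on the
// covariance estimate W, lasso subproblem per column), with warm starts
// along a decreasing lambda path. Only off-diagonal precision entries
// are penalized, so diag(W) stays equal to diag(S) throughout. Problem
// sizes here are small (p ~ 7), so the inner loops use plain index
// arithmetic rather than submatrix views.

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// one glasso solve at penalty lam, warm-started from (W, Beta);
// returns sweeps used, or maxit + 1 when not converged
static int glasso_one(const arma::mat& S, double lam, arma::mat& W,
                      arma::mat& Beta, double thr, int maxit,
                      double inner_tol, int inner_maxit) {
  const int p = S.n_rows;
  double off_mean = 0.0;
  int cnt = 0;
  for (int i = 0; i < p; ++i)
    for (int j = i + 1; j < p; ++j) { off_mean += std::fabs(S(i, j)); ++cnt; }
  off_mean = (cnt > 0) ? off_mean / cnt : 0.0;
  const double t_outer = thr * std::max(off_mean, 1e-12);

  std::vector<int> idx(p - 1);
  std::vector<double> beta(p - 1);
  bool conv = false;
  int it = 0;
  for (it = 0; it < maxit; ++it) {
    double dmax = 0.0;
    for (int j = 0; j < p; ++j) {
      int q = 0;
      for (int i = 0; i < p; ++i) if (i != j) idx[q++] = i;
      for (int k = 0; k < p - 1; ++k) beta[k] = Beta(idx[k], j);
      // lasso subproblem: min (1/2) b' W11 b - s12' b + lam ||b||_1
      for (int in_it = 0; in_it < inner_maxit; ++in_it) {
        double dm = 0.0;
        for (int k = 0; k < p - 1; ++k) {
          const int row = idx[k];
          const double old = beta[k];
          double r = S(row, j);
          for (int l = 0; l < p - 1; ++l)
            if (l != k) r -= W(row, idx[l]) * beta[l];
          const double nb = soft(r, lam) / W(row, row);
          if (nb != old) {
            beta[k] = nb;
            const double d = std::fabs(nb - old);
            if (d > dm) dm = d;
          }
        }
        if (dm < inner_tol) break;
      }
      // w12 = W11 beta; write back
      for (int k = 0; k < p - 1; ++k) {
        const int row = idx[k];
        double v = 0.0;
        for (int l = 0; l < p - 1; ++l) v += W(row, idx[l]) * beta[l];
        const double d = std::fabs(W(row, j) - v);
        if (d > dmax) dmax = d;
        W(row, j) = v;
        W(j, row) = v;
        Beta(row, j) = beta[k];
      }
    }
    if (dmax < t_outer) { conv = true; ++it; break; }
  }
  return conv ? it : maxit + 1;   // maxit + 1 flags non-convergence
}

// recover the precision matrix from (W, Beta), symmetrized
static void recover_theta(const arma::mat& W, const arma::mat& Beta,
                          arma::mat& K) {
  const int p = W.n_rows;
  K.zeros();
  for (int j = 0; j < p; ++j) {
    double dot = 0.0;
    for (int i = 0; i < p; ++i)
      if (i != j) dot += W(i, j) * Beta(i, j);
    const double kjj = 1.0 / (W(j, j) - dot);
    K(j, j) = kjj;
    for (int i = 0; i < p; ++i)
      if (i != j) K(i, j) = -Beta(i, j) * kjj;
  }
  for (int i = 0; i < p; ++i)
    for (int j = i + 1; j < p; ++j) {
      const double v = 0.5 * (K(i, j) + K(j, i));
      K(i, j) = v;
      K(j, i) = v;
    }
}

// [[Rcpp::export]]
List glasso_path_cpp(const arma::mat& S, const arma::vec& lambdas,
                     double n, double gamma,
                     double thr = 1e-7, int maxit = 500,
                     double inner_tol = 1e-9, int inner_maxit = 2000,
                     double zero_tol = 1e-8) {
  const int p = S.n_rows;
  const int nl = lambdas.n_elem;
  arma::cube K(p, p, nl);
  arma::vec loglik(nl), ebic(nl);
  arma::ivec edges(nl), iters(nl);

  arma::mat W = S;                       // unpenalized diagonal: W_jj = S_jj
  arma::mat Beta(p, p, arma::fill::zeros);
  arma::mat Km(p, p);
  const double logp = std::log((double) p);

  for (int m = 0; m < nl; ++m) {
    iters(m) = glasso_one(S, lambdas(m), W, Beta, thr, maxit,
                          inner_tol, inner_maxit);
    recover_theta(W, Beta, Km);
    // exact-zero cleanup for support reporting
    int E = 0;
    for (int i = 0; i < p; ++i)
      for (int j = i + 1; j < p; ++j) {
        if (std::fabs(Km(i, j)) < zero_tol) { Km(i, j) = 0.0; Km(j, i) = 0.0; }
        else ++E;
      }
    double ld, sign;
    arma::log_det(ld, sign, Km);
    const double ll = 0.5 * n * (ld - arma::accu(S % Km));
    K.slice(m) = Km;
    loglik(m) = ll;
    edges(m) = E;
    ebic(m) = -2.0 * ll + E * std::log(n) + 4.0 * gamma * E * logp;
  }

  return List::create(_["K"] = K, _["loglik"] = loglik, _["ebic"] = ebic,
                      _["edges"] = edges, _["iters"] = iters);
}
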