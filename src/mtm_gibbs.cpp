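// Gibbs sampler for the multi-trait genomic model
//   Y = 1 M' + A + R,  A ~ MN(0, G, Sigma_A),  rows of R ~ N(0, Sigma_R),
// with Sigma_R diagonal. G is eigendecomposed once (G = U D U'); in the
// rotated basis the rows of A* = U'A are conditionally independent, so one
// sweep costs O(n r^3) plus two n x n GEMMs. Missing cells are handled by
// data augmentation. All randomness comes from R's RNG, so chains are
// bit-identical for a given seed.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat rwishart_bartlett(double df, const mat& scale_chol_lower) {
  const uword p = scale_chol_lower.n_rows;
  mat A(p, p, fill::zeros);
  for (uword i = 0; i < p; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - (double)i));
    for (uword j = 0; j < i; ++j) A(i, j) = R::rnorm(0.0, 1.0);
  }
  mat LA = scale_chol_lower * A;
  return LA * LA.t();
}

static mat rinvwishart(double df, const mat& S) {
  mat Sinv = inv_sympd(symmatu(S));
  mat L = chol(symmatu(Sinv), "lower");
  mat W = rwishart_bartlett(df, L);
  return inv_sympd(symmatu(W));
}

// [[Rcpp::export(name = ".mtm_gibbs")]]
Rcpp::List mtm_gibbs(const arma::mat& Y, const arma::umat& obs,
                     const arma::mat& U, const arma::vec& d,
                     const arma::mat& S0, double nu0,
                     const arma::vec& s0R, double df0,
                     int niter, int burnin, int thin) {
  Rcpp::RNGScope scope;
  const uword n = Y.n_rows, r = Y.n_cols;
  vec dinv = 1.0 / d;

  // initial values: observed trait means / variances, A = 0
  vec M(r), sigmaR(r);
  for (uword j = 0; j < r; ++j) {
    uvec oj = find(obs.col(j));
    vec yj = Y.col(j);
    M(j) = mean(yj(oj));
    double v = var(yj(oj));
    sigmaR(j) = (v > 0.0) ? 0.5 * v : 1.0;
  }
  mat SigmaA = S0 / (nu0 + (double)r + 1.0);  // prior mode
  mat A(n, r, fill::zeros), Astar(n, r, fill::zeros);
  mat Ycomp = Y;

  const int nstore = (niter - burnin) / thin;
  mat sampSigmaA(nstore, r * r), sampSigmaR(nstore, r);
  mat Asum(n, r, fill::zeros);
  vec Msum(r, fill::zeros);
  mat SigmaAsum(r, r, fill::zeros);
  vec sigmaRsum(r, fill::zeros);
  int stored = 0;

  for (int it = 1; it <= niter; ++it) {
    // 1. impute missing cells from their Gaussian predictive
    for (uword j = 0; j < r; ++j) {
      double sdj = std::sqrt(sigmaR(j));
      for (uword i = 0; i < n; ++i)
        if (!obs(i, j)) Ycomp(i, j) = M(j) + A(i, j) + R::rnorm(0.0, sdj);
    }
    // 2. intercepts (flat prior)
    for (uword j = 0; j < r; ++j) {
      double mbar = mean(Ycomp.col(j) - A.col(j));
      M(j) = R::rnorm(mbar, std::sqrt(sigmaR(j) / (double)n));
    }
    // 3. genetic values in the eigenbasis of G
    mat Ytil = U.t() * (Ycomp - repmat(M.t(), n, 1));
    mat SAinv = inv_sympd(symmatu(SigmaA));
    mat Rinv = diagmat(1.0 / sigmaR);
    for (uword k = 0; k < n; ++k) {
      mat Prec = Rinv + dinv(k) * SAinv;
      mat Lp = chol(symmatu(Prec), "lower");
      vec rhs = Rinv * Ytil.row(k).t();
      vec mu = solve(trimatl(Lp), rhs);
      mu = solve(trimatu(Lp.t()), mu);
      vec z(r);
      for (uword j = 0; j < r; ++j) z(j) = R::rnorm(0.0, 1.0);
      Astar.row(k) = (mu + solve(trimatu(Lp.t()), z)).t();
    }
    A = U * Astar;
    // 4. genetic covariance
    mat Sa = S0 + Astar.t() * (Astar.each_col() % dinv);
    SigmaA = rinvwishart(nu0 + (double)n, symmatu(Sa));
    // 5. residual variances
    mat E = Ycomp - repmat(M.t(), n, 1) - A;
    for (uword j = 0; j < r; ++j) {
      double ss = df0 * s0R(j) + dot(E.col(j), E.col(j));
      sigmaR(j) = ss / R::rchisq(df0 + (double)n);
    }
    if (it > burnin && (it - burnin) % thin == 0) {
      sampSigmaA.row(stored) = vectorise(SigmaA).t();
      sampSigmaR.row(stored) = sigmaR.t();
      Asum += A;
      Msum += M;
      SigmaAsum += SigmaA;
      sigmaRsum += sigmaR;
      ++stored;
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("M") = Msum / stored,
      Rcpp::Named("Ahat") = Asum / stored,
      Rcpp::Named("SigmaA") = SigmaAsum / stored,
      Rcpp::Named("sigmaR") = sigmaRsum / stored,
      Rcpp::Named("sampSigmaA") = sampSigmaA,
      Rcpp::Named("sampSigmaR") = sampSigmaR);
}
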