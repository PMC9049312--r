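#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Statistics of the clustered linear combination test for every cut
// L = 1..K, for one or many score vectors sharing the same precision
// matrix and cluster assignments.
//
// tmat : n x K matrix, one score vector per row
// sinv : K x K precision matrix (inverse of the trait correlation matrix,
//        ridged upstream if near-singular)
// cl   : K x K integer matrix; column L holds the partition with L clusters,
//        labels in 1..L (the layout produced by stats::cutree(hc, k = 1:K))
//
// For a 0/1 membership matrix B (K x L) and W = B^T S^{-1}, the statistic
// (WT)^T (W S W^T)^{-1} (WT) collapses algebraically to q^T M^{-1} q with
// q = B^T S^{-1} T and M = B^T S^{-1} B, which is what is evaluated here.
//
// Returns an n x K matrix of statistics; column L is the L-cluster statistic.
// [[Rcpp::export(name = ".clc_profile_cpp")]]
arma::mat clc_profile_cpp(const arma::mat& tmat, const arma::mat& sinv,
                          const arma::imat& cl) {
  const arma::uword n = tmat.n_rows, K = tmat.n_cols;
  if (sinv.n_rows != K || cl.n_rows != K || cl.n_cols != K)
    Rcpp::stop("dimension mismatch between scores, precision and cuts");
  const arma::mat S = sinv * tmat.t();  // K x n, shared across cuts
  arma::mat out(n, K);
  for (arma::uword Lc = 0; Lc < K; ++Lc) {
    const arma::uword L = Lc + 1;
    arma::mat Q(L, n, arma::fill::zeros);
    arma::mat Agg(L, K, arma::fill::zeros);
    for (arma::uword k = 0; k < K; ++k) {
      const arma::uword l = static_cast<arma::uword>(cl(k, Lc)) - 1;
      if (l >= L) Rcpp::stop("cluster label out of range in column %d", (int)L);
      Q.row(l) += S.row(k);
      Agg(l, k) = 1.0;
    }
    const arma::mat M = Agg * sinv * Agg.t();  // L x L
    arma::mat Z;
    if (!arma::solve(Z, M, Q, arma::solve_opts::likely_sympd))
      Rcpp::stop("singular within-cluster matrix at L = %d", (int)L);
    out.col(Lc) = arma::sum(Q % Z, 0).t();
  }
  return out;
}
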