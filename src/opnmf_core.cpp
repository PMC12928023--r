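// Multiplicative-update loop for orthonormal projective NMF and the
// subset enumeration behind dominance analysis. Kept in compiled code
// because both are tight numeric loops run thousands of times.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// W <- W % (A W) / (W (W' A W)), columns L2-normalized each iteration,
// with A = X X' precomputed by the caller. Convergence on the relative
// Frobenius change of W.
// [[Rcpp::export]]
Rcpp::List opnmf_core(const arma::mat& A, arma::mat W, int max_iter,
                      double tol, double eps) {
  int it = 0;
  bool converged = false;
  for (it = 1; it <= max_iter; ++it) {
    mat AW = A * W;
    mat WtAW = W.t() * AW;
    mat denom = W * WtAW;
    mat Wn = W % AW / (denom + eps);
    if (!Wn.is_finite())
      Rcpp::stop("non-finite update at iteration %d", it);
    rowvec nrm = sqrt(sum(square(Wn), 0));
    nrm.replace(0.0, 1.0);
    Wn.each_row() /= nrm;
    double diff = norm(Wn - W, "fro") / std::max(norm(W, "fro"), eps);
    W = Wn;
    if (diff < tol) { converged = true; break; }
  }
  if (it > max_iter) it = max_iter;
  return Rcpp::List::create(Rcpp::Named("W") = W,
                            Rcpp::Named("n_iter") = it,
                            Rcpp::Named("converged") = converged);
}

// General dominance by exact subset enumeration. Inputs: Cxx = predictor
// correlation matrix (q x q), b = correlations of each predictor with the
// standardized response. R2 of subset S is b_S' Cxx_SS^{-1} b_S. Returns
// per-predictor general dominance (incremental R2 averaged within
// subset-size strata, then across sizes) and the full-model R2.
// [[Rcpp::export]]
Rcpp::List dominance_core(const arma::mat& Cxx, const arma::vec& b) {
  const int q = b.n_elem;
  const size_t nmask = ((size_t)1) << q;
  std::vector<double> r2(nmask, 0.0);
  std::vector<int> popcnt(nmask, 0);
  for (size_t mask = 1; mask < nmask; ++mask) {
    popcnt[mask] = popcnt[mask >> 1] + (mask & 1);
    int s = popcnt[mask];
    uvec idx(s);
    int k = 0;
    for (int j = 0; j < q; ++j)
      if (mask & (((size_t)1) << j)) idx(k++) = j;
    vec bs = b.elem(idx);
    mat Cs = Cxx.submat(idx, idx);
    vec sol;
    if (!solve(sol, Cs, bs, solve_opts::likely_sympd + solve_opts::no_approx))
      solve(sol, Cs, bs);  // fall back to generic solver
    r2[mask] = dot(bs, sol);
  }
  // accumulate increments per predictor and subset size
  mat sum_inc(q, q, fill::zeros);   // predictor x size-of-S (0..q-1)
  mat cnt_inc(q, q, fill::zeros);
  for (size_t mask = 0; mask < nmask; ++mask) {
    int s = popcnt[mask];
    if (s >= q) continue;
    for (int j = 0; j < q; ++j) {
      if (mask & (((size_t)1) << j)) continue;
      size_t with_j = mask | (((size_t)1) << j);
      sum_inc(j, s) += r2[with_j] - r2[mask];
      cnt_inc(j, s) += 1.0;
    }
  }
  vec dom(q, fill::zeros);
  for (int j = 0; j < q; ++j) {
    double acc = 0.0;
    for (int s = 0; s < q; ++s) acc += sum_inc(j, s) / cnt_inc(j, s);
    dom(j) = acc / q;
  }
  return Rcpp::List::create(Rcpp::Named("dominance") = dom,
                            Rcpp::Named("r2_full") = r2[nmask - 1]);
}
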