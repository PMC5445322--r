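#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Least-squares rigid superposition of A onto B (rows = points, columns =
// x/y/z).  Convention: fitted = A * R + t with det(R) = +1 (reflections
// excluded by flipping the smallest singular direction).
static void kabsch_fit(const arma::mat& A, const arma::mat& B,
                       arma::mat& R, arma::rowvec& t, double& rmsd) {
  arma::rowvec ca = arma::mean(A, 0), cb = arma::mean(B, 0);
  arma::mat Ac = A.each_row() - ca;
  arma::mat Bc = B.each_row() - cb;
  arma::mat H = Ac.t() * Bc;
  arma::mat U, V;
  arma::vec s;
  if (!arma::svd(U, s, V, H)) Rcpp::stop("SVD failed in superposition");
  double d = (arma::det(U * V.t()) < 0.0) ? -1.0 : 1.0;
  arma::mat D = arma::eye(3, 3);
  D(2, 2) = d;
  R = U * D * V.t();
  t = cb - ca * R;
  arma::mat diff = Ac * R - Bc;
  rmsd = std::sqrt(arma::accu(diff % diff) / (double)A.n_rows);
}

// [[Rcpp::export]]
List cpp_kabsch(const arma::mat& A, const arma::mat& B) {
  if (A.n_rows != B.n_rows || A.n_cols != 3 || B.n_cols != 3)
    Rcpp::stop("coordinate sets must be matched N x 3 matrices");
  if (A.n_rows < 3) Rcpp::stop("at least 3 paired points are required");
  arma::mat R;
  arma::rowvec t;
  double rmsd;
  kabsch_fit(A, B, R, t, rmsd);
  return List::create(_["rotation"] = R, _["translation"] = t,
                      _["rmsd"] = rmsd);
}

// Distances of every row of P (transformed by the fit of P[sel] onto
// Q[sel]) to the matching row of Q.
static arma::vec fit_distances(const arma::mat& P, const arma::mat& Q,
                               const arma::uvec& sel) {
  arma::mat R;
  arma::rowvec t;
  double rmsd;
  kabsch_fit(P.rows(sel), Q.rows(sel), R, t, rmsd);
  arma::mat moved = P * R;
  moved.each_row() += t;
  arma::mat diff = moved - Q;
  return arma::sqrt(arma::sum(diff % diff, 1));
}

static std::vector<arma::uvec> make_seeds(int n, const IntegerVector& lens) {
  std::vector<arma::uvec> seeds;
  for (int k = 0; k < lens.size(); ++k) {
    int L = lens[k];
    if (L < 3 || L > n) continue;
    for (int s = 0; s + L <= n; ++s) {
      arma::uvec w(L);
      for (int i = 0; i < L; ++i) w[i] = s + i;
      seeds.push_back(w);
    }
  }
  // full-length fit is always one of the seeds (lower-bound guarantee)
  arma::uvec all = arma::regspace<arma::uvec>(0, n - 1);
  seeds.push_back(all);
  return seeds;
}

// GDT-style search: for each threshold, the maximal number of matched CA
// pairs that a seeded iteratively-refined superposition brings within the
// threshold.  P and Q are matched common-residue CA coordinates.
// [[Rcpp::export]]
IntegerVector cpp_gdt_counts(const arma::mat& P, const arma::mat& Q,
                             NumericVector thresholds,
                             IntegerVector window_lengths, int max_iter) {
  int n = P.n_rows;
  if (n < 3) Rcpp::stop("need >= 3 matched residues");
  std::vector<arma::uvec> seeds = make_seeds(n, window_lengths);
  IntegerVector best(thresholds.size());
  for (int ti = 0; ti < thresholds.size(); ++ti) {
    double d = thresholds[ti];
    int bestc = 0;
    for (size_t si = 0; si < seeds.size(); ++si) {
      arma::uvec sel = seeds[si];
      for (int it = 0; it < max_iter; ++it) {
        arma::vec dist = fit_distances(P, Q, sel);
        arma::uvec inl = arma::find(dist < d);
        if ((int)inl.n_elem > bestc) bestc = inl.n_elem;
        if (inl.n_elem < 3) break;
        if (inl.n_elem == sel.n_elem && arma::all(inl == sel)) break;
        sel = inl;
      }
      if (bestc == n) break;
    }
    best[ti] = bestc;
  }
  return best;
}

// TM-score search with the same seeding scheme: returns the maximal sum of
// 1 / (1 + (d_i/d0)^2) over matched residues (caller divides by the
// reference length).
// [[Rcpp::export]]
double cpp_tm_best(const arma::mat& P, const arma::mat& Q, double d0,
                   IntegerVector window_lengths, int max_iter) {
  int n = P.n_rows;
  if (n < 3) Rcpp::stop("need >= 3 matched residues");
  double dsel = std::max(d0, 3.5);
  std::vector<arma::uvec> seeds = make_seeds(n, window_lengths);
  double best = 0.0;
  for (size_t si = 0; si < seeds.size(); ++si) {
    arma::uvec sel = seeds[si];
    for (int it = 0; it < max_iter; ++it) {
      arma::vec dist = fit_distances(P, Q, sel);
      double tm = 0.0;
      for (int i = 0; i < n; ++i) tm += 1.0 / (1.0 + std::pow(dist[i] / d0, 2));
      if (tm > best) best = tm;
      arma::uvec inl = arma::find(dist < dsel);
      if (inl.n_elem < 3) break;
      if (inl.n_elem == sel.n_elem && arma::all(inl == sel)) break;
      sel = inl;
    }
  }
  return best;
}
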