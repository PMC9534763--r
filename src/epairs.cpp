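// Hot loops for the ePAIRS nonuniformity test: per-point mean
// nearest-neighbor angles and Monte-Carlo null medians. The angle metric is
// arccos of the (optionally folded) cosine similarity; nearest neighbors are
// found on the cosine scale so arccos is only evaluated for the k selected
// neighbors of each point.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static inline void push_top(double* buf, int k, double v) {
  // buf holds the k largest seen so far, ascending; buf[0] is their minimum
  if (v > buf[0]) {
    buf[0] = v;
    for (int m = 1; m < k && buf[m] < buf[m - 1]; ++m)
      std::swap(buf[m], buf[m - 1]);
  }
}

static void mean_nn_angles(const mat& X, int k, bool fold, vec& out) {
  const int n = X.n_rows;
  mat Xn = normalise(X, 2, 1);
  mat C = Xn * Xn.t();
  // single pass over the upper triangle, updating both endpoints' top-k
  std::vector<double> top((size_t) n * k, -2.0);
  for (int j = 1; j < n; ++j) {
    const double* col = C.colptr(j);
    double* tj = &top[(size_t) j * k];
    for (int i = 0; i < j; ++i) {
      double v = fold ? std::fabs(col[i]) : col[i];
      push_top(&top[(size_t) i * k], k, v);
      push_top(tj, k, v);
    }
  }
  for (int i = 0; i < n; ++i) {
    const double* ti = &top[(size_t) i * k];
    double s = 0.0;
    for (int m = 0; m < k; ++m)
      s += std::acos(std::min(1.0, std::max(-1.0, ti[m])));
    out[i] = s / k;
  }
}

// [[Rcpp::export]]
arma::vec nn_angles_cpp(const arma::mat& X, int k, bool fold) {
  vec out(X.n_rows);
  mean_nn_angles(X, k, fold, out);
  return out;
}

// B null replicates: n draws from N(0, diag(sds^2)), median of the per-point
// mean nearest-neighbor angles of each replicate. Uses R's RNG so results are
// reproducible under set.seed().
// [[Rcpp::export]]
Rcpp::NumericVector epairs_null_medians_cpp(int n, const arma::vec& sds,
                                            int k, int B, bool fold) {
  const int d = sds.n_elem;
  Rcpp::NumericVector out(B);
  vec ang(n);
  for (int b = 0; b < B; ++b) {
    Rcpp::NumericVector z = Rcpp::rnorm(n * d);
    mat X(z.begin(), n, d, false);
    mat Xs = X;
    for (int j = 0; j < d; ++j) Xs.col(j) *= sds[j];
    mean_nn_angles(Xs, k, fold, ang);
    out[b] = arma::median(ang);
    if (b % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
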