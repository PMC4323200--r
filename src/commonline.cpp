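#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Polar-Fourier images arrive transposed (n_radial x n_lines) so that
// each line is a contiguous column.
//
// Line-pair discrepancy modes:
//   0: mean per-sample complex modulus |F_A(i) - F_B(i)|
//   1: mean per-sample modulus difference ||F_A(i)| - |F_B(i)||
//   2: literal form |sum_i (F_A(i) - F_B(i))| / N
//   3: mode 0 minimized over a set of relative 1-D shifts (phase ramps
//      supplied via set_shift_ramps)
static arma::cx_mat g_ramps;   // n_shifts x N phase-ramp table for mode 3

// [[Rcpp::export]]
void set_shift_ramps(const arma::cx_mat& ramps) { g_ramps = ramps; }

static inline double line_disc(const std::complex<double>* a,
                               const std::complex<double>* b,
                               const arma::uword N, const int mode) {
  if (mode == 2) {
    std::complex<double> acc(0.0, 0.0);
    for (arma::uword i = 0; i < N; ++i) acc += a[i] - b[i];
    return std::abs(acc) / double(N);
  }
  if (mode == 3) {
    double best = R_PosInf;
    for (arma::uword k = 0; k < g_ramps.n_rows; ++k) {
      double s = 0.0;
      for (arma::uword i = 0; i < N; ++i)
        s += std::abs(a[i] - b[i] * g_ramps(k, i));
      if (s < best) best = s;
    }
    return best / double(N);
  }
  double s = 0.0;
  if (mode == 1) {
    for (arma::uword i = 0; i < N; ++i)
      s += std::fabs(std::abs(a[i]) - std::abs(b[i]));
  } else {
    for (arma::uword i = 0; i < N; ++i)
      s += std::abs(a[i] - b[i]);
  }
  return s / double(N);
}

// Full discrepancy matrix between the line sets of two images
// (element [i, j] = discrepancy of line i of A vs line j of B).
// [[Rcpp::export]]
arma::mat cl_line_matrix(const arma::cx_mat& At, const arma::cx_mat& Bt,
                         const int mode) {
  const arma::uword la = At.n_cols, lb = Bt.n_cols, N = At.n_rows;
  arma::mat D(la, lb);
  for (arma::uword j = 0; j < lb; ++j) {
    const std::complex<double>* bp = Bt.colptr(j);
    for (arma::uword i = 0; i < la; ++i)
      D(i, j) = line_disc(At.colptr(i), bp, N, mode);
  }
  return D;
}

// Best-matching line pair (minimum discrepancy); 1-based indices.
// [[Rcpp::export]]
List cl_best_match(const arma::cx_mat& At, const arma::cx_mat& Bt,
                   const int mode) {
  const arma::uword la = At.n_cols, lb = Bt.n_cols, N = At.n_rows;
  double best = R_PosInf;
  arma::uword bi = 0, bj = 0;
  for (arma::uword j = 0; j < lb; ++j) {
    const std::complex<double>* bp = Bt.colptr(j);
    for (arma::uword i = 0; i < la; ++i) {
      const double d = line_disc(At.colptr(i), bp, N, mode);
      if (d < best) { best = d; bi = i; bj = j; }
    }
  }
  return List::create(_["distance"] = best,
                      _["line_a"] = int(bi) + 1,
                      _["line_b"] = int(bj) + 1);
}

// All-pairs image distance with matched line indices.
// [[Rcpp::export]]
List cl_pairwise(const List& pf, const int mode) {
  const int m = pf.size();
  arma::mat D(m, m, arma::fill::zeros);
  arma::imat LA(m, m, arma::fill::zeros), LB(m, m, arma::fill::zeros);
  std::vector<arma::cx_mat> mats(m);
  for (int i = 0; i < m; ++i) mats[i] = as<arma::cx_mat>(pf[i]);
  for (int i = 0; i < m; ++i) {
    for (int j = i + 1; j < m; ++j) {
      List r = cl_best_match(mats[i], mats[j], mode);
      const double d = r["distance"];
      D(i, j) = D(j, i) = d;
      LA(i, j) = r["line_a"]; LB(i, j) = r["line_b"];
      LA(j, i) = r["line_b"]; LB(j, i) = r["line_a"];
    }
  }
  return List::create(_["D"] = D, _["line_a"] = LA, _["line_b"] = LB);
}
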