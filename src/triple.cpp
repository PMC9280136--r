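// Core tensor algebra for the triple decomposition of 3x3 velocity
// gradient tensors, plus 26-connectivity component labeling for
// thresholded modality fields.  The real Schur factorization is
// delegated to LAPACK (dgees via Armadillo); the block ordering and
// standardization conventions are implemented here:
//   (i)  the 1x1 real-eigenvalue block is moved to position (1,1);
//   (ii) the 2x2 block is rotated to equal diagonal entries;
//   (iii) |beta| >= |gamma| via the off-diagonal swap permutation;
//   (iv) gamma >= 0 via a column sign flip.
// Magnitudes are unaffected by (i)-(iv); the conventions exist so that
// lambda, alpha, beta, gamma, eps, zeta are deterministic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// Standardize an upper quasi-triangular 3x3 T (and accumulate into Q).
// On entry T comes from dgees: exact zeros below the diagonal blocks.
// Returns true when a complex-conjugate eigenvalue pair is present.
bool standardize(arma::mat& Q, arma::mat& T) {
  const bool block_top = (T(1, 0) != 0.0);
  const bool block_bot = (T(2, 1) != 0.0);
  if (!block_top && !block_bot) {
    // all eigenvalues real: T already upper triangular
    return false;
  }

  if (block_top) {
    // 2x2 block occupies rows/cols 0:1, real eigenvalue at (2,2).
    // Move the real block first via the invariant subspace of lambda:
    // solve (A11 - lambda I) x = -a12, v = [x; 1].
    const double lam = T(2, 2);
    arma::mat A = T.submat(0, 0, 1, 1);
    A(0, 0) -= lam;
    A(1, 1) -= lam;
    arma::vec rhs = { -T(0, 2), -T(1, 2) };
    arma::vec x = arma::solve(A, rhs);
    arma::vec v = { x(0), x(1), 1.0 };
    v /= arma::norm(v);
    // Householder P (symmetric, orthogonal) with P e1 = v
    arma::vec w = v;
    w(0) -= 1.0;
    const double wn2 = arma::dot(w, w);
    if (wn2 > 0.0) {
      arma::mat P = arma::eye(3, 3) - (2.0 / wn2) * (w * w.t());
      T = P * T * P;
      Q = Q * P;
    }
    T(1, 0) = 0.0;
    T(2, 0) = 0.0;
    T(0, 0) = lam;
  }

  // 2x2 block now at rows/cols 1:2; rotate to equal diagonal
  // (dgees blocks arrive standardized, but the reordering above and
  // roundoff make this worth enforcing unconditionally).
  {
    const double a = T(1, 1), b = T(1, 2), c = T(2, 1), d = T(2, 2);
    const double two_theta = std::atan2(-(a - d), b + c);
    const double th = 0.5 * two_theta;
    const double ct = std::cos(th), st = std::sin(th);
    arma::mat G = arma::eye(3, 3);
    G(1, 1) = ct;  G(1, 2) = -st;
    G(2, 1) = st;  G(2, 2) = ct;
    T = G.t() * T * G;
    Q = Q * G;
    const double alpha = 0.5 * (T(1, 1) + T(2, 2));
    T(1, 1) = alpha;
    T(2, 2) = alpha;
    T(1, 0) = 0.0;
    T(2, 0) = 0.0;
  }

  // |beta| >= |gamma|: conjugate by the permutation swapping rows/cols 2,3
  if (std::abs(T(1, 2)) < std::abs(T(2, 1))) {
    std::swap(T(1, 2), T(2, 1));
    std::swap(T(0, 1), T(0, 2));
    Q.swap_cols(1, 2);
  }

  // gamma >= 0: conjugate by diag(1, 1, -1)
  if (T(2, 1) < 0.0) {
    T(0, 2) = -T(0, 2);
    T(1, 2) = -T(1, 2);
    T(2, 1) = -T(2, 1);
    Q.col(2) = -Q.col(2);
  }
  return true;
}

inline double sss_of(const arma::mat& g) {
  const double t00 = 2.0 * g(0, 0), t11 = 2.0 * g(1, 1), t22 = 2.0 * g(2, 2);
  const double t01 = g(0, 1) + g(1, 0);
  const double t02 = g(0, 2) + g(2, 0);
  const double t12 = g(1, 2) + g(2, 1);
  const double d = ((t00 - t11) * (t00 - t11) + (t11 - t22) * (t11 - t22) +
                    (t00 - t22) * (t00 - t22)) / 6.0;
  return std::sqrt(d + t01 * t01 + t12 * t12 + t02 * t02);
}

} // namespace

// [[Rcpp::export(name = ".schur_standardized_cpp")]]
List schur_standardized_cpp(const arma::mat& g) {
  arma::mat Q, T;
  if (!arma::schur(Q, T, g)) {
    stop("real Schur factorization failed");
  }
  const bool cp = standardize(Q, T);
  return List::create(
    _["q"] = Q, _["t"] = T, _["has_complex_pair"] = cp,
    _["lam"] = cp ? T(0, 0) : NA_REAL,
    _["alpha"] = cp ? T(1, 1) : NA_REAL,
    _["beta"] = cp ? T(1, 2) : NA_REAL,
    _["gamma"] = cp ? T(2, 1) : NA_REAL,
    _["eps"] = T(0, 1), _["zeta"] = T(0, 2));
}

// Batch magnitudes for N tensors, each a column-major flattened 3x3 in
// one row of G (N x 9).  Columns of the result: el, rr, sh, sss.
// [[Rcpp::export(name = ".triple_magnitudes_cpp")]]
arma::mat triple_magnitudes_cpp(const arma::mat& G) {
  const arma::uword n = G.n_rows;
  arma::mat out(n, 4);
  arma::mat g(3, 3), Q, T;
  for (arma::uword i = 0; i < n; ++i) {
    for (arma::uword k = 0; k < 9; ++k) g(k % 3, k / 3) = G(i, k);
    if (!arma::schur(Q, T, g)) stop("real Schur factorization failed");
    const bool cp = standardize(Q, T);
    double el, rr, sh;
    if (cp) {
      const double lam = T(0, 0), alpha = T(1, 1);
      const double beta = T(1, 2), gamma = T(2, 1);
      el = std::sqrt(lam * lam + 2.0 * alpha * alpha);
      rr = std::sqrt(2.0) * std::abs(gamma);
      sh = std::sqrt(T(0, 1) * T(0, 1) + T(0, 2) * T(0, 2) +
                     (beta + gamma) * (beta + gamma));
    } else {
      el = std::sqrt(T(0, 0) * T(0, 0) + T(1, 1) * T(1, 1) + T(2, 2) * T(2, 2));
      rr = 0.0;
      sh = std::sqrt(T(0, 1) * T(0, 1) + T(0, 2) * T(0, 2) + T(1, 2) * T(1, 2));
    }
    out(i, 0) = el;
    out(i, 1) = rr;
    out(i, 2) = sh;
    out(i, 3) = sss_of(g);
  }
  return out;
}

// 26-connectivity component labeling of a 3D logical array (column-major,
// x fastest).  Returns integer labels, 0 = background; label numbering is
// by discovery order (relabeled by size on the R side).
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(const LogicalVector& bin,
                                   const IntegerVector& dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = static_cast<R_xlen_t>(nx) * ny * nz;
  if (bin.size() != n) stop("dims do not match array length");
  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!bin[start] || labels[start] != 0) continue;
    ++next;
    labels[start] = next;
    stack.push_back(start);
    while (!stack.empty()) {
      const R_xlen_t idx = stack.back();
      stack.pop_back();
      const int x = static_cast<int>(idx % nx);
      const int y = static_cast<int>((idx / nx) % ny);
      const int z = static_cast<int>(idx / (static_cast<R_xlen_t>(nx) * ny));
      for (int dz = -1; dz <= 1; ++dz) {
        for (int dy = -1; dy <= 1; ++dy) {
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            const int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
              continue;
            const R_xlen_t j = xx + static_cast<R_xlen_t>(nx) * (yy + static_cast<R_xlen_t>(ny) * zz);
            if (bin[j] && labels[j] == 0) {
              labels[j] = next;
              stack.push_back(j);
            }
          }
        }
      }
    }
  }
  return labels;
}
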