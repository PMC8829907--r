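// Finite-field linear algebra for the fountain codecs.
//
// GF(256) is realized with the primitive polynomial x^8+x^4+x^3+x^2+1
// (0x11D, generator 2) via log/antilog tables; GF(2) systems use plain XOR
// row reduction. Matrices travel as IntegerMatrix with entries 0..255
// (coefficients) or 0/1 (GF(2) membership); payload symbol bytes as
// IntegerMatrix 0..255.

#include <Rcpp.h>
using namespace Rcpp;

static unsigned char gf_exp[512];
static unsigned char gf_log[256];
static bool gf_ready = false;

static void gf_init() {
  if (gf_ready) return;
  int x = 1;
  for (int i = 0; i < 255; ++i) {
    gf_exp[i] = (unsigned char)x;
    gf_log[x] = (unsigned char)i;
    x <<= 1;
    if (x & 0x100) x ^= 0x11D;
  }
  for (int i = 255; i < 512; ++i) gf_exp[i] = gf_exp[i - 255];
  gf_log[0] = 0;
  gf_ready = true;
}

static inline unsigned char gmul(unsigned char a, unsigned char b) {
  if (a == 0 || b == 0) return 0;
  return gf_exp[gf_log[a] + gf_log[b]];
}

static inline unsigned char ginv(unsigned char a) {
  return gf_exp[255 - gf_log[a]];
}

// [[Rcpp::export]]
IntegerMatrix gf256_matmul_cpp(IntegerMatrix A, IntegerMatrix X) {
  gf_init();
  int n = A.nrow(), k = A.ncol(), L = X.ncol();
  if (X.nrow() != k) stop("dimension mismatch in GF(256) matmul");
  IntegerMatrix Y(n, L);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < k; ++j) {
      unsigned char c = (unsigned char)A(i, j);
      if (c == 0) continue;
      for (int l = 0; l < L; ++l) {
        Y(i, l) ^= gmul(c, (unsigned char)X(j, l));
      }
    }
  }
  return Y;
}

// [[Rcpp::export]]
int gf256_rank_cpp(IntegerMatrix A) {
  gf_init();
  int n = A.nrow(), k = A.ncol();
  std::vector<std::vector<unsigned char> > M(n, std::vector<unsigned char>(k));
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < k; ++j) M[i][j] = (unsigned char)A(i, j);
  int rank = 0;
  for (int col = 0; col < k && rank < n; ++col) {
    int piv = -1;
    for (int i = rank; i < n; ++i) if (M[i][col] != 0) { piv = i; break; }
    if (piv < 0) continue;
    std::swap(M[piv], M[rank]);
    unsigned char inv = ginv(M[rank][col]);
    for (int j = col; j < k; ++j) M[rank][j] = gmul(M[rank][j], inv);
    for (int i = 0; i < n; ++i) {
      if (i == rank || M[i][col] == 0) continue;
      unsigned char f = M[i][col];
      for (int j = col; j < k; ++j) M[i][j] ^= gmul(f, M[rank][j]);
    }
    ++rank;
  }
  return rank;
}

// Solve A x = Y over GF(256); A is n x k (n >= k for solvability), Y is
// n x L. Returns ok = FALSE when rank(A) < k; consistency of redundant rows
// is verified when the system is overdetermined.
// [[Rcpp::export]]
List gf256_solve_cpp(IntegerMatrix A, IntegerMatrix Y) {
  gf_init();
  int n = A.nrow(), k = A.ncol(), L = Y.ncol();
  if (Y.nrow() != n) stop("dimension mismatch in GF(256) solve");
  std::vector<std::vector<unsigned char> > M(n, std::vector<unsigned char>(k));
  std::vector<std::vector<unsigned char> > B(n, std::vector<unsigned char>(L));
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < k; ++j) M[i][j] = (unsigned char)A(i, j);
    for (int l = 0; l < L; ++l) B[i][l] = (unsigned char)Y(i, l);
  }
  int rank = 0;
  std::vector<int> pivcol;
  for (int col = 0; col < k && rank < n; ++col) {
    int piv = -1;
    for (int i = rank; i < n; ++i) if (M[i][col] != 0) { piv = i; break; }
    if (piv < 0) continue;
    std::swap(M[piv], M[rank]);
    std::swap(B[piv], B[rank]);
    unsigned char inv = ginv(M[rank][col]);
    for (int j = col; j < k; ++j) M[rank][j] = gmul(M[rank][j], inv);
    for (int l = 0; l < L; ++l) B[rank][l] = gmul(B[rank][l], inv);
    for (int i = 0; i < n; ++i) {
      if (i == rank || M[i][col] == 0) continue;
      unsigned char f = M[i][col];
      for (int j = col; j < k; ++j) M[i][j] ^= gmul(f, M[rank][j]);
      for (int l = 0; l < L; ++l) B[i][l] ^= gmul(f, B[rank][l]);
    }
    pivcol.push_back(col);
    ++rank;
  }
  if (rank < k) {
    return List::create(Named("ok") = false, Named("rank") = rank,
                        Named("x") = R_NilValue);
  }
  // redundant rows must have been reduced to zero = zero
  bool consistent = true;
  for (int i = rank; i < n && consistent; ++i)
    for (int l = 0; l < L; ++l) if (B[i][l] != 0) { consistent = false; break; }
  IntegerMatrix X(k, L);
  for (int r = 0; r < rank; ++r)
    for (int l = 0; l < L; ++l) X(pivcol[r], l) = B[r][l];
  return List::create(Named("ok") = consistent, Named("rank") = rank,
                      Named("x") = X);
}

// [[Rcpp::export]]
int gf2_rank_cpp(IntegerMatrix A) {
  int n = A.nrow(), k = A.ncol();
  std::vector<std::vector<unsigned char> > M(n, std::vector<unsigned char>(k));
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < k; ++j) M[i][j] = (unsigned char)(A(i, j) & 1);
  int rank = 0;
  for (int col = 0; col < k && rank < n; ++col) {
    int piv = -1;
    for (int i = rank; i < n; ++i) if (M[i][col]) { piv = i; break; }
    if (piv < 0) continue;
    std::swap(M[piv], M[rank]);
    for (int i = 0; i < n; ++i) {
      if (i == rank || !M[i][col]) continue;
      for (int j = col; j < k; ++j) M[i][j] ^= M[rank][j];
    }
    ++rank;
  }
  return rank;
}

// Solve A x = Y over GF(2) where payload bytes are XORed whenever rows are
// added; A is n x k with 0/1 entries, Y is n x L bytes.
// [[Rcpp::export]]
List gf2_solve_cpp(IntegerMatrix A, IntegerMatrix Y) {
  int n = A.nrow(), k = A.ncol(), L = Y.ncol();
  if (Y.nrow() != n) stop("dimension mismatch in GF(2) solve");
  std::vector<std::vector<unsigned char> > M(n, std::vector<unsigned char>(k));
  std::vector<std::vector<unsigned char> > B(n, std::vector<unsigned char>(L));
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < k; ++j) M[i][j] = (unsigned char)(A(i, j) & 1);
    for (int l = 0; l < L; ++l) B[i][l] = (unsigned char)Y(i, l);
  }
  int rank = 0;
  std::vector<int> pivcol;
  for (int col = 0; col < k && rank < n; ++col) {
    int piv = -1;
    for (int i = rank; i < n; ++i) if (M[i][col]) { piv = i; break; }
    if (piv < 0) continue;
    std::swap(M[piv], M[rank]);
    std::swap(B[piv], B[rank]);
    for (int i = 0; i < n; ++i) {
      if (i == rank || !M[i][col]) continue;
      for (int j = col; j < k; ++j) M[i][j] ^= M[rank][j];
      for (int l = 0; l < L; ++l) B[i][l] ^= B[rank][l];
    }
    pivcol.push_back(col);
    ++rank;
  }
  if (rank < k) {
    return List::create(Named("ok") = false, Named("rank") = rank,
                        Named("x") = R_NilValue);
  }
  bool consistent = true;
  for (int i = rank; i < n && consistent; ++i)
    for (int l = 0; l < L; ++l) if (B[i][l] != 0) { consistent = false; break; }
  IntegerMatrix X(k, L);
  for (int r = 0; r < rank; ++r)
    for (int l = 0; l < L; ++l) X(pivcol[r], l) = B[r][l];
  return List::create(Named("ok") = consistent, Named("rank") = rank,
                      Named("x") = X);
}
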