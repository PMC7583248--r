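#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap global alignment (Gotoh) over a precomputed cross-score matrix.
//
// S(i, j) holds the substitution score for aligning column i of profile A
// against column j of profile B (for plain sequences these are one-hot
// profiles, so S is just the substitution matrix lookup). A gap of length k
// costs gap_open + k * gap_extend, scaled per consumed column by that
// column's weight (wa / wb; the non-gap fraction of the column), so new
// gaps preferentially align with existing gaps in profile alignment. With
// unit weights this is the textbook affine scheme.
//
// Tie-breaking on traceback is fixed so results are identical across
// platforms: prefer the diagonal (match/mismatch), then a gap in A (consume
// a column of B), then a gap in B.
//
// Returns the optimal score and the edit path encoded as integers:
// 1 = diagonal, 2 = gap in A (advance B only), 3 = gap in B (advance A only),
// ordered from the start of the alignment.

static const double NEG_INF = -1e30;

// [[Rcpp::export]]
List gotoh_align(NumericMatrix S, double gap_open, double gap_extend,
                 Nullable<NumericVector> wa_ = R_NilValue,
                 Nullable<NumericVector> wb_ = R_NilValue) {
  const int n = S.nrow();  // columns of A
  const int m = S.ncol();  // columns of B

  NumericVector wa = wa_.isNotNull() ? NumericVector(wa_) : NumericVector(n, 1.0);
  NumericVector wb = wb_.isNotNull() ? NumericVector(wb_) : NumericVector(m, 1.0);
  if (wa.size() != n || wb.size() != m) stop("gap-weight length mismatch");

  // M: end in match; X: end with gap in B (A advances); Y: gap in A.
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);

  // per-column gap costs (charged when the column is consumed by a gap)
  std::vector<double> open_a(n), ext_a(n), open_b(m), ext_b(m);
  for (int i = 0; i < n; ++i) {
    open_a[i] = (gap_open + gap_extend) * wa[i];
    ext_a[i] = gap_extend * wa[i];
  }
  for (int j = 0; j < m; ++j) {
    open_b[j] = (gap_open + gap_extend) * wb[j];
    ext_b[j] = gap_extend * wb[j];
  }

  M(0, 0) = 0.0;
  X(0, 0) = Y(0, 0) = NEG_INF;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG_INF;
    Y(i, 0) = NEG_INF;
    X(i, 0) = (i == 1 ? -open_a[0] : X(i - 1, 0) - ext_a[i - 1]);
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG_INF;
    X(0, j) = NEG_INF;
    Y(0, j) = (j == 1 ? -open_b[0] : Y(0, j - 1) - ext_b[j - 1]);
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double best_prev = M(i - 1, j - 1);
      if (Y(i - 1, j - 1) > best_prev) best_prev = Y(i - 1, j - 1);
      if (X(i - 1, j - 1) > best_prev) best_prev = X(i - 1, j - 1);
      M(i, j) = best_prev + S(i - 1, j - 1);

      // X: gap in B consumes A column i-1
      double from_m = M(i - 1, j) - open_a[i - 1];
      double from_x = X(i - 1, j) - ext_a[i - 1];
      double from_y = Y(i - 1, j) - open_a[i - 1];
      X(i, j) = std::max(from_m, std::max(from_x, from_y));

      // Y: gap in A consumes B column j-1
      double fm = M(i, j - 1) - open_b[j - 1];
      double fy = Y(i, j - 1) - ext_b[j - 1];
      double fx = X(i, j - 1) - open_b[j - 1];
      Y(i, j) = std::max(fm, std::max(fy, fx));
    }
  }

  double score = M(n, m);
  int state = 0;  // 0 = M, 1 = Y (gap in A), 2 = X (gap in B); preference order
  if (Y(n, m) > score) { score = Y(n, m); state = 1; }
  if (X(n, m) > score) { score = X(n, m); state = 2; }

  std::vector<int> path;
  path.reserve(n + m);
  int i = n, j = m;
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    if (i == 0) { path.push_back(2); --j; continue; }
    if (j == 0) { path.push_back(3); --i; continue; }
    if (state == 0) {
      path.push_back(1);
      double target = M(i, j) - S(i - 1, j - 1);
      --i; --j;
      if (std::abs(M(i, j) - target) < eps) state = 0;
      else if (std::abs(Y(i, j) - target) < eps) state = 1;
      else state = 2;
    } else if (state == 1) {  // gap in A, consumed B column j-1
      path.push_back(2);
      double target = Y(i, j);
      double oc = open_b[j - 1], ec = ext_b[j - 1];
      --j;
      if (std::abs(M(i, j) - (target + oc)) < eps) state = 0;
      else if (std::abs(Y(i, j) - (target + ec)) < eps) state = 1;
      else state = 2;
    } else {  // gap in B, consumed A column i-1
      path.push_back(3);
      double target = X(i, j);
      double oc = open_a[i - 1], ec = ext_a[i - 1];
      --i;
      if (std::abs(M(i, j) - (target + oc)) < eps) state = 0;
      else if (std::abs(X(i, j) - (target + ec)) < eps) state = 2;
      else state = 1;
    }
  }
  std::reverse(path.begin(), path.end());
  return List::create(_["score"] = score,
                      _["path"] = IntegerVector(path.begin(), path.end()));
}
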