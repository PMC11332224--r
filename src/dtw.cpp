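#include <Rcpp.h>
using namespace Rcpp;

// Classic dynamic time warping with symmetric steps
// (diagonal/horizontal/vertical), Euclidean local cost over feature rows,
// total path cost divided by path length. Ties in the backtrack prefer the
// diagonal step, giving the shortest path among minimum-cost paths.
// [[Rcpp::export(name = ".dtw_core")]]
double dtw_core(NumericMatrix a, NumericMatrix b) {
  const int n = a.nrow(), m = b.nrow(), p = a.ncol();
  if (n == 0 || m == 0) stop("empty contour");
  if (b.ncol() != p) stop("feature dimension mismatch");

  NumericMatrix cost(n, m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int k = 0; k < p; ++k) {
        double d = a(i, k) - b(j, k);
        s += d * d;
      }
      cost(i, j) = std::sqrt(s);
    }
  }

  NumericMatrix D(n, m);
  IntegerMatrix from(n, m); // 0 = diag, 1 = up (i-1), 2 = left (j-1)
  D(0, 0) = cost(0, 0);
  for (int i = 1; i < n; ++i) { D(i, 0) = D(i - 1, 0) + cost(i, 0); from(i, 0) = 1; }
  for (int j = 1; j < m; ++j) { D(0, j) = D(0, j - 1) + cost(0, j); from(0, j) = 2; }
  for (int i = 1; i < n; ++i) {
    for (int j = 1; j < m; ++j) {
      double dd = D(i - 1, j - 1), du = D(i - 1, j), dl = D(i, j - 1);
      double best = dd; int arg = 0;
      if (du < best) { best = du; arg = 1; }
      if (dl < best) { best = dl; arg = 2; }
      D(i, j) = best + cost(i, j);
      from(i, j) = arg;
    }
  }

  int i = n - 1, j = m - 1, len = 1;
  while (i > 0 || j > 0) {
    int f = from(i, j);
    if (f == 0) { --i; --j; }
    else if (f == 1) { --i; }
    else { --j; }
    ++len;
  }
  return D(n - 1, m - 1) / len;
}
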