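#include <Rcpp.h>
using namespace Rcpp;

// Cubic smoothing spline at the knots (Reinsch / Green-Silverman formulation).
// Minimises sum_i (y_i - f_i)^2 + lambda * int f''(t)^2 dt over natural cubic
// splines with knots at the strictly increasing x. Returns fitted values f and
// second derivatives M at every knot (M[0] = M[n-1] = 0, natural boundary).
// The interior system (R + lambda Q'Q) gamma = Q'y is symmetric positive
// definite and pentadiagonal; solved by banded LDL' in O(n).
// [[Rcpp::export(name = ".reinsch_fit_cpp")]]
List reinsch_fit_cpp(NumericVector x, NumericVector y, double lambda) {
  int n = x.size();
  if (y.size() != n) stop("x and y lengths differ");
  if (n < 2) stop("need at least 2 points");
  if (lambda < 0) stop("lambda must be nonnegative");
  NumericVector f(n), M(n);
  if (n == 2) { // no curvature possible: straight line through the points
    f[0] = y[0]; f[1] = y[1];
    return List::create(_["f"] = f, _["M"] = M);
  }
  int m = n - 2;
  std::vector<double> h(n - 1), p(n - 1);
  for (int i = 0; i < n - 1; ++i) {
    h[i] = x[i + 1] - x[i];
    if (h[i] <= 0) stop("x must be strictly increasing");
    p[i] = 1.0 / h[i];
  }
  // Q has column c (c = 0..m-1) with nonzeros at rows c, c+1, c+2:
  //   a_c = 1/h_c,  b_c = -(1/h_c + 1/h_{c+1}),  d_c = 1/h_{c+1}
  std::vector<double> a(m), b(m), d(m);
  for (int c = 0; c < m; ++c) {
    a[c] = p[c];
    b[c] = -(p[c] + p[c + 1]);
    d[c] = p[c + 1];
  }
  // A = R + lambda * Q'Q, pentadiagonal symmetric: diagonals D0, D1, D2
  std::vector<double> D0(m), D1(std::max(m - 1, 0)), D2(std::max(m - 2, 0)), r(m);
  for (int c = 0; c < m; ++c) {
    D0[c] = lambda * (a[c] * a[c] + b[c] * b[c] + d[c] * d[c]) +
            (h[c] + h[c + 1]) / 3.0;
    r[c] = a[c] * y[c] + b[c] * y[c + 1] + d[c] * y[c + 2];
  }
  for (int c = 0; c + 1 < m; ++c)
    D1[c] = lambda * (b[c] * a[c + 1] + d[c] * b[c + 1]) + h[c + 1] / 6.0;
  for (int c = 0; c + 2 < m; ++c)
    D2[c] = lambda * d[c] * a[c + 2];
  // banded LDL' factorisation, bandwidth 2 (in place: D0 -> D, D1/D2 -> L)
  for (int i = 0; i < m; ++i) {
    double di = D0[i];
    if (i >= 1) di -= D1[i - 1] * D1[i - 1] * D0[i - 1];
    if (i >= 2) di -= D2[i - 2] * D2[i - 2] * D0[i - 2];
    if (di <= 0) stop("banded factorisation failed (system not SPD)");
    D0[i] = di;
    if (i + 1 < m) {
      double l1 = D1[i];
      if (i >= 1) l1 -= D1[i - 1] * D0[i - 1] * D2[i - 1];
      D1[i] = l1 / di;
    }
    if (i + 2 < m) D2[i] = D2[i] / di;
  }
  // solve L z = r, D u = z, L' gamma = u
  std::vector<double> g(m);
  for (int i = 0; i < m; ++i) {
    double zi = r[i];
    if (i >= 1) zi -= D1[i - 1] * g[i - 1];
    if (i >= 2) zi -= D2[i - 2] * g[i - 2];
    g[i] = zi;
  }
  for (int i = 0; i < m; ++i) g[i] /= D0[i];
  for (int i = m - 1; i >= 0; --i) {
    double gi = g[i];
    if (i + 1 < m) gi -= D1[i] * g[i + 1];
    if (i + 2 < m) gi -= D2[i] * g[i + 2];
    g[i] = gi;
  }
  // f = y - lambda * Q gamma
  for (int i = 0; i < n; ++i) {
    double qg = 0.0;
    if (i >= 2 && i - 2 < m) qg += d[i - 2] * g[i - 2];
    if (i >= 1 && i - 1 < m) qg += b[i - 1] * g[i - 1];
    if (i < m) qg += a[i] * g[i];
    f[i] = y[i] - lambda * qg;
  }
  for (int i = 1; i <= n - 2; ++i) M[i] = g[i - 1];
  return List::create(_["f"] = f, _["M"] = M);
}

// Evaluate a natural cubic spline given knots x, values f and second
// derivatives M; linear extrapolation beyond the boundary knots.
// [[Rcpp::export(name = ".spline_eval_cpp")]]
NumericVector spline_eval_cpp(NumericVector x, NumericVector f,
                              NumericVector M, NumericVector t) {
  int n = x.size();
  if (f.size() != n || M.size() != n) stop("x, f, M lengths differ");
  if (n < 2) stop("need at least 2 knots");
  int nt = t.size();
  NumericVector out(nt);
  double h0 = x[1] - x[0], hn = x[n - 1] - x[n - 2];
  double s0 = (f[1] - f[0]) / h0 - h0 * (2.0 * M[0] + M[1]) / 6.0;
  double sn = (f[n - 1] - f[n - 2]) / hn + hn * (M[n - 2] + 2.0 * M[n - 1]) / 6.0;
  for (int k = 0; k < nt; ++k) {
    double tk = t[k];
    if (tk <= x[0]) { out[k] = f[0] + s0 * (tk - x[0]); continue; }
    if (tk >= x[n - 1]) { out[k] = f[n - 1] + sn * (tk - x[n - 1]); continue; }
    // binary search for interval i with x[i] <= tk < x[i+1]
    int lo = 0, hi = n - 1;
    while (hi - lo > 1) {
      int mid = (lo + hi) / 2;
      if (x[mid] <= tk) lo = mid; else hi = mid;
    }
    double h = x[lo + 1] - x[lo], u = tk - x[lo], v = x[lo + 1] - tk;
    out[k] = M[lo] * v * v * v / (6.0 * h) + M[lo + 1] * u * u * u / (6.0 * h) +
             (f[lo] / h - M[lo] * h / 6.0) * v +
             (f[lo + 1] / h - M[lo + 1] * h / 6.0) * u;
  }
  return out;
}
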