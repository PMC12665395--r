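// Dip statistic: minimal sup-norm distance between the ECDF and a unimodal
// CDF (convex, then an optional jump at the mode, then concave), with the
// mode searched over observed values and gap midpoints.
//
// For a trial distance e, each point x_i carries a box
//   [A_i - e, A_{i-1} + e]
// that any admissible CDF must pass through (A_i = ECDF at x_i, A_0 = 0).
// A mode candidate splits the points into a convex prefix and a concave
// suffix, each ending at a mode anchor box; a side is feasible iff the
// greatest convex minorant of its upper bounds stays above its lower bounds
// (mirrored for the concave side), and the two sides connect iff the lowest
// reachable prefix end value does not exceed the highest reachable suffix
// start value.  Bisection on e yields the dip.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// Feasibility of a convex nondecreasing function through boxes
// (x[0..p-1], lo, hi) plus terminal anchor (xa, la, ha).
// Returns feasibility; if feasible, *tmin = minimal achievable terminal value.
// s[i] = max slope from any earlier upper corner to (x[i], lo[i]) (precomputed
// for the normal boxes, shared across mode candidates).
static bool left_side(const std::vector<double>& x,
                      const std::vector<double>& lo,
                      const std::vector<double>& hi,
                      const std::vector<double>& s,
                      int p, double xa, double la, double ha,
                      double* tmin) {
  if (p == 0) { *tmin = la; return la <= ha + 1e-14; }
  // quick box sanity
  // hull over points 0..p-1 with upper bounds hi, then anchor (xa, ha)
  std::vector<int> hv; hv.reserve(p + 1);
  std::vector<double> hx(p + 1), hy(p + 1);
  for (int i = 0; i <= p; ++i) {
    double xi = (i < p) ? x[i] : xa;
    double yi = (i < p) ? hi[i] : ha;
    hx[i] = xi; hy[i] = yi;
    while (hv.size() >= 2) {
      int i1 = hv[hv.size() - 2], i2 = hv[hv.size() - 1];
      // keep if slope(i1,i2) <= slope(i2,i)
      if ((hy[i2] - hy[i1]) * (xi - hx[i2]) <= (yi - hy[i2]) * (hx[i2] - hx[i1]))
        break;
      hv.pop_back();
    }
    hv.push_back(i);
  }
  // evaluate hull at every point, compare with lo
  {
    size_t seg = 0;
    for (int i = 0; i <= p; ++i) {
      double need = (i < p) ? lo[i] : la;
      while (seg + 1 < hv.size() && hx[hv[seg + 1]] < hx[i]) ++seg;
      double val;
      int a = hv[seg];
      if (hx[i] <= hx[a]) val = hy[a];
      else {
        int b = hv[seg + 1 < hv.size() ? seg + 1 : seg];
        val = (b == a || hx[b] == hx[a]) ? hy[a]
            : hy[a] + (hy[b] - hy[a]) * (hx[i] - hx[a]) / (hx[b] - hx[a]);
      }
      if (val < need - 1e-12) return false;
    }
  }
  // minimal terminal value: monotonicity floor + convex extrapolation bounds
  double t = la;
  if (t < lo[p - 1]) t = lo[p - 1];
  for (int i2 = 1; i2 < p; ++i2) {
    if (s[i2] == NEG_INF) continue;
    double b = lo[i2] + s[i2] * (xa - x[i2]);
    if (b > t) t = b;
  }
  *tmin = t;
  return t <= ha + 1e-12;
}

struct Sides {
  std::vector<char> feas;   // per candidate
  std::vector<double> bound; // tmin (left) or -umax (right)
};

// Evaluate all mode candidates' left sides for trial e.
// Candidates: c = 0..m-1 -> mode at point c; c = m..2m-2 -> midpoint after c-m.
static void all_left(const std::vector<double>& x,
                     const std::vector<double>& A,
                     const std::vector<double>& A0,
                     double e, Sides* out) {
  int m = (int)x.size();
  std::vector<double> lo(m), hi(m);
  for (int i = 0; i < m; ++i) { lo[i] = A[i] - e; hi[i] = A0[i] + e; }
  // s[i2]: max slope from (x[i1], hi[i1]) to (x[i2], lo[i2]), i1 < i2
  std::vector<double> s(m, NEG_INF);
  for (int i2 = 1; i2 < m; ++i2) {
    double best = NEG_INF;
    for (int i1 = 0; i1 < i2; ++i1) {
      double sl = (lo[i2] - hi[i1]) / (x[i2] - x[i1]);
      if (sl > best) best = sl;
    }
    s[i2] = best;
  }
  out->feas.assign(2 * m - 1, 0);
  out->bound.assign(2 * m - 1, 0.0);
  double t;
  for (int j = 0; j < m; ++j) {  // mode at point j: prefix 0..j-1, anchor A0[j] +- e
    bool ok = left_side(x, lo, hi, s, j, x[j], A0[j] - e, A0[j] + e, &t);
    out->feas[j] = ok; out->bound[j] = t;
  }
  for (int k = 0; k + 1 < m; ++k) { // midpoint mode: prefix 0..k, anchor A[k] +- e
    double xm = 0.5 * (x[k] + x[k + 1]);
    bool ok = left_side(x, lo, hi, s, k + 1, xm, A[k] - e, A[k] + e, &t);
    out->feas[m + k] = ok; out->bound[m + k] = t;
  }
}

static bool feasible(const std::vector<double>& x,
                     const std::vector<double>& A,
                     const std::vector<double>& A0,
                     double e) {
  int m = (int)x.size();
  Sides L;
  all_left(x, A, A0, e, &L);
  // right side by mirror: y = -x reversed, G' = 1 - G
  std::vector<double> xr(m), Ar(m), A0r(m);
  for (int i = 0; i < m; ++i) {
    xr[i] = -x[m - 1 - i];
    // G' at xr[i] corresponds to 1 - G at x[m-1-i]; ECDF of mirrored sample:
    // jump at xr[i] has mass of point m-1-i; cumulative after = 1 - A0[m-1-i]
    Ar[i] = 1.0 - A0[m - 1 - i];
    A0r[i] = 1.0 - A[m - 1 - i];
  }
  Sides R;
  all_left(xr, Ar, A0r, e, &R);
  // mirrored candidate for mode at point j (orig) = point m-1-j; midpoint after k
  // (orig, between k,k+1) = mirrored midpoint between (m-2-k, m-1-k) = index m-2-k.
  for (int j = 0; j < m; ++j) {
    int jr = m - 1 - j;
    if (L.feas[j] && R.feas[jr]) {
      double umax = 1.0 - R.bound[jr];
      if (L.bound[j] <= umax + 1e-12) return true;
    }
  }
  for (int k = 0; k + 1 < m; ++k) {
    int kr = m - 2 - k;
    if (L.feas[m + k] && R.feas[m + kr]) {
      double umax = 1.0 - R.bound[m + kr];
      if (L.bound[m + k] <= umax + 1e-12) return true;
    }
  }
  return false;
}

// [[Rcpp::export]]
double dip_stat_cpp(NumericVector xv, NumericVector av) {
  int m = xv.size();
  if (m <= 1) return 0.0;
  std::vector<double> x(xv.begin(), xv.end());
  std::vector<double> A(av.begin(), av.end());
  std::vector<double> A0(m);
  A0[0] = 0.0;
  for (int i = 1; i < m; ++i) A0[i] = A[i - 1];
  double lo = 0.0, hi = 0.2500001;
  if (feasible(x, A, A0, lo + 1e-13)) return 0.0;
  for (int it = 0; it < 42; ++it) {
    double mid = 0.5 * (lo + hi);
    if (feasible(x, A, A0, mid)) hi = mid; else lo = mid;
  }
  return 0.5 * (lo + hi);
}

// Dips of n_mc uniform(0,1) samples of size n (uses R's RNG).
// [[Rcpp::export]]
NumericVector dip_null_cpp(int n, int n_mc) {
  NumericVector out(n_mc);
  for (int r = 0; r < n_mc; ++r) {
    NumericVector u = runif(n);
    std::sort(u.begin(), u.end());
    NumericVector a(n);
    for (int i = 0; i < n; ++i) a[i] = (i + 1.0) / n;
    out[r] = dip_stat_cpp(u, a);
  }
  return out;
}
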