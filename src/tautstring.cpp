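#include <Rcpp.h>
#include <deque>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Taut string through a tube around the running-sum curve R_i = sum_{u<=i} r_u.
//
// The tube at interior position i (1 <= i <= n-1) has lower bound R_i - theta_i
// and upper bound R_i + theta_i; both endpoints are pinned: s_0 = 0, s_n = R_n.
// The shortest (taut) string through the tube is computed left to right with
// the greatest convex minorant (GCM) of the upper bounds and the least concave
// majorant (LCM) of the lower bounds; a knot is emitted where the two envelopes
// cross, and the walk restarts from the knot.  The derivative f_i = s_i -
// s_{i-1} is the exact minimizer of
//    (1/2) sum (r_i - f_i)^2 + theta * sum |f_{i+1} - f_i|
// when theta is a constant tube radius.
//
// Hull bookkeeping: hull vertices are base-independent (a convex chain stays a
// convex chain when its first vertex becomes the new knot), so the hull whose
// vertex becomes the knot only drops its front; the opposite hull is rebuilt
// from the raw bound array over the span (knot, i].

struct TsPt {
  double x, y;
};

static inline double ts_slope(const TsPt &a, const TsPt &b) {
  return (b.y - a.y) / (b.x - a.x);
}

// [[Rcpp::export(name = ".taut_string_tube")]]
NumericVector taut_string_tube(NumericVector r, NumericVector theta) {
  const int n = r.size();
  if (n < 1) stop("empty signal");
  if ((int)theta.size() != n) stop("theta must have length n");

  std::vector<double> R(n + 1), up(n + 1), lo(n + 1);
  R[0] = 0.0;
  for (int i = 0; i < n; ++i) {
    if (theta[i] < 0) stop("negative tube radius");
    R[i + 1] = R[i] + r[i];
  }
  up[0] = lo[0] = 0.0;
  for (int i = 1; i < n; ++i) {
    up[i] = R[i] + theta[i - 1];
    lo[i] = R[i] - theta[i - 1];
  }
  up[n] = lo[n] = R[n];  // pinned right endpoint

  NumericVector f(n);
  double kx = 0.0, ky = 0.0;  // current knot
  std::deque<TsPt> U, L;      // hull vertices strictly after the knot

  auto push_upper = [&](TsPt p) {
    while (!U.empty()) {
      TsPt a = (U.size() >= 2) ? U[U.size() - 2] : TsPt{kx, ky};
      if (ts_slope(a, U.back()) >= ts_slope(U.back(), p))
        U.pop_back();
      else
        break;
    }
    U.push_back(p);
  };
  auto push_lower = [&](TsPt p) {
    while (!L.empty()) {
      TsPt a = (L.size() >= 2) ? L[L.size() - 2] : TsPt{kx, ky};
      if (ts_slope(a, L.back()) <= ts_slope(L.back(), p))
        L.pop_back();
      else
        break;
    }
    L.push_back(p);
  };
  auto rebuild_upper = [&](int upto) {
    U.clear();
    for (int x = (int)kx + 1; x <= upto; ++x) push_upper(TsPt{(double)x, up[x]});
  };
  auto rebuild_lower = [&](int upto) {
    L.clear();
    for (int x = (int)kx + 1; x <= upto; ++x) push_lower(TsPt{(double)x, lo[x]});
  };
  auto emit_to = [&](double vx, double vy) {
    double sl = (vy - ky) / (vx - kx);
    for (int x = (int)kx + 1; x <= (int)vx; ++x) f[x - 1] = sl;
    kx = vx;
    ky = vy;
  };

  for (int i = 1; i <= n; ++i) {
    push_upper(TsPt{(double)i, up[i]});
    push_lower(TsPt{(double)i, lo[i]});
    for (;;) {
      if (U.empty() || L.empty()) break;
      double a = ts_slope(TsPt{kx, ky}, U.front());
      double b = ts_slope(TsPt{kx, ky}, L.front());
      if (a >= b) break;  // funnel still open
      TsPt fu = U.front(), fl = L.front();
      if (fu.x < fl.x) {
        emit_to(fu.x, fu.y);
        U.pop_front();
        rebuild_lower(i);
      } else if (fl.x < fu.x) {
        emit_to(fl.x, fl.y);
        L.pop_front();
        rebuild_upper(i);
      } else {
        // same abscissa: tube radius zero there, single knot
        emit_to(fu.x, fu.y);
        U.pop_front();
        L.pop_front();
        rebuild_upper(i);
        rebuild_lower(i);
      }
    }
  }
  if ((int)kx < n) emit_to((double)n, R[n]);
  return f;
}
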