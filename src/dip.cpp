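// Hartigan & Hartigan dip statistic.
//
// The dip of an empirical CDF F_n is the smallest sup-norm distance from
// F_n to any unimodal CDF (convex up to the mode, concave after; an atom at
// the mode is allowed).  Writing the sample as unique sorted values u_1 <
// ... < u_m with b_i = #(x < u_i) and c_i = #(x <= u_i), a candidate mode
// at u_j is feasible at sup-distance d iff
//
//   (left)  the greatest convex minorant H of the points (u_i, b_i), i <= j,
//           satisfies c_i - H(u_i) <= 2 d n for every i < j, and
//   (right) the least concave majorant U of (u_j, c_j) and (u_i, c_i),
//           i > j, satisfies U(u_i) - b_i <= 2 d n for every i > j.
//
// A mode strictly inside a gap (u_j, u_{j+1}) adds the virtual hull point
// (mode, c_j) on both sides; as the mode slides across the gap the left
// requirement is non-decreasing and the right one non-increasing, so the
// max of the two is quasiconvex and the in-gap minimum is found by ternary
// search.  Gaps are only searched when a cheap lower bound beats the best
// data-point mode.  The dip is half the smallest max(left, right), in ECDF
// units.

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

namespace {

// Greatest-convex-minorant sweep: DL[j] = max_{i<j} (c_i - H_j(u_i)) where
// H_j is the lower hull of (u_i, b_i), i <= j.  Count units.
std::vector<double> dl_sweep(const std::vector<double>& u,
                             const std::vector<double>& b,
                             const std::vector<double>& c) {
  const int m = (int) u.size();
  std::vector<double> DL(m, 0.0);
  std::vector<int> st;
  st.reserve(m);
  st.push_back(0);
  double running = 0.0;
  for (int j = 1; j < m; ++j) {
    while (st.size() >= 2) {
      int p2 = st[st.size() - 1], p1 = st[st.size() - 2];
      double cr = (u[p2] - u[p1]) * (b[j] - b[p1]) -
                  (b[p2] - b[p1]) * (u[j] - u[p1]);
      if (cr <= 0) st.pop_back(); else break;
    }
    int a = st.back();
    if (a == j - 1) {
      double dev = c[j - 1] - b[j - 1];
      if (dev > running) running = dev;
    } else {
      for (int i = a + 1; i < j; ++i) {
        double hv = b[a] + (b[j] - b[a]) * (u[i] - u[a]) / (u[j] - u[a]);
        double dev = c[i] - hv;
        if (dev > running) running = dev;
      }
    }
    st.push_back(j);
    DL[j] = running;
  }
  return DL;
}

// Left requirement for a mode at position pos inside the gap just right of
// index j: lower hull of (u_i, b_i), i <= j, plus the virtual point
// (pos, c_j); deviations checked at i <= j.
double dl_gap(const std::vector<double>& u,
              const std::vector<double>& b,
              const std::vector<double>& c,
              int j, double pos) {
  std::vector<int> st;
  st.reserve(j + 2);
  std::vector<double> ux(u.begin(), u.begin() + (j + 1));
  std::vector<double> yx(b.begin(), b.begin() + (j + 1));
  ux.push_back(pos);
  yx.push_back(c[j]);
  const int np = (int) ux.size();
  st.push_back(0);
  for (int k = 1; k < np; ++k) {
    while (st.size() >= 2) {
      int p2 = st[st.size() - 1], p1 = st[st.size() - 2];
      double cr = (ux[p2] - ux[p1]) * (yx[k] - yx[p1]) -
                  (yx[p2] - yx[p1]) * (ux[k] - ux[p1]);
      if (cr <= 0) st.pop_back(); else break;
    }
    st.push_back(k);
  }
  // evaluate hull at every real point and take max deviation vs c
  double dev = 0.0;
  int seg = 0;
  for (int i = 0; i <= j; ++i) {
    while (seg + 1 < (int) st.size() - 1 && ux[st[seg + 1]] <= ux[i]) ++seg;
    int p1 = st[seg], p2 = st[seg + 1];
    double hv;
    if (ux[p2] == ux[p1]) hv = std::min(yx[p1], yx[p2]);
    else hv = yx[p1] + (yx[p2] - yx[p1]) * (ux[i] - ux[p1]) / (ux[p2] - ux[p1]);
    if (yx[i] < hv) hv = yx[i];  // points on the hull evaluate to themselves
    double d = c[i] - hv;
    if (d > dev) dev = d;
  }
  return dev;
}

struct Collapsed {
  std::vector<double> u, b, c;   // unique values, counts below / through
  int n;
};

Collapsed collapse(std::vector<double> x) {
  std::sort(x.begin(), x.end());
  Collapsed out;
  out.n = (int) x.size();
  int i = 0;
  while (i < out.n) {
    int j = i;
    while (j < out.n && x[j] == x[i]) ++j;
    out.u.push_back(x[i]);
    out.b.push_back((double) i);
    out.c.push_back((double) j);
    i = j;
  }
  return out;
}

Collapsed reflect(const Collapsed& s) {
  Collapsed r;
  r.n = s.n;
  const int m = (int) s.u.size();
  for (int i = m - 1; i >= 0; --i) {
    r.u.push_back(-s.u[i]);
    r.b.push_back(s.n - s.c[i]);
    r.c.push_back(s.n - s.b[i]);
  }
  return r;
}

}  // namespace

//' Dip statistic of a numeric sample (internal C++ kernel)
//'
//' @param x numeric vector, length >= 4 after removing non-finite values
//' @return the dip statistic, between 0 and 0.25
//' @keywords internal
// [[Rcpp::export(name = ".dip_stat_cpp")]]
double dip_stat_cpp(NumericVector x) {
  std::vector<double> v(x.begin(), x.end());
  const int n = (int) v.size();
  if (n < 4) stop("dip statistic requires at least 4 observations");
  Collapsed s = collapse(v);
  const int m = (int) s.u.size();
  if (m == 1) return 0.0;
  Collapsed r = reflect(s);

  std::vector<double> DL = dl_sweep(s.u, s.b, s.c);
  std::vector<double> DLr = dl_sweep(r.u, r.b, r.c);
  std::vector<double> DU(m);
  for (int j = 0; j < m; ++j) DU[j] = DLr[m - 1 - j];

  double best = R_PosInf;
  for (int j = 0; j < m; ++j) {
    double f = std::max(DL[j], DU[j]);
    if (f < best) best = f;
  }

  // in-gap modes: refine only where the endpoint lower bound can improve
  for (int j = 0; j + 1 < m; ++j) {
    double tie_j = s.c[j] - s.b[j];
    double tie_j1 = s.c[j + 1] - s.b[j + 1];
    double lb = std::max(std::max(DL[j], tie_j), std::max(DU[j + 1], tie_j1));
    if (lb >= best - 1e-12) continue;
    double lo = s.u[j], hi = s.u[j + 1];
    for (int it = 0; it < 80; ++it) {
      double m1 = lo + (hi - lo) / 3.0, m2 = hi - (hi - lo) / 3.0;
      double f1 = std::max(dl_gap(s.u, s.b, s.c, j, m1),
                           dl_gap(r.u, r.b, r.c, m - 2 - j, -m1));
      double f2 = std::max(dl_gap(s.u, s.b, s.c, j, m2),
                           dl_gap(r.u, r.b, r.c, m - 2 - j, -m2));
      if (f1 < f2) hi = m2; else lo = m1;
    }
    double mid = (lo + hi) / 2.0;
    double f = std::max(dl_gap(s.u, s.b, s.c, j, mid),
                        dl_gap(r.u, r.b, r.c, m - 2 - j, -mid));
    if (f < best) best = f;
  }

  return best / (2.0 * n);
}
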