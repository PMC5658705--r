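#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 4- or 8-connected component labeling of a binary mask.
// Returns an integer matrix: 0 background, components numbered 1..K in
// scan order (column-major, as R stores matrices).
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity = 4) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<std::pair<int,int> > stack;
  const int dr4[] = {-1, 1, 0, 0}, dc4[] = {0, 0, -1, 1};
  const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1}, dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int *dr = connectivity == 8 ? dr8 : dr4;
  const int *dc = connectivity == 8 ? dc8 : dc4;
  int nn = connectivity == 8 ? 8 : 4;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(r, c));
      lab(r, c) = next;
      while (!stack.empty()) {
        std::pair<int,int> p = stack.back(); stack.pop_back();
        for (int k = 0; k < nn; ++k) {
          int rr = p.first + dr[k], cc = p.second + dc[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back(std::make_pair(rr, cc));
          }
        }
      }
    }
  }
  return lab;
}

// 1-D squared distance transform (Felzenszwalb & Huttenlocher).
static void dt1d(const std::vector<double> &f, std::vector<double> &d) {
  int n = (int) f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -INFINITY; z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double) q) - (f[v[k]] + v[k] * (double) v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// Exact squared Euclidean distance to the nearest background (FALSE) pixel.
// [[Rcpp::export]]
NumericMatrix cpp_edt_sq(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  const double INF = 1e20;
  NumericMatrix g(nr, nc);
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) f[r] = mask(r, c) ? INF : 0.0;
    dt1d(std::vector<double>(f.begin(), f.begin() + nr), d);
    for (int r = 0; r < nr; ++r) g(r, c) = d[r];
  }
  NumericMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) f[c] = g(r, c);
    dt1d(std::vector<double>(f.begin(), f.begin() + nc), d);
    for (int c = 0; c < nc; ++c) out(r, c) = d[c];
  }
  return out;
}

struct WsNode {
  double prio; long order; int r, c, lab;
};
struct WsCmp {
  bool operator()(const WsNode &a, const WsNode &b) const {
    if (a.prio != b.prio) return a.prio > b.prio;
    return a.order > b.order;
  }
};

// Marker-based watershed: flood `mask` from `markers` in increasing order of
// `priority` (use the negated distance transform to split touching cells).
// [[Rcpp::export]]
IntegerMatrix cpp_watershed(NumericMatrix priority, IntegerMatrix markers,
                            LogicalMatrix mask) {
  int nr = priority.nrow(), nc = priority.ncol();
  IntegerMatrix lab(nr, nc);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  long order = 0;
  const int dr[] = {-1, 1, 0, 0}, dc[] = {0, 0, -1, 1};
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (markers(r, c) > 0 && mask(r, c)) {
        lab(r, c) = markers(r, c);
        WsNode n = {priority(r, c), order++, r, c, markers(r, c)};
        pq.push(n);
      }
  while (!pq.empty()) {
    WsNode n = pq.top(); pq.pop();
    for (int k = 0; k < 4; ++k) {
      int rr = n.r + dr[k], cc = n.c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (!mask(rr, cc) || lab(rr, cc) != 0) continue;
      lab(rr, cc) = n.lab;
      WsNode m = {priority(rr, cc), order++, rr, cc, n.lab};
      pq.push(m);
    }
  }
  return lab;
}

// One radius of the fast radial symmetry transform, bright polarity only.
// Each pixel with gradient magnitude above gthresh votes at
// p + round(radius * ghat), where ghat points up the intensity gradient
// (towards the bright center). Returns the orientation-count image O and
// the gradient-magnitude image M.
// [[Rcpp::export]]
List cpp_frst_vote(NumericMatrix gr, NumericMatrix gc, int radius,
                   double gthresh) {
  int nr = gr.nrow(), nc = gr.ncol();
  NumericMatrix O(nr, nc), M(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double gx = gr(r, c), gy = gc(r, c);
      double g = std::sqrt(gx * gx + gy * gy);
      if (g <= gthresh) continue;
      int vr = r + (int) std::lround(radius * gx / g);
      int vc = c + (int) std::lround(radius * gy / g);
      if (vr < 0 || vr >= nr || vc < 0 || vc >= nc) continue;
      O(vr, vc) += 1.0;
      M(vr, vc) += g;
    }
  }
  return List::create(_["O"] = O, _["M"] = M);
}

// Local maxima: pixel equals the maximum of its (2*radius+1)^2 window.
// [[Rcpp::export]]
LogicalMatrix cpp_local_maxima(NumericMatrix img, int radius) {
  int nr = img.nrow(), nc = img.ncol();
  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double v = img(r, c);
      bool ismax = true;
      for (int dc2 = -radius; dc2 <= radius && ismax; ++dc2) {
        for (int dr2 = -radius; dr2 <= radius; ++dr2) {
          int rr = r + dr2, cc = c + dc2;
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (img(rr, cc) > v) { ismax = false; break; }
        }
      }
      out(r, c) = ismax;
    }
  }
  return out;
}
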