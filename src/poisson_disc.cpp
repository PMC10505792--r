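#include <Rcpp.h>
using namespace Rcpp;

// Poisson-disc sampling inside a disc of radius R (centered at origin) with
// minimum pairwise separation s: Bridson's annulus dart-throwing followed by
// a random-sequential-adsorption densification pass that fills residual gaps.
// Uses R's RNG so that set.seed() upstream makes results reproducible.

namespace {

struct Grid {
  double cell, R;
  int ncell;
  std::vector<int> idx; // -1 empty; cell size < s/sqrt(2) => at most one point
  Grid(double R_, double s) : cell(s / std::sqrt(2.0)), R(R_) {
    ncell = (int)std::ceil(2.0 * R / cell) + 1;
    idx.assign((size_t)ncell * ncell, -1);
  }
  inline int cx(double x) const {
    int c = (int)std::floor((x + R) / cell);
    if (c < 0) c = 0;
    if (c >= ncell) c = ncell - 1;
    return c;
  }
  inline int at(int i, int j) const { return idx[(size_t)i * ncell + j]; }
  inline void set(int i, int j, int v) { idx[(size_t)i * ncell + j] = v; }
};

inline bool farEnough(const Grid &g, const std::vector<double> &px,
                      const std::vector<double> &py, double x, double y,
                      double s2) {
  int ci = g.cx(x), cj = g.cx(y);
  int i0 = std::max(0, ci - 2), i1 = std::min(g.ncell - 1, ci + 2);
  int j0 = std::max(0, cj - 2), j1 = std::min(g.ncell - 1, cj + 2);
  for (int i = i0; i <= i1; ++i)
    for (int j = j0; j <= j1; ++j) {
      int p = g.at(i, j);
      if (p >= 0) {
        double dx = px[p] - x, dy = py[p] - y;
        if (dx * dx + dy * dy < s2) return false;
      }
    }
  return true;
}

} // namespace

// [[Rcpp::export(name = ".poissonDiscDisc")]]
NumericMatrix poissonDiscDisc(double R, double s, int k = 30,
                              int densifyAttempts = 60000) {
  if (R <= 0 || s <= 0) stop("R and s must be positive");
  Grid g(R, s);
  std::vector<double> px, py;
  std::vector<int> active;
  double s2 = s * s;

  // initial point
  double x0, y0;
  do {
    x0 = R::runif(-R, R);
    y0 = R::runif(-R, R);
  } while (x0 * x0 + y0 * y0 > R * R);
  px.push_back(x0);
  py.push_back(y0);
  g.set(g.cx(x0), g.cx(y0), 0);
  active.push_back(0);

  while (!active.empty()) {
    int ai = active.back();
    bool placed = false;
    for (int t = 0; t < k; ++t) {
      double rr = s * std::sqrt(R::runif(1.0, 4.0));
      double th = R::runif(0.0, 2.0 * M_PI);
      double x = px[ai] + rr * std::cos(th);
      double y = py[ai] + rr * std::sin(th);
      if (x * x + y * y > R * R) continue;
      if (!farEnough(g, px, py, x, y, s2)) continue;
      px.push_back(x);
      py.push_back(y);
      int id = (int)px.size() - 1;
      g.set(g.cx(x), g.cx(y), id);
      active.push_back(id);
      placed = true;
      break;
    }
    if (!placed) active.pop_back();
  }

  // RSA densification: uniform candidate darts into remaining gaps
  for (int t = 0; t < densifyAttempts; ++t) {
    double x = R::runif(-R, R), y = R::runif(-R, R);
    if (x * x + y * y > R * R) continue;
    if (!farEnough(g, px, py, x, y, s2)) continue;
    px.push_back(x);
    py.push_back(y);
    g.set(g.cx(x), g.cx(y), (int)px.size() - 1);
  }

  NumericMatrix out((int)px.size(), 2);
  for (int i = 0; i < (int)px.size(); ++i) {
    out(i, 0) = px[i];
    out(i, 1) = py[i];
  }
  return out;
}
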