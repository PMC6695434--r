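// Geodesic distance over the 180x360 theta-phi pixel grid: iterative
// lowest-value expansion (Dijkstra) where each step costs the Cartesian
// distance between neighbouring pixel-centre surface points. 8-connected,
// wrapping in phi.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline void surf_pt(double a, double b, double c, double th,
                           double ph, double* out) {
  double st = std::sin(th), ct = std::cos(th);
  double sp = std::sin(ph), cp = std::cos(ph);
  double t = a * b * c /
    std::sqrt(b * b * c * c * ct * ct + a * a * c * c * st * st * cp * cp +
              a * a * b * b * st * st * sp * sp);
  out[0] = t * ct;
  out[1] = t * st * cp;
  out[2] = t * st * sp;
}

// [[Rcpp::export]]
NumericVector geodesic_grid_cpp(double a, double b, double c, int src_row,
                                int src_col, double max_distance) {
  const int NR = 180, NC = 360;
  const double d2r = M_PI / 180.0;
  std::vector<double> px(3 * NR * NC);
  for (int i = 0; i < NR; ++i)
    for (int j = 0; j < NC; ++j)
      surf_pt(a, b, c, (i + 0.5) * d2r, (j + 0.5) * d2r,
              &px[3 * (i * NC + j)]);

  std::vector<double> dist((size_t)NR * NC, R_PosInf);
  std::vector<char> done((size_t)NR * NC, 0);
  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE>> q;
  int s = src_row * NC + src_col;
  dist[s] = 0.0;
  q.push({0.0, s});
  const int dri[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dci[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  while (!q.empty()) {
    QE top = q.top();
    q.pop();
    int u = top.second;
    if (done[u]) continue;
    done[u] = 1;
    if (top.first > max_distance) continue;
    int ui = u / NC, uj = u % NC;
    const double* pu = &px[3 * u];
    for (int k = 0; k < 8; ++k) {
      int vi = ui + dri[k];
      if (vi < 0 || vi >= NR) continue;
      int vj = (uj + dci[k] + NC) % NC;
      int v = vi * NC + vj;
      if (done[v]) continue;
      const double* pv = &px[3 * v];
      double dx = pu[0] - pv[0], dy = pu[1] - pv[1], dz = pu[2] - pv[2];
      double nd = top.first + std::sqrt(dx * dx + dy * dy + dz * dz);
      if (nd < dist[v]) {
        dist[v] = nd;
        q.push({nd, v});
      }
    }
  }
  return NumericVector(dist.begin(), dist.end());
}
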