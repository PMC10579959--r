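#include <Rcpp.h>
#include <cmath>
#include <unordered_map>
#include <vector>
#include <queue>
#include <algorithm>
#include <limits>
using namespace Rcpp;

// Spatial grid hash over 3D points. Cell size is chosen by the caller; keys
// pack the integer cell coordinates into a single 64-bit value.
namespace {

inline long long cell_key(int ix, int iy, int iz) {
  // offset to keep coordinates positive; meshes here span far less than 2^20 cells
  const long long B = 1 << 20;
  return ((long long)(ix + (1 << 19)) * B + (iy + (1 << 19))) * B + (iz + (1 << 19));
}

} // namespace

// Nearest fixed point for every query point (brute force over grid cells).
// Returns 1-based index and distance. Exact: expands the searched cell ring
// until the best distance is provably correct.
// [[Rcpp::export(name = ".nn_nearest")]]
List nn_nearest(NumericMatrix query, NumericMatrix ref, double cell_size) {
  const int nq = query.nrow(), nr = ref.nrow();
  if (nr == 0) stop("reference cloud is empty");
  std::unordered_map<long long, std::vector<int> > bins;
  bins.reserve(nr * 2);
  const double cs = cell_size;
  for (int j = 0; j < nr; ++j) {
    int ix = (int)std::floor(ref(j, 0) / cs);
    int iy = (int)std::floor(ref(j, 1) / cs);
    int iz = (int)std::floor(ref(j, 2) / cs);
    bins[cell_key(ix, iy, iz)].push_back(j);
  }
  IntegerVector idx(nq);
  NumericVector dist(nq);
  for (int i = 0; i < nq; ++i) {
    const double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    const int cx = (int)std::floor(qx / cs);
    const int cy = (int)std::floor(qy / cs);
    const int cz = (int)std::floor(qz / cs);
    double best = std::numeric_limits<double>::infinity();
    int besti = -1;
    for (int ring = 0;; ++ring) {
      for (int ix = cx - ring; ix <= cx + ring; ++ix)
        for (int iy = cy - ring; iy <= cy + ring; ++iy)
          for (int iz = cz - ring; iz <= cz + ring; ++iz) {
            if (std::max(std::abs(ix - cx), std::max(std::abs(iy - cy), std::abs(iz - cz))) != ring)
              continue; // visit only the shell of this ring
            auto it = bins.find(cell_key(ix, iy, iz));
            if (it == bins.end()) continue;
            for (int j : it->second) {
              const double dx = ref(j, 0) - qx, dy = ref(j, 1) - qy, dz = ref(j, 2) - qz;
              const double d2 = dx * dx + dy * dy + dz * dz;
              if (d2 < best) { best = d2; besti = j; }
            }
          }
      // any point in a ring beyond this one is at Euclidean distance
      // >= ring*cs from the query, so the current best is final
      if (besti >= 0 && best <= (double)ring * cs * (double)ring * cs) break;
      if (ring > 1 << 20) stop("nearest-neighbour search failed to terminate");
    }
    idx[i] = besti + 1;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}

// k nearest neighbours (excluding self when query and ref are the same set,
// controlled by `drop_self`). Brute force; fine for the cloud sizes used here.
// [[Rcpp::export(name = ".knn_brute")]]
IntegerMatrix knn_brute(NumericMatrix pts, int k, bool drop_self) {
  const int n = pts.nrow();
  if (k >= n && drop_self) stop("k must be smaller than the number of points");
  IntegerMatrix out(n, k);
  std::vector<std::pair<double, int> > d(n);
  for (int i = 0; i < n; ++i) {
    const double xi = pts(i, 0), yi = pts(i, 1), zi = pts(i, 2);
    for (int j = 0; j < n; ++j) {
      const double dx = pts(j, 0) - xi, dy = pts(j, 1) - yi, dz = pts(j, 2) - zi;
      d[j] = std::make_pair(dx * dx + dy * dy + dz * dz, j);
    }
    if (drop_self) d[i].first = std::numeric_limits<double>::infinity();
    std::partial_sort(d.begin(), d.begin() + k, d.end());
    for (int m = 0; m < k; ++m) out(i, m) = d[m].second + 1;
  }
  return out;
}

// Greedy Poisson-disk thinning: visit points in the given order, keep a point
// iff no previously kept point lies within rmin. Grid-hash accelerated.
// [[Rcpp::export(name = ".thin_points")]]
LogicalVector thin_points(NumericMatrix pts, IntegerVector order, double rmin) {
  const int n = pts.nrow();
  LogicalVector keep(n, false);
  std::unordered_map<long long, std::vector<int> > bins;
  const double cs = rmin;
  const double r2 = rmin * rmin;
  for (int m = 0; m < order.size(); ++m) {
    const int i = order[m] - 1;
    const double xi = pts(i, 0), yi = pts(i, 1), zi = pts(i, 2);
    const int cx = (int)std::floor(xi / cs);
    const int cy = (int)std::floor(yi / cs);
    const int cz = (int)std::floor(zi / cs);
    bool ok = true;
    for (int ix = cx - 1; ix <= cx + 1 && ok; ++ix)
      for (int iy = cy - 1; iy <= cy + 1 && ok; ++iy)
        for (int iz = cz - 1; iz <= cz + 1 && ok; ++iz) {
          auto it = bins.find(cell_key(ix, iy, iz));
          if (it == bins.end()) continue;
          for (int j : it->second) {
            const double dx = pts(j, 0) - xi, dy = pts(j, 1) - yi, dz = pts(j, 2) - zi;
            if (dx * dx + dy * dy + dz * dz < r2) { ok = false; break; }
          }
        }
    if (ok) {
      keep[i] = true;
      bins[cell_key(cx, cy, cz)].push_back(i);
    }
  }
  return keep;
}

// Consistent orientation of point-cloud normals: sign propagation along a
// minimum spanning forest of the symmetrized kNN graph with edge weight
// 1 - |n_i . n_j| (Prim), so signs avoid crossing sharp creases where a
// smooth path exists. Roots are seeded at the topmost unvisited point with
// the normal forced upward; the caller applies a global outward flip.
// [[Rcpp::export(name = ".orient_normals_msf")]]
NumericMatrix orient_normals_msf(NumericMatrix pts, NumericMatrix normals,
                                 IntegerMatrix nb) {
  const int n = pts.nrow(), k = nb.ncol();
  NumericMatrix out(clone(normals));
  std::vector<std::vector<int> > adj(n);
  for (int i = 0; i < n; ++i)
    for (int m = 0; m < k; ++m) {
      int j = nb(i, m) - 1;
      adj[i].push_back(j);
      adj[j].push_back(i);
    }
  auto dot3 = [&](int a, int b) {
    return out(a, 0) * out(b, 0) + out(a, 1) * out(b, 1) + out(a, 2) * out(b, 2);
  };
  std::vector<bool> visited(n, false);
  typedef std::pair<double, std::pair<int, int> > Edge; // (w, (from, to))
  std::priority_queue<Edge, std::vector<Edge>, std::greater<Edge> > pq;
  int done = 0;
  while (done < n) {
    int root = -1;
    double zmax = -std::numeric_limits<double>::infinity();
    for (int i = 0; i < n; ++i)
      if (!visited[i] && pts(i, 2) > zmax) { zmax = pts(i, 2); root = i; }
    if (out(root, 2) < 0)
      for (int d = 0; d < 3; ++d) out(root, d) = -out(root, d);
    visited[root] = true;
    ++done;
    for (int j : adj[root])
      if (!visited[j])
        pq.push(std::make_pair(1.0 - std::abs(dot3(root, j)),
                               std::make_pair(root, j)));
    while (!pq.empty()) {
      Edge e = pq.top();
      pq.pop();
      int p = e.second.first, v = e.second.second;
      if (visited[v]) continue;
      if (dot3(p, v) < 0)
        for (int d = 0; d < 3; ++d) out(v, d) = -out(v, d);
      visited[v] = true;
      ++done;
      for (int j : adj[v])
        if (!visited[j])
          pq.push(std::make_pair(1.0 - std::abs(dot3(v, j)),
                                 std::make_pair(v, j)));
    }
  }
  return out;
}

namespace {
// Closest point on triangle (a,b,c) to p; Ericson, Real-Time Collision Detection.
inline double tri_dist2(const double* p, const double* a, const double* b, const double* c) {
  double ab[3] = { b[0] - a[0], b[1] - a[1], b[2] - a[2] };
  double ac[3] = { c[0] - a[0], c[1] - a[1], c[2] - a[2] };
  double ap[3] = { p[0] - a[0], p[1] - a[1], p[2] - a[2] };
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  double q[3];
  if (d1 <= 0.0 && d2 <= 0.0) { q[0] = a[0]; q[1] = a[1]; q[2] = a[2]; }
  else {
    double bp[3] = { p[0] - b[0], p[1] - b[1], p[2] - b[2] };
    double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
    double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
    if (d3 >= 0.0 && d4 <= d3) { q[0] = b[0]; q[1] = b[1]; q[2] = b[2]; }
    else {
      double vc = d1 * d4 - d3 * d2;
      if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
        double v = d1 / (d1 - d3);
        q[0] = a[0] + v * ab[0]; q[1] = a[1] + v * ab[1]; q[2] = a[2] + v * ab[2];
      } else {
        double cp[3] = { p[0] - c[0], p[1] - c[1], p[2] - c[2] };
        double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
        double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
        if (d6 >= 0.0 && d5 <= d6) { q[0] = c[0]; q[1] = c[1]; q[2] = c[2]; }
        else {
          double vb = d5 * d2 - d1 * d6;
          if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
            double w = d2 / (d2 - d6);
            q[0] = a[0] + w * ac[0]; q[1] = a[1] + w * ac[1]; q[2] = a[2] + w * ac[2];
          } else {
            double va = d3 * d6 - d5 * d4;
            if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
              double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
              q[0] = b[0] + w * (c[0] - b[0]); q[1] = b[1] + w * (c[1] - b[1]); q[2] = b[2] + w * (c[2] - b[2]);
            } else {
              double denom = 1.0 / (va + vb + vc);
              double v = vb * denom, w = vc * denom;
              q[0] = a[0] + ab[0] * v + ac[0] * w;
              q[1] = a[1] + ab[1] * v + ac[1] * w;
              q[2] = a[2] + ab[2] * v + ac[2] * w;
            }
          }
        }
      }
    }
  }
  double dx = p[0] - q[0], dy = p[1] - q[1], dz = p[2] - q[2];
  return dx * dx + dy * dy + dz * dz;
}
} // namespace

// Distance from each query point to a triangulated surface (brute force over
// triangles; adequate for the fixture sizes this package tests with).
// [[Rcpp::export(name = ".point_surface_dist")]]
NumericVector point_surface_dist(NumericMatrix query, NumericMatrix verts, IntegerMatrix faces) {
  const int nq = query.nrow(), nf = faces.nrow();
  if (nf == 0) stop("surface has no faces");
  NumericVector out(nq);
  std::vector<double> V(verts.nrow() * 3);
  for (int i = 0; i < verts.nrow(); ++i)
    for (int d = 0; d < 3; ++d) V[3 * i + d] = verts(i, d);
  for (int i = 0; i < nq; ++i) {
    double p[3] = { query(i, 0), query(i, 1), query(i, 2) };
    double best = std::numeric_limits<double>::infinity();
    for (int f = 0; f < nf; ++f) {
      const double* a = &V[3 * (faces(f, 0) - 1)];
      const double* b = &V[3 * (faces(f, 1) - 1)];
      const double* c = &V[3 * (faces(f, 2) - 1)];
      double d2 = tri_dist2(p, a, b, c);
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
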