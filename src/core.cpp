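#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Uniform-grid spatial index with cell size eps: any eps-neighbour of a
// point lies in its own or one of the 8 adjacent cells.
typedef std::unordered_map<int64_t, std::vector<int> > CellMap;

static inline int64_t cell_key(int ix, int iy) {
  return (static_cast<int64_t>(static_cast<uint32_t>(ix)) << 32) |
         static_cast<int64_t>(static_cast<uint32_t>(iy));
}

static void neighbours_of(int i, const NumericVector &x, const NumericVector &y,
                          double eps2, double inv_eps, const CellMap &grid,
                          std::vector<int> &out) {
  out.clear();
  const int ix = static_cast<int>(std::floor(x[i] * inv_eps));
  const int iy = static_cast<int>(std::floor(y[i] * inv_eps));
  for (int dx = -1; dx <= 1; ++dx) {
    for (int dy = -1; dy <= 1; ++dy) {
      CellMap::const_iterator it = grid.find(cell_key(ix + dx, iy + dy));
      if (it == grid.end()) continue;
      const std::vector<int> &cell = it->second;
      for (size_t k = 0; k < cell.size(); ++k) {
        const int j = cell[k];
        const double ddx = x[i] - x[j], ddy = y[i] - y[j];
        if (ddx * ddx + ddy * ddy <= eps2) out.push_back(j);
      }
    }
  }
  // deterministic ascending order regardless of grid insertion order
  std::sort(out.begin(), out.end());
}

// DBSCAN over 2D points. Closed eps-ball neighbourhoods include the point
// itself; labels are 0-based cluster ids with -1 for noise, renumbered by
// first member row. Border points attach to the cluster of their first
// (lowest-index) core neighbour.
// [[Rcpp::export(name = ".dbscan_grid")]]
List dbscan_grid(NumericVector x, NumericVector y, double eps, int min_pts) {
  const int n = x.size();
  IntegerVector labels(n, -1);
  LogicalVector core(n, false);
  if (n == 0)
    return List::create(_["labels"] = labels, _["core"] = core,
                        _["n_clusters"] = 0);

  const double eps2 = eps * eps;
  const double inv_eps = 1.0 / eps;
  CellMap grid;
  grid.reserve(static_cast<size_t>(n) * 2);
  for (int i = 0; i < n; ++i) {
    const int ix = static_cast<int>(std::floor(x[i] * inv_eps));
    const int iy = static_cast<int>(std::floor(y[i] * inv_eps));
    grid[cell_key(ix, iy)].push_back(i);
  }

  std::vector<int> nb;
  nb.reserve(64);
  for (int i = 0; i < n; ++i) {
    neighbours_of(i, x, y, eps2, inv_eps, grid, nb);
    if (static_cast<int>(nb.size()) >= min_pts) core[i] = true;
  }

  // connected components of core points under mutual eps-reachability
  int cid = 0;
  std::queue<int> q;
  for (int i = 0; i < n; ++i) {
    if (!core[i] || labels[i] != -1) continue;
    labels[i] = cid;
    q.push(i);
    while (!q.empty()) {
      const int j = q.front();
      q.pop();
      neighbours_of(j, x, y, eps2, inv_eps, grid, nb);
      for (size_t k = 0; k < nb.size(); ++k) {
        const int m = nb[k];
        if (core[m] && labels[m] == -1) {
          labels[m] = cid;
          q.push(m);
        }
      }
    }
    ++cid;
  }

  // border points: first core neighbour in ascending row order
  for (int i = 0; i < n; ++i) {
    if (core[i] || labels[i] != -1) continue;
    neighbours_of(i, x, y, eps2, inv_eps, grid, nb);
    for (size_t k = 0; k < nb.size(); ++k) {
      if (core[nb[k]]) {
        labels[i] = labels[nb[k]];
        break;
      }
    }
  }

  // renumber cluster ids in order of first member row
  std::vector<int> remap(cid, -1);
  int next_id = 0;
  for (int i = 0; i < n; ++i) {
    const int l = labels[i];
    if (l >= 0 && remap[l] == -1) remap[l] = next_id++;
  }
  for (int i = 0; i < n; ++i)
    if (labels[i] >= 0) labels[i] = remap[labels[i]];

  return List::create(_["labels"] = labels, _["core"] = core,
                      _["n_clusters"] = next_id);
}

// Maximum pairwise Euclidean distance (max Feret diameter) of a 2D point set.
// [[Rcpp::export(name = ".max_pairwise_dist")]]
double max_pairwise_dist(NumericVector x, NumericVector y) {
  const int n = x.size();
  double best = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      const double dx = x[i] - x[j], dy = y[i] - y[j];
      const double d2 = dx * dx + dy * dy;
      if (d2 > best) best = d2;
    }
  return std::sqrt(best);
}
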