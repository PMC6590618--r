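#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <queue>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Internal grids are row-major uint8 vectors; (row, col) are 0-based here and
// converted to the package's (x, y) or R's 1-based indices at the interface.

static inline int gidx(int r, int c, int nc) { return r * nc + c; }

// ---------------------------------------------------------------------------
// Zhang-Suen two-subiteration thinning
// ---------------------------------------------------------------------------

// circular neighbourhood P2..P9, clockwise from north
static const int ZSR[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
static const int ZSC[8] = {0, 1, 1, 1, 0, -1, -1, -1};

// Deletions are applied sequentially (each candidate re-validated against
// the current image) rather than in parallel: parallel two-subiteration
// thinning annihilates 2x2 blocks and 2-pixel-wide diagonal staircases,
// which are exactly what a rasterized diagonal stroke looks like.
static size_t zs_pass(std::vector<uint8_t>& g, int nr, int nc, int pass,
                      const std::vector<uint8_t>* protect) {
  size_t removed = 0;
  for (int r = 0; r < nr; r++) {
    for (int c = 0; c < nc; c++) {
      if (!g[gidx(r, c, nc)]) continue;
      if (protect && (*protect)[gidx(r, c, nc)]) continue;
      int p[8];
      for (int k = 0; k < 8; k++) {
        int rr = r + ZSR[k], cc = c + ZSC[k];
        p[k] = (rr >= 0 && rr < nr && cc >= 0 && cc < nc) ? g[gidx(rr, cc, nc)] : 0;
      }
      int B = 0;
      for (int k = 0; k < 8; k++) B += p[k];
      if (B < 2 || B > 6) continue;
      int A = 0;
      for (int k = 0; k < 8; k++)
        if (p[k] == 0 && p[(k + 1) % 8] == 1) A++;
      if (A != 1) continue;
      // p[0]=N, p[2]=E, p[4]=S, p[6]=W
      if (pass == 0) {
        if (p[0] && p[2] && p[4]) continue;
        if (p[2] && p[4] && p[6]) continue;
      } else {
        if (p[0] && p[2] && p[6]) continue;
        if (p[0] && p[4] && p[6]) continue;
      }
      g[gidx(r, c, nc)] = 0;
      removed++;
    }
  }
  return removed;
}

// `protect` (optional) marks anchor pixels that are never deleted; the
// rasterizer anchors the pixels containing the contour's true endpoints so
// the skeleton keeps the full end-to-end extent of the curve.
static void thin_inplace(std::vector<uint8_t>& g, int nr, int nc,
                         const std::vector<uint8_t>* protect = nullptr) {
  for (;;) {
    size_t n1 = zs_pass(g, nr, nc, 0, protect);
    size_t n2 = zs_pass(g, nr, nc, 1, protect);
    if (n1 + n2 == 0) break;
  }
}

// [[Rcpp::export]]
LogicalMatrix cpp_thin(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  std::vector<uint8_t> g((size_t)nr * nc, 0);
  for (int r = 0; r < nr; r++)
    for (int c = 0; c < nc; c++)
      if (mask(r, c)) g[gidx(r, c, nc)] = 1;
  thin_inplace(g, nr, nc);
  LogicalMatrix out(nr, nc);
  for (int r = 0; r < nr; r++)
    for (int c = 0; c < nc; c++) out(r, c) = g[gidx(r, c, nc)] != 0;
  return out;
}

// ---------------------------------------------------------------------------
// Connected-component labelling (8-connectivity)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_label(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<std::pair<int, int>> stack;
  for (int r = 0; r < nr; r++) {
    for (int c = 0; c < nc; c++) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      next++;
      stack.clear();
      stack.push_back({r, c});
      lab(r, c) = next;
      while (!stack.empty()) {
        auto pc = stack.back();
        stack.pop_back();
        for (int k = 0; k < 8; k++) {
          int rr = pc.first + ZSR[k], cc = pc.second + ZSC[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back({rr, cc});
          }
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Backbone extraction: longest endpoint-to-endpoint simple path on a skeleton
// ---------------------------------------------------------------------------

struct Backbone {
  std::vector<std::pair<int, int>> path;  // (row, col), 0-based
  int status;  // 0 ok, 1 empty, 2 disconnected, 3 loop (no endpoints),
               // 4 not single-width after pruning
  int pruned;  // skeleton pixels not on the retained path
};

// Endpoint ordering follows the package's (x, y) convention (x = col,
// y = nrow-1-row, increasing upward): lexicographically smallest (x, y) first.
struct EndpointLess {
  bool operator()(const std::pair<int, int>& a, const std::pair<int, int>& b) const {
    if (a.second != b.second) return a.second < b.second;  // col == x
    return a.first > b.first;                              // larger row == smaller y
  }
};

// If `anchor_a`/`anchor_b` are non-negative grid indices, the path is traced
// between those two pixels (the rasterizer passes the pixels containing the
// contour's true endpoints); otherwise path ends are the farthest pair of
// degree-1 skeleton endpoints.
static void extract_backbone(const std::vector<uint8_t>& g, int nr, int nc,
                             Backbone& out, int anchor_a = -1,
                             int anchor_b = -1) {
  out.path.clear();
  out.status = 0;
  out.pruned = 0;

  std::vector<std::pair<int, int>> pix;
  for (int r = 0; r < nr; r++)
    for (int c = 0; c < nc; c++)
      if (g[gidx(r, c, nc)]) pix.push_back({r, c});
  int V = (int)pix.size();
  if (V == 0) {
    out.status = 1;
    return;
  }
  if (V == 1) {
    out.path.push_back(pix[0]);
    return;
  }

  std::vector<int> pos((size_t)nr * nc, -1);
  for (int i = 0; i < V; i++) pos[gidx(pix[i].first, pix[i].second, nc)] = i;

  // connectivity check (BFS from pixel 0)
  {
    std::vector<uint8_t> seen(V, 0);
    std::queue<int> q;
    q.push(0);
    seen[0] = 1;
    int nseen = 1;
    while (!q.empty()) {
      int i = q.front();
      q.pop();
      for (int k = 0; k < 8; k++) {
        int rr = pix[i].first + ZSR[k], cc = pix[i].second + ZSC[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        int j = pos[gidx(rr, cc, nc)];
        if (j >= 0 && !seen[j]) {
          seen[j] = 1;
          nseen++;
          q.push(j);
        }
      }
    }
    if (nseen != V) {
      out.status = 2;
      return;
    }
  }

  // endpoints: anchors if given, otherwise degree-1 skeleton pixels
  std::vector<std::pair<int, int>> ends;
  if (anchor_a >= 0 && anchor_b >= 0) {
    if (pos[anchor_a] < 0 || pos[anchor_b] < 0 || anchor_a == anchor_b) {
      out.status = 5;
      return;
    }
    ends.push_back(pix[pos[anchor_a]]);
    ends.push_back(pix[pos[anchor_b]]);
  } else {
    for (int i = 0; i < V; i++) {
      int deg = 0;
      for (int k = 0; k < 8; k++) {
        int rr = pix[i].first + ZSR[k], cc = pix[i].second + ZSC[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (pos[gidx(rr, cc, nc)] >= 0) deg++;
      }
      if (deg == 1) ends.push_back(pix[i]);
    }
    if (ends.empty()) {
      out.status = 3;  // closed loop
      return;
    }
  }
  std::sort(ends.begin(), ends.end(), EndpointLess());

  // BFS hop distances from each endpoint; pick the farthest endpoint pair,
  // ties resolved by endpoint order.
  auto bfs = [&](std::pair<int, int> from, std::vector<int>& dist,
                 std::vector<int>& parent) {
    dist.assign(V, -1);
    parent.assign(V, -1);
    int s = pos[gidx(from.first, from.second, nc)];
    std::queue<int> q;
    q.push(s);
    dist[s] = 0;
    while (!q.empty()) {
      int i = q.front();
      q.pop();
      for (int k = 0; k < 8; k++) {
        int rr = pix[i].first + ZSR[k], cc = pix[i].second + ZSC[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        int j = pos[gidx(rr, cc, nc)];
        if (j >= 0 && dist[j] < 0) {
          dist[j] = dist[i] + 1;
          parent[j] = i;
          q.push(j);
        }
      }
    }
  };

  int best = -1, bi = -1, bj = -1;
  std::vector<int> dist, parent;
  for (int i = 0; i < (int)ends.size(); i++) {
    bfs(ends[i], dist, parent);
    for (int j = 0; j < (int)ends.size(); j++) {
      if (j == i) continue;
      int d = dist[pos[gidx(ends[j].first, ends[j].second, nc)]];
      if (d > best) {
        best = d;
        bi = i;
        bj = j;
      }
    }
  }
  if (best < 0) {  // single endpoint attached to a loop
    out.status = 3;
    return;
  }
  if (bi > bj) std::swap(bi, bj);  // deterministic orientation

  bfs(ends[bi], dist, parent);
  int cur = pos[gidx(ends[bj].first, ends[bj].second, nc)];
  std::vector<int> chain;
  while (cur >= 0) {
    chain.push_back(cur);
    cur = parent[cur];
  }
  std::reverse(chain.begin(), chain.end());
  for (int i : chain) out.path.push_back(pix[i]);

  std::vector<int> ppos((size_t)nr * nc, -1);
  for (int i = 0; i < (int)chain.size(); i++)
    ppos[gidx(out.path[i].first, out.path[i].second, nc)] = i;

  // lost extent: skeleton pixels neither on the path nor 8-adjacent to it
  // (pixels skipped when the path cuts a staircase corner stay adjacent and
  // do not count as lost)
  out.pruned = 0;
  for (int i = 0; i < V; i++) {
    if (ppos[gidx(pix[i].first, pix[i].second, nc)] >= 0) continue;
    bool near = false;
    for (int k = 0; k < 8 && !near; k++) {
      int rr = pix[i].first + ZSR[k], cc = pix[i].second + ZSC[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (ppos[gidx(rr, cc, nc)] >= 0) near = true;
    }
    if (!near) out.pruned++;
  }

  // single-width check on the retained path: every 8-adjacent pair of path
  // pixels must be consecutive along the path
  for (int i = 0; i < (int)out.path.size(); i++) {
    for (int k = 0; k < 8; k++) {
      int rr = out.path[i].first + ZSR[k], cc = out.path[i].second + ZSC[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      int j = ppos[gidx(rr, cc, nc)];
      if (j >= 0 && std::abs(i - j) != 1) {
        out.status = 4;
        return;
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_backbone(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  std::vector<uint8_t> g((size_t)nr * nc, 0);
  for (int r = 0; r < nr; r++)
    for (int c = 0; c < nc; c++)
      if (mask(r, c)) g[gidx(r, c, nc)] = 1;
  Backbone bb;
  extract_backbone(g, nr, nc, bb);
  int m = (int)bb.path.size();
  IntegerMatrix path(m, 2);
  for (int i = 0; i < m; i++) {  // 1-based (row, col) for R
    path(i, 0) = bb.path[i].first + 1;
    path(i, 1) = bb.path[i].second + 1;
  }
  return List::create(_["path"] = path, _["status"] = bb.status,
                      _["pruned"] = bb.pruned);
}

// ---------------------------------------------------------------------------
// 2D worm-like chain generation with self-intersection rejection
// ---------------------------------------------------------------------------

// Spatial hash over cells of size `cell`; detects the polyline approaching
// itself closer than 0.9*step between vertices more than 4 steps apart along
// the chain, which covers every true segment crossing (crossing unit segments
// always have a vertex pair within ~0.71*step).
static bool wlc_try(double lc, double lp, double step, bool reject_self,
                    std::vector<double>& xs, std::vector<double>& ys) {
  int n = (int)std::lround(lc / step);
  if (n < 2) stop("contour length must span at least two steps");
  xs.assign(n + 1, 0.0);
  ys.assign(n + 1, 0.0);
  double theta = R::runif(0.0, 2.0 * M_PI);
  double sd = std::sqrt(step / lp);
  double x = 0.0, y = 0.0;

  std::unordered_map<int64_t, std::vector<int>> grid;
  double cell = step;
  double lim2 = 0.81 * step * step;
  auto key = [&](double px, double py) {
    int64_t cx = (int64_t)std::floor(px / cell);
    int64_t cy = (int64_t)std::floor(py / cell);
    return (cx << 32) ^ (cy & 0xffffffffLL);
  };
  auto put = [&](double px, double py, int i) {
    grid[key(px, py)].push_back(i);
  };
  auto clash = [&](double px, double py, int i) {
    int64_t cx = (int64_t)std::floor(px / cell);
    int64_t cy = (int64_t)std::floor(py / cell);
    for (int64_t dx = -1; dx <= 1; dx++) {
      for (int64_t dy = -1; dy <= 1; dy++) {
        auto it = grid.find(((cx + dx) << 32) ^ ((cy + dy) & 0xffffffffLL));
        if (it == grid.end()) continue;
        for (int j : it->second) {
          if (i - j <= 4) continue;
          double ddx = px - xs[j], ddy = py - ys[j];
          if (ddx * ddx + ddy * ddy < lim2) return true;
        }
      }
    }
    return false;
  };

  if (reject_self) put(x, y, 0);
  for (int i = 1; i <= n; i++) {
    if (i > 1) theta += R::norm_rand() * sd;
    x += step * std::cos(theta);
    y += step * std::sin(theta);
    xs[i] = x;
    ys[i] = y;
    if (reject_self) {
      if (clash(x, y, i)) return false;
      put(x, y, i);
    }
  }
  return true;
}

// [[Rcpp::export]]
NumericMatrix cpp_wlc(double lc, double lp, double step, bool reject_self,
                      int max_tries) {
  std::vector<double> xs, ys;
  for (int t = 0; t < max_tries; t++) {
    if (wlc_try(lc, lp, step, reject_self, xs, ys)) {
      int m = (int)xs.size();
      NumericMatrix out(m, 2);
      for (int i = 0; i < m; i++) {
        out(i, 0) = xs[i];
        out(i, 1) = ys[i];
      }
      return out;
    }
  }
  stop("self-intersection rejection rate too high for these parameters");
}

// ---------------------------------------------------------------------------
// Rasterization of a continuous contour to a single-width pixel path
// ---------------------------------------------------------------------------

// Digitizes the continuous contour to an ordered single-pixel-width chain:
// the sequence of pixels containing the curve, visited in arc-length order
// at sub-pixel sampling r/sub.  Immediate re-entries of the previous pixel
// (boundary jitter) are collapsed, and staircase corner pixels whose two
// path neighbours are themselves 8-adjacent are shortcut away so the chain
// satisfies the strict single-width property.  Draws whose chain still
// revisits a pixel or touches itself (the curve approaching within a pixel
// of itself) are rejected.
//
// status: 0 ok, 4 not single-width (self-touching), 5 too short
static int rasterize_core(const std::vector<double>& xs,
                          const std::vector<double>& ys, double r, int sub,
                          std::vector<std::pair<int, int>>& path) {
  int n = (int)xs.size();
  double ds = r / sub;
  path.clear();

  auto cell = [&](double px, double py) {
    return std::make_pair((int)std::floor(px / r), (int)std::floor(py / r));
  };
  auto push = [&](std::pair<int, int> p) {
    if (!path.empty() && p == path.back()) return;
    if (path.size() >= 2 && p == path[path.size() - 2]) {
      path.pop_back();  // grazed the neighbouring pixel and came back
      return;
    }
    path.push_back(p);
  };

  push(cell(xs[0], ys[0]));
  for (int i = 1; i < n; i++) {
    double dx = xs[i] - xs[i - 1], dy = ys[i] - ys[i - 1];
    double len = std::sqrt(dx * dx + dy * dy);
    int ns = std::max(1, (int)std::ceil(len / ds));
    for (int k = 1; k <= ns; k++) {
      double t = (double)k / ns;
      push(cell(xs[i - 1] + t * dx, ys[i - 1] + t * dy));
    }
  }

  if ((int)path.size() < 4) return 5;

  // shortcut staircase corners until the chain is locally minimal
  for (;;) {
    bool changed = false;
    size_t w = 1;
    for (size_t i = 1; i + 1 < path.size(); i++) {
      int dxc = std::abs(path[w - 1].first - path[i + 1].first);
      int dyc = std::abs(path[w - 1].second - path[i + 1].second);
      if (std::max(dxc, dyc) <= 1) {
        changed = true;  // drop path[i]
        continue;
      }
      path[w++] = path[i];
    }
    path[w++] = path.back();
    path.resize(w);
    if (!changed) break;
  }
  if ((int)path.size() < 4) return 5;

  // strict single-width validation on a local grid
  int xmin = path[0].first, xmax = path[0].first;
  int ymin = path[0].second, ymax = path[0].second;
  for (auto& p : path) {
    xmin = std::min(xmin, p.first);
    xmax = std::max(xmax, p.first);
    ymin = std::min(ymin, p.second);
    ymax = std::max(ymax, p.second);
  }
  int nc = xmax - xmin + 3, nr = ymax - ymin + 3;
  if ((double)nr * nc > 6.4e7) stop("raster grid too large");
  std::vector<int> ppos((size_t)nr * nc, -1);
  for (size_t i = 0; i < path.size(); i++) {
    int id = gidx(path[i].second - ymin + 1, path[i].first - xmin + 1, nc);
    if (ppos[id] >= 0) return 4;  // pixel revisited
    ppos[id] = (int)i;
  }
  for (size_t i = 0; i < path.size(); i++) {
    for (int k = 0; k < 8; k++) {
      int rr = path[i].second - ymin + 1 + ZSR[k];
      int cc = path[i].first - xmin + 1 + ZSC[k];
      int j = ppos[gidx(rr, cc, nc)];
      if (j >= 0 && std::abs((int)i - j) != 1 && j != (int)i) return 4;
    }
  }
  return 0;
}

// [[Rcpp::export]]
List cpp_rasterize(NumericMatrix pts, double r, int sub) {
  int n = pts.nrow();
  std::vector<double> xs(n), ys(n);
  for (int i = 0; i < n; i++) {
    xs[i] = pts(i, 0);
    ys[i] = pts(i, 1);
  }
  std::vector<std::pair<int, int>> path;
  int status = rasterize_core(xs, ys, r, sub, path);
  IntegerMatrix out((int)path.size(), 2);
  for (int i = 0; i < (int)path.size(); i++) {
    out(i, 0) = path[i].first;
    out(i, 1) = path[i].second;
  }
  return List::create(_["path"] = out, _["status"] = status);
}

// [[Rcpp::export]]
List cpp_simulate_batch(int n, double lc, double lp, double step, double r,
                        int sub, int max_tries) {
  List paths(n);
  long attempts = 0;
  std::vector<double> xs, ys;
  std::vector<std::pair<int, int>> path;
  for (int i = 0; i < n; i++) {
    bool ok = false;
    for (int t = 0; t < max_tries; t++) {
      attempts++;
      if (!wlc_try(lc, lp, step, true, xs, ys)) continue;
      if (rasterize_core(xs, ys, r, sub, path) != 0) continue;
      ok = true;
      break;
    }
    if (!ok)
      stop("could not produce a clean single-width skeleton after %d draws",
           max_tries);
    IntegerMatrix pm((int)path.size(), 2);
    for (int k = 0; k < (int)path.size(); k++) {
      pm(k, 0) = path[k].first;
      pm(k, 1) = path[k].second;
    }
    paths[i] = pm;
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["paths"] = paths, _["attempts"] = (double)attempts);
}
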