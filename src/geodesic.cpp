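#include <Rcpp.h>
#include <vector>
#include <queue>
#include <limits>
#include <climits>
using namespace Rcpp;

// 8-neighbour offsets (row, col)
static const int DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// 8-connected labelling of a binary mask, labels assigned in raster-scan
// order of each component's first pixel (deterministic).
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  // column-major scan matches R's which() ordering
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.clear();
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int pr = idx % nr, pc = idx / nr;
        for (int k = 0; k < 8; ++k) {
          int qr = pr + DR[k], qc = pc + DC[k];
          if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
          if (mask(qr, qc) && lab(qr, qc) == 0) {
            lab(qr, qc) = next;
            stack.push_back(qr + qc * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Geodesic influence zones (SKIZ partition) of labelled seeds inside a mask.
// Multi-source level-synchronous BFS with the 8-neighbour (chessboard)
// metric; equidistant pixels go to the lowest seed label (deterministic).
// Unreachable mask pixels (mask components with no seed) stay 0.
// [[Rcpp::export]]
IntegerMatrix cpp_influence_zones(IntegerMatrix labels, LogicalMatrix roi) {
  int nr = labels.nrow(), nc = labels.ncol();
  IntegerMatrix zone(nr, nc);
  std::vector<int> frontier, nxt;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (roi(r, c) && labels(r, c) > 0) {
        zone(r, c) = labels(r, c);
        frontier.push_back(r + c * nr);
      }
  // claims for the next level: 0 = unclaimed
  std::vector<int> claim((size_t) nr * nc, 0);
  while (!frontier.empty()) {
    nxt.clear();
    for (size_t i = 0; i < frontier.size(); ++i) {
      int idx = frontier[i];
      int pr = idx % nr, pc = idx / nr;
      int lab = zone(pr, pc);
      for (int k = 0; k < 8; ++k) {
        int qr = pr + DR[k], qc = pc + DC[k];
        if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
        if (!roi(qr, qc) || zone(qr, qc) != 0) continue;
        size_t qidx = (size_t) qr + (size_t) qc * nr;
        if (claim[qidx] == 0) {
          claim[qidx] = lab;
          nxt.push_back((int) qidx);
        } else if (lab < claim[qidx]) {
          claim[qidx] = lab;
        }
      }
    }
    for (size_t i = 0; i < nxt.size(); ++i) {
      int idx = nxt[i];
      zone(idx % nr, idx / nr) = claim[idx];
      claim[idx] = 0;
    }
    frontier.swap(nxt);
  }
  return zone;
}

// BFS geodesic distances from one source over a flat adjacency list
// (CSR layout); helper for cpp_geodesic_centers.
static void bfs_from(int src, const std::vector<int> &adjStart,
                     const std::vector<int> &adjList,
                     std::vector<int> &dist, std::vector<int> &queue) {
  std::fill(dist.begin(), dist.end(), -1);
  size_t head = 0;
  queue.clear();
  dist[src] = 0;
  queue.push_back(src);
  while (head < queue.size()) {
    int u = queue[head++];
    for (int k = adjStart[u]; k < adjStart[u + 1]; ++k) {
      int v = adjList[k];
      if (dist[v] < 0) { dist[v] = dist[u] + 1; queue.push_back(v); }
    }
  }
}

// Geodesic center of every zone of a label image: the zone pixel minimising
// the maximum within-zone geodesic (8-neighbour) distance to all zone
// pixels. The chessboard metric produces large plateaus of equal
// eccentricity, so ties are broken first by maximal geodesic depth
// (distance to the zone boundary: the most interior plateau pixel), then
// by smallest (row, col). Exact branch-and-bound: BFS from directional
// extreme pixels gives per-pixel eccentricity lower bounds (max of
// observed distances); candidates are then verified in preference order,
// each verification BFS tightening every bound, until no unverified pixel
// can beat the best verified one.
// Returns an nzones x 2 matrix of 1-based (row, col).
// [[Rcpp::export]]
NumericMatrix cpp_geodesic_centers(IntegerMatrix zones, int nzones) {
  int nr = zones.nrow(), nc = zones.ncol();
  NumericMatrix out(nzones, 2);
  std::fill(out.begin(), out.end(), NA_REAL);
  std::vector< std::vector<int> > pix(nzones + 1);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int z = zones(r, c);
      if (z >= 1 && z <= nzones) pix[z].push_back(r + c * nr);
    }
  std::vector<int> local((size_t) nr * nc, -1);
  std::vector<int> adjStart, adjList, lb, dist, queue, order;
  std::vector<bool> done;
  for (int z = 1; z <= nzones; ++z) {
    const std::vector<int> &p = pix[z];
    int n = (int) p.size();
    if (n == 0) continue;
    if (n == 1) {
      out(z - 1, 0) = p[0] % nr + 1;
      out(z - 1, 1) = p[0] / nr + 1;
      continue;
    }
    for (int i = 0; i < n; ++i) local[p[i]] = i;
    adjStart.assign(n + 1, 0);
    adjList.clear();
    for (int i = 0; i < n; ++i) {
      int pr = p[i] % nr, pc = p[i] / nr;
      adjStart[i] = (int) adjList.size();
      for (int k = 0; k < 8; ++k) {
        int qr = pr + DR[k], qc = pc + DC[k];
        if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
        int q = local[(size_t) qr + (size_t) qc * nr];
        if (q >= 0) adjList.push_back(q);
      }
    }
    adjStart[n] = (int) adjList.size();

    // geodesic depth: multi-source BFS inward from the boundary pixels
    std::vector<int> depth(n, 0);
    {
      std::vector<int> q;
      for (int i = 0; i < n; ++i)
        if (adjStart[i + 1] - adjStart[i] < 8) { depth[i] = 1; q.push_back(i); }
      size_t head = 0;
      while (head < q.size()) {
        int u = q[head++];
        for (int k = adjStart[u]; k < adjStart[u + 1]; ++k) {
          int v = adjList[k];
          if (depth[v] == 0) { depth[v] = depth[u] + 1; q.push_back(v); }
        }
      }
    }

    // seed sources: extremes in 8 directions (deterministic)
    int seed[8];
    long bestVal[8];
    for (int s = 0; s < 8; ++s) { seed[s] = 0; bestVal[s] = LONG_MIN; }
    for (int i = 0; i < n; ++i) {
      long r = p[i] % nr, c = p[i] / nr;
      long vals[8] = {-r, r, -c, c, -(r + c), r + c, -(r - c), r - c};
      for (int s = 0; s < 8; ++s)
        if (vals[s] > bestVal[s]) { bestVal[s] = vals[s]; seed[s] = i; }
    }
    lb.assign(n, 0);
    dist.resize(n);
    done.assign(n, false);
    int best = -1, bestEcc = std::numeric_limits<int>::max();
    int bestDepth = -1, bestR = 0, bestC = 0;
    // does (depth, row, col) beat the current best on the tie criteria?
    auto tieBeats = [&](int d, int r, int c) {
      if (d != bestDepth) return d > bestDepth;
      if (r != bestR) return r < bestR;
      return c < bestC;
    };
    auto runSource = [&](int src) {
      bfs_from(src, adjStart, adjList, dist, queue);
      int ecc = 0;
      for (int j = 0; j < n; ++j) {
        if (dist[j] > lb[j]) lb[j] = dist[j];
        if (dist[j] > ecc) ecc = dist[j];
      }
      done[src] = true;
      int pr = p[src] % nr, pc = p[src] / nr;
      if (ecc < bestEcc || (ecc == bestEcc && tieBeats(depth[src], pr, pc))) {
        best = src; bestEcc = ecc; bestDepth = depth[src];
        bestR = pr; bestC = pc;
      }
    };
    for (int s = 0; s < 8; ++s)
      if (!done[seed[s]]) runSource(seed[s]);
    // verify candidates in preference order of their lower bounds
    for (;;) {
      int cand = -1, candLb = std::numeric_limits<int>::max();
      int candDepth = -1, candR = 0, candC = 0;
      for (int i = 0; i < n; ++i) {
        if (done[i]) continue;
        int pr = p[i] % nr, pc = p[i] / nr;
        bool pref;
        if (lb[i] != candLb) pref = lb[i] < candLb;
        else if (depth[i] != candDepth) pref = depth[i] > candDepth;
        else if (pr != candR) pref = pr < candR;
        else pref = pc < candC;
        if (pref) {
          cand = i; candLb = lb[i]; candDepth = depth[i];
          candR = pr; candC = pc;
        }
      }
      if (cand < 0) break;
      bool canBeat = candLb < bestEcc ||
        (candLb == bestEcc && tieBeats(candDepth, candR, candC));
      if (!canBeat) break;
      runSource(cand);
    }
    out(z - 1, 0) = bestR + 1;
    out(z - 1, 1) = bestC + 1;
    for (int i = 0; i < n; ++i) local[p[i]] = -1;
  }
  return out;
}
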