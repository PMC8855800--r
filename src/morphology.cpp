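#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// 8-neighbour offsets, fixed scan order for deterministic BFS tie-breaking
static const int DR8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix fg) {
  int nr = fg.nrow(), nc = fg.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<int> q;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!fg(r, c) || lab(r, c) != 0) continue;
      lab(r, c) = ++next;
      q.push(r + c * nr);
      while (!q.empty()) {
        int idx = q.front(); q.pop();
        int rr = idx % nr, cc = idx / nr;
        for (int k = 0; k < 8; ++k) {
          int r2 = rr + DR8[k], c2 = cc + DC8[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (fg(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            q.push(r2 + c2 * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Background pixels 4-connected to the image border; the complement of the
// result within the background is the set of fully enclosed holes.
// [[Rcpp::export]]
LogicalMatrix cpp_reachable_background(LogicalMatrix fg) {
  int nr = fg.nrow(), nc = fg.ncol();
  LogicalMatrix reach(nr, nc);
  std::queue<int> q;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      bool border = (r == 0 || r == nr - 1 || c == 0 || c == nc - 1);
      if (border && !fg(r, c) && !reach(r, c)) {
        reach(r, c) = true;
        q.push(r + c * nr);
      }
    }
  }
  static const int DR4[4] = {-1, 1, 0, 0};
  static const int DC4[4] = {0, 0, -1, 1};
  while (!q.empty()) {
    int idx = q.front(); q.pop();
    int rr = idx % nr, cc = idx / nr;
    for (int k = 0; k < 4; ++k) {
      int r2 = rr + DR4[k], c2 = cc + DC4[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (!fg(r2, c2) && !reach(r2, c2)) {
        reach(r2, c2) = true;
        q.push(r2 + c2 * nr);
      }
    }
  }
  return reach;
}

static inline int nb(const LogicalMatrix &im, int r, int c) {
  if (r < 0 || r >= im.nrow() || c < 0 || c >= im.ncol()) return 0;
  return im(r, c) ? 1 : 0;
}

// Zhang-Suen thinning; preserves 8-connectivity of the foreground.
// [[Rcpp::export]]
LogicalMatrix cpp_thin(LogicalMatrix fg) {
  int nr = fg.nrow(), nc = fg.ncol();
  LogicalMatrix im = clone(fg);
  bool changed = true;
  std::vector<int> kill;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
          if (!im(r, c)) continue;
          // p2..p9 clockwise from north
          int p2 = nb(im, r - 1, c), p3 = nb(im, r - 1, c + 1);
          int p4 = nb(im, r, c + 1), p5 = nb(im, r + 1, c + 1);
          int p6 = nb(im, r + 1, c), p7 = nb(im, r + 1, c - 1);
          int p8 = nb(im, r, c - 1), p9 = nb(im, r - 1, c - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          bool ok;
          if (pass == 0)
            ok = (p2 * p4 * p6 == 0) && (p4 * p6 * p8 == 0);
          else
            ok = (p2 * p4 * p8 == 0) && (p2 * p6 * p8 == 0);
          if (ok) kill.push_back(r + c * nr);
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t i = 0; i < kill.size(); ++i)
        im(kill[i] % nr, kill[i] / nr) = false;
    }
  }
  return im;
}

// BFS over the skeleton's 8-adjacency graph from (r0, c0); returns geodesic
// step distances (-1 where unreachable/off-skeleton) and BFS parents.
static void skel_bfs(const LogicalMatrix &sk, int r0, int c0,
                     IntegerMatrix &dist, IntegerMatrix &parent) {
  int nr = sk.nrow(), nc = sk.ncol();
  std::fill(dist.begin(), dist.end(), -1);
  std::fill(parent.begin(), parent.end(), -1);
  std::queue<int> q;
  dist(r0, c0) = 0;
  q.push(r0 + c0 * nr);
  while (!q.empty()) {
    int idx = q.front(); q.pop();
    int rr = idx % nr, cc = idx / nr;
    for (int k = 0; k < 8; ++k) {
      int r2 = rr + DR8[k], c2 = cc + DC8[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (sk(r2, c2) && dist(r2, c2) < 0) {
        dist(r2, c2) = dist(rr, cc) + 1;
        parent(r2, c2) = idx;
        q.push(r2 + c2 * nr);
      }
    }
  }
}

// Farthest skeleton pixel by step distance; ties broken by column-major
// (lexicographic in 0-based (col,row) scan == row-within-column) order.
static void farthest(const IntegerMatrix &dist, int &rb, int &cb) {
  int best = -1;
  rb = -1; cb = -1;
  for (int c = 0; c < dist.ncol(); ++c)
    for (int r = 0; r < dist.nrow(); ++r)
      if (dist(r, c) > best) { best = dist(r, c); rb = r; cb = c; }
}

// Longest geodesic path on a skeleton via double farthest-point sweep.
// Returns an n x 2 matrix of 1-based (row, col) coordinates.
// [[Rcpp::export]]
IntegerMatrix cpp_longest_geodesic(LogicalMatrix sk) {
  int nr = sk.nrow(), nc = sk.ncol();
  int r0 = -1, c0 = -1;
  for (int c = 0; c < nc && r0 < 0; ++c)
    for (int r = 0; r < nr; ++r)
      if (sk(r, c)) { r0 = r; c0 = c; break; }
  if (r0 < 0) stop("empty skeleton");
  IntegerMatrix dist(nr, nc), parent(nr, nc);
  skel_bfs(sk, r0, c0, dist, parent);
  int ru, cu; farthest(dist, ru, cu);
  skel_bfs(sk, ru, cu, dist, parent);
  int rv, cv; farthest(dist, rv, cv);
  std::vector<int> path;
  int idx = rv + cv * nr;
  while (idx >= 0) {
    path.push_back(idx);
    idx = parent(idx % nr, idx / nr);
  }
  IntegerMatrix out(path.size(), 2);
  for (size_t i = 0; i < path.size(); ++i) {
    // reverse: start at the first sweep's anchor (ru, cu)
    int id = path[path.size() - 1 - i];
    out(i, 0) = id % nr + 1;
    out(i, 1) = id / nr + 1;
  }
  return out;
}
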