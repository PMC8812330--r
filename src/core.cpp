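// Low-level image primitives with ImageJ-compatible semantics.
// Matrices are R column-major; deterministic orderings use the row-major
// rank (row first, then column) so that "first" means top-left raster order.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline long rank_rc(int i, int j, int nc) { return (long)i * nc + j; }

// ---------------------------------------------------------------- median ---

// [[Rcpp::export]]
NumericMatrix cpp_median_disk(NumericMatrix x, double radius) {
  int nr = x.nrow(), nc = x.ncol();
  // circular kernel: offsets with dy^2 + dx^2 <= r^2
  std::vector<std::pair<int,int> > off;
  int r = (int)std::floor(radius);
  double r2 = radius * radius;
  for (int dy = -r; dy <= r; ++dy)
    for (int dx = -r; dx <= r; ++dx)
      if (dy * dy + dx * dx <= r2) off.push_back(std::make_pair(dy, dx));
  size_t k = off.size();
  NumericMatrix out(nr, nc);
  std::vector<double> buf(k);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      for (size_t q = 0; q < k; ++q) {
        int ii = i + off[q].first, jj = j + off[q].second;
        if (ii < 0) ii = 0; else if (ii >= nr) ii = nr - 1;   // nearest-edge
        if (jj < 0) jj = 0; else if (jj >= nc) jj = nc - 1;
        buf[q] = x(ii, jj);
      }
      size_t m = k / 2;
      std::nth_element(buf.begin(), buf.begin() + m, buf.end());
      double med = buf[m];
      if (k % 2 == 0) {
        double lo = *std::max_element(buf.begin(), buf.begin() + m);
        med = 0.5 * (lo + med);
      }
      out(i, j) = med;
    }
  }
  return out;
}

// ------------------------------------------------------------ union-find ---

struct UF {
  std::vector<int> parent;
  UF(long n) : parent(n, -1) {}
  int find(int a) {
    int r = a;
    while (parent[r] != r) r = parent[r];
    while (parent[a] != r) { int nxt = parent[a]; parent[a] = r; a = nxt; }
    return r;
  }
};

// Prominence-based maxima (ImageJ Find Maxima noise-tolerance semantics).
// A maximum survives iff its height above the highest saddle connecting it
// to strictly higher ground exceeds `prominence`. Plateaus yield a single
// representative: the lexicographically smallest (row, col) pixel.
// [[Rcpp::export]]
IntegerMatrix cpp_find_maxima(NumericMatrix x, double prominence) {
  int nr = x.nrow(), nc = x.ncol();
  long n = (long)nr * nc;
  std::vector<int> ord(n);
  for (long k = 0; k < n; ++k) ord[k] = (int)k;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    double xa = x[a], xb = x[b];
    if (xa != xb) return xa > xb;
    long ra = rank_rc(a % nr, a / nr, nc), rb = rank_rc(b % nr, b / nr, nc);
    return ra < rb;
  });

  UF uf(n);
  std::vector<double> maxh(n, 0.0);
  // pending maxima (pixels at the component's max height whose fate is
  // undecided); indexed by current root
  std::vector<std::vector<int> > pending(n);
  std::vector<int> confirmed;
  std::vector<char> processed(n, 0);

  auto plateau_rep = [&](std::vector<int>& v) {
    // collapse to the pixel with smallest row-major rank
    int best = v[0];
    long bestr = rank_rc(best % nr, best / nr, nc);
    for (size_t q = 1; q < v.size(); ++q) {
      long rq = rank_rc(v[q] % nr, v[q] / nr, nc);
      if (rq < bestr) { best = v[q]; bestr = rq; }
    }
    v.clear(); v.push_back(best);
  };

  for (long t = 0; t < n; ++t) {
    int k = ord[t];
    int i = k % nr, j = k / nr;
    double h = x[k];
    // distinct processed neighbour roots (8-connectivity)
    int roots[8]; int nroots = 0;
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0) continue;
        int ii = i + di, jj = j + dj;
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        int q = ii + jj * nr;
        if (!processed[q]) continue;
        int r = uf.find(q);
        bool seen = false;
        for (int s = 0; s < nroots; ++s) if (roots[s] == r) { seen = true; break; }
        if (!seen) roots[nroots++] = r;
      }
    }
    if (nroots == 0) {
      uf.parent[k] = k;
      maxh[k] = h;
      pending[k].assign(1, k);
    } else {
      int master = roots[0];
      for (int s = 1; s < nroots; ++s) {
        int a = master, b = roots[s];
        if (maxh[a] < maxh[b]) std::swap(a, b);
        if (maxh[a] > maxh[b]) {
          // b's pending maxima meet strictly higher ground at saddle h
          for (size_t q = 0; q < pending[b].size(); ++q) {
            if (maxh[b] - h > prominence) confirmed.push_back(pending[b][q]);
          }
          pending[b].clear();
        } else {
          // equal summit heights
          pending[a].insert(pending[a].end(), pending[b].begin(), pending[b].end());
          pending[b].clear();
          if (maxh[a] == h) plateau_rep(pending[a]);  // same connected plateau
        }
        uf.parent[b] = a;
        master = a;
      }
      uf.parent[k] = master;
      if (h == maxh[master] && pending[master].size() > 0) {
        // plateau extension: representative stays the earliest pixel
      }
    }
    processed[k] = 1;
  }
  // whatever is still pending has no higher ground: global maxima, confirmed
  for (long k = 0; k < n; ++k) {
    if (uf.parent[k] == (int)k) {
      for (size_t q = 0; q < pending[k].size(); ++q)
        confirmed.push_back(pending[k][q]);
    }
  }
  std::sort(confirmed.begin(), confirmed.end(), [&](int a, int b) {
    return rank_rc(a % nr, a / nr, nc) < rank_rc(b % nr, b / nr, nc);
  });
  IntegerMatrix peaks(confirmed.size(), 2);
  for (size_t q = 0; q < confirmed.size(); ++q) {
    peaks(q, 0) = confirmed[q] % nr + 1;  // 1-based row
    peaks(q, 1) = confirmed[q] / nr + 1;  // 1-based col
  }
  return peaks;
}

// Marker flooding on the descending landscape ("segmented particles").
// Seeds grow downhill in order of decreasing intensity. Within one
// intensity level the flood advances in synchronous BFS waves, so that
// on plateaus (notably the flat background of a distance transform)
// fronts grow geodesically and meeting lines fall near the equidistant
// ridge; inside a wave pixels are visited in (row, col) order, which
// keeps the partition bit-reproducible. A pixel whose 4-neighbours
// carry two distinct labels becomes a ridge ("limit") pixel, encoded 0.
// Regions are 4-connected.
// [[Rcpp::export]]
IntegerMatrix cpp_flood_particles(NumericMatrix x, IntegerMatrix peaks) {
  int nr = x.nrow(), nc = x.ncol();
  long n = (long)nr * nc;
  std::vector<int> lab(n, 0);           // 0 unassigned, -1 limit, >0 region
  std::vector<char> queued(n, 0);
  struct Item { double h; long rk; int px; int lab; };
  struct Cmp {
    bool operator()(const Item& a, const Item& b) const {
      return a.h < b.h;                          // max-heap on height only
    }
  };
  std::priority_queue<Item, std::vector<Item>, Cmp> pq;
  const int di4[4] = { -1, 1, 0, 0 };
  const int dj4[4] = { 0, 0, -1, 1 };

  int npeaks = peaks.nrow();
  auto push_nbrs = [&](int k, int assign) {
    int i = k % nr, j = k / nr;
    for (int d = 0; d < 4; ++d) {
      int ii = i + di4[d], jj = j + dj4[d];
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
      int q = ii + jj * nr;
      if (lab[q] == 0 && !queued[q]) {
        queued[q] = 1;
        Item it = { x[q], rank_rc(ii, jj, nc), q, assign };
        pq.push(it);
      }
    }
  };
  for (int p = 0; p < npeaks; ++p) {
    int i = peaks(p, 0) - 1, j = peaks(p, 1) - 1;
    lab[i + j * nr] = p + 1;
  }
  for (int p = 0; p < npeaks; ++p) {
    int i = peaks(p, 0) - 1, j = peaks(p, 1) - 1;
    push_nbrs(i + j * nr, p + 1);
  }
  std::vector<Item> wave;
  while (!pq.empty()) {
    double h0 = pq.top().h;
    wave.clear();
    while (!pq.empty() && pq.top().h == h0) {   // one BFS ring at this level
      wave.push_back(pq.top()); pq.pop();
    }
    std::sort(wave.begin(), wave.end(), [](const Item& a, const Item& b) {
      return a.rk < b.rk;
    });
    for (size_t w = 0; w < wave.size(); ++w) {
      int k = wave[w].px;
      if (lab[k] != 0) continue;
      int i = k % nr, j = k / nr;
      int found = 0; bool multi = false;
      for (int d = 0; d < 4; ++d) {
        int ii = i + di4[d], jj = j + dj4[d];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        int l = lab[ii + jj * nr];
        if (l > 0) {
          if (found == 0) found = l;
          else if (found != l) { multi = true; break; }
        }
      }
      if (multi) { lab[k] = -1; continue; }
      int assign = found > 0 ? found : wave[w].lab;
      lab[k] = assign;
      push_nbrs(k, assign);
    }
  }
  IntegerMatrix out(nr, nc);
  // limits and (rare) pixels enclosed by limit junctions are encoded 0
  for (long k = 0; k < n; ++k) out[k] = lab[k] > 0 ? lab[k] : 0;
  return out;
}

// ----------------------------------------------------- connected labels ---

// Raster-order connected-component labelling, connectivity 4 or 8.
// [[Rcpp::export]]
IntegerMatrix cpp_label(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  const int di8[8] = { -1, 1, 0, 0, -1, -1, 1, 1 };
  const int dj8[8] = { 0, 0, -1, 1, -1, 1, -1, 1 };
  int nd = (connectivity == 8) ? 8 : 4;
  for (int i = 0; i < nr; ++i) {       // row-major scan: top-left first
    for (int j = 0; j < nc; ++j) {
      int k = i + j * nr;
      if (!mask[k] || lab[k] != 0) continue;
      ++next;
      stack.clear(); stack.push_back(k);
      lab[k] = next;
      while (!stack.empty()) {
        int q = stack.back(); stack.pop_back();
        int qi = q % nr, qj = q / nr;
        for (int d = 0; d < nd; ++d) {
          int ii = qi + di8[d], jj = qj + dj8[d];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          int p = ii + jj * nr;
          if (mask[p] && lab[p] == 0) { lab[p] = next; stack.push_back(p); }
        }
      }
    }
  }
  return lab;
}

// -------------------------------------------------- Zhang-Suen thinning ---

// [[Rcpp::export]]
LogicalMatrix cpp_thin(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  std::vector<char> img((long)nr * nc);
  for (long k = 0; k < (long)nr * nc; ++k) img[k] = mask[k] ? 1 : 0;
  auto at = [&](int i, int j) -> int {
    if (i < 0 || i >= nr || j < 0 || j >= nc) return 0;
    return img[i + (long)j * nr];
  };
  std::vector<long> kill;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
          long k = i + (long)j * nr;
          if (!img[k]) continue;
          int p2 = at(i - 1, j),     p3 = at(i - 1, j + 1), p4 = at(i, j + 1);
          int p5 = at(i + 1, j + 1), p6 = at(i + 1, j),     p7 = at(i + 1, j - 1);
          int p8 = at(i, j - 1),     p9 = at(i - 1, j - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(k);
        }
      }
      if (!kill.empty()) {
        changed = true;
        for (size_t q = 0; q < kill.size(); ++q) img[kill[q]] = 0;
      }
    }
  }
  LogicalMatrix out(nr, nc);
  for (long k = 0; k < (long)nr * nc; ++k) out[k] = img[k] != 0;
  return out;
}

// -------------------------------------------- Moore boundary chain code ---

// Per-label outer-boundary chain: returns an n_labels x 2 matrix of
// (orthogonal step count, diagonal step count) along the traced contour.
// Single-pixel labels return (0, 0).
// [[Rcpp::export]]
NumericMatrix cpp_boundary_chain(IntegerMatrix lab, int n_labels) {
  int nr = lab.nrow(), nc = lab.ncol();
  NumericMatrix out(n_labels, 2);
  // clockwise Moore neighbourhood starting East (image coords: row down)
  const int mi[8] = { 0, 1, 1, 1, 0, -1, -1, -1 };
  const int mj[8] = { 1, 1, 0, -1, -1, -1, 0, 1 };
  std::vector<char> started(n_labels, 0);
  for (int i = 0; i < nr && true; ++i) {
    for (int j = 0; j < nc; ++j) {
      int l = lab(i, j);
      if (l <= 0 || l > n_labels || started[l - 1]) continue;
      started[l - 1] = 1;
      // start pixel: first in raster order; its West neighbour is background
      int si = i, sj = j;
      // backtrack direction index: pointing West (index 4)
      int ci = si, cj = sj, bdir = 4;
      long north = 0, ndiag = 0;
      long guard = 8L * nr * nc + 16;
      int fi = -1, fj = -2, ffound = 0; // first move, for stop criterion
      while (guard-- > 0) {
        int dir = (bdir + 1) % 8;  // start clockwise after backtrack
        int step = -1;
        for (int s = 0; s < 8; ++s) {
          int d = (dir + s) % 8;
          int ii = ci + mi[d], jj = cj + mj[d];
          if (ii >= 0 && ii < nr && jj >= 0 && jj < nc && lab(ii, jj) == l) {
            step = d; break;
          }
        }
        if (step < 0) break;  // isolated pixel
        int ni = ci + mi[step], nj = cj + mj[step];
        if (!ffound) { fi = ni; fj = nj; ffound = 1; }
        else if (ci == si && cj == sj && ni == fi && nj == fj) break; // loop closed
        if (mi[step] != 0 && mj[step] != 0) ++ndiag; else ++north;
        // new backtrack: direction from new pixel to previous contour pixel
        int back = (step + 4) % 8;
        // rotate to the neighbour just before `step` seen from new pixel:
        // standard Moore: backtrack is the pixel we came from
        bdir = back;
        ci = ni; cj = nj;
        if (ci == si && cj == sj && ffound) {
          // potentially closed; loop continues until repeat of first move
        }
      }
      out(l - 1, 0) = (double)north;
      out(l - 1, 1) = (double)ndiag;
    }
  }
  return out;
}
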