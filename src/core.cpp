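#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Multi-source BFS hole fill over the 8-neighbourhood (chessboard metric).
// Each zero ("hole") pixel receives the minimum depth among the valid pixels
// at minimal chessboard distance. Level-synchronous so the result is
// independent of traversal order.
// [[Rcpp::export]]
IntegerMatrix cpp_fill_holes(IntegerMatrix m) {
  int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix out(nr, nc);
  std::vector<int> dist(nr * nc, -1);
  std::vector<int> cur, nxt;
  cur.reserve(nr * nc);
  const int *src = INTEGER(m);
  int *dst = INTEGER(out);
  long npix = (long)nr * nc;
  std::vector<int> holes;
  for (long idx = 0; idx < npix; ++idx) {
    dst[idx] = src[idx];
    if (src[idx] > 0) dist[idx] = 0; else holes.push_back((int)idx);
  }
  if (holes.empty()) return out;
  if ((long)holes.size() == npix)
    stop("all-zero frame: no valid pixels to fill from");
  const int di0[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj0[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  // frontier: valid pixels bordering a hole (duplicates are harmless)
  for (size_t k = 0; k < holes.size(); ++k) {
    int i = holes[k] % nr, j = holes[k] / nr;
    for (int n = 0; n < 8; ++n) {
      int ii = i + di0[n], jj = j + dj0[n];
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
      if (src[jj * nr + ii] > 0) cur.push_back(jj * nr + ii);
    }
  }
  int level = 0;
  const int di[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  while (!cur.empty()) {
    ++level;
    nxt.clear();
    // first mark the next frontier, then combine by min over filled neighbours
    for (size_t k = 0; k < cur.size(); ++k) {
      int i = cur[k] % nr, j = cur[k] / nr;
      for (int n = 0; n < 8; ++n) {
        int ii = i + di[n], jj = j + dj[n];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        int idx = jj * nr + ii;
        if (dist[idx] == -1) { dist[idx] = level; nxt.push_back(idx); }
      }
    }
    for (size_t k = 0; k < nxt.size(); ++k) {
      int i = nxt[k] % nr, j = nxt[k] / nr;
      int best = -1;
      for (int n = 0; n < 8; ++n) {
        int ii = i + di[n], jj = j + dj[n];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        if (dist[jj * nr + ii] == level - 1) {
          int v = out(ii, jj);
          if (best < 0 || v < best) best = v;
        }
      }
      out(i, j) = best;
    }
    cur.swap(nxt);
  }
  return out;
}

// Sliding-window median with edge-replicated borders (window = odd side
// length). Huang's running-histogram algorithm with a serpentine walk over
// the padded image: the histogram and the count of elements below the
// current median are updated incrementally, so the cost per pixel is the
// window side, not the window area.
// [[Rcpp::export]]
IntegerMatrix cpp_median_filter(IntegerMatrix m, int window) {
  int nr = m.nrow(), nc = m.ncol();
  int r = window / 2, w = window, w2 = w * w;
  int target = w2 / 2;  // 0-based rank of the median
  IntegerMatrix out(nr, nc);
  const int *src = INTEGER(m);
  int *dst = INTEGER(out);
  // replicated padding
  int pr = nr + 2 * r, pcn = nc + 2 * r;
  std::vector<int> pad((size_t)pr * pcn);
  int vmax = 0;
  for (int j = 0; j < pcn; ++j) {
    int sj = j - r;
    if (sj < 0) sj = 0; else if (sj >= nc) sj = nc - 1;
    const int *col = src + (size_t)sj * nr;
    int *pcol = pad.data() + (size_t)j * pr;
    for (int i = 0; i < pr; ++i) {
      int si = i - r;
      if (si < 0) si = 0; else if (si >= nr) si = nr - 1;
      int v = col[si];
      pcol[i] = v;
      if (v > vmax) vmax = v;
    }
  }
  // fine histogram plus 64-value coarse blocks to skip empty depth ranges
  int nbins = ((vmax >> 6) + 2) << 6;
  std::vector<int> hist(nbins, 0);
  std::vector<int> coarse(nbins >> 6, 0);
  auto padv = [&](int i, int j) { return pad[(size_t)j * pr + i]; };
  int med = 0, less = 0;  // 'less' = #elements < med
  auto add = [&](int v) { ++hist[v]; ++coarse[v >> 6]; if (v < med) ++less; };
  auto rem = [&](int v) { --hist[v]; --coarse[v >> 6]; if (v < med) --less; };
  // window top-left in padded coords = output pixel (i, j)
  int i = 0, j = 0;
  for (int a = 0; a < w; ++a)
    for (int b = 0; b < w; ++b) { int v = padv(a, b); ++hist[v]; ++coarse[v >> 6]; }
  less = 0;  // med = 0: nothing below
  bool down = true;
  while (true) {
    // adjust median to rank `target`, skipping empty 64-value blocks
    while (less > target) {
      if ((med & 63) == 0 && med >= 64 && coarse[(med >> 6) - 1] == 0) {
        med -= 64;
        continue;
      }
      --med; less -= hist[med];
    }
    while (less + hist[med] <= target) {
      if ((med & 63) == 0 && coarse[med >> 6] == 0) { med += 64; continue; }
      less += hist[med]; ++med;
    }
    dst[(size_t)j * nr + i] = med;
    if (down) {
      if (i + 1 < nr) {
        for (int b = 0; b < w; ++b) { rem(padv(i, j + b)); add(padv(i + w, j + b)); }
        ++i;
        continue;
      }
    } else {
      if (i > 0) {
        for (int b = 0; b < w; ++b) { rem(padv(i + w - 1, j + b)); add(padv(i - 1, j + b)); }
        --i;
        continue;
      }
    }
    if (j + 1 >= nc) break;
    for (int a = 0; a < w; ++a) { rem(padv(i + a, j)); add(padv(i + a, j + w)); }
    ++j;
    down = !down;
  }
  return out;
}

// 8-connected component labelling; labels assigned in column-major
// first-encounter order (deterministic).
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  const int di[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  std::queue<int> q;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      lab(i, j) = ++next;
      q.push(j * nr + i);
      while (!q.empty()) {
        int idx = q.front(); q.pop();
        int ci = idx % nr, cj = idx / nr;
        for (int n = 0; n < 8; ++n) {
          int ii = ci + di[n], jj = cj + dj[n];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (mask(ii, jj) && lab(ii, jj) == 0) {
            lab(ii, jj) = next;
            q.push(jj * nr + ii);
          }
        }
      }
    }
  return lab;
}

// Sensor-noise model for the synthetic renderer: zero-mean Gaussian mm
// noise everywhere (values clamped to >= 1 mm) plus hole dropout within
// `band` chessboard pixels of a depth discontinuity (neighbour jump >
// `jump_mm`). Uses R's RNG so a set.seed() in R makes it reproducible.
// [[Rcpp::export]]
IntegerMatrix cpp_scene_noise(IntegerMatrix m, double sigma,
                              double hole_rate, double jump_mm, int band) {
  int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix out(nr, nc);
  const int *src = INTEGER(m);
  int *dst = INTEGER(out);
  RNGScope scope;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      size_t idx = (size_t)j * nr + i;
      int v = src[idx];
      if (sigma > 0) {
        v += (int)std::lround(R::rnorm(0.0, sigma));
        if (v < 1) v = 1;
      }
      if (hole_rate > 0) {
        bool near_edge = false;
        int centre = src[idx];
        for (int dj = -band; dj <= band && !near_edge; ++dj) {
          int jj = j + dj;
          if (jj < 0) jj = 0; else if (jj >= nc) jj = nc - 1;
          const int *col = src + (size_t)jj * nr;
          for (int di = -band; di <= band && !near_edge; ++di) {
            int ii = i + di;
            if (ii < 0) ii = 0; else if (ii >= nr) ii = nr - 1;
            if (std::abs(col[ii] - centre) > jump_mm) near_edge = true;
          }
        }
        if (near_edge && R::unif_rand() < hole_rate) v = 0;
      }
      dst[idx] = v;
    }
  return out;
}

static double energy_raw(const double *nx, const double *ny, const double *nz,
                         int K, const double *px, const double *py,
                         const double *pz, int n) {
  double total = 0.0;
  for (int k = 0; k < K; ++k) {
    double best = R_PosInf;
    double ax = nx[k], ay = ny[k], az = nz[k];
    for (int p = 0; p < n; ++p) {
      double dx = ax - px[p], dy = ay - py[p], dz = az - pz[p];
      double d = dx * dx + dy * dy + dz * dz;
      if (d < best) best = d;
    }
    total += std::sqrt(best);
  }
  return total / K;
}

// Mean over nodes of the distance to the nearest cloud point (fit energy).
// [[Rcpp::export]]
double cpp_fit_energy(NumericMatrix nodes, NumericMatrix pts) {
  int K = nodes.nrow(), n = pts.nrow();
  const double *nd = REAL(nodes), *pd = REAL(pts);
  return energy_raw(nd, nd + K, nd + 2 * K, K, pd, pd + n, pd + 2 * n, n);
}

// Damped batch Kohonen competitive learning, `epochs` rounds per call.
// Each round: every point elects its winner node (minimal Euclidean
// distance, ties -> lowest index); each node's target is the Gaussian
// hop-weighted centroid of the points won by it and its topological
// neighbours; nodes move a fraction `lr` toward their target. Batch
// accumulation makes the round independent of point order. Learning rate
// and radius decay linearly over the rounds. The returned node matrix is
// the round snapshot (warm start included) with the lowest fit energy, so
// the energy never increases across a call.
// [[Rcpp::export]]
List cpp_som_fit(NumericMatrix nodes0, NumericMatrix pts, NumericMatrix hops,
                 int epochs, double lr0, double lr1,
                 double rad0, double rad1) {
  int K = nodes0.nrow(), n = pts.nrow();
  std::vector<double> cx(K), cy(K), cz(K);
  for (int k = 0; k < K; ++k) {
    cx[k] = nodes0(k, 0); cy[k] = nodes0(k, 1); cz[k] = nodes0(k, 2);
  }
  const double *pd = REAL(pts);
  const double *px = pd, *py = pd + n, *pz = pd + 2 * n;
  std::vector<int> hop(K * K);
  int hmax = 0;
  for (int a = 0; a < K; ++a)
    for (int b = 0; b < K; ++b) {
      int h = (int)hops(a, b);
      hop[a * K + b] = h;
      if (h > hmax) hmax = h;
    }
  std::vector<double> gtab(hmax + 1);
  std::vector<double> W(K), Sx(K), Sy(K), Sz(K);
  double best_e = energy_raw(cx.data(), cy.data(), cz.data(), K,
                             px, py, pz, n);
  std::vector<double> bx(cx), by(cy), bz(cz);
  NumericVector trace(epochs + 1);
  trace[0] = best_e;
  for (int e = 0; e < epochs; ++e) {
    double frac = epochs > 1 ? (double)e / (double)(epochs - 1) : 0.0;
    double lr = lr0 + (lr1 - lr0) * frac;
    double sigma = rad0 + (rad1 - rad0) * frac;
    if (sigma < 1e-9) sigma = 1e-9;
    int hcut = hmax;
    for (int h = 0; h <= hmax; ++h) {
      gtab[h] = std::exp(-(double)(h * h) / (2.0 * sigma * sigma));
      if (gtab[h] < 0.01) { hcut = h - 1; break; }
    }
    std::fill(W.begin(), W.end(), 0.0);
    std::fill(Sx.begin(), Sx.end(), 0.0);
    std::fill(Sy.begin(), Sy.end(), 0.0);
    std::fill(Sz.begin(), Sz.end(), 0.0);
    for (int p = 0; p < n; ++p) {
      double qx = px[p], qy = py[p], qz = pz[p];
      int win = 0;
      double wd = R_PosInf;
      for (int k = 0; k < K; ++k) {
        double dx = cx[k] - qx, dy = cy[k] - qy, dz = cz[k] - qz;
        double d = dx * dx + dy * dy + dz * dz;
        if (d < wd) { wd = d; win = k; }
      }
      const int *hrow = hop.data() + (size_t)win * K;
      for (int k = 0; k < K; ++k) {
        int h = hrow[k];
        if (h > hcut) continue;
        double g = gtab[h];
        W[k] += g;
        Sx[k] += g * qx; Sy[k] += g * qy; Sz[k] += g * qz;
      }
    }
    for (int k = 0; k < K; ++k) {
      if (W[k] <= 1e-12) continue;  // no support: node keeps its position
      cx[k] += lr * (Sx[k] / W[k] - cx[k]);
      cy[k] += lr * (Sy[k] / W[k] - cy[k]);
      cz[k] += lr * (Sz[k] / W[k] - cz[k]);
    }
    double en = energy_raw(cx.data(), cy.data(), cz.data(), K, px, py, pz, n);
    trace[e + 1] = en;
    if (en < best_e) { best_e = en; bx = cx; by = cy; bz = cz; }
  }
  // accept the final round unless it worsened the warm start, in which case
  // fall back to the best snapshot: the energy never exceeds the entry value
  double final_e = trace[epochs];
  if (final_e <= trace[0] + 1e-12) {
    best_e = final_e; bx = cx; by = cy; bz = cz;
  }
  NumericMatrix best(K, 3);
  for (int k = 0; k < K; ++k) {
    best(k, 0) = bx[k]; best(k, 1) = by[k]; best(k, 2) = bz[k];
  }
  return List::create(_["nodes"] = best, _["energy"] = best_e,
                      _["trace"] = trace);
}
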