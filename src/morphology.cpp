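#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher, 2-pass
// lower-envelope-of-parabolas). Returns, for every pixel, the distance in
// pixel units to the nearest background (false) pixel; 0 on background.
// ---------------------------------------------------------------------------

static const double DT_INF = 1e20;

static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = (double)q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_edt(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  NumericMatrix out(nr, nc);
  int nmax = std::max(nr, nc);
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // squared distance, columns then rows
  std::vector<double> sq((size_t)nr * nc);
  for (int j = 0; j < nc; j++) {
    for (int i = 0; i < nr; i++) f[i] = mask(i, j) ? DT_INF : 0.0;
    dt1d(f, d, nr, v, z);
    for (int i = 0; i < nr; i++) sq[(size_t)j * nr + i] = d[i];
  }
  for (int i = 0; i < nr; i++) {
    for (int j = 0; j < nc; j++) f[j] = sq[(size_t)j * nr + i];
    dt1d(f, d, nc, v, z);
    for (int j = 0; j < nc; j++) out(i, j) = std::sqrt(d[j]);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Zhang-Suen morphological thinning to a one-pixel-wide 8-connected skeleton.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
LogicalMatrix cpp_thin(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  // pad by 1 to avoid border checks
  int h = nr + 2, w = nc + 2;
  std::vector<unsigned char> img((size_t)h * w, 0);
  for (int j = 0; j < nc; j++)
    for (int i = 0; i < nr; i++)
      img[(size_t)(j + 1) * h + (i + 1)] = mask(i, j) ? 1 : 0;

  std::vector<size_t> to_clear;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; pass++) {
      to_clear.clear();
      for (int j = 1; j <= nc; j++) {
        for (int i = 1; i <= nr; i++) {
          size_t idx = (size_t)j * h + i;
          if (!img[idx]) continue;
          // neighbours clockwise from north: p2..p9
          unsigned char p2 = img[idx - 1];
          unsigned char p3 = img[idx + h - 1];
          unsigned char p4 = img[idx + h];
          unsigned char p5 = img[idx + h + 1];
          unsigned char p6 = img[idx + 1];
          unsigned char p7 = img[idx - h + 1];
          unsigned char p8 = img[idx - h];
          unsigned char p9 = img[idx - h - 1];
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0) continue;
            if (p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0) continue;
            if (p2 * p6 * p8 != 0) continue;
          }
          to_clear.push_back(idx);
        }
      }
      if (!to_clear.empty()) changed = true;
      for (size_t k = 0; k < to_clear.size(); k++) img[to_clear[k]] = 0;
    }
  }

  // final sequential pass: delete remaining 8-simple pixels (Yokoi
  // connectivity number C8 == 1, 2 <= B <= 6). Zhang-Suen's parallel
  // sub-iterations can leave two-pixel-wide diagonal staircases whose
  // pixels have crossing number 2 but are nonetheless simple (the two arcs
  // meet around a corner); sequential deletion collapses them while
  // preserving topology and endpoints.
  changed = true;
  while (changed) {
    changed = false;
    for (int j = 1; j <= nc; j++) {
      for (int i = 1; i <= nr; i++) {
        size_t idx = (size_t)j * h + i;
        if (!img[idx]) continue;
        // neighbours clockwise from north: p2..p9 (p index k -> pk)
        unsigned char p[10];
        p[2] = img[idx - 1];
        p[3] = img[idx + h - 1];
        p[4] = img[idx + h];
        p[5] = img[idx + h + 1];
        p[6] = img[idx + 1];
        p[7] = img[idx - h + 1];
        p[8] = img[idx - h];
        p[9] = img[idx - h - 1];
        int B = p[2] + p[3] + p[4] + p[5] + p[6] + p[7] + p[8] + p[9];
        if (B < 2 || B > 6) continue;
        int C8 = 0;
        for (int k = 2; k <= 8; k += 2) {
          int b0 = 1 - p[k];
          int b1 = 1 - p[k + 1];
          int b2_ = 1 - p[k + 2 > 9 ? 2 : k + 2];
          C8 += b0 - b0 * b1 * b2_;
        }
        if (C8 != 1) continue;
        img[idx] = 0;
        changed = true;
      }
    }
  }

  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; j++)
    for (int i = 0; i < nr; i++)
      out(i, j) = img[(size_t)(j + 1) * h + (i + 1)] != 0;
  return out;
}

// ---------------------------------------------------------------------------
// Connected-component labelling (4- or 8-connectivity), iterative flood fill.
// Labels are 1..K in scan order; 0 = not in foreground.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_label(LogicalMatrix mask, int connectivity = 8) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int ndirs = (connectivity == 4) ? 4 : 8;
  int dr[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  int dc[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < nc; j++) {
    for (int i = 0; i < nr; i++) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      next++;
      stack.clear();
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        int cur = stack.back();
        stack.pop_back();
        int ci = cur % nr, cj = cur / nr;
        for (int d = 0; d < ndirs; d++) {
          int ni = ci + dr[d], nj = cj + dc[d];
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
          if (mask(ni, nj) && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            stack.push_back(ni + nj * nr);
          }
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Capsule rasterisation. Segments are rows (x1, y1, x2, y2, r) in micrometre
// coordinates; the image frame spans x in [0, ncol*px], y in [0, nrow*px]
// with pixel (i, j) centred at x = (j - 0.5)px, y = (i - 0.5)px (1-based).
// ---------------------------------------------------------------------------

static inline double seg_dist2(double px_, double py_, double x1, double y1,
                               double x2, double y2) {
  double dx = x2 - x1, dy = y2 - y1;
  double L2 = dx * dx + dy * dy;
  double t = 0.0;
  if (L2 > 0.0) {
    t = ((px_ - x1) * dx + (py_ - y1) * dy) / L2;
    if (t < 0.0) t = 0.0;
    if (t > 1.0) t = 1.0;
  }
  double ex = px_ - (x1 + t * dx), ey = py_ - (y1 + t * dy);
  return ex * ex + ey * ey;
}

// [[Rcpp::export]]
LogicalMatrix cpp_capsule_mask(NumericMatrix segs, int nrow_px, int ncol_px,
                               double pixel_size) {
  LogicalMatrix out(nrow_px, ncol_px);
  std::fill(out.begin(), out.end(), false);
  for (int s = 0; s < segs.nrow(); s++) {
    double x1 = segs(s, 0), y1 = segs(s, 1), x2 = segs(s, 2), y2 = segs(s, 3),
           r = segs(s, 4);
    double r2 = r * r;
    double xmin = std::min(x1, x2) - r, xmax = std::max(x1, x2) + r;
    double ymin = std::min(y1, y2) - r, ymax = std::max(y1, y2) + r;
    int j0 = std::max(0, (int)std::floor(xmin / pixel_size));
    int j1 = std::min(ncol_px - 1, (int)std::ceil(xmax / pixel_size));
    int i0 = std::max(0, (int)std::floor(ymin / pixel_size));
    int i1 = std::min(nrow_px - 1, (int)std::ceil(ymax / pixel_size));
    for (int j = j0; j <= j1; j++) {
      double xc = (j + 0.5) * pixel_size;
      for (int i = i0; i <= i1; i++) {
        if (out(i, j)) continue;
        double yc = (i + 0.5) * pixel_size;
        if (seg_dist2(xc, yc, x1, y1, x2, y2) <= r2) out(i, j) = true;
      }
    }
  }
  return out;
}

// Supersampled area fraction of the capsule union over the frame.
// [[Rcpp::export]]
double cpp_capsule_coverage(NumericMatrix segs, int nrow_px, int ncol_px,
                            double pixel_size, int supersample) {
  int H = nrow_px * supersample, W = ncol_px * supersample;
  double sub = pixel_size / supersample;
  std::vector<unsigned char> hit((size_t)H * W, 0);
  for (int s = 0; s < segs.nrow(); s++) {
    double x1 = segs(s, 0), y1 = segs(s, 1), x2 = segs(s, 2), y2 = segs(s, 3),
           r = segs(s, 4);
    double r2 = r * r;
    double xmin = std::min(x1, x2) - r, xmax = std::max(x1, x2) + r;
    double ymin = std::min(y1, y2) - r, ymax = std::max(y1, y2) + r;
    int j0 = std::max(0, (int)std::floor(xmin / sub));
    int j1 = std::min(W - 1, (int)std::ceil(xmax / sub));
    int i0 = std::max(0, (int)std::floor(ymin / sub));
    int i1 = std::min(H - 1, (int)std::ceil(ymax / sub));
    for (int j = j0; j <= j1; j++) {
      double xc = (j + 0.5) * sub;
      for (int i = i0; i <= i1; i++) {
        size_t idx = (size_t)j * H + i;
        if (hit[idx]) continue;
        double yc = (i + 0.5) * sub;
        if (seg_dist2(xc, yc, x1, y1, x2, y2) <= r2) hit[idx] = 1;
      }
    }
  }
  size_t n = 0;
  for (size_t k = 0; k < hit.size(); k++) n += hit[k];
  return (double)n / ((double)H * W);
}

// Count of true 8-neighbours at every pixel.
// [[Rcpp::export]]
IntegerMatrix cpp_neighbor_count(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix out(nr, nc);
  for (int j = 0; j < nc; j++) {
    for (int i = 0; i < nr; i++) {
      int n = 0;
      for (int dj = -1; dj <= 1; dj++) {
        for (int di = -1; di <= 1; di++) {
          if (di == 0 && dj == 0) continue;
          int ni = i + di, nj = j + dj;
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
          if (mask(ni, nj)) n++;
        }
      }
      out(i, j) = n;
    }
  }
  return out;
}

// Crossing number: 0->1 transitions around the 8-neighbourhood cycle.
// Branch pixels of a thin skeleton have >= 3, endpoints exactly 1.
// [[Rcpp::export]]
IntegerMatrix cpp_crossing_number(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix out(nr, nc);
  int dri[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  int dcj[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  for (int j = 0; j < nc; j++) {
    for (int i = 0; i < nr; i++) {
      if (!mask(i, j)) { out(i, j) = 0; continue; }
      int v[8];
      for (int k = 0; k < 8; k++) {
        int ni = i + dri[k], nj = j + dcj[k];
        v[k] = (ni >= 0 && ni < nr && nj >= 0 && nj < nc && mask(ni, nj)) ? 1 : 0;
      }
      int t = 0;
      for (int k = 0; k < 8; k++) t += (v[k] == 0 && v[(k + 1) % 8] == 1);
      out(i, j) = t;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Order the pixels of each labelled arc (degree <= 2 path) into a walk.
// Returns 1-based column-major linear indices per arc plus a closed flag
// (cycle without termini). Pixels unreachable from the chosen start (only
// possible for degenerate non-path arcs) are dropped.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_trace_arcs(IntegerMatrix lab, int n_arcs) {
  int nr = lab.nrow(), nc = lab.ncol();
  std::vector<std::vector<int>> members(n_arcs + 1);
  for (int j = 0; j < nc; j++)
    for (int i = 0; i < nr; i++)
      if (lab(i, j) > 0) members[lab(i, j)].push_back(i + j * nr);

  // orthogonal first, then diagonal
  int dr[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  int dc[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  std::vector<char> vis((size_t)nr * nc, 0);

  List paths(n_arcs);
  LogicalVector closed(n_arcs);
  for (int a = 1; a <= n_arcs; a++) {
    std::vector<int>& px = members[a];
    int start = -1;
    for (size_t k = 0; k < px.size(); k++) {
      int ci = px[k] % nr, cj = px[k] / nr;
      int deg = 0;
      for (int d = 0; d < 8; d++) {
        int ni = ci + dr[d], nj = cj + dc[d];
        if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
        if (lab(ni, nj) == a) deg++;
      }
      if (deg <= 1) { start = px[k]; break; }
    }
    bool is_cycle = (start < 0);
    if (is_cycle) start = px.empty() ? -1 : px[0];
    std::vector<int> path;
    if (start >= 0) {
      int cur = start;
      vis[cur] = 1;
      path.push_back(cur);
      bool moved = true;
      while (moved) {
        moved = false;
        int ci = cur % nr, cj = cur / nr;
        for (int d = 0; d < 8; d++) {
          int ni = ci + dr[d], nj = cj + dc[d];
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
          if (lab(ni, nj) == a && !vis[ni + nj * nr]) {
            cur = ni + nj * nr;
            vis[cur] = 1;
            path.push_back(cur);
            moved = true;
            break;
          }
        }
      }
    }
    for (size_t k = 0; k < px.size(); k++) vis[px[k]] = 0;
    IntegerVector pv(path.size());
    for (size_t k = 0; k < path.size(); k++) pv[k] = path[k] + 1;
    paths[a - 1] = pv;
    closed[a - 1] = is_cycle;
  }
  return List::create(_["paths"] = paths, _["closed"] = closed);
}
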