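#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Windowed per-pixel statistics over a square structure-size window, clipped at
// the image border (|W| shrinks, divisors use the actual |W|). mean/variance/
// edge-factor come from integral images; on 8-bit input all integer sums are
// exact in double, so results are bit-reproducible no matter how the image is
// cropped (tile + halo equals whole-image computation).
// [[Rcpp::export]]
List cpp_window_stats(const NumericMatrix& img, const int structure_size) {
  if (structure_size < 3 || structure_size % 2 == 0)
    stop("structure_size must be an odd integer >= 3");
  const int H = img.nrow(), W = img.ncol(), r = structure_size / 2;

  // integral images of values and squared values, (H+1) x (W+1)
  std::vector<double> S((H + 1) * (W + 1), 0.0), S2((H + 1) * (W + 1), 0.0);
  const int LW = W + 1;
  for (int i = 0; i < H; ++i) {
    double rs = 0.0, rs2 = 0.0;
    for (int j = 0; j < W; ++j) {
      const double v = img(i, j);
      rs += v; rs2 += v * v;
      S [(i + 1) * LW + (j + 1)] = S [i * LW + (j + 1)] + rs;
      S2[(i + 1) * LW + (j + 1)] = S2[i * LW + (j + 1)] + rs2;
    }
  }

  NumericMatrix m_mean(H, W), m_min(H, W), m_max(H, W), m_var(H, W), m_edge(H, W);

  for (int i = 0; i < H; ++i) {
    const int i0 = std::max(0, i - r), i1 = std::min(H - 1, i + r);
    for (int j = 0; j < W; ++j) {
      const int j0 = std::max(0, j - r), j1 = std::min(W - 1, j + r);
      const double n = (double)(i1 - i0 + 1) * (j1 - j0 + 1);
      const double s  = S [(i1 + 1) * LW + (j1 + 1)] - S [i0 * LW + (j1 + 1)]
                      - S [(i1 + 1) * LW + j0]       + S [i0 * LW + j0];
      const double s2 = S2[(i1 + 1) * LW + (j1 + 1)] - S2[i0 * LW + (j1 + 1)]
                      - S2[(i1 + 1) * LW + j0]       + S2[i0 * LW + j0];
      const double c = img(i, j);
      m_mean(i, j) = s / n;
      if (n > 1.0) {
        double v = (s2 - s * s / n) / (n - 1.0);
        if (v < 0) v = 0; // guard fp round-off
        m_var(i, j) = v;
        double e = (s2 - 2.0 * c * s + n * c * c) / (n - 1.0);
        if (e < 0) e = 0;
        m_edge(i, j) = e;
      } else {
        m_var(i, j) = 0.0;
        m_edge(i, j) = 0.0;
      }
    }
  }

  // separable min/max with clipped windows: rows then columns
  NumericMatrix rmin(H, W), rmax(H, W);
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      const int j0 = std::max(0, j - r), j1 = std::min(W - 1, j + r);
      double lo = img(i, j0), hi = img(i, j0);
      for (int jj = j0 + 1; jj <= j1; ++jj) {
        const double v = img(i, jj);
        if (v < lo) lo = v;
        if (v > hi) hi = v;
      }
      rmin(i, j) = lo; rmax(i, j) = hi;
    }
  }
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      const int i0 = std::max(0, i - r), i1 = std::min(H - 1, i + r);
      double lo = rmin(i0, j), hi = rmax(i0, j);
      for (int ii = i0 + 1; ii <= i1; ++ii) {
        if (rmin(ii, j) < lo) lo = rmin(ii, j);
        if (rmax(ii, j) > hi) hi = rmax(ii, j);
      }
      m_min(i, j) = lo; m_max(i, j) = hi;
    }
  }

  return List::create(_["mean"] = m_mean, _["min"] = m_min, _["max"] = m_max,
                      _["variance"] = m_var, _["edge_factor"] = m_edge);
}

// 2x mean-pooling (pyramid level construction); odd trailing row/col dropped.
// [[Rcpp::export]]
NumericMatrix cpp_mean_downsample2(const NumericMatrix& img) {
  const int H = img.nrow() / 2, W = img.ncol() / 2;
  NumericMatrix out(H, W);
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j)
      out(i, j) = 0.25 * (img(2 * i, 2 * j) + img(2 * i + 1, 2 * j) +
                          img(2 * i, 2 * j + 1) + img(2 * i + 1, 2 * j + 1));
  return out;
}

// Majority-vote (mode) label pooling by an integer factor; ties break toward
// the smallest label so the result is deterministic.
// [[Rcpp::export]]
IntegerMatrix cpp_mode_downsample(const IntegerMatrix& lab, const int factor) {
  if (factor < 1) stop("factor must be >= 1");
  const int H = lab.nrow() / factor, W = lab.ncol() / factor;
  int maxlab = 0;
  for (int k = 0; k < lab.size(); ++k)
    if (lab[k] > maxlab) maxlab = lab[k];
  IntegerMatrix out(H, W);
  std::vector<int> cnt(maxlab + 1);
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      std::fill(cnt.begin(), cnt.end(), 0);
      for (int di = 0; di < factor; ++di)
        for (int dj = 0; dj < factor; ++dj)
          ++cnt[lab(i * factor + di, j * factor + dj)];
      int best = 0;
      for (int l = 1; l <= maxlab; ++l)
        if (cnt[l] > cnt[best]) best = l;
      out(i, j) = best;
    }
  }
  return out;
}

// Binary erosion by a square structuring element of half-width r.
// [[Rcpp::export]]
LogicalMatrix cpp_erode(const LogicalMatrix& mask, const int r) {
  const int H = mask.nrow(), W = mask.ncol();
  LogicalMatrix rowo(H, W), out(H, W);
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      const int j0 = std::max(0, j - r), j1 = std::min(W - 1, j + r);
      bool all = true;
      for (int jj = j0; jj <= j1 && all; ++jj) all = mask(i, jj);
      rowo(i, j) = all;
    }
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      const int i0 = std::max(0, i - r), i1 = std::min(H - 1, i + r);
      bool all = true;
      for (int ii = i0; ii <= i1 && all; ++ii) all = rowo(ii, j);
      out(i, j) = all;
    }
  return out;
}

// Ridge image of a Voronoi tessellation: TRUE where the distance difference
// between the two nearest seeds is below `thickness` (the septal lattice of the
// synthetic alveolar texture). Seeds are bucketed on a coarse grid; the 5x5
// bucket neighbourhood is searched, which is exact for the near-Poisson seed
// layouts the generator produces.
// [[Rcpp::export]]
LogicalMatrix cpp_voronoi_ridge(const int H, const int W,
                                const NumericVector& sy, const NumericVector& sx,
                                const double cell, const double thickness) {
  const int n = sy.size();
  if (n < 2) stop("need at least 2 seeds");
  const int gb = std::max(1.0, cell);
  const int GH = H / gb + 1, GW = W / gb + 1;
  std::vector<std::vector<int>> bucket((size_t)GH * GW);
  for (int k = 0; k < n; ++k) {
    int bi = std::min(GH - 1, std::max(0, (int)(sy[k] / gb)));
    int bj = std::min(GW - 1, std::max(0, (int)(sx[k] / gb)));
    bucket[(size_t)bi * GW + bj].push_back(k);
  }
  LogicalMatrix out(H, W);
  for (int i = 0; i < H; ++i) {
    const int bi = std::min(GH - 1, i / gb);
    for (int j = 0; j < W; ++j) {
      const int bj = std::min(GW - 1, j / gb);
      double d1 = 1e30, d2 = 1e30;
      int reach = 2;
      while (true) {
        d1 = 1e30; d2 = 1e30;
        for (int oi = std::max(0, bi - reach); oi <= std::min(GH - 1, bi + reach); ++oi)
          for (int oj = std::max(0, bj - reach); oj <= std::min(GW - 1, bj + reach); ++oj)
            for (int k : bucket[(size_t)oi * GW + oj]) {
              const double dy = sy[k] - i, dx = sx[k] - j;
              const double d = std::sqrt(dy * dy + dx * dx);
              if (d < d1) { d2 = d1; d1 = d; }
              else if (d < d2) { d2 = d; }
            }
        if (d2 < 1e29 || reach > std::max(GH, GW)) break;
        reach *= 2;
      }
      out(i, j) = (d2 - d1) < thickness;
    }
  }
  return out;
}

// FNV-1a hash of a raw vector, as a hex string (model fingerprints in logs).
// [[Rcpp::export]]
std::string cpp_fnv1a(const RawVector& bytes) {
  uint64_t h = 14695981039346656037ULL;
  for (int i = 0; i < bytes.size(); ++i) {
    h ^= (uint64_t)bytes[i];
    h *= 1099511628211ULL;
  }
  char buf[17];
  snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)h);
  return std::string(buf);
}
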