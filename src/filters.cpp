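#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Sliding-window median with edge replication.
//
// The window is `side` x `side`; the output pixel sits at index
// floor(side/2) inside the window, so even sides (20, 50) are honoured
// with an asymmetric footprint. Exact medians on arbitrary doubles are
// obtained by rank-transforming the frame (unique sorted values) and
// running Huang's sliding histogram per output row, with a coarse
// 256-bucket index to locate order statistics quickly. For windows with
// an even pixel count the median is the midpoint of the two central
// order statistics, matching stats::median.
// [[Rcpp::export]]
NumericMatrix median_filter_cpp(NumericMatrix x, int side) {
  const int nr = x.nrow(), nc = x.ncol();
  if (side < 1) stop("kernel side must be >= 1");
  if (side > nr || side > nc) stop("kernel larger than frame");
  const int lo = side / 2;           // window start offset
  const int pr = nr + side - 1, pc = nc + side - 1;

  // rank transform over the frame's value set
  std::vector<double> vals(x.begin(), x.end());
  std::sort(vals.begin(), vals.end());
  vals.erase(std::unique(vals.begin(), vals.end()), vals.end());
  const int K = (int)vals.size();

  std::vector<int> rankimg((size_t)pr * pc);
  for (int j = 0; j < pc; ++j) {
    const int sj = clampi(j - lo, 0, nc - 1);
    for (int i = 0; i < pr; ++i) {
      const int si = clampi(i - lo, 0, nr - 1);
      const double v = x(si, sj);
      rankimg[(size_t)j * pr + i] =
        (int)(std::lower_bound(vals.begin(), vals.end(), v) - vals.begin());
    }
  }

  const int nb = std::max(1, (K + 255) / 256);  // bucket width
  const int NB = (K + nb - 1) / nb;
  std::vector<int> hist(K), bucket(NB);
  const int m = side * side;
  const int k1 = (m + 1) / 2;                   // lower central order stat
  const int k2 = (m % 2 == 0) ? m / 2 + 1 : k1; // upper central order stat

  NumericMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r) {
    std::fill(hist.begin(), hist.end(), 0);
    std::fill(bucket.begin(), bucket.end(), 0);
    for (int wc = 0; wc < side; ++wc) {
      const size_t base = (size_t)wc * pr;
      for (int wr = r; wr < r + side; ++wr) {
        const int v = rankimg[base + wr];
        hist[v]++; bucket[v / nb]++;
      }
    }
    for (int c = 0; c < nc; ++c) {
      if (c > 0) {
        const size_t oldb = (size_t)(c - 1) * pr;
        const size_t newb = (size_t)(c + side - 1) * pr;
        for (int wr = r; wr < r + side; ++wr) {
          const int v0 = rankimg[oldb + wr];
          hist[v0]--; bucket[v0 / nb]--;
          const int v1 = rankimg[newb + wr];
          hist[v1]++; bucket[v1 / nb]++;
        }
      }
      int cnt = 0, b = 0;
      while (cnt + bucket[b] < k1) { cnt += bucket[b]; ++b; }
      int idx = b * nb;
      while (cnt + hist[idx] < k1) { cnt += hist[idx]; ++idx; }
      double med;
      if (k2 == k1 || cnt + hist[idx] >= k2) {
        med = vals[idx];
      } else {
        int idx2 = idx + 1;
        while (hist[idx2] == 0) ++idx2;
        med = 0.5 * (vals[idx] + vals[idx2]);
      }
      out(r, c) = med;
    }
  }
  return out;
}

// Rigid warp of a frame: the output frame is the source scene observed
// under a rotation `theta` (radians) about the centre (c_r, c_c) plus a
// translation (t_r, t_c), i.e. out(p) = src(T^{-1}(p)) with
// T(x) = R (x - c) + c + t. Bilinear interpolation, edge replication.
// Coordinates are 0-based (row, col).
// [[Rcpp::export]]
NumericMatrix warp_rigid_cpp(NumericMatrix src, double theta,
                             double t_r, double t_c,
                             double c_r, double c_c) {
  const int nr = src.nrow(), nc = src.ncol();
  NumericMatrix out(nr, nc);
  const double ct = std::cos(theta), st = std::sin(theta);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      const double pr = r - c_r - t_r;
      const double pc = c - c_c - t_c;
      // R^T (p - c - t) + c
      const double xr = ct * pr + st * pc + c_r;
      const double xc = -st * pr + ct * pc + c_c;
      int r0 = (int)std::floor(xr), c0 = (int)std::floor(xc);
      const double fr = xr - r0, fc = xc - c0;
      const int r0c = clampi(r0, 0, nr - 1), r1c = clampi(r0 + 1, 0, nr - 1);
      const int c0c = clampi(c0, 0, nc - 1), c1c = clampi(c0 + 1, 0, nc - 1);
      const double v00 = src(r0c, c0c), v01 = src(r0c, c1c);
      const double v10 = src(r1c, c0c), v11 = src(r1c, c1c);
      out(r, c) = (1 - fr) * ((1 - fc) * v00 + fc * v01) +
                  fr * ((1 - fc) * v10 + fc * v11);
    }
  }
  return out;
}

// Normalized cross-correlation of `frm` against `ref` for every integer
// shift (dr, dc) in [-radius, radius]^2, computed over the overlap of
// ref(p) with frm(p + d). Per-shift means/variances come from summed-area
// tables; only the cross term is accumulated directly. Shifts whose
// overlap is constant in either image get NA (correlation undefined).
// Returned matrix is indexed [dr + radius + 1, dc + radius + 1] (1-based).
// [[Rcpp::export]]
NumericMatrix ncc_grid_cpp(NumericMatrix ref, NumericMatrix frm, int radius) {
  const int nr = ref.nrow(), nc = ref.ncol();
  if (frm.nrow() != nr || frm.ncol() != nc) stop("frame dimension mismatch");
  const int R = radius;
  NumericMatrix grid(2 * R + 1, 2 * R + 1);

  // summed-area tables, (nr+1) x (nc+1), column-major with leading zeros
  const int sr = nr + 1, sc = nc + 1;
  std::vector<double> Sa((size_t)sr * sc, 0.0), Saa((size_t)sr * sc, 0.0),
      Sb((size_t)sr * sc, 0.0), Sbb((size_t)sr * sc, 0.0);
  for (int j = 1; j < sc; ++j) {
    for (int i = 1; i < sr; ++i) {
      const double a = ref(i - 1, j - 1), b = frm(i - 1, j - 1);
      const size_t k = (size_t)j * sr + i;
      Sa[k]  = a     + Sa[k - 1]  + Sa[k - sr]  - Sa[k - sr - 1];
      Saa[k] = a * a + Saa[k - 1] + Saa[k - sr] - Saa[k - sr - 1];
      Sb[k]  = b     + Sb[k - 1]  + Sb[k - sr]  - Sb[k - sr - 1];
      Sbb[k] = b * b + Sbb[k - 1] + Sbb[k - sr] - Sbb[k - sr - 1];
    }
  }
  auto rectsum = [&](const std::vector<double>& S, int r0, int r1,
                     int c0, int c1) -> double {
    // inclusive pixel rect [r0..r1] x [c0..c1]
    return S[(size_t)(c1 + 1) * sr + (r1 + 1)] -
           S[(size_t)(c0)     * sr + (r1 + 1)] -
           S[(size_t)(c1 + 1) * sr + (r0)] +
           S[(size_t)(c0)     * sr + (r0)];
  };

  for (int dr = -R; dr <= R; ++dr) {
    const int r0 = std::max(0, -dr), r1 = std::min(nr - 1, nr - 1 - dr);
    for (int dc = -R; dc <= R; ++dc) {
      const int c0 = std::max(0, -dc), c1 = std::min(nc - 1, nc - 1 - dc);
      const double n = (double)(r1 - r0 + 1) * (double)(c1 - c0 + 1);
      double sab = 0.0;
      const double* pref = &ref(0, 0);
      const double* pfrm = &frm(0, 0);
      const int span = r1 - r0 + 1;
      for (int c = c0; c <= c1; ++c) {
        const double* a = pref + (size_t)c * nr + r0;
        const double* b = pfrm + (size_t)(c + dc) * nr + r0 + dr;
        for (int r = 0; r < span; ++r) sab += a[r] * b[r];
      }
      const double sa = rectsum(Sa, r0, r1, c0, c1);
      const double saa = rectsum(Saa, r0, r1, c0, c1);
      const double sb = rectsum(Sb, r0 + dr, r1 + dr, c0 + dc, c1 + dc);
      const double sbb = rectsum(Sbb, r0 + dr, r1 + dr, c0 + dc, c1 + dc);
      const double va = saa - sa * sa / n;
      const double vb = sbb - sb * sb / n;
      const double tol_a = 1e-9 * (saa + 1.0);
      const double tol_b = 1e-9 * (sbb + 1.0);
      if (va <= tol_a || vb <= tol_b) {
        grid(dr + R, dc + R) = NA_REAL;
      } else {
        grid(dr + R, dc + R) = (sab - sa * sb / n) / std::sqrt(va * vb);
      }
    }
  }
  return grid;
}
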