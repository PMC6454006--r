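// Pixel-level kernels with the exact semantics the pipeline pins down:
// 8/4-connected labeling, geodesic nearest-core assignment over a support
// (the marker-controlled watershed step), and affine resampling with
// reflection fill for augmentation.
#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Label connected components of equal-valued nonzero cells. Labels are
// assigned in column-major scan order, 1..n.
// [[Rcpp::export(name = ".label_connected")]]
IntegerMatrix label_connected(IntegerMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  if (connectivity != 4 && connectivity != 8) stop("connectivity must be 4 or 8");
  IntegerMatrix lab(H, W);
  std::vector<std::pair<int, int>> stack;
  const int dr8[] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[] = {-1, 0, 0, 1};
  const int dc4[] = {0, -1, 1, 0};
  const int* dr = connectivity == 8 ? dr8 : dr4;
  const int* dc = connectivity == 8 ? dc8 : dc4;
  const int nd = connectivity;
  int next = 0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      const int v = mask(i, j);
      ++next;
      lab(i, j) = next;
      stack.clear();
      stack.push_back({i, j});
      while (!stack.empty()) {
        auto [r, c] = stack.back();
        stack.pop_back();
        for (int k = 0; k < nd; ++k) {
          const int rr = r + dr[k], cc = c + dc[k];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          if (mask(rr, cc) == v && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back({rr, cc});
          }
        }
      }
    }
  }
  return lab;
}

// Assign every support pixel to its geodesically nearest marker (multi-source
// Dijkstra over the support with 8-connectivity, step costs 1 / sqrt(2)).
// Ties in distance go to the smaller marker id, then to scan order.
// [[Rcpp::export(name = ".geodesic_label")]]
IntegerMatrix geodesic_label(IntegerMatrix support, IntegerMatrix markers) {
  const int H = support.nrow(), W = support.ncol();
  if (markers.nrow() != H || markers.ncol() != W) stop("dimension mismatch");
  IntegerMatrix lab(H, W);
  std::vector<double> dist((size_t)H * W, R_PosInf);
  std::vector<int> best((size_t)H * W, INT_MAX);
  // queue entries: (distance, label, cell index); smallest first
  typedef std::tuple<double, int, int> Entry;
  std::priority_queue<Entry, std::vector<Entry>, std::greater<Entry>> pq;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      const int id = markers(i, j);
      if (id > 0 && support(i, j) != 0) {
        const size_t p = i + (size_t)H * j;
        if (id < best[p]) {
          dist[p] = 0.0;
          best[p] = id;
          pq.push({0.0, id, (int)p});
        }
      }
    }
  const int dr[] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const double sq2 = std::sqrt(2.0);
  std::vector<char> done((size_t)H * W, 0);
  while (!pq.empty()) {
    auto [d, id, p] = pq.top();
    pq.pop();
    if (done[p]) continue;
    done[p] = 1;
    const int i = p % H, j = p / H;
    lab(i, j) = id;
    for (int k = 0; k < 8; ++k) {
      const int rr = i + dr[k], cc = j + dc[k];
      if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
      if (support(rr, cc) == 0) continue;
      const size_t q = rr + (size_t)H * cc;
      if (done[q]) continue;
      const double ndist = d + ((dr[k] != 0 && dc[k] != 0) ? sq2 : 1.0);
      if (ndist < dist[q] - 1e-9 ||
          (std::abs(ndist - dist[q]) <= 1e-9 && id < best[q])) {
        dist[q] = ndist;
        best[q] = id;
        pq.push({ndist, id, (int)q});
      }
    }
  }
  return lab;
}

static inline int mirror_index(int s, int n) {
  if (n == 1) return 0;
  while (s < 0 || s >= n) {
    if (s < 0) s = -s - 1;
    if (s >= n) s = 2 * n - 1 - s;
  }
  return s;
}

// Sample an (H,W,C) image under an affine map taking output pixel coords
// (r, c, 1) to source coords. Out-of-range samples are filled by mirror
// reflection. bilinear = FALSE gives nearest-neighbor (for label targets).
// [[Rcpp::export(name = ".affine_sample")]]
NumericVector affine_sample(NumericVector img, NumericMatrix M,
                            int oh, int ow, bool bilinear) {
  IntegerVector d = img.attr("dim");
  if (d.size() != 3) stop("expected an (H, W, C) array");
  const int H = d[0], W = d[1], C = d[2];
  NumericVector out(Dimension(oh, ow, C));
  for (int j = 0; j < ow; ++j) {
    for (int i = 0; i < oh; ++i) {
      const double sr = M(0, 0) * i + M(0, 1) * j + M(0, 2);
      const double sc = M(1, 0) * i + M(1, 1) * j + M(1, 2);
      if (bilinear) {
        const int r0 = (int)std::floor(sr), c0 = (int)std::floor(sc);
        const double fr = sr - r0, fc = sc - c0;
        const int r0m = mirror_index(r0, H), r1m = mirror_index(r0 + 1, H);
        const int c0m = mirror_index(c0, W), c1m = mirror_index(c0 + 1, W);
        for (int ch = 0; ch < C; ++ch) {
          const double* xp = img.begin() + (size_t)H * W * ch;
          out[i + (size_t)oh * j + (size_t)oh * ow * ch] =
              (1 - fr) * (1 - fc) * xp[r0m + H * c0m] +
              (1 - fr) * fc * xp[r0m + H * c1m] +
              fr * (1 - fc) * xp[r1m + H * c0m] +
              fr * fc * xp[r1m + H * c1m];
        }
      } else {
        const int rn = mirror_index((int)std::lround(sr), H);
        const int cn = mirror_index((int)std::lround(sc), W);
        for (int ch = 0; ch < C; ++ch)
          out[i + (size_t)oh * j + (size_t)oh * ow * ch] =
              img[rn + (size_t)H * cn + (size_t)H * W * ch];
      }
    }
  }
  return out;
}
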