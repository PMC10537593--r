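#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// Gaussian-mixture background/foreground segmentation (Stauffer-Grimson /
// Zivkovic family) over a rectangular detection window of a clip.
// Per pixel: up to K modes with scalar variance shared across the three
// channels. A pixel is foreground when its squared distance to every
// background mode exceeds var_threshold * variance. Learning rate is the
// constant 1/history. Frame 0 initialises the model (all background).
// `frames` is the full clip, column-major [h, w, 3, T]; the window is
// x0..x1 / y0..y1 (0-based, inclusive). Returns masks [wh, ww, T] (raw 0/1).
// [[Rcpp::export]]
RawVector cpp_segment_window(RawVector frames, IntegerVector dim,
                             int x0, int x1, int y0, int y1,
                             int history, double var_threshold,
                             int n_modes, double var_init, double var_min,
                             double background_ratio) {
  const int h = dim[0], w = dim[1], T = dim[3];
  if (x0 < 0 || y0 < 0 || x1 >= w || y1 >= h || x1 < x0 || y1 < y0)
    stop("detection window outside frame");
  const int wh = y1 - y0 + 1, ww = x1 - x0 + 1;
  const size_t np = (size_t)wh * ww;
  const int K = n_modes;
  const double alpha = 1.0 / (double)history;

  std::vector<double> wt(np * K, 0.0), var(np * K, 0.0), mu(np * K * 3, 0.0);
  std::vector<unsigned char> nm(np, 0);  // number of active modes

  RawVector masks(np * (size_t)T);

  auto px_val = [&](int t, int c, int y, int x) -> double {
    return (double)frames[(size_t)y + (size_t)h * x +
                          (size_t)h * w * (c + 3 * (size_t)t)];
  };

  for (int t = 0; t < T; ++t) {
    size_t p = 0;
    for (int x = x0; x <= x1; ++x) {
      for (int y = y0; y <= y1; ++y, ++p) {
        double v0 = px_val(t, 0, y, x), v1 = px_val(t, 1, y, x),
               v2 = px_val(t, 2, y, x);
        double* W = &wt[p * K];
        double* V = &var[p * K];
        double* M = &mu[p * K * 3];
        int n = nm[p];

        if (n == 0) {  // first frame: seed the model
          W[0] = 1.0; V[0] = var_init;
          M[0] = v0; M[1] = v1; M[2] = v2;
          nm[p] = 1;
          continue;  // frame 0 mask stays 0 (background)
        }

        // fast path: single mode matching the pixel (the overwhelmingly
        // common case of a static background)
        if (n == 1) {
          double d0 = v0 - M[0], d1 = v1 - M[1], d2 = v2 - M[2];
          double d2sum = d0 * d0 + d1 * d1 + d2 * d2;
          if (d2sum <= var_threshold * V[0]) {
            M[0] += alpha * d0;
            M[1] += alpha * d1;
            M[2] += alpha * d2;
            V[0] += alpha * (d2sum / 3.0 - V[0]);
            if (V[0] < var_min) V[0] = var_min;
            continue;  // weight stays 1; mask stays background (0)
          }
        }

        // classification against background modes (modes kept sorted by
        // weight, descending; background = leading modes covering the ratio)
        bool fg = true;
        double cum = 0.0;
        for (int k = 0; k < n; ++k) {
          double d0 = v0 - M[3 * k], d1 = v1 - M[3 * k + 1],
                 d2 = v2 - M[3 * k + 2];
          double d2sum = d0 * d0 + d1 * d1 + d2 * d2;
          if (d2sum <= var_threshold * V[k]) { fg = false; }
          cum += W[k];
          if (cum > background_ratio) break;
          if (!fg) break;
        }
        size_t mp = (size_t)wh * ww * t + p;
        masks[mp] = fg ? 1 : 0;

        // update: match = closest mode within the threshold (any mode)
        int match = -1;
        for (int k = 0; k < n; ++k) {
          double d0 = v0 - M[3 * k], d1 = v1 - M[3 * k + 1],
                 d2 = v2 - M[3 * k + 2];
          if (d0 * d0 + d1 * d1 + d2 * d2 <= var_threshold * V[k]) {
            match = k; break;
          }
        }
        if (match >= 0) {
          for (int k = 0; k < n; ++k)
            W[k] += alpha * ((k == match ? 1.0 : 0.0) - W[k]);
          double d0 = v0 - M[3 * match], d1 = v1 - M[3 * match + 1],
                 d2 = v2 - M[3 * match + 2];
          double rho = alpha;
          M[3 * match] += rho * d0;
          M[3 * match + 1] += rho * d1;
          M[3 * match + 2] += rho * d2;
          double d2sum = (d0 * d0 + d1 * d1 + d2 * d2) / 3.0;
          V[match] += rho * (d2sum - V[match]);
          if (V[match] < var_min) V[match] = var_min;
        } else {
          int k = (n < K) ? n : (K - 1);  // replace weakest (last) mode
          if (n < K) nm[p] = (unsigned char)(n + 1);
          W[k] = alpha;
          V[k] = var_init;
          M[3 * k] = v0; M[3 * k + 1] = v1; M[3 * k + 2] = v2;
          for (int j = 0; j < n && j != k; ++j) W[j] *= (1.0 - alpha);
        }
        // renormalise and keep sorted by weight (insertion sort, K tiny)
        n = nm[p];
        double sw = 0.0;
        for (int k = 0; k < n; ++k) sw += W[k];
        for (int k = 0; k < n; ++k) W[k] /= sw;
        for (int k = 1; k < n; ++k) {
          int j = k;
          while (j > 0 && W[j] > W[j - 1]) {
            std::swap(W[j], W[j - 1]);
            std::swap(V[j], V[j - 1]);
            for (int c = 0; c < 3; ++c) std::swap(M[3 * j + c], M[3 * (j - 1) + c]);
            --j;
          }
        }
      }
    }
  }
  masks.attr("dim") = IntegerVector::create(wh, ww, T);
  return masks;
}

// ---- contour extraction ----------------------------------------------------

// Moore-neighbour (radial sweep) boundary trace of the 8-connected component
// containing (sy, sx), which must be its top-most-then-left-most pixel.
// Jacob's stopping criterion: terminate on re-entering the start pixel from
// the same backtrack position. Area by the shoelace formula over the ordered
// boundary pixel polygon (the enclosed-polygon convention, not pixel count).
static double trace_area(const std::vector<int>& lab, int h, int w,
                         int id, int sy, int sx, int* bb) {
  // neighbours swept clockwise (y down), starting W
  static const int dy[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  static const int dx[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  auto at = [&](int y, int x) -> bool {
    return y >= 0 && y < h && x >= 0 && x < w && lab[y + (size_t)h * x] == id;
  };
  bb[0] = bb[2] = sx; bb[1] = bb[3] = sy;
  int cy = sy, cx = sx;
  int ib = 0;  // backtrack = W neighbour of the start (outside the region)
  double area2 = 0.0;
  int sec_y = -1, sec_x = -1;  // second pixel of the contour
  long guard = 8L * h * w + 16;
  while (guard-- > 0) {
    int found = -1;
    for (int k = 1; k <= 8; ++k) {
      int d = (ib + k) % 8;
      if (at(cy + dy[d], cx + dx[d])) { found = k; break; }
    }
    if (found < 0) return 0.0;  // isolated pixel
    int d = (ib + found) % 8;
    int ny = cy + dy[d], nx = cx + dx[d];
    // closed: back at the start and heading to the same second pixel
    if (cy == sy && cx == sx && sec_y >= 0 && ny == sec_y && nx == sec_x)
      break;
    area2 += (double)cx * ny - (double)nx * cy;  // shoelace edge (c -> n)
    // backtrack for the new pixel: the previously swept (non-region)
    // neighbour of the old pixel, expressed as a direction from n
    int pd = (ib + found - 1) % 8;
    int by = cy + dy[pd], bx = cx + dx[pd];
    cy = ny; cx = nx;
    ib = 0;
    for (int q = 0; q < 8; ++q)
      if (cy + dy[q] == by && cx + dx[q] == bx) { ib = q; break; }
    if (sec_y < 0) { sec_y = cy; sec_x = cx; }
    if (cx < bb[0]) bb[0] = cx;
    if (cx > bb[2]) bb[2] = cx;
    if (cy < bb[1]) bb[1] = cy;
    if (cy > bb[3]) bb[3] = cy;
  }
  return std::fabs(area2) / 2.0;
}

// Per-frame contour statistics of a binary mask stack [h, w, T]: the largest
// enclosed-contour area and its bounding box. Used by the soft trigger.
// [[Rcpp::export]]
NumericMatrix cpp_contour_stats(RawVector masks, IntegerVector dim) {
  const int h = dim[0], w = dim[1], T = dim[2];
  NumericMatrix out(T, 6);  // area, x0, y0, x1, y1, n_components
  std::vector<int> lab((size_t)h * w);
  std::vector<int> stack;
  for (int t = 0; t < T; ++t) {
    std::fill(lab.begin(), lab.end(), 0);
    const size_t off = (size_t)h * w * t;
    int nid = 0;
    double best = 0.0;
    bool any = false;
    int bb_best[4] = {0, 0, 0, 0};
    for (int x = 0; x < w; ++x)
      for (int y = 0; y < h; ++y) {
        size_t i = (size_t)y + (size_t)h * x;
        if (!masks[off + i] || lab[i]) continue;
        // flood fill (8-connected) a new component; remember its
        // top-most-then-left-most pixel as the trace start
        ++nid;
        int sy = y, sx = x;
        stack.clear(); stack.push_back((int)i);
        lab[i] = nid;
        while (!stack.empty()) {
          int ci = stack.back(); stack.pop_back();
          int cy = ci % h, cx = ci / h;
          if (cy < sy || (cy == sy && cx < sx)) { sy = cy; sx = cx; }
          for (int ddx = -1; ddx <= 1; ++ddx)
            for (int ddy = -1; ddy <= 1; ++ddy) {
              int ny = cy + ddy, nx = cx + ddx;
              if (ny < 0 || ny >= h || nx < 0 || nx >= w) continue;
              size_t j = (size_t)ny + (size_t)h * nx;
              if (masks[off + j] && !lab[j]) {
                lab[j] = nid;
                stack.push_back((int)j);
              }
            }
        }
        int bb[4];
        double a = trace_area(lab, h, w, nid, sy, sx, bb);
        if (!any || a > best) {
          best = a;
          for (int q = 0; q < 4; ++q) bb_best[q] = bb[q];
          any = true;
        }
      }
    out(t, 0) = best;
    if (any) {
      out(t, 1) = bb_best[0]; out(t, 2) = bb_best[1];
      out(t, 3) = bb_best[2]; out(t, 4) = bb_best[3];
    } else {
      out(t, 1) = NA_REAL; out(t, 2) = NA_REAL;
      out(t, 3) = NA_REAL; out(t, 4) = NA_REAL;
    }
    out(t, 5) = nid;
  }
  return out;
}

// Extract one frame's crop window as a numeric [ch, cw, 3] array.
// `t` is 0-based.
// [[Rcpp::export]]
NumericVector cpp_crop_frame(RawVector frames, IntegerVector dim, int t,
                             int cx0, int cy0, int ch, int cw) {
  const int h = dim[0], w = dim[1], T = dim[3];
  if (t < 0 || t >= T) stop("frame index out of range");
  if (cx0 < 0 || cy0 < 0 || cx0 + cw > w || cy0 + ch > h)
    stop("crop region outside the frame");
  NumericVector out((size_t)ch * cw * 3);
  for (int c = 0; c < 3; ++c)
    for (int x = 0; x < cw; ++x) {
      const size_t src0 = (size_t)(cy0) + (size_t)h * (cx0 + x) +
                          (size_t)h * w * (c + 3 * (size_t)t);
      double* dst = &out[(size_t)ch * (x + (size_t)cw * c)];
      for (int y = 0; y < ch; ++y) dst[y] = (double)frames[src0 + y];
    }
  out.attr("dim") = IntegerVector::create(ch, cw, 3);
  return out;
}

// Per-pixel median over selected frames of a crop window; used to build the
// spliced background (left half from trailing frames, right half from
// leading frames). Returns the crop as a numeric [ch, cw, 3] array.
// [[Rcpp::export]]
NumericVector cpp_spliced_background(RawVector frames, IntegerVector dim,
                                     int cx0, int cy0, int ch, int cw,
                                     int n_edge, int split_col) {
  const int h = dim[0], w = dim[1], T = dim[3];
  if (cx0 < 0 || cy0 < 0 || cx0 + cw > w || cy0 + ch > h)
    stop("crop window outside frame");
  if (2 * n_edge > T) stop("clip too short for the requested edge frames");
  NumericVector out((size_t)ch * cw * 3);
  std::vector<double> buf(n_edge);
  for (int c = 0; c < 3; ++c)
    for (int x = 0; x < cw; ++x) {
      bool left = x < split_col;  // left half <- last frames (cell has left)
      for (int y = 0; y < ch; ++y) {
        for (int e = 0; e < n_edge; ++e) {
          int t = left ? (T - 1 - e) : e;
          buf[e] = (double)frames[(size_t)(cy0 + y) + (size_t)h * (cx0 + x) +
                                  (size_t)h * w * (c + 3 * (size_t)t)];
        }
        std::nth_element(buf.begin(), buf.begin() + n_edge / 2, buf.end());
        double med = buf[n_edge / 2];
        if (n_edge % 2 == 0) {
          std::nth_element(buf.begin(), buf.begin() + n_edge / 2 - 1,
                           buf.begin() + n_edge / 2);
          med = 0.5 * (med + buf[n_edge / 2 - 1]);
        }
        out[(size_t)y + (size_t)ch * x + (size_t)ch * cw * c] = med;
      }
    }
  out.attr("dim") = IntegerVector::create(ch, cw, 3);
  return out;
}
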