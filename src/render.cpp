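#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include "simrng.h"

uint32_t SimRng::kn_[128];
double SimRng::wn_[128];
double SimRng::fn_[128];
bool SimRng::tables_ready_ = false;

using namespace Rcpp;

// Separable Gaussian blur of an h x w field with reflect boundary.
static void blur_field(std::vector<double>& img, int h, int w, double sigma) {
  if (sigma <= 0) return;
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (auto& v : k) v /= s;
  std::vector<double> tmp(img.size());
  // rows (vertical pass), reflect at borders
  for (int x = 0; x < w; ++x)
    for (int y = 0; y < h; ++y) {
      double a = 0.0;
      for (int i = -r; i <= r; ++i) {
        int yy = y + i;
        if (yy < 0) yy = -yy - 1;
        if (yy >= h) yy = 2 * h - yy - 1;
        a += k[i + r] * img[yy + (size_t)h * x];
      }
      tmp[y + (size_t)h * x] = a;
    }
  for (int y = 0; y < h; ++y)
    for (int x = 0; x < w; ++x) {
      double a = 0.0;
      for (int i = -r; i <= r; ++i) {
        int xx = x + i;
        if (xx < 0) xx = -xx - 1;
        if (xx >= w) xx = 2 * w - xx - 1;
        a += k[i + r] * tmp[y + (size_t)h * xx];
      }
      img[y + (size_t)h * x] = a;
    }
}

static inline unsigned char clamp8(double v) {
  int r = (int)(v + 0.5);  // round half up; negatives clamp to 0 anyway
  if (r < 0) return 0;
  if (r > 255) return 255;
  return (unsigned char)r;
}

// Render one clip. Layout of `frames` is column-major [h, w, 3, T]; masks
// [h, w, T]. The background (texture + darker walls, optionally defocused)
// is static; the cell is a hard-edged superellipse blob whose pre-blur
// support is the ground-truth mask. Focal blur is applied to background and
// cell layer (zero-padded compact support), then pixel noise is added.
// [[Rcpp::export]]
List cpp_render_clip(int h, int w, NumericMatrix traj, double blob_exp,
                     NumericVector cell_rgb, NumericVector halfwidth_px,
                     double channel_cy, double wall_atten,
                     double tex_base, double tex_amp, double tex_scale_px,
                     int tex_seed, double noise_sigma, double blur_sigma,
                     int noise_seed) {
  const int T = traj.nrow();
  if ((int)halfwidth_px.size() != w) stop("halfwidth profile length != frame width");

  // --- static background: low-frequency filtered noise + channel walls ---
  std::vector<double> bg((size_t)h * w);
  {
    SimRng rg((uint64_t)(uint32_t)tex_seed);
    int gh = (int)std::floor((h - 1) / tex_scale_px) + 2;
    int gw = (int)std::floor((w - 1) / tex_scale_px) + 2;
    std::vector<double> grid((size_t)gh * gw);
    for (auto& g : grid) g = rg.norm();
    for (int x = 0; x < w; ++x) {
      double gx = x / tex_scale_px;
      int j0 = (int)std::floor(gx);
      double fx = gx - j0;
      for (int y = 0; y < h; ++y) {
        double gy = y / tex_scale_px;
        int i0 = (int)std::floor(gy);
        double fy = gy - i0;
        double v00 = grid[i0 + (size_t)gh * j0];
        double v01 = grid[i0 + (size_t)gh * (j0 + 1)];
        double v10 = grid[i0 + 1 + (size_t)gh * j0];
        double v11 = grid[i0 + 1 + (size_t)gh * (j0 + 1)];
        double v = (1 - fy) * ((1 - fx) * v00 + fx * v01) +
                   fy * ((1 - fx) * v10 + fx * v11);
        double val = tex_base + tex_amp * v;
        if (std::fabs(y - channel_cy) > halfwidth_px[x]) val *= wall_atten;
        bg[y + (size_t)h * x] = val;
      }
    }
  }
  blur_field(bg, h, w, blur_sigma);

  RawVector frames((size_t)h * w * 3 * T);
  RawVector masks((size_t)h * w * T);
  RawVector clean((size_t)h * w * 3);
  for (int c = 0; c < 3; ++c)
    for (size_t i = 0; i < (size_t)h * w; ++i)
      clean[i + (size_t)h * w * c] = clamp8(bg[i]);

  SimRng rn((uint64_t)(uint32_t)noise_seed);
  int br = (blur_sigma > 0) ? std::max(1, (int)std::ceil(3.0 * blur_sigma)) : 0;

  for (int t = 0; t < T; ++t) {
    double cx = traj(t, 0), cy = traj(t, 1), a = traj(t, 2), b = traj(t, 3);
    // bounding box of the blob support, expanded for the blur kernel
    int x0 = (int)std::floor(cx - a) - br - 1, x1 = (int)std::ceil(cx + a) + br + 1;
    int y0 = (int)std::floor(cy - b) - br - 1, y1 = (int)std::ceil(cy + b) + br + 1;
    x0 = std::max(x0, 0); y0 = std::max(y0, 0);
    x1 = std::min(x1, w - 1); y1 = std::min(y1, h - 1);
    int bw = x1 - x0 + 1, bh = y1 - y0 + 1;

    std::vector<double> cell;
    bool has_cell = (bw > 0 && bh > 0 && a > 0 && b > 0);
    if (has_cell) {
      cell.assign((size_t)bh * bw, 0.0);
      for (int x = x0; x <= x1; ++x) {
        double dx = std::fabs((x - cx) / a);
        for (int y = y0; y <= y1; ++y) {
          double dy = std::fabs((y - cy) / b);
          if (std::pow(dx, blob_exp) + std::pow(dy, blob_exp) <= 1.0) {
            cell[(y - y0) + (size_t)bh * (x - x0)] = 1.0;
            masks[y + (size_t)h * (x + (size_t)w * t)] = 1;
          }
        }
      }
      if (blur_sigma > 0) {
        // zero-padded blur of the compact cell support: pad the local patch
        std::vector<double> pad((size_t)(bh + 2 * br) * (bw + 2 * br), 0.0);
        for (int x = 0; x < bw; ++x)
          for (int y = 0; y < bh; ++y)
            pad[(y + br) + (size_t)(bh + 2 * br) * (x + br)] =
              cell[y + (size_t)bh * x];
        blur_field(pad, bh + 2 * br, bw + 2 * br, blur_sigma);
        // crop back to frame coordinates (padding may exceed frame edges;
        // outside-frame mass is discarded — the support was clipped already)
        for (int x = 0; x < bw; ++x)
          for (int y = 0; y < bh; ++y)
            cell[y + (size_t)bh * x] =
              pad[(y + br) + (size_t)(bh + 2 * br) * (x + br)];
      }
    }

    for (int c = 0; c < 3; ++c) {
      size_t off = (size_t)h * w * (c + 3 * (size_t)t);
      double amp = cell_rgb[c];
      for (int x = 0; x < w; ++x)
        for (int y = 0; y < h; ++y) {
          double v = bg[y + (size_t)h * x];
          if (has_cell && x >= x0 && x <= x1 && y >= y0 && y <= y1)
            v += amp * cell[(y - y0) + (size_t)bh * (x - x0)];
          if (noise_sigma > 0) v += noise_sigma * rn.norm();
          frames[y + (size_t)h * x + off] = clamp8(v);
        }
    }
  }

  return List::create(_["frames"] = frames, _["masks"] = masks,
                      _["clean"] = clean);
}
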