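#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>

using namespace Rcpp;

// All coordinates here are 0-based (row, col), origin top-left, matching the
// convention used throughout the R layer.

static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// [[Rcpp::export]]
NumericMatrix gaussian_blur_cpp(const NumericMatrix& img, double sigma) {
  int nr = img.nrow(), nc = img.ncol();
  if (sigma <= 1e-8) return clone(img);
  int radius = std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<double> k(2 * radius + 1);
  double s = 0.0;
  for (int i = -radius; i <= radius; ++i) {
    k[i + radius] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + radius];
  }
  for (size_t i = 0; i < k.size(); ++i) k[i] /= s;

  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double acc = 0.0;
      for (int i = -radius; i <= radius; ++i)
        acc += k[i + radius] * img(reflect_idx(r + i, nr), c);
      tmp(r, c) = acc;
    }
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      double acc = 0.0;
      for (int i = -radius; i <= radius; ++i)
        acc += k[i + radius] * tmp(r, reflect_idx(c + i, nc));
      out(r, c) = acc;
    }
  return out;
}

// [[Rcpp::export]]
NumericMatrix downsample2_cpp(const NumericMatrix& img) {
  int nr = std::max(1, img.nrow() / 2), nc = std::max(1, img.ncol() / 2);
  NumericMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      out(r, c) = img(2 * r, 2 * c);
  return out;
}

static inline double sample_bilinear(const NumericMatrix& img, double r, double c) {
  int nr = img.nrow(), nc = img.ncol();
  if (r < 0) r = 0;
  if (r > nr - 1) r = nr - 1;
  if (c < 0) c = 0;
  if (c > nc - 1) c = nc - 1;
  int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  int r1 = std::min(r0 + 1, nr - 1), c1 = std::min(c0 + 1, nc - 1);
  double fr = r - r0, fc = c - c0;
  return (1 - fr) * (1 - fc) * img(r0, c0) + (1 - fr) * fc * img(r0, c1) +
         fr * (1 - fc) * img(r1, c0) + fr * fc * img(r1, c1);
}

// [[Rcpp::export]]
NumericMatrix resize_bilinear_cpp(const NumericMatrix& img, int out_h, int out_w) {
  NumericMatrix out(out_h, out_w);
  double sr = (double)img.nrow() / out_h, sc = (double)img.ncol() / out_w;
  for (int r = 0; r < out_h; ++r) {
    double ir = (r + 0.5) * sr - 0.5;
    for (int c = 0; c < out_w; ++c) {
      double ic = (c + 0.5) * sc - 0.5;
      out(r, c) = sample_bilinear(img, ir, ic);
    }
  }
  return out;
}

// minv is 2x3: input_row = m(0,0)*r + m(0,1)*c + m(0,2); input_col = m(1,0)*r + ...
// (backward mapping from output pixel to input location)
// [[Rcpp::export]]
NumericMatrix warp_affine_cpp(const NumericMatrix& img, const NumericMatrix& minv,
                              int out_h, int out_w, double fill) {
  NumericMatrix out(out_h, out_w);
  int nr = img.nrow(), nc = img.ncol();
  for (int r = 0; r < out_h; ++r)
    for (int c = 0; c < out_w; ++c) {
      double ir = minv(0, 0) * r + minv(0, 1) * c + minv(0, 2);
      double ic = minv(1, 0) * r + minv(1, 1) * c + minv(1, 2);
      if (ir < 0 || ir > nr - 1 || ic < 0 || ic > nc - 1)
        out(r, c) = fill;
      else
        out(r, c) = sample_bilinear(img, ir, ic);
    }
  return out;
}

// 3x3x3 local extrema of a difference-of-Gaussians stack with optional
// quadratic sub-pixel refinement, contrast and edge-response filtering.
// dog: list of equally sized matrices (the stack for ONE octave).
// Returns 0-based octave-frame coordinates, a continuous stack index s,
// and the refined |DoG| response.
// [[Rcpp::export]]
DataFrame detect_extrema_cpp(List dog, double contrast_threshold,
                             double edge_ratio, bool refine) {
  int K = dog.size();
  std::vector<NumericMatrix> D;
  for (int i = 0; i < K; ++i) D.push_back(as<NumericMatrix>(dog[i]));
  int nr = D[0].nrow(), nc = D[0].ncol();
  const int border = 5;
  double prelim = 0.5 * contrast_threshold;
  double edge_lim = (edge_ratio + 1.0) * (edge_ratio + 1.0) / edge_ratio;

  std::vector<double> out_r, out_c, out_s, out_resp;

  for (int s = 1; s <= K - 2; ++s) {
    const NumericMatrix &dm = D[s - 1], &dc0 = D[s], &dp = D[s + 1];
    for (int r = border; r < nr - border; ++r) {
      for (int c = border; c < nc - border; ++c) {
        double v = dc0(r, c);
        if (std::fabs(v) < prelim) continue;
        bool is_max = true, is_min = true;
        for (int dr = -1; dr <= 1 && (is_max || is_min); ++dr)
          for (int dcc = -1; dcc <= 1; ++dcc) {
            double a = dm(r + dr, c + dcc), b = dc0(r + dr, c + dcc),
                   e = dp(r + dr, c + dcc);
            if (dr != 0 || dcc != 0) {
              if (v <= b) is_max = false;
              if (v >= b) is_min = false;
            }
            if (v <= a || v <= e) is_max = false;
            if (v >= a || v >= e) is_min = false;
            if (!is_max && !is_min) break;
          }
        if (!is_max && !is_min) continue;

        int ri = r, ci = c, si = s;
        double xr = 0, xc = 0, xs = 0, vhat = v;
        double hrr = 0, hcc = 0, hrc = 0;
        bool ok = true;
        if (refine) {
          ok = false;
          for (int iter = 0; iter < 5; ++iter) {
            const NumericMatrix &d0 = D[si - 1], &d1 = D[si], &d2 = D[si + 1];
            double gr = 0.5 * (d1(ri + 1, ci) - d1(ri - 1, ci));
            double gc = 0.5 * (d1(ri, ci + 1) - d1(ri, ci - 1));
            double gs = 0.5 * (d2(ri, ci) - d0(ri, ci));
            hrr = d1(ri + 1, ci) - 2 * d1(ri, ci) + d1(ri - 1, ci);
            hcc = d1(ri, ci + 1) - 2 * d1(ri, ci) + d1(ri, ci - 1);
            double hss = d2(ri, ci) - 2 * d1(ri, ci) + d0(ri, ci);
            hrc = 0.25 * (d1(ri + 1, ci + 1) - d1(ri + 1, ci - 1) -
                          d1(ri - 1, ci + 1) + d1(ri - 1, ci - 1));
            double hrs = 0.25 * (d2(ri + 1, ci) - d2(ri - 1, ci) -
                                 d0(ri + 1, ci) + d0(ri - 1, ci));
            double hcs = 0.25 * (d2(ri, ci + 1) - d2(ri, ci - 1) -
                                 d0(ri, ci + 1) + d0(ri, ci - 1));
            double det = hrr * (hcc * hss - hcs * hcs) -
                         hrc * (hrc * hss - hcs * hrs) +
                         hrs * (hrc * hcs - hcc * hrs);
            if (std::fabs(det) < 1e-14) break;
            // offset = -H^{-1} g  (Cramer's rule)
            double br = -gr, bc = -gc, bs = -gs;
            xr = (br * (hcc * hss - hcs * hcs) -
                  hrc * (bc * hss - hcs * bs) +
                  hrs * (bc * hcs - hcc * bs)) / det;
            xc = (hrr * (bc * hss - hcs * bs) -
                  br * (hrc * hss - hcs * hrs) +
                  hrs * (hrc * bs - bc * hrs)) / det;
            xs = (hrr * (hcc * bs - bc * hcs) -
                  hrc * (hrc * bs - bc * hrs) +
                  br * (hrc * hcs - hcc * hrs)) / det;
            if (std::fabs(xr) < 0.5 && std::fabs(xc) < 0.5 && std::fabs(xs) < 0.5) {
              vhat = d1(ri, ci) + 0.5 * (gr * xr + gc * xc + gs * xs);
              ok = true;
              break;
            }
            ri += (int)std::lround(xr);
            ci += (int)std::lround(xc);
            si += (int)std::lround(xs);
            if (si < 1 || si > K - 2 || ri < border || ri >= nr - border ||
                ci < border || ci >= nc - border)
              break;
          }
        } else {
          const NumericMatrix& d1 = D[si];
          hrr = d1(ri + 1, ci) - 2 * d1(ri, ci) + d1(ri - 1, ci);
          hcc = d1(ri, ci + 1) - 2 * d1(ri, ci) + d1(ri, ci - 1);
          hrc = 0.25 * (d1(ri + 1, ci + 1) - d1(ri + 1, ci - 1) -
                        d1(ri - 1, ci + 1) + d1(ri - 1, ci - 1));
        }
        if (!ok) continue;
        if (std::fabs(vhat) < contrast_threshold) continue;
        double tr = hrr + hcc, det2 = hrr * hcc - hrc * hrc;
        if (det2 <= 0) continue;
        if (tr * tr / det2 >= edge_lim) continue;

        out_r.push_back(ri + xr);
        out_c.push_back(ci + xc);
        out_s.push_back(si + xs);
        out_resp.push_back(std::fabs(vhat));
      }
    }
  }
  return DataFrame::create(_["row"] = out_r, _["col"] = out_c,
                           _["s"] = out_s, _["response"] = out_resp);
}

// 36-bin gradient orientation histogram around (r, c) at blur level sigma,
// Gaussian-weighted with 1.5*sigma, smoothed with a circular box filter.
// Angles measured as atan2(d_row, d_col) in degrees, [0, 360).
// [[Rcpp::export]]
NumericVector orientation_hist_cpp(const NumericMatrix& gauss, double r, double c,
                                   double sigma, int nbins) {
  int nr = gauss.nrow(), nc = gauss.ncol();
  int R = (int)std::lround(r), C = (int)std::lround(c);
  double sw = 1.5 * sigma;
  int radius = std::max(1, (int)std::lround(3.0 * sw));
  NumericVector hist(nbins);
  for (int dr = -radius; dr <= radius; ++dr) {
    int pr = R + dr;
    if (pr < 1 || pr > nr - 2) continue;
    for (int dcc = -radius; dcc <= radius; ++dcc) {
      int pc = C + dcc;
      if (pc < 1 || pc > nc - 2) continue;
      double dx = gauss(pr, pc + 1) - gauss(pr, pc - 1);
      double dy = gauss(pr + 1, pc) - gauss(pr - 1, pc);
      double mag = std::sqrt(dx * dx + dy * dy);
      double ang = std::atan2(dy, dx) * 180.0 / M_PI;
      if (ang < 0) ang += 360.0;
      double w = std::exp(-(dr * dr + dcc * dcc) / (2.0 * sw * sw));
      int bin = (int)std::floor(ang * nbins / 360.0);
      if (bin >= nbins) bin = 0;
      hist[bin] += w * mag;
    }
  }
  // 6 passes of a circular [1 1 1]/3 smoother
  NumericVector tmp(nbins);
  for (int pass = 0; pass < 6; ++pass) {
    for (int i = 0; i < nbins; ++i)
      tmp[i] = (hist[(i + nbins - 1) % nbins] + hist[i] + hist[(i + 1) % nbins]) / 3.0;
    hist = clone(tmp);
  }
  return hist;
}

// 4x4x8 gradient-histogram descriptor at (r, c), scale sigma (octave frame),
// orientation ori_deg. Trilinear scatter, Gaussian spatial weight, clamp and
// renormalize. Returns a length-128 vector, or length-0 when the sampling
// window leaves the image (caller drops the keypoint).
// [[Rcpp::export]]
NumericVector descriptor_cpp(const NumericMatrix& gauss, double r, double c,
                             double sigma, double ori_deg, double clamp_ceiling) {
  const int d = 4, nb = 8;
  int nr = gauss.nrow(), nc = gauss.ncol();
  double hist_width = 3.0 * sigma;
  int radius = (int)std::lround(hist_width * std::sqrt(2.0) * (d + 1) * 0.5);
  int R = (int)std::lround(r), C = (int)std::lround(c);
  if (R - radius < 1 || R + radius > nr - 2 || C - radius < 1 || C + radius > nc - 2)
    return NumericVector(0);

  double th = ori_deg * M_PI / 180.0;
  double ct = std::cos(th), st = std::sin(th);
  std::vector<double> hist((d + 2) * (d + 2) * nb, 0.0);
  double sigma_w = 0.5 * d * hist_width;

  for (int dr = -radius; dr <= radius; ++dr) {
    for (int dcc = -radius; dcc <= radius; ++dcc) {
      // rotate the offset by -orientation into the keypoint frame
      // (angles follow atan2(d_row, d_col): an offset along the keypoint
      // orientation maps to the local +col axis)
      double rrot = ct * dr - st * dcc;
      double crot = st * dr + ct * dcc;
      double rbin = rrot / hist_width + d / 2.0 - 0.5;
      double cbin = crot / hist_width + d / 2.0 - 0.5;
      if (rbin <= -1 || rbin >= d || cbin <= -1 || cbin >= d) continue;
      int pr = R + dr, pc = C + dcc;
      double dx = gauss(pr, pc + 1) - gauss(pr, pc - 1);
      double dy = gauss(pr + 1, pc) - gauss(pr - 1, pc);
      double mag = std::sqrt(dx * dx + dy * dy);
      if (mag <= 0) continue;
      double ang = std::atan2(dy, dx) * 180.0 / M_PI - ori_deg;
      while (ang < 0) ang += 360.0;
      while (ang >= 360.0) ang -= 360.0;
      double obin = ang * nb / 360.0;
      double w = std::exp(-(rrot * rrot + crot * crot) / (2.0 * sigma_w * sigma_w));
      double val = w * mag;

      int r0 = (int)std::floor(rbin), c0 = (int)std::floor(cbin),
          o0 = (int)std::floor(obin);
      double fr = rbin - r0, fc = cbin - c0, fo = obin - o0;
      for (int ir = 0; ir <= 1; ++ir) {
        int rb = r0 + ir;
        if (rb < 0 || rb >= d) continue;
        double wr = val * (ir ? fr : 1 - fr);
        for (int icb = 0; icb <= 1; ++icb) {
          int cb = c0 + icb;
          if (cb < 0 || cb >= d) continue;
          double wc = wr * (icb ? fc : 1 - fc);
          for (int io = 0; io <= 1; ++io) {
            int ob = (o0 + io) % nb;
            double wo = wc * (io ? fo : 1 - fo);
            hist[(rb * d + cb) * nb + ob] += wo;
          }
        }
      }
    }
  }

  NumericVector out(d * d * nb);
  for (int i = 0; i < d * d * nb; ++i) out[i] = hist[i];
  double norm = 0;
  for (int i = 0; i < d * d * nb; ++i) norm += out[i] * out[i];
  norm = std::sqrt(norm);
  if (norm < 1e-12) return out;
  for (int i = 0; i < d * d * nb; ++i) {
    out[i] /= norm;
    if (out[i] > clamp_ceiling) out[i] = clamp_ceiling;
  }
  norm = 0;
  for (int i = 0; i < d * d * nb; ++i) norm += out[i] * out[i];
  norm = std::sqrt(norm);
  for (int i = 0; i < d * d * nb; ++i) out[i] /= norm;
  return out;
}

// 4-connected component labelling of a logical mask; labels 1..k in
// scan order, 0 for background.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(const LogicalMatrix& mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        int pr = p.first, pc = p.second;
        const int drs[4] = {-1, 1, 0, 0}, dcs[4] = {0, 0, -1, 1};
        for (int i = 0; i < 4; ++i) {
          int r2 = pr + drs[i], c2 = pc + dcs[i];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            q.push(std::make_pair(r2, c2));
          }
        }
      }
    }
  return lab;
}
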