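#include <Rcpp.h>
#include <queue>
#include <algorithm>
using namespace Rcpp;

// Grayscale morphological reconstruction by dilation (8-connectivity),
// hybrid raster/anti-raster scan followed by FIFO propagation
// (Vincent 1993). marker must be pointwise <= mask.
static void reconstruct_inplace(std::vector<double>& J,
                                const double* I, int nr, int nc) {
  // forward scan, column-major order; causal neighbors:
  // (r-1,c), (r-1,c-1), (r,c-1), (r+1,c-1)
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double v = J[c * nr + r];
      if (r > 0) v = std::max(v, J[c * nr + r - 1]);
      if (c > 0) {
        const double* prev = &J[(c - 1) * nr];
        if (r > 0) v = std::max(v, prev[r - 1]);
        v = std::max(v, prev[r]);
        if (r < nr - 1) v = std::max(v, prev[r + 1]);
      }
      J[c * nr + r] = std::min(v, I[c * nr + r]);
    }
  }
  // backward scan; anti-causal neighbors, enqueue unstable pixels
  std::queue<int> fifo;
  for (int c = nc - 1; c >= 0; --c) {
    for (int r = nr - 1; r >= 0; --r) {
      int p = c * nr + r;
      double v = J[p];
      if (r < nr - 1) v = std::max(v, J[p + 1]);
      if (c < nc - 1) {
        const double* nxt = &J[(c + 1) * nr];
        if (r > 0) v = std::max(v, nxt[r - 1]);
        v = std::max(v, nxt[r]);
        if (r < nr - 1) v = std::max(v, nxt[r + 1]);
      }
      v = std::min(v, I[p]);
      J[p] = v;
      // check whether propagation into an anti-causal neighbor is pending
      bool push = false;
      if (r < nr - 1 && J[p + 1] < v && J[p + 1] < I[p + 1]) push = true;
      if (!push && c < nc - 1) {
        for (int dr = -1; dr <= 1 && !push; ++dr) {
          int rq = r + dr;
          if (rq < 0 || rq >= nr) continue;
          int q = (c + 1) * nr + rq;
          if (J[q] < v && J[q] < I[q]) push = true;
        }
      }
      if (push) fifo.push(p);
    }
  }
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  while (!fifo.empty()) {
    int p = fifo.front();
    fifo.pop();
    int r = p % nr, c = p / nr;
    double vp = J[p];
    for (int k = 0; k < 8; ++k) {
      int rq = r + dr8[k], cq = c + dc8[k];
      if (rq < 0 || rq >= nr || cq < 0 || cq >= nc) continue;
      int q = cq * nr + rq;
      if (J[q] < vp && I[q] != J[q]) {
        J[q] = std::min(vp, I[q]);
        fifo.push(q);
      }
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_reconstruct_dilate(NumericMatrix marker, NumericMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  if (marker.nrow() != nr || marker.ncol() != nc)
    stop("marker and mask dimensions differ");
  std::vector<double> J(marker.begin(), marker.end());
  for (int i = 0; i < nr * nc; ++i)
    if (J[i] > mask[i]) stop("marker must be <= mask everywhere");
  reconstruct_inplace(J, mask.begin(), nr, nc);
  NumericMatrix out(nr, nc);
  std::copy(J.begin(), J.end(), out.begin());
  return out;
}

// Suppress bright structures connected to the image border: subtract the
// reconstruction of the image from a border-seeded marker. Border-connected
// structures go to zero; interior maxima survive as residuals above their
// surrounding background level.
static void clear_border_core(std::vector<double>& out,
                              const double* I, int nr, int nc) {
  double mn = I[0];
  for (int i = 0; i < nr * nc; ++i) mn = std::min(mn, I[i]);
  std::vector<double> J(static_cast<size_t>(nr) * nc, mn);
  for (int r = 0; r < nr; ++r) {
    J[r] = I[r];
    J[(nc - 1) * nr + r] = I[(nc - 1) * nr + r];
  }
  for (int c = 0; c < nc; ++c) {
    J[c * nr] = I[c * nr];
    J[c * nr + nr - 1] = I[c * nr + nr - 1];
  }
  reconstruct_inplace(J, I, nr, nc);
  out.resize(static_cast<size_t>(nr) * nc);
  for (int i = 0; i < nr * nc; ++i) out[i] = I[i] - J[i];
}

// [[Rcpp::export]]
NumericMatrix cpp_clear_border(NumericMatrix image) {
  int nr = image.nrow(), nc = image.ncol();
  std::vector<double> out;
  clear_border_core(out, image.begin(), nr, nc);
  NumericMatrix res(nr, nc);
  std::copy(out.begin(), out.end(), res.begin());
  return res;
}

// Otsu threshold over a 256-bin histogram spanning [min, max]; returns the
// upper edge of the last below-threshold bin (first argmax of the
// between-class variance). NA when the image is constant.
static double otsu_core(const double* x, int n) {
  const int nb = 256;
  double mn = x[0], mx = x[0];
  for (int i = 1; i < n; ++i) {
    mn = std::min(mn, x[i]);
    mx = std::max(mx, x[i]);
  }
  if (mx <= mn) return NA_REAL;
  double w = (mx - mn) / nb;
  std::vector<double> cnt(nb, 0.0);
  for (int i = 0; i < n; ++i) {
    int b = static_cast<int>((x[i] - mn) / (mx - mn) * nb);
    if (b >= nb) b = nb - 1;
    cnt[b] += 1.0;
  }
  std::vector<double> mid(nb);
  for (int b = 0; b < nb; ++b) mid[b] = mn + (b + 0.5) * w;
  double total = n, sumT = 0.0;
  for (int b = 0; b < nb; ++b) sumT += cnt[b] * mid[b];
  double w0 = 0.0, s0 = 0.0, best = -1.0;
  int kbest = -1;
  for (int k = 0; k < nb - 1; ++k) {
    w0 += cnt[k];
    s0 += cnt[k] * mid[k];
    double w1 = total - w0;
    if (w0 <= 0.0 || w1 <= 0.0) continue;
    double mu0 = s0 / w0, mu1 = (sumT - s0) / w1;
    double v = w0 * w1 * (mu0 - mu1) * (mu0 - mu1);
    if (v > best) {
      best = v;
      kbest = k;
    }
  }
  if (kbest < 0) return NA_REAL;
  return mn + (kbest + 1) * w;
}

// [[Rcpp::export]]
double cpp_otsu_threshold(NumericMatrix image) {
  return otsu_core(image.begin(), image.nrow() * image.ncol());
}

// 8-connected component labeling by breadth-first search in column-major
// scan order (labels are assigned in order of first encounter).
static int label_core(const int* mask, std::vector<int>& lab, int nr, int nc) {
  std::fill(lab.begin(), lab.end(), 0);
  int nlab = 0;
  std::queue<int> fifo;
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int p = c * nr + r;
      if (!mask[p] || lab[p]) continue;
      lab[p] = ++nlab;
      fifo.push(p);
      while (!fifo.empty()) {
        int q = fifo.front();
        fifo.pop();
        int rq = q % nr, cq = q / nr;
        for (int k = 0; k < 8; ++k) {
          int rn = rq + dr8[k], cn = cq + dc8[k];
          if (rn < 0 || rn >= nr || cn < 0 || cn >= nc) continue;
          int pn = cn * nr + rn;
          if (mask[pn] && !lab[pn]) {
            lab[pn] = nlab;
            fifo.push(pn);
          }
        }
      }
    }
  }
  return nlab;
}

// [[Rcpp::export]]
IntegerMatrix cpp_label_blobs(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  std::vector<int> m(mask.begin(), mask.end());
  std::vector<int> lab(static_cast<size_t>(nr) * nc);
  int n = label_core(m.data(), lab, nr, nc);
  IntegerMatrix out(nr, nc);
  std::copy(lab.begin(), lab.end(), out.begin());
  out.attr("n") = n;
  return out;
}

// Per-label area, unweighted centroid (row, col) and bounding box, all in
// 1-based pixel coordinates. Columns: area, row_centroid, col_centroid,
// row_min, row_max, col_min, col_max.
static NumericMatrix stats_core(const std::vector<int>& lab, int n,
                                int nr, int nc) {
  NumericMatrix st(n, 7);
  for (int j = 0; j < n; ++j) {
    st(j, 3) = nr + 1;
    st(j, 5) = nc + 1;
  }
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int l = lab[c * nr + r];
      if (!l) continue;
      int j = l - 1;
      st(j, 0) += 1.0;
      st(j, 1) += r + 1;
      st(j, 2) += c + 1;
      st(j, 3) = std::min(st(j, 3), double(r + 1));
      st(j, 4) = std::max(st(j, 4), double(r + 1));
      st(j, 5) = std::min(st(j, 5), double(c + 1));
      st(j, 6) = std::max(st(j, 6), double(c + 1));
    }
  }
  for (int j = 0; j < n; ++j) {
    st(j, 1) /= st(j, 0);
    st(j, 2) /= st(j, 0);
  }
  return st;
}

// [[Rcpp::export]]
NumericMatrix cpp_blob_stats(IntegerMatrix labels, int n) {
  int nr = labels.nrow(), nc = labels.ncol();
  std::vector<int> lab(labels.begin(), labels.end());
  return stats_core(lab, n, nr, nc);
}

// Fused per-window schedule: for each intensity level, zero out sub-level
// pixels (keeping the grayscale above), clear border-connected structures,
// Otsu-binarize and label blobs. Equivalent to composing the exported
// single-step operations; fused to avoid repeated matrix copies on the
// 15-level schedule.
// [[Rcpp::export]]
List cpp_detect_levels(NumericMatrix coeffs, NumericVector levels) {
  int nr = coeffs.nrow(), nc = coeffs.ncol();
  int nlev = levels.size();
  List out(nlev);
  std::vector<double> clip(static_cast<size_t>(nr) * nc), cleared;
  std::vector<int> maskv(static_cast<size_t>(nr) * nc),
      lab(static_cast<size_t>(nr) * nc);
  for (int li = 0; li < nlev; ++li) {
    double level = levels[li];
    for (int i = 0; i < nr * nc; ++i)
      clip[i] = coeffs[i] >= level ? coeffs[i] : 0.0;
    clear_border_core(cleared, clip.data(), nr, nc);
    double thr = otsu_core(cleared.data(), nr * nc);
    int n = 0;
    NumericMatrix st(0, 7);
    if (R_finite(thr)) {
      for (int i = 0; i < nr * nc; ++i) maskv[i] = cleared[i] > thr ? 1 : 0;
      n = label_core(maskv.data(), lab, nr, nc);
      st = stats_core(lab, n, nr, nc);
    }
    out[li] = List::create(_["blobs"] = st, _["otsu"] = thr);
  }
  return out;
}
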