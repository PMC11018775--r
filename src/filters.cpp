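#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Separable convolution with replicate (nearest-edge) padding.
// k must have odd length and sum to whatever the caller wants preserved.
// [[Rcpp::export]]
NumericMatrix cpp_sepconv(const NumericMatrix& img, const NumericVector& k) {
  const int nr = img.nrow(), nc = img.ncol(), m = k.size(), h = m / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  // along rows (vertical, dim 1)
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      for (int t = -h; t <= h; ++t) {
        int ii = i + t;
        if (ii < 0) ii = 0; else if (ii >= nr) ii = nr - 1;
        s += img(ii, j) * k[t + h];
      }
      tmp(i, j) = s;
    }
  }
  // along columns (horizontal, dim 2)
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      for (int t = -h; t <= h; ++t) {
        int jj = j + t;
        if (jj < 0) jj = 0; else if (jj >= nc) jj = nc - 1;
        s += tmp(i, jj) * k[t + h];
      }
      out(i, j) = s;
    }
  }
  return out;
}

// Grayscale erosion (dilate = false) / dilation (dilate = true) with a
// possibly non-flat structuring element given as pixel offsets (dy, dx) and
// per-offset heights. Erosion: min(img(p+o) - h(o)); dilation: max(img(p+o) + h(o)).
// Replicate padding at the borders.
// [[Rcpp::export]]
NumericMatrix cpp_morph(const NumericMatrix& img, const IntegerMatrix& offsets,
                        const NumericVector& height, bool dilate) {
  const int nr = img.nrow(), nc = img.ncol(), no = offsets.nrow();
  NumericMatrix out(nr, nc);
  const double* p = &img(0, 0);
  double* q = &out(0, 0);
  std::vector<int> di(no), dj(no), lin(no);
  std::vector<double> hs(no);
  int rmax = 0, cmax = 0;
  for (int o = 0; o < no; ++o) {
    di[o] = offsets(o, 0); dj[o] = offsets(o, 1);
    lin[o] = dj[o] * nr + di[o];
    hs[o] = dilate ? height[o] : -height[o];
    rmax = std::max(rmax, std::abs(di[o]));
    cmax = std::max(cmax, std::abs(dj[o]));
  }
  const double sgn = dilate ? 1.0 : -1.0; // maximize sgn * value
  for (int j = 0; j < nc; ++j) {
    bool jint = (j >= cmax && j < nc - cmax);
    for (int i = 0; i < nr; ++i) {
      double best = -R_PosInf;
      if (jint && i >= rmax && i < nr - rmax) {
        const double* c = p + (size_t)j * nr + i;
        for (int o = 0; o < no; ++o) {
          double v = sgn * c[lin[o]] + sgn * hs[o];
          if (v > best) best = v;
        }
      } else {
        for (int o = 0; o < no; ++o) {
          int ii = i + di[o], jj = j + dj[o];
          if (ii < 0) ii = 0; else if (ii >= nr) ii = nr - 1;
          if (jj < 0) jj = 0; else if (jj >= nc) jj = nc - 1;
          double v = sgn * p[(size_t)jj * nr + ii] + sgn * hs[o];
          if (v > best) best = v;
        }
      }
      q[(size_t)j * nr + i] = sgn * best;
    }
  }
  return out;
}

// 4-connected component labeling of a logical mask (BFS).
// [[Rcpp::export]]
IntegerMatrix cpp_label4(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  const int di[4] = {-1, 1, 0, 0}, dj[4] = {0, 0, -1, 1};
  std::queue<std::pair<int,int> > q;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      lab(i, j) = ++next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int,int> p = q.front(); q.pop();
        for (int d = 0; d < 4; ++d) {
          int ii = p.first + di[d], jj = p.second + dj[d];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (mask(ii, jj) && lab(ii, jj) == 0) {
            lab(ii, jj) = next;
            q.push(std::make_pair(ii, jj));
          }
        }
      }
    }
  }
  return lab;
}

// Chamfer (3-4) distance transform of a mask: distance from each TRUE pixel
// to the nearest FALSE pixel, in pixel units (weights 3,4 scaled back by 1/3).
// [[Rcpp::export]]
NumericMatrix cpp_edt(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const double BIG = 1e12;
  NumericMatrix d(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      d(i, j) = mask(i, j) ? BIG : 0.0;
  // forward pass
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (d(i, j) == 0.0) continue;
      double v = d(i, j);
      if (i > 0 && d(i - 1, j) + 3 < v) v = d(i - 1, j) + 3;
      if (j > 0 && d(i, j - 1) + 3 < v) v = d(i, j - 1) + 3;
      if (i > 0 && j > 0 && d(i - 1, j - 1) + 4 < v) v = d(i - 1, j - 1) + 4;
      if (i < nr - 1 && j > 0 && d(i + 1, j - 1) + 4 < v) v = d(i + 1, j - 1) + 4;
      d(i, j) = v;
    }
  }
  // backward pass
  for (int j = nc - 1; j >= 0; --j) {
    for (int i = nr - 1; i >= 0; --i) {
      if (d(i, j) == 0.0) continue;
      double v = d(i, j);
      if (i < nr - 1 && d(i + 1, j) + 3 < v) v = d(i + 1, j) + 3;
      if (j < nc - 1 && d(i, j + 1) + 3 < v) v = d(i, j + 1) + 3;
      if (i < nr - 1 && j < nc - 1 && d(i + 1, j + 1) + 4 < v) v = d(i + 1, j + 1) + 4;
      if (i > 0 && j < nc - 1 && d(i - 1, j + 1) + 4 < v) v = d(i - 1, j + 1) + 4;
      d(i, j) = v;
    }
  }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      d(i, j) /= 3.0;
  return d;
}

// 3x3 median filter with replicate edges (shot-noise suppression that does
// not displace edges, unlike a linear blur).
// [[Rcpp::export]]
NumericMatrix cpp_median3(const NumericMatrix& img) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  double buf[9];
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int n = 0;
      for (int dj = -1; dj <= 1; ++dj) {
        int jj = j + dj;
        if (jj < 0) jj = 0; else if (jj >= nc) jj = nc - 1;
        for (int di = -1; di <= 1; ++di) {
          int ii = i + di;
          if (ii < 0) ii = 0; else if (ii >= nr) ii = nr - 1;
          buf[n++] = img(ii, jj);
        }
      }
      std::nth_element(buf, buf + 4, buf + 9);
      out(i, j) = buf[4];
    }
  }
  return out;
}

// Local mean and standard deviation over a (2h+1)x(2h+1) window via integral
// images, replicate-free: windows are clipped at borders (population sd).
// Returns list(mean, sd).
// [[Rcpp::export]]
List cpp_local_mean_sd(const NumericMatrix& img, int h) {
  const int nr = img.nrow(), nc = img.ncol();
  // integral images with a zero top row / left column
  std::vector<double> S((nr + 1) * (nc + 1), 0.0), S2((nr + 1) * (nc + 1), 0.0);
  const int W = nr + 1;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double v = img(i, j);
      S[(j + 1) * W + (i + 1)]  = v     + S[j * W + (i + 1)] + S[(j + 1) * W + i] - S[j * W + i];
      S2[(j + 1) * W + (i + 1)] = v * v + S2[j * W + (i + 1)] + S2[(j + 1) * W + i] - S2[j * W + i];
    }
  }
  NumericMatrix mu(nr, nc), sd(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int i0 = std::max(0, i - h), i1 = std::min(nr - 1, i + h);
      int j0 = std::max(0, j - h), j1 = std::min(nc - 1, j + h);
      double n = (double)(i1 - i0 + 1) * (j1 - j0 + 1);
      double s  = S[(j1 + 1) * W + (i1 + 1)] - S[j0 * W + (i1 + 1)] - S[(j1 + 1) * W + i0] + S[j0 * W + i0];
      double s2 = S2[(j1 + 1) * W + (i1 + 1)] - S2[j0 * W + (i1 + 1)] - S2[(j1 + 1) * W + i0] + S2[j0 * W + i0];
      double m = s / n;
      double var = s2 / n - m * m;
      mu(i, j) = m;
      sd(i, j) = var > 0 ? std::sqrt(var) : 0.0;
    }
  }
  return List::create(_["mean"] = mu, _["sd"] = sd);
}
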