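#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Offsets of the ball structuring element: all (du, dv) with u^2+v^2 <= r^2,
// each with the ball height k = sqrt(r^2 - u^2 - v^2). Height is in the same
// numeric units as the image intensities (1 gray level per pixel of radius).
struct BallSE {
  std::vector<int> du, dv;
  std::vector<double> k;
};

static BallSE make_ball(double radius) {
  BallSE se;
  int r = (int)std::floor(radius);
  double r2 = radius * radius;
  // u outer / v inner: linear offsets into a column-major buffer are then
  // contiguous runs, which keeps the erosion inner loop cache-friendly
  for (int u = -r; u <= r; ++u) {
    for (int v = -r; v <= r; ++v) {
      double d2 = (double)u * u + (double)v * v;
      if (d2 <= r2) {
        se.du.push_back(u);
        se.dv.push_back(v);
        se.k.push_back(std::sqrt(r2 - d2));
      }
    }
  }
  return se;
}

// Shared worker: grayscale erosion (sign = +1) or dilation (sign = -1) by
// the ball. The image is copied into a border-padded buffer whose padding
// holds +Inf (erosion) or -Inf (dilation), so offsets outside the image
// never contribute and the inner loop needs no bounds checks; each SE
// element becomes a single linear offset into the padded buffer.
static NumericMatrix ball_morph(const NumericMatrix& img, double radius,
                                int sign) {
  int nr = img.nrow(), nc = img.ncol();
  BallSE se = make_ball(radius);
  size_t m = se.k.size();
  int pad = (int)std::floor(radius);
  int pnr = nr + 2 * pad;
  // the min below must ignore out-of-image offsets in both directions,
  // and dilation is computed as -erode(-img), so the padding is +Inf
  std::vector<double> buf((size_t)pnr * (nc + 2 * pad), R_PosInf);
  for (int c = 0; c < nc; ++c) {
    const double* src = &img(0, c);
    double* dst = &buf[(size_t)(c + pad) * pnr + pad];
    if (sign > 0) {
      for (int r = 0; r < nr; ++r) dst[r] = src[r];
    } else {
      for (int r = 0; r < nr; ++r) dst[r] = -src[r];
    }
  }
  // linear offsets into the padded buffer, with signed heights folded in
  std::vector<long> off(m);
  std::vector<double> kk(m);
  for (size_t i = 0; i < m; ++i) {
    off[i] = (long)se.du[i] * pnr + se.dv[i];
    kk[i] = se.k[i];
  }
  // offset-outer / pixel-inner order: each SE element updates the whole
  // output with a streaming elementwise min, which the compiler vectorizes
  NumericMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), R_PosInf);
  for (size_t i = 0; i < m; ++i) {
    double ki = kk[i];
    long oi = off[i];
    for (int c = 0; c < nc; ++c) {
      double* o = &out(0, c);
      const double* base = &buf[(size_t)(c + pad) * pnr + pad] + oi;
      for (int r = 0; r < nr; ++r) {
        double v = base[r] - ki;
        o[r] = o[r] < v ? o[r] : v;
      }
    }
  }
  if (sign < 0) {
    for (double* p = out.begin(); p != out.end(); ++p) *p = -*p;
  }
  return out;
}

// Grayscale erosion by the ball: out(x) = min over SE of img(x+o) - k(o).
// Offsets falling outside the image are ignored, so a constant image erodes
// to (constant - radius) everywhere including near borders.
// [[Rcpp::export(name = ".cpp_ball_erode")]]
NumericMatrix cpp_ball_erode(const NumericMatrix& img, double radius) {
  return ball_morph(img, radius, +1);
}

// Grayscale dilation by the ball: out(x) = max over SE of img(x+o) + k(o).
// [[Rcpp::export(name = ".cpp_ball_dilate")]]
NumericMatrix cpp_ball_dilate(const NumericMatrix& img, double radius) {
  return ball_morph(img, radius, -1);
}

// Connected-component labeling of a logical mask under 8-connectivity.
// Labels are dense from 1 in raster (column-major) order of first encounter.
// [[Rcpp::export(name = ".cpp_label8")]]
IntegerMatrix cpp_label8(const LogicalMatrix& mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::vector<std::pair<int, int> > stack;
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(r, c));
      lab(r, c) = next;
      while (!stack.empty()) {
        std::pair<int, int> p = stack.back();
        stack.pop_back();
        for (int i = 0; i < 8; ++i) {
          int rr = p.first + dr[i], cc = p.second + dc[i];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back(std::make_pair(rr, cc));
          }
        }
      }
    }
  }
  return lab;
}

// Moore-neighbour tracing of the outer boundary of one labeled particle,
// clockwise in image coordinates (rows grow downward). Returns the ordered
// boundary pixel path (1-based row, col), start pixel not repeated at the
// end. Single isolated pixels yield a one-row path.
// [[Rcpp::export(name = ".cpp_trace_boundary")]]
IntegerMatrix cpp_trace_boundary(const IntegerMatrix& lab, int id) {
  int nr = lab.nrow(), nc = lab.ncol();
  // clockwise neighbour order (row down): E SE S SW W NW N NE
  const int dr[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  const int dc[8] = {1, 1, 0, -1, -1, -1, 0, 1};
  int sr = -1, sc = -1;
  for (int r = 0; r < nr && sr < 0; ++r)
    for (int c = 0; c < nc; ++c)
      if (lab(r, c) == id) { sr = r; sc = c; break; }
  if (sr < 0) stop("label id not present in image");

  std::vector<int> rows, cols;
  rows.push_back(sr); cols.push_back(sc);
  int cr = sr, cc = sc;
  int dir_prev = 4; // virtual previous pixel to the west of the start
  int first_move = -1;
  long guard = 8L * (long)nr * (long)nc + 16;
  while (guard-- > 0) {
    int found = -1;
    for (int i = 0; i < 8; ++i) {
      int d = (dir_prev + 1 + i) % 8;
      int rr = cr + dr[d], ccx = cc + dc[d];
      if (rr < 0 || rr >= nr || ccx < 0 || ccx >= nc) continue;
      if (lab(rr, ccx) == id) { found = d; break; }
    }
    if (found < 0) break; // isolated pixel
    int rr = cr + dr[found], ccx = cc + dc[found];
    if (first_move < 0) {
      first_move = found;
    } else if (cr == sr && cc == sc && found == first_move) {
      break; // Jacob's stopping criterion: re-leaving start the same way
    }
    cr = rr; cc = ccx;
    if (!(cr == sr && cc == sc)) { rows.push_back(cr); cols.push_back(cc); }
    dir_prev = (found + 4) % 8;
  }
  IntegerMatrix path(rows.size(), 2);
  for (size_t i = 0; i < rows.size(); ++i) {
    path(i, 0) = rows[i] + 1;
    path(i, 1) = cols[i] + 1;
  }
  return path;
}
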