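// Numerical kernels for 3D registration: strided 3x3x3 convolution
// (forward and backward via im2col + GEMM), nearest-neighbour 2x
// upsampling, trilinear warping with analytic coordinate gradients,
// and separable zero-padded box sums used by the windowed NCC loss.
//
// Feature-map layout: channels x voxels (arma::mat), voxel columns in
// R array order (x fastest). Volumes arrive as flat NumericVectors with
// an explicit dims argument; displacement fields as N x 3 matrices in
// voxel units, component order (dx, dy, dz).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int conv_outdim(int n, int stride) {
  // kernel 3, pad 1: stride 1 keeps n, stride 2 gives floor((n-1)/2)+1
  return (stride == 1) ? n : ((n - 1) / 2 + 1);
}

// The convolution is evaluated one kernel tap at a time: for each of the
// 27 offsets the input is gathered into a shifted buffer (zero padding,
// contiguous x-runs copied en bloc for stride 1) and a single GEMM
// accumulates W_k * shifted. This keeps the working set at one
// C x N_out buffer instead of a 27C x N_out im2col matrix.
static void gather_shift(const arma::mat& input, arma::mat& buf,
                         int X, int Y, int Z, int stride,
                         int OX, int OY, int OZ, int kx, int ky, int kz) {
  const int C = input.n_rows;
  buf.zeros();
  for (int oz = 0; oz < OZ; ++oz) {
    int iz = oz * stride + kz - 1;
    if (iz < 0 || iz >= Z) continue;
    for (int oy = 0; oy < OY; ++oy) {
      int iy = oy * stride + ky - 1;
      if (iy < 0 || iy >= Y) continue;
      arma::uword obase = (arma::uword)OX * (oy + (arma::uword)OY * oz);
      arma::uword ibase = (arma::uword)X * (iy + (arma::uword)Y * iz);
      if (stride == 1) {
        int ox0 = std::max(0, 1 - kx);           // first ox with ix >= 0
        int ox1 = std::min(OX - 1, X - kx);      // last ox with ix <= X-1
        if (ox1 < ox0) continue;
        std::memcpy(buf.colptr(obase + ox0),
                    input.colptr(ibase + ox0 + kx - 1),
                    (size_t)(ox1 - ox0 + 1) * C * sizeof(double));
      } else {
        for (int ox = 0; ox < OX; ++ox) {
          int ix = ox * stride + kx - 1;
          if (ix < 0 || ix >= X) continue;
          std::memcpy(buf.colptr(obase + ox), input.colptr(ibase + ix),
                      C * sizeof(double));
        }
      }
    }
  }
}

// Scatter-add the reverse mapping of gather_shift: buf columns flow back
// to their source input columns.
static void scatter_shift(arma::mat& grad_input, const arma::mat& buf,
                          int X, int Y, int Z, int stride,
                          int OX, int OY, int OZ, int kx, int ky, int kz) {
  const int C = grad_input.n_rows;
  for (int oz = 0; oz < OZ; ++oz) {
    int iz = oz * stride + kz - 1;
    if (iz < 0 || iz >= Z) continue;
    for (int oy = 0; oy < OY; ++oy) {
      int iy = oy * stride + ky - 1;
      if (iy < 0 || iy >= Y) continue;
      arma::uword obase = (arma::uword)OX * (oy + (arma::uword)OY * oz);
      arma::uword ibase = (arma::uword)X * (iy + (arma::uword)Y * iz);
      if (stride == 1) {
        int ox0 = std::max(0, 1 - kx);
        int ox1 = std::min(OX - 1, X - kx);
        if (ox1 < ox0) continue;
        double* dst = grad_input.colptr(ibase + ox0 + kx - 1);
        const double* src = buf.colptr(obase + ox0);
        size_t len = (size_t)(ox1 - ox0 + 1) * C;
        for (size_t t = 0; t < len; ++t) dst[t] += src[t];
      } else {
        for (int ox = 0; ox < OX; ++ox) {
          int ix = ox * stride + kx - 1;
          if (ix < 0 || ix >= X) continue;
          double* dst = grad_input.colptr(ibase + ix);
          const double* src = buf.colptr(obase + ox);
          for (int c = 0; c < C; ++c) dst[c] += src[c];
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::mat conv3d_fw(const arma::mat& W, const arma::vec& b,
                    const arma::mat& input, IntegerVector dims, int stride) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const int OX = conv_outdim(X, stride), OY = conv_outdim(Y, stride),
            OZ = conv_outdim(Z, stride);
  const int C = input.n_rows;
  const arma::uword Nout = (arma::uword)OX * OY * OZ;
  arma::mat out(W.n_rows, Nout);
  out.each_col() = b;
  arma::mat buf(C, Nout);
  for (int k = 0; k < 27; ++k) {
    gather_shift(input, buf, X, Y, Z, stride, OX, OY, OZ,
                 k % 3, (k / 3) % 3, k / 9);
    out += W.cols((arma::uword)k * C, (arma::uword)(k + 1) * C - 1) * buf;
  }
  return out;
}

// [[Rcpp::export]]
List conv3d_bw(const arma::mat& W, const arma::mat& input,
               const arma::mat& grad_out, IntegerVector dims, int stride) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const int OX = conv_outdim(X, stride), OY = conv_outdim(Y, stride),
            OZ = conv_outdim(Z, stride);
  const int C = input.n_rows;
  const arma::uword Nout = (arma::uword)OX * OY * OZ;
  arma::mat grad_W(W.n_rows, W.n_cols);
  arma::vec grad_b = arma::sum(grad_out, 1);
  arma::mat grad_input(C, input.n_cols, arma::fill::zeros);
  arma::mat buf(C, Nout);
  arma::mat delta(C, Nout);
  for (int k = 0; k < 27; ++k) {
    const int kx = k % 3, ky = (k / 3) % 3, kz = k / 9;
    gather_shift(input, buf, X, Y, Z, stride, OX, OY, OZ, kx, ky, kz);
    arma::uword c0 = (arma::uword)k * C, c1 = (arma::uword)(k + 1) * C - 1;
    grad_W.cols(c0, c1) = grad_out * buf.t();
    delta = W.cols(c0, c1).t() * grad_out;
    scatter_shift(grad_input, delta, X, Y, Z, stride, OX, OY, OZ, kx, ky, kz);
  }
  return List::create(_["grad_input"] = grad_input,
                      _["grad_W"] = grad_W,
                      _["grad_b"] = grad_b);
}

// [[Rcpp::export]]
arma::mat upsample2_fw(const arma::mat& input, IntegerVector dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const int OX = 2 * X, OY = 2 * Y, OZ = 2 * Z;
  arma::mat out(input.n_rows, (arma::uword)OX * OY * OZ);
  for (int oz = 0; oz < OZ; ++oz)
    for (int oy = 0; oy < OY; ++oy)
      for (int ox = 0; ox < OX; ++ox) {
        arma::uword ocol = (arma::uword)ox + (arma::uword)OX * (oy + (arma::uword)OY * oz);
        arma::uword icol = (arma::uword)(ox / 2) + (arma::uword)X * ((oy / 2) + (arma::uword)Y * (oz / 2));
        out.col(ocol) = input.col(icol);
      }
  return out;
}

// [[Rcpp::export]]
arma::mat upsample2_bw(const arma::mat& grad_out, IntegerVector dims_in) {
  const int X = dims_in[0], Y = dims_in[1], Z = dims_in[2];
  const int OX = 2 * X, OY = 2 * Y, OZ = 2 * Z;
  arma::mat grad_in(grad_out.n_rows, (arma::uword)X * Y * Z, arma::fill::zeros);
  for (int oz = 0; oz < OZ; ++oz)
    for (int oy = 0; oy < OY; ++oy)
      for (int ox = 0; ox < OX; ++ox) {
        arma::uword ocol = (arma::uword)ox + (arma::uword)OX * (oy + (arma::uword)OY * oz);
        arma::uword icol = (arma::uword)(ox / 2) + (arma::uword)X * ((oy / 2) + (arma::uword)Y * (oz / 2));
        grad_in.col(icol) += grad_out.col(ocol);
      }
  return grad_in;
}

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Trilinear sample of vol at absolute voxel coordinates (px,py,pz),
// coordinates clamped to the grid (border replication).
static inline double trilin_at(const double* v, int X, int Y, int Z,
                               double px, double py, double pz) {
  px = clampd(px, 0.0, X - 1.0);
  py = clampd(py, 0.0, Y - 1.0);
  pz = clampd(pz, 0.0, Z - 1.0);
  int x0 = (int)std::floor(px), y0 = (int)std::floor(py), z0 = (int)std::floor(pz);
  if (x0 > X - 2) x0 = X - 2; if (x0 < 0) x0 = 0;
  if (y0 > Y - 2) y0 = Y - 2; if (y0 < 0) y0 = 0;
  if (z0 > Z - 2) z0 = Z - 2; if (z0 < 0) z0 = 0;
  int x1 = std::min(x0 + 1, X - 1), y1 = std::min(y0 + 1, Y - 1), z1 = std::min(z0 + 1, Z - 1);
  double fx = px - x0, fy = py - y0, fz = pz - z0;
  const arma::uword XY = (arma::uword)X * Y;
  #define V(i, j, k) v[(arma::uword)(i) + (arma::uword)X * (j) + XY * (k)]
  double c00 = V(x0, y0, z0) * (1 - fx) + V(x1, y0, z0) * fx;
  double c10 = V(x0, y1, z0) * (1 - fx) + V(x1, y1, z0) * fx;
  double c01 = V(x0, y0, z1) * (1 - fx) + V(x1, y0, z1) * fx;
  double c11 = V(x0, y1, z1) * (1 - fx) + V(x1, y1, z1) * fx;
  #undef V
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// [[Rcpp::export]]
NumericVector warp_fw(NumericVector vol, IntegerVector dims,
                      const arma::mat& field, bool nearest) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const arma::uword N = (arma::uword)X * Y * Z;
  if (field.n_rows != N || field.n_cols != 3)
    stop("field must be N x 3 with N matching the volume");
  NumericVector out(N);
  const double* v = vol.begin();
  arma::uword idx = 0;
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y)
      for (int x = 0; x < X; ++x, ++idx) {
        double px = x + field(idx, 0);
        double py = y + field(idx, 1);
        double pz = z + field(idx, 2);
        if (nearest) {
          int ix = (int)clampd(std::round(px), 0.0, X - 1.0);
          int iy = (int)clampd(std::round(py), 0.0, Y - 1.0);
          int iz = (int)clampd(std::round(pz), 0.0, Z - 1.0);
          out[idx] = v[(arma::uword)ix + (arma::uword)X * (iy + (arma::uword)Y * iz)];
        } else {
          out[idx] = trilin_at(v, X, Y, Z, px, py, pz);
        }
      }
  return out;
}

// Gradient of sum(grad_out * warped) with respect to the displacement
// field. Samples clamped to the border get zero coordinate gradient.
// [[Rcpp::export]]
arma::mat warp_bw(NumericVector vol, IntegerVector dims,
                  const arma::mat& field, NumericVector grad_out) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const arma::uword N = (arma::uword)X * Y * Z;
  arma::mat grad_field(N, 3, arma::fill::zeros);
  const double* v = vol.begin();
  const arma::uword XY = (arma::uword)X * Y;
  arma::uword idx = 0;
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y)
      for (int x = 0; x < X; ++x, ++idx) {
        double g = grad_out[idx];
        if (g == 0.0) continue;
        double px = x + field(idx, 0);
        double py = y + field(idx, 1);
        double pz = z + field(idx, 2);
        bool inx = (px > 0.0 && px < X - 1.0);
        bool iny = (py > 0.0 && py < Y - 1.0);
        bool inz = (pz > 0.0 && pz < Z - 1.0);
        px = clampd(px, 0.0, X - 1.0);
        py = clampd(py, 0.0, Y - 1.0);
        pz = clampd(pz, 0.0, Z - 1.0);
        int x0 = std::min((int)std::floor(px), X - 2); if (x0 < 0) x0 = 0;
        int y0 = std::min((int)std::floor(py), Y - 2); if (y0 < 0) y0 = 0;
        int z0 = std::min((int)std::floor(pz), Z - 2); if (z0 < 0) z0 = 0;
        int x1 = std::min(x0 + 1, X - 1), y1 = std::min(y0 + 1, Y - 1), z1 = std::min(z0 + 1, Z - 1);
        double fx = px - x0, fy = py - y0, fz = pz - z0;
        #define V(i, j, k) v[(arma::uword)(i) + (arma::uword)X * (j) + XY * (k)]
        double c000 = V(x0, y0, z0), c100 = V(x1, y0, z0);
        double c010 = V(x0, y1, z0), c110 = V(x1, y1, z0);
        double c001 = V(x0, y0, z1), c101 = V(x1, y0, z1);
        double c011 = V(x0, y1, z1), c111 = V(x1, y1, z1);
        #undef V
        if (inx)
          grad_field(idx, 0) = g * ((c100 - c000) * (1 - fy) * (1 - fz) +
                                    (c110 - c010) * fy * (1 - fz) +
                                    (c101 - c001) * (1 - fy) * fz +
                                    (c111 - c011) * fy * fz);
        if (iny)
          grad_field(idx, 1) = g * ((c010 - c000) * (1 - fx) * (1 - fz) +
                                    (c110 - c100) * fx * (1 - fz) +
                                    (c011 - c001) * (1 - fx) * fz +
                                    (c111 - c101) * fx * fz);
        if (inz)
          grad_field(idx, 2) = g * ((c001 - c000) * (1 - fx) * (1 - fy) +
                                    (c101 - c100) * fx * (1 - fy) +
                                    (c011 - c010) * (1 - fx) * fy +
                                    (c111 - c110) * fx * fy);
      }
  return grad_field;
}

// Trilinear sampling at arbitrary absolute coordinates (used by resize).
// [[Rcpp::export]]
NumericVector trilinear_sample(NumericVector vol, IntegerVector dims,
                               const arma::mat& coords) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  NumericVector out(coords.n_rows);
  const double* v = vol.begin();
  for (arma::uword i = 0; i < coords.n_rows; ++i)
    out[i] = trilin_at(v, X, Y, Z, coords(i, 0), coords(i, 1), coords(i, 2));
  return out;
}

// Separable sliding-window sum with zero padding; window w odd, output
// the same size as the input.
// [[Rcpp::export]]
NumericVector boxsum3(NumericVector vol, IntegerVector dims, int w) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const int r = w / 2;
  const arma::uword N = (arma::uword)X * Y * Z;
  std::vector<double> buf(vol.begin(), vol.end());
  std::vector<double> tmp(N);
  const int D[3] = {X, Y, Z};
  const arma::uword strides[3] = {1, (arma::uword)X, (arma::uword)X * Y};
  for (int ax = 0; ax < 3; ++ax) {
    const int n = D[ax];
    const arma::uword s = strides[ax];
    const arma::uword nlines = N / n;
    for (arma::uword line = 0; line < nlines; ++line) {
      // base index of this line: decompose line over the other two axes
      arma::uword base = 0, rem = line;
      for (int a2 = 0; a2 < 3; ++a2) {
        if (a2 == ax) continue;
        base += (rem % D[a2]) * strides[a2];
        rem /= D[a2];
      }
      double run = 0.0;
      for (int i = 0; i < n + r; ++i) {
        if (i < n) run += buf[base + (arma::uword)i * s];
        int j = i - r;                      // centre whose window ends at i
        int k = j - r - 1;                  // element leaving the window
        if (k >= 0) run -= buf[base + (arma::uword)k * s];
        if (j >= 0 && j < n) tmp[base + (arma::uword)j * s] = run;
      }
    }
    std::swap(buf, tmp);
  }
  return NumericVector(buf.begin(), buf.end());
}
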