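#include <Rcpp.h>
using namespace Rcpp;

// Separable 1D convolution along one axis of a 3D array stored in
// column-major order, with replicate (clamped) edge padding.  The kernel
// must have odd length and sum to 1 if intensities are to be preserved.
static void conv_axis(const std::vector<double> &in, std::vector<double> &out,
                      const int n1, const int n2, const int n3,
                      const int axis, const std::vector<double> &k) {
  const int r = (static_cast<int>(k.size()) - 1) / 2;
  const int klen = static_cast<int>(k.size());

  if (axis == 0) {
    for (int z = 0; z < n3; ++z) {
      for (int y = 0; y < n2; ++y) {
        const std::size_t base = static_cast<std::size_t>(z) * n2 * n1 +
                                 static_cast<std::size_t>(y) * n1;
        for (int x = 0; x < n1; ++x) {
          double acc = 0.0;
          for (int t = 0; t < klen; ++t) {
            int xx = x + t - r;
            if (xx < 0) xx = 0; else if (xx >= n1) xx = n1 - 1;
            acc += k[t] * in[base + xx];
          }
          out[base + x] = acc;
        }
      }
    }
  } else if (axis == 1) {
    for (int z = 0; z < n3; ++z) {
      const std::size_t zoff = static_cast<std::size_t>(z) * n2 * n1;
      for (int x = 0; x < n1; ++x) {
        for (int y = 0; y < n2; ++y) {
          double acc = 0.0;
          for (int t = 0; t < klen; ++t) {
            int yy = y + t - r;
            if (yy < 0) yy = 0; else if (yy >= n2) yy = n2 - 1;
            acc += k[t] * in[zoff + static_cast<std::size_t>(yy) * n1 + x];
          }
          out[zoff + static_cast<std::size_t>(y) * n1 + x] = acc;
        }
      }
    }
  } else {
    const std::size_t plane = static_cast<std::size_t>(n2) * n1;
    for (int y = 0; y < n2; ++y) {
      for (int x = 0; x < n1; ++x) {
        const std::size_t base = static_cast<std::size_t>(y) * n1 + x;
        for (int z = 0; z < n3; ++z) {
          double acc = 0.0;
          for (int t = 0; t < klen; ++t) {
            int zz = z + t - r;
            if (zz < 0) zz = 0; else if (zz >= n3) zz = n3 - 1;
            acc += k[t] * in[base + static_cast<std::size_t>(zz) * plane];
          }
          out[base + static_cast<std::size_t>(z) * plane] = acc;
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector sepconv3_cpp(NumericVector x, IntegerVector dims, List kernels) {
  if (dims.size() != 3) stop("dims must have length 3");
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  if (static_cast<std::size_t>(n1) * n2 * n3 != static_cast<std::size_t>(x.size()))
    stop("array size does not match dims");
  std::vector<double> a(x.begin(), x.end());
  std::vector<double> b(a.size());
  for (int axis = 0; axis < 3; ++axis) {
    NumericVector kr = kernels[axis];
    if (kr.size() <= 1) continue;  // identity along this axis
    if (kr.size() % 2 == 0) stop("kernels must have odd length");
    std::vector<double> k(kr.begin(), kr.end());
    conv_axis(a, b, n1, n2, n3, axis, k);
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dims;
  return out;
}
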