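// Minimal 3D convolution for the default patch encoder.  Tensors are flat
// vectors laid out channel-slowest: channel c occupies a contiguous block
// that is itself a standard R (z, y, x) column-major array.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".conv3d_valid")]]
List conv3d_cpp(NumericVector input, IntegerVector in_dims,
                NumericVector w, IntegerVector w_dims,
                NumericVector bias, int stride, bool relu) {
  const int Ci = in_dims[0], Z = in_dims[1], Y = in_dims[2], X = in_dims[3];
  const int Co = w_dims[0], Cw = w_dims[1], K = w_dims[2];
  if (Cw != Ci) stop("weight/input channel mismatch");
  const int Zo = (Z - K) / stride + 1;
  const int Yo = (Y - K) / stride + 1;
  const int Xo = (X - K) / stride + 1;
  if (Zo < 1 || Yo < 1 || Xo < 1) stop("kernel larger than input");
  const long planeI = (long)Z * Y * X;
  const long planeO = (long)Zo * Yo * Xo;
  NumericVector out((long)Co * planeO);

  for (int co = 0; co < Co; ++co) {
    const double b = bias[co];
    for (int xo = 0; xo < Xo; ++xo) {
      for (int yo = 0; yo < Yo; ++yo) {
        for (int zo = 0; zo < Zo; ++zo) {
          double acc = b;
          const int z0 = zo * stride, y0 = yo * stride, x0 = xo * stride;
          for (int ci = 0; ci < Ci; ++ci) {
            const double* in = &input[ci * planeI];
            const double* ww = &w[(((long)co * Ci + ci) * K) * K * K];
            for (int dx = 0; dx < K; ++dx)
              for (int dy = 0; dy < K; ++dy)
                for (int dz = 0; dz < K; ++dz)
                  acc += ww[(dz * K + dy) * K + dx] *
                         in[(z0 + dz) + (long)Z * ((y0 + dy) + (long)Y * (x0 + dx))];
          }
          if (relu && acc < 0) acc = 0;
          out[co * planeO + (zo + (long)Zo * (yo + (long)Yo * xo))] = acc;
        }
      }
    }
  }
  return List::create(_["values"] = out,
                      _["dims"] = IntegerVector::create(Co, Zo, Yo, Xo));
}
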