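#include <Rcpp.h>
using namespace Rcpp;

// Poisson shot noise (gain-scaled) plus Gaussian read noise, one pass.
// lambda is the noiseless expected gray level per pixel; with gain g
// (gray units per photoelectron) the detected value is
//   g * Poisson(lambda / g) + N(0, read_sigma^2),
// so an object-free frame has variance g * lambda + read_sigma^2.
// Uses R's RNG: deterministic under set.seed and stable across platforms.
// g <= 0 disables the shot-noise term (lambda passed through).
// For large Poisson means (> 1000) the Poisson is replaced by its Gaussian
// limit and folded into the read noise (one draw; skewness < 0.04 there).
// [[Rcpp::export(name = ".add_noise_cpp")]]
NumericVector add_noise_cpp(NumericVector lambda, double gain, double read_sigma) {
  R_xlen_t n = lambda.size();
  NumericVector out(n);
  RNGScope scope;
  for (R_xlen_t i = 0; i < n; ++i) {
    double lam = lambda[i];
    double v;
    if (gain > 0.0 && lam / gain <= 1000.0) {
      v = gain * R::rpois(lam / gain);
      if (read_sigma > 0.0) v += R::rnorm(0.0, read_sigma);
    } else {
      double var = (gain > 0.0 ? gain * lam : 0.0) + read_sigma * read_sigma;
      v = lam + (var > 0.0 ? R::rnorm(0.0, std::sqrt(var)) : 0.0);
    }
    out[i] = v;
  }
  return out;
}

// Full frame formation in one pass: expected intensity = bg + diffuse +
// signal (clamped at 0), then shot + read noise (unless noiseless), then
// 16-bit quantization. Avoids intermediate 2-Mpx temporaries in R.
// [[Rcpp::export(name = ".render_frame_cpp")]]
IntegerMatrix render_frame_cpp(NumericMatrix signal, Nullable<NumericMatrix> diffuse,
                               double bg, double gain, double read_sigma,
                               bool noiseless) {
  int nr = signal.nrow(), nc = signal.ncol();
  IntegerMatrix out(nr, nc);
  bool has_diff = diffuse.isNotNull();
  NumericMatrix D;
  if (has_diff) D = diffuse.get();
  RNGScope scope;
  R_xlen_t n = (R_xlen_t)nr * nc;
  for (R_xlen_t i = 0; i < n; ++i) {
    double lam = bg + signal[i];
    if (has_diff) lam += D[i];
    if (lam < 0.0) lam = 0.0;
    double v = lam;
    if (!noiseless) {
      if (gain > 0.0 && lam / gain <= 1000.0) {
        v = gain * R::rpois(lam / gain);
        if (read_sigma > 0.0) v += R::rnorm(0.0, read_sigma);
      } else {
        double var = (gain > 0.0 ? gain * lam : 0.0) + read_sigma * read_sigma;
        v = lam + (var > 0.0 ? R::rnorm(0.0, std::sqrt(var)) : 0.0);
      }
    }
    v = std::floor(v + 0.5);
    if (v < 0.0) v = 0.0;
    if (v > 65535.0) v = 65535.0;
    out[i] = (int)v;
  }
  return out;
}

// Quantize to the 16-bit integer pixel range.
// [[Rcpp::export(name = ".quantize_u16_cpp")]]
IntegerVector quantize_u16_cpp(NumericVector x) {
  R_xlen_t n = x.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = std::floor(x[i] + 0.5);
    if (v < 0.0) v = 0.0;
    if (v > 65535.0) v = 65535.0;
    out[i] = (int)v;
  }
  return out;
}

// Block-mean downsample by integer factor (remainder rows/cols trimmed).
// [[Rcpp::export(name = ".downsample_cpp")]]
NumericMatrix downsample_cpp(NumericMatrix x, int f) {
  int nr = x.nrow() / f, nc = x.ncol() / f;
  NumericMatrix out(nr, nc);
  double inv = 1.0 / (f * f);
  for (int j = 0; j < nc; ++j) {
    for (int jj = 0; jj < f; ++jj) {
      int col = j * f + jj;
      for (int i = 0; i < nr; ++i) {
        double s = 0.0;
        for (int ii = 0; ii < f; ++ii) s += x(i * f + ii, col);
        out(i, j) += s;
      }
    }
  }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) out(i, j) *= inv;
  return out;
}
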