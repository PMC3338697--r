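#include <Rcpp.h>
using namespace Rcpp;

// Render point emitters blurred by a 2D Gaussian beam profile onto a pixel
// grid. Pixel (r, c) has its center at ((r + 0.5) * px, (c + 0.5) * px) in
// micrometre coordinates (y = rows, x = columns). Each particle contributes
// b * exp(-2 d^2 / w0^2) to every pixel whose center lies within `cutoff`
// of the particle; beyond the cutoff the profile is below ~1e-8 of peak for
// cutoff >= 3 w0 and is dropped.
// [[Rcpp::export]]
NumericMatrix render_particles_cpp(NumericVector x, NumericVector y,
                                   NumericVector b, int nrow, int ncol,
                                   double pixel_size, double e2_radius,
                                   double cutoff) {
  NumericMatrix img(nrow, ncol);
  const double inv = 2.0 / (e2_radius * e2_radius);
  const double c2 = cutoff * cutoff;
  const int np = x.size();
  for (int p = 0; p < np; ++p) {
    const double xp = x[p], yp = y[p], bp = b[p];
    if (bp == 0.0) continue;
    int r0 = (int)std::floor((yp - cutoff) / pixel_size - 0.5);
    int r1 = (int)std::ceil((yp + cutoff) / pixel_size - 0.5);
    int c0 = (int)std::floor((xp - cutoff) / pixel_size - 0.5);
    int c1 = (int)std::ceil((xp + cutoff) / pixel_size - 0.5);
    if (r0 < 0) r0 = 0;
    if (c0 < 0) c0 = 0;
    if (r1 > nrow - 1) r1 = nrow - 1;
    if (c1 > ncol - 1) c1 = ncol - 1;
    for (int r = r0; r <= r1; ++r) {
      const double dy = (r + 0.5) * pixel_size - yp;
      const double dy2 = dy * dy;
      if (dy2 > c2) continue;
      for (int c = c0; c <= c1; ++c) {
        const double dx = (c + 0.5) * pixel_size - xp;
        const double d2 = dx * dx + dy2;
        if (d2 <= c2) img(r, c) += bp * std::exp(-inv * d2);
      }
    }
  }
  return img;
}

// Detector broadening of a probability mass function over integer intensity
// bins: the mass at bin k is redistributed as a discretized Gaussian centered
// at k with variance intercept + slope * (k + offset). Mass falling at or
// below zero accumulates in bin 0; the upper tail is folded into the top
// bin of the output so total mass is preserved exactly.
// [[Rcpp::export]]
NumericVector broaden_cpp(NumericVector mass, double slope, double intercept,
                          double offset, double nsd) {
  const int kin = mass.size();          // bins 0 .. kin-1
  const double vmax = intercept + slope * ((kin - 1) + offset);
  const int pad = (int)std::ceil(nsd * std::sqrt(vmax > 0.0 ? vmax : 0.0)) + 1;
  const int kout = kin + pad;
  NumericVector out(kout);
  const double inv_sqrt2 = 0.7071067811865475244;
  for (int k = 0; k < kin; ++k) {
    const double m = mass[k];
    if (m <= 1e-16) { if (m > 0.0) out[k] += m; continue; }
    double v = intercept + slope * (k + offset);
    if (v <= 0.0) { out[k] += m; continue; }
    const double sd = std::sqrt(v);
    const double isd = inv_sqrt2 / sd;
    int jlo = (int)std::floor(k - nsd * sd);
    int jhi = (int)std::ceil(k + nsd * sd);
    if (jlo < 0) jlo = 0;
    if (jhi > kout - 1) jhi = kout - 1;
    // Phi(x) = erfc(-x/sqrt(2))/2; tails folded into the edge bins
    double lo = 0.0;
    for (int j = jlo; j <= jhi; ++j) {
      double hi = (j == jhi) ? 1.0
        : 0.5 * std::erfc(-(j + 0.5 - k) * isd);
      out[j] += m * (hi - lo);
      lo = hi;
    }
  }
  return out;
}
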