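#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Delay-and-sum accumulation over elements for a pixel grid.
// Analytic (complex) element signals are passed as re/im matrices
// (elements x samples); returns the complex sum per pixel with dynamic
// aperture and optional Hann apodization, using linear interpolation in
// sample index.

// [[Rcpp::export(name = ".das_accumulate")]]
List das_accumulate(NumericMatrix re, NumericMatrix im,
                    NumericVector xe, NumericVector px, NumericVector pz,
                    double c_mmus, double dt, double start_time,
                    bool pulse_echo, double f_number, bool hann) {
  const int n_el = re.nrow(), nt = re.ncol();
  const int nx = px.size(), nz = pz.size();
  NumericMatrix out_re(nz, nx), out_im(nz, nx);
  for (int e = 0; e < n_el; ++e) {
    double xel = xe[e];
    for (int j = 0; j < nx; ++j) {
      double dx = px[j] - xel;
      double adx = std::fabs(dx);
      for (int i = 0; i < nz; ++i) {
        double z = pz[i];
        double half_ap = (f_number > 0) ? z / (2.0 * f_number) : 1e9;
        if (adx > half_ap) continue;
        double w = hann ? 0.5 + 0.5 * std::cos(M_PI * adx / half_ap) : 1.0;
        double d_rx = std::sqrt(dx * dx + z * z);
        double tau = d_rx / c_mmus + (pulse_echo ? z / c_mmus : 0.0);
        double idx = (tau - start_time) / dt;       // 0-based sample
        if (idx < 0.0 || idx > nt - 1.0) continue;
        int i0 = (int)idx;
        if (i0 >= nt - 1) i0 = nt - 2;
        double fr = idx - i0;
        out_re(i, j) += w * (re(e, i0) * (1 - fr) + re(e, i0 + 1) * fr);
        out_im(i, j) += w * (im(e, i0) * (1 - fr) + im(e, i0 + 1) * fr);
      }
    }
  }
  return List::create(_["re"] = out_re, _["im"] = out_im);
}
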