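#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

// One synthetic background LFP channel: white Gaussian noise shaped by a
// cascade of first-order IIR sections (a pole-zero shelving approximation of
// a band-limited 1/f^alpha spectrum, designed on the R side), scaled to
// rms_core and soft-clipped at `clip` core-SD units, plus an
// amplitude-modulated rhythmic component and a mains line component with
// random phases.
//
// Determinism: the only draws from R's RNG are one seed value and the three
// oscillator phases, so set.seed() gives bit-identical channels; the bulk
// normals come from a private mt19937_64 via explicit Box-Muller (stable
// across platforms and compilers).
// [[Rcpp::export]]
arma::vec background_channel(int n, const arma::mat& sos, double fs,
                             double rms_core, double clip,
                             double osc_amp, double osc_freq,
                             double line_amp, double line_freq,
                             double am_freq) {
  const double TWOPI = 6.283185307179586476925286766559;
  uint64_t seed = (uint64_t) std::floor(R::unif_rand() * 4294967296.0);
  std::mt19937_64 rng(seed);
  arma::vec x(n);
  const double inv = 1.0 / 9007199254740992.0;   // 2^-53
  for (int i = 0; i < n; i += 2) {
    double u1 = (double)(rng() >> 11) * inv;
    double u2 = (double)(rng() >> 11) * inv;
    if (u1 < 1e-300) u1 = 1e-300;
    double r = std::sqrt(-2.0 * std::log(u1));
    x[i] = r * std::cos(TWOPI * u2);
    if (i + 1 < n) x[i + 1] = r * std::sin(TWOPI * u2);
  }
  // first-order cascade; each row of sos is (b0, b1, a1) with a0 = 1
  for (arma::uword s = 0; s < sos.n_rows; ++s) {
    const double b0 = sos(s, 0), b1 = sos(s, 1), a1 = sos(s, 2);
    double x1 = 0.0, y1 = 0.0;
    for (int i = 0; i < n; ++i) {
      const double xi = x[i];
      const double yi = b0 * xi + b1 * x1 - a1 * y1;
      x1 = xi; y1 = yi; x[i] = yi;
    }
  }
  const double g = rms_core / arma::stddev(x);
  const double cmax = clip * rms_core;
  // oscillators advanced by complex rotation (no per-sample trig calls)
  double ph[3];
  for (int o = 0; o < 3; ++o) ph[o] = R::unif_rand() * TWOPI;
  double w[3] = {TWOPI * am_freq / fs, TWOPI * osc_freq / fs,
                 TWOPI * line_freq / fs};
  double c[3], s_[3], cw[3], sw[3];
  for (int o = 0; o < 3; ++o) {
    c[o] = std::cos(ph[o] + w[o]); s_[o] = std::sin(ph[o] + w[o]);
    cw[o] = std::cos(w[o]);        sw[o] = std::sin(w[o]);
  }
  for (int i = 0; i < n; ++i) {
    const double core = cmax * std::tanh(g * x[i] / cmax);
    x[i] = core + osc_amp * (1.0 + 0.3 * s_[0]) * s_[1] + line_amp * s_[2];
    for (int o = 0; o < 3; ++o) {
      const double cn = c[o] * cw[o] - s_[o] * sw[o];
      s_[o] = s_[o] * cw[o] + c[o] * sw[o];
      c[o] = cn;
    }
  }
  return x;
}
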