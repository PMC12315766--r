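// Superlet time-frequency decomposition: geometric mean of complex Morlet
// wavelet amplitudes over an additively growing cycle ladder. The wavelet
// bank is built in the frequency domain once per call and shared across all
// input signals, which makes batched trial x channel transforms cheap.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// FFT of a unit-energy complex Morlet (sd = n_cycles / (2 pi f), support
// +/- 3 sd) centered at sample 0 with wrap-around, ready for circular
// convolution of a zero-padded signal.
static cx_vec wavelet_fft(double f, double n_cycles, double fs, uword L) {
  double sigma = n_cycles / (2.0 * datum::pi * f);
  int half = (int)std::ceil(3.0 * sigma * fs);
  cx_vec psi(L, fill::zeros);
  double energy = 0.0;
  std::vector<std::complex<double>> vals(2 * half + 1);
  for (int i = -half; i <= half; ++i) {
    double t = i / fs;
    double env = std::exp(-t * t / (2.0 * sigma * sigma));
    vals[i + half] = env * std::exp(std::complex<double>(0.0, 2.0 * datum::pi * f * t));
    energy += std::norm(vals[i + half]);
  }
  double nrm = std::sqrt(energy);
  for (int i = -half; i <= half; ++i) {
    uword idx = (i >= 0) ? (uword)i : (uword)((int)L + i);
    psi[idx] = vals[i + half] / nrm;
  }
  return fft(psi);
}

// signals: n_signals x n matrix (one row per signal). Returns a cube
// n_freqs x n x n_signals of superlet amplitudes.
// [[Rcpp::export]]
arma::cube cpp_superlet(const arma::mat& signals, double fs,
                        const arma::vec& freqs, const arma::ivec& orders,
                        double c_cycles, double eps) {
  const uword n = signals.n_cols, nsig = signals.n_rows, nf = freqs.n_elem;
  double max_half = 0.0;
  for (uword i = 0; i < nf; ++i) {
    double sigma = (orders[i] * c_cycles) / (2.0 * datum::pi * freqs[i]);
    max_half = std::max(max_half, std::ceil(3.0 * sigma * fs));
  }
  uword L = 1;
  while (L < n + 2 * (uword)max_half + 1) L <<= 1;

  cx_mat sigF(L, nsig);
  {
    cx_vec x(L);
    for (uword s = 0; s < nsig; ++s) {
      x.zeros();
      for (uword t = 0; t < n; ++t) x[t] = signals(s, t);
      sigF.col(s) = fft(x);
    }
  }

  cube out(nf, n, nsig);
  mat acc(n, nsig);
  for (uword i = 0; i < nf; ++i) {
    acc.zeros();
    int o = orders[i];
    for (int k = 1; k <= o; ++k) {
      cx_vec wF = wavelet_fft(freqs[i], k * c_cycles, fs, L);
      for (uword s = 0; s < nsig; ++s) {
        cx_vec conv = ifft(cx_vec(wF % sigF.col(s)));
        for (uword t = 0; t < n; ++t)
          acc(t, s) += std::log(std::abs(conv[t]) + eps);
      }
    }
    for (uword s = 0; s < nsig; ++s)
      for (uword t = 0; t < n; ++t)
        out(i, t, s) = std::exp(acc(t, s) / (double)o);
  }
  return out;
}
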