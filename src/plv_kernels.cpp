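// Hot kernels of the connectivity stage: batched frequency-domain
// zero-phase band filtering (squared Butterworth magnitude response,
// optionally one-sided for the analytic signal) and the across-trials
// phase-locking accumulation. Columns are independent signals, so one
// padded FFT serves every trial, node and subject of a batch.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// squared (two-pass) Butterworth magnitude response at physical frequency f;
// f_lo <= 0 degenerates to a low-pass
static double butter2_gain(double f, double f_lo, double f_hi, int order) {
  double r;
  if (f_lo <= 0.0) {
    r = std::pow(f / f_hi, 2.0 * order);
  } else if (f == 0.0) {
    return 0.0;
  } else {
    double f0sq = f_lo * f_hi;
    double bw = f_hi - f_lo;
    double base = (f * f - f0sq) / (f * bw);
    r = std::pow(base * base, order);
  }
  double g = 1.0 / (1.0 + r);
  return g * g;
}

// [[Rcpp::export(name = ".cpp_filter_bands")]]
List cpp_filter_bands(const arma::mat& xp, double fs,
                      const arma::mat& band_edges, int order,
                      bool analytic) {
  const arma::uword m = xp.n_rows;
  arma::cx_mat xf = arma::fft(xp);
  arma::vec f(m);
  for (arma::uword k = 0; k < m; ++k) {
    double kk = std::min<double>(k, m - k);
    f[k] = kk * fs / m;
  }
  // one-sided (analytic-signal) spectrum multiplier
  arma::vec hmask(m, arma::fill::ones);
  if (analytic) {
    hmask.zeros();
    hmask[0] = 1.0;
    if (m % 2 == 0) {
      hmask[m / 2] = 1.0;
      for (arma::uword k = 1; k < m / 2; ++k) hmask[k] = 2.0;
    } else {
      for (arma::uword k = 1; k <= (m - 1) / 2; ++k) hmask[k] = 2.0;
    }
  }
  List out(band_edges.n_rows);
  for (arma::uword b = 0; b < band_edges.n_rows; ++b) {
    arma::vec g(m);
    for (arma::uword k = 0; k < m; ++k)
      g[k] = butter2_gain(f[k], band_edges(b, 0), band_edges(b, 1), order) *
        hmask[k];
    arma::cx_mat yf = xf;
    yf.each_col() %= arma::conv_to<arma::cx_vec>::from(g);
    arma::cx_mat y = arma::ifft(yf);
    if (analytic) {
      out[b] = wrap(y);
    } else {
      out[b] = wrap(arma::mat(arma::real(y)));
    }
  }
  return out;
}

// internal: across-trials PLV for one subject block of the windowed
// analytic matrix (columns col0 .. col0 + K*N - 1, trial index fastest)
static arma::mat plv_block(const arma::cx_mat& win, arma::uword col0,
                           arma::uword K, arma::uword N) {
  const arma::uword n_t = win.n_rows;
  const arma::uword nc = K * N;
  arma::mat ca(nc, n_t), sa(nc, n_t);
  for (arma::uword c = 0; c < nc; ++c) {
    const std::complex<double>* src = win.colptr(col0 + c);
    for (arma::uword t = 0; t < n_t; ++t) {
      double re = src[t].real(), im = src[t].imag();
      double mod = std::sqrt(re * re + im * im);
      if (mod < 1e-300) mod = 1e-300;
      ca(c, t) = re / mod;
      sa(c, t) = im / mod;
    }
  }
  arma::mat acc(N, N, arma::fill::zeros);
  for (arma::uword t = 0; t < n_t; ++t) {
    const arma::mat ct(const_cast<double*>(ca.colptr(t)), K, N, false, true);
    const arma::mat st(const_cast<double*>(sa.colptr(t)), K, N, false, true);
    arma::mat re = ct.t() * ct + st.t() * st;
    arma::mat sc = st.t() * ct;
    arma::mat im = sc - sc.t();
    acc += arma::sqrt(re % re + im % im);
  }
  acc /= static_cast<double>(n_t) * static_cast<double>(K);
  acc = (acc + acc.t()) / 2.0;
  acc.clamp(0.0, 1.0);
  acc.diag().zeros();
  return acc;
}

// Fused chunk kernel: padded signal matrix in, per-band per-subject PLV
// matrices out. Avoids shipping any full-size filtered matrix back to R.
// `keep` holds 0-based row indices of the analysis window within the
// padded frame.
// [[Rcpp::export(name = ".cpp_band_plv")]]
List cpp_band_plv(const arma::mat& xp, double fs,
                  const arma::mat& band_edges, int order,
                  const arma::uvec& keep, const arma::uvec& n_trials,
                  int n_nodes) {
  const arma::uword m = xp.n_rows;
  const arma::uword N = static_cast<arma::uword>(n_nodes);
  arma::cx_mat xf = arma::fft(xp);
  arma::vec f(m);
  for (arma::uword k = 0; k < m; ++k) {
    double kk = std::min<double>(k, m - k);
    f[k] = kk * fs / m;
  }
  List out(band_edges.n_rows);
  for (arma::uword b = 0; b < band_edges.n_rows; ++b) {
    arma::cx_vec gc(m);
    for (arma::uword k = 0; k < m; ++k) {
      double g = butter2_gain(f[k], band_edges(b, 0), band_edges(b, 1),
                              order);
      double h;  // analytic-signal mask
      if (k == 0 || (m % 2 == 0 && k == m / 2)) h = 1.0;
      else if (k < (m + 1) / 2) h = 2.0;
      else h = 0.0;
      gc[k] = std::complex<double>(g * h, 0.0);
    }
    arma::cx_mat yf = xf;
    yf.each_col() %= gc;
    arma::cx_mat y = arma::ifft(yf);
    arma::cx_mat win = y.rows(keep);
    List subj(n_trials.n_elem);
    arma::uword col0 = 0;
    for (arma::uword s = 0; s < n_trials.n_elem; ++s) {
      subj[s] = wrap(plv_block(win, col0, n_trials[s], N));
      col0 += n_trials[s] * N;
    }
    out[b] = subj;
  }
  return out;
}

// Across-trials PLV for a batch of subjects sharing one windowed analytic
// matrix `win` (time x sum_s(K_s * n_nodes), subject blocks contiguous,
// trial index fastest within a block). For every time sample t the entry
// (i, j) accumulates | sum_k exp(i (phi_ki - phi_kj)) | via real BLAS:
// Re = C'C + S'S, Im = S'C - (S'C)'.
// [[Rcpp::export(name = ".cpp_plv_subjects")]]
List cpp_plv_subjects(const arma::cx_mat& win, const arma::uvec& n_trials,
                      int n_nodes) {
  const arma::uword N = static_cast<arma::uword>(n_nodes);
  List out(n_trials.n_elem);
  arma::uword col0 = 0;
  for (arma::uword s = 0; s < n_trials.n_elem; ++s) {
    out[s] = wrap(plv_block(win, col0, n_trials[s], N));
    col0 += n_trials[s] * N;
  }
  return out;
}
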