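// Core numerical kernels: zero-phase FIR filtering, Hilbert transform,
// Welch PSD, Tort modulation index, burst run-length statistics,
// approximate/sample entropy. Kept in C++ because the screening pipeline
// evaluates them on ~10^5 two-second windows per cohort.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Zero-phase filtering with a symmetric (linear-phase, odd-length) FIR.
// The input is reflect-padded by half the filter length on both sides so
// that edge transients use mirrored data; the central part of the full
// convolution is returned. For a symmetric kernel this is zero-phase.
// [[Rcpp::export]]
arma::vec cpp_fir_zerophase(const arma::vec& x, const arma::vec& h) {
  const arma::uword n = x.n_elem, L = h.n_elem;
  if (L % 2 == 0) stop("FIR kernel must have odd length");
  const arma::uword p = (L - 1) / 2;
  if (p >= n) stop("FIR kernel longer than signal");
  arma::vec xp(n + 2 * p);
  // reflect without repeating the edge sample: x[p], ..., x[1] | x | x[n-2], ...
  for (arma::uword i = 0; i < p; ++i) xp(i) = x(p - i);
  xp.subvec(p, p + n - 1) = x;
  for (arma::uword i = 0; i < p; ++i) xp(p + n + i) = x(n - 2 - i);
  arma::vec y = arma::conv(xp, h, "full");
  // full conv has length n + 2p + L - 1; central n samples start at 2p
  return y.subvec(2 * p, 2 * p + n - 1);
}

// Analytic signal via FFT; returns cbind(envelope, phase).
// [[Rcpp::export]]
arma::mat cpp_hilbert(const arma::vec& x) {
  const arma::uword n = x.n_elem;
  arma::cx_vec X = arma::fft(x);
  arma::vec w(n, arma::fill::zeros);
  w(0) = 1.0;
  if (n % 2 == 0) {
    w(n / 2) = 1.0;
    for (arma::uword k = 1; k < n / 2; ++k) w(k) = 2.0;
  } else {
    for (arma::uword k = 1; k <= (n - 1) / 2; ++k) w(k) = 2.0;
  }
  X %= arma::cx_vec(w, arma::vec(n, arma::fill::zeros));
  arma::cx_vec a = arma::ifft(X);
  arma::mat out(n, 2);
  out.col(0) = arma::abs(a);
  for (arma::uword i = 0; i < n; ++i) out(i, 1) = std::arg(a(i));
  return out;
}

// Welch one-sided PSD with a Hann window. Returns (nperseg/2 + 1) values on
// the grid f_k = k * fs / nperseg. Density scaling: sum(P) * df ~ var(x).
// [[Rcpp::export]]
arma::vec cpp_welch(const arma::vec& x, double fs, int nperseg, int step) {
  const int n = x.n_elem;
  if (nperseg > n) stop("nperseg longer than signal");
  arma::vec w(nperseg);
  for (int i = 0; i < nperseg; ++i)
    w(i) = 0.5 - 0.5 * std::cos(2.0 * M_PI * i / (nperseg - 1));
  const double wss = arma::dot(w, w);
  const int nf = nperseg / 2 + 1;
  arma::vec psd(nf, arma::fill::zeros);
  int nseg = 0;
  for (int start = 0; start + nperseg <= n; start += step) {
    arma::vec seg = x.subvec(start, start + nperseg - 1);
    seg -= arma::mean(seg);
    seg %= w;
    arma::cx_vec X = arma::fft(seg);
    for (int k = 0; k < nf; ++k) {
      double m2 = std::norm(X(k));
      double sc = (k == 0 || (nperseg % 2 == 0 && k == nf - 1)) ? 1.0 : 2.0;
      psd(k) += sc * m2 / (fs * wss);
    }
    ++nseg;
  }
  if (nseg == 0) stop("no complete Welch segment");
  return psd / nseg;
}

// Tort modulation index: KL divergence of the phase-binned mean-amplitude
// distribution from uniform, normalized by log(n_bins).
// [[Rcpp::export]]
double cpp_tort_mi(const arma::vec& phase, const arma::vec& amp, int nbins) {
  const arma::uword n = phase.n_elem;
  arma::vec s(nbins, arma::fill::zeros);
  arma::vec cnt(nbins, arma::fill::zeros);
  for (arma::uword i = 0; i < n; ++i) {
    double ph = phase(i);
    int b = (int)std::floor((ph + M_PI) / (2.0 * M_PI) * nbins);
    if (b < 0) b = 0;
    if (b >= nbins) b = nbins - 1;
    s(b) += amp(i);
    cnt(b) += 1.0;
  }
  arma::vec m(nbins);
  for (int b = 0; b < nbins; ++b) m(b) = cnt(b) > 0 ? s(b) / cnt(b) : 0.0;
  double tot = arma::accu(m);
  if (tot <= 0.0) return 0.0;
  double kl = 0.0;
  for (int b = 0; b < nbins; ++b) {
    double p = m(b) / tot;
    if (p > 0.0) kl += p * std::log(p * nbins);
  }
  double mi = kl / std::log((double)nbins);
  if (mi < 0.0) mi = 0.0;
  if (mi > 1.0) mi = 1.0;
  return mi;
}

// Supra-threshold run statistics on an amplitude envelope.
// Returns (mean duration s, mean per-burst peak, mean per-burst energy, count).
// [[Rcpp::export]]
arma::vec cpp_bursts(const arma::vec& env, double thr, int min_samples, double fs) {
  const arma::uword n = env.n_elem;
  double sum_dur = 0.0, sum_peak = 0.0, sum_energy = 0.0;
  int count = 0;
  arma::uword i = 0;
  while (i < n) {
    if (env(i) > thr) {
      arma::uword j = i;
      double peak = 0.0, energy = 0.0;
      while (j < n && env(j) > thr) {
        if (env(j) > peak) peak = env(j);
        energy += env(j) * env(j);
        ++j;
      }
      if ((int)(j - i) >= min_samples) {
        sum_dur += (double)(j - i) / fs;
        sum_peak += peak;
        sum_energy += energy / fs;
        ++count;
      }
      i = j;
    } else {
      ++i;
    }
  }
  arma::vec out(4, arma::fill::zeros);
  if (count > 0) {
    out(0) = sum_dur / count;
    out(1) = sum_peak / count;
    out(2) = sum_energy / count;
    out(3) = count;
  }
  return out;
}

// Approximate and sample entropy (embedding m, Chebyshev tolerance r).
// ApEn uses N-m+1 templates with self-matches; SampEn uses N-m templates
// without self-matches. Returns c(apen, sampen).
// [[Rcpp::export]]
arma::vec cpp_apen_sampen(const arma::vec& x, int m, double r) {
  const int n = x.n_elem;
  arma::vec out(2, arma::fill::zeros);
  if (n < m + 2 || r <= 0.0) return out;

  // SampEn: pairs over templates 0..n-m-1
  {
    const int nt = n - m;
    double A = 0.0, B = 0.0;
    const double* xs = x.memptr();
    for (int i = 0; i < nt - 1; ++i) {
      for (int j = i + 1; j < nt; ++j) {
        bool match = true;
        for (int k = 0; k < m; ++k) {
          if (std::fabs(xs[i + k] - xs[j + k]) > r) { match = false; break; }
        }
        if (match) {
          B += 1.0;
          if (std::fabs(xs[i + m] - xs[j + m]) <= r) A += 1.0;
        }
      }
    }
    out(1) = (A > 0.0 && B > 0.0) ? -std::log(A / B) : 0.0;
  }

  // ApEn: phi(m) - phi(m+1), counts include self-matches
  {
    const double* xs = x.memptr();
    double phi_m = 0.0, phi_m1 = 0.0;
    const int nt_m = n - m + 1;
    const int nt_m1 = n - m;
    std::vector<double> cm(nt_m, 1.0);   // self-match
    std::vector<double> cm1(nt_m1, 1.0);
    for (int i = 0; i < nt_m - 1; ++i) {
      for (int j = i + 1; j < nt_m; ++j) {
        bool match = true;
        for (int k = 0; k < m; ++k) {
          if (std::fabs(xs[i + k] - xs[j + k]) > r) { match = false; break; }
        }
        if (match) {
          cm[i] += 1.0; cm[j] += 1.0;
          if (i < nt_m1 && j < nt_m1 && std::fabs(xs[i + m] - xs[j + m]) <= r) {
            cm1[i] += 1.0; cm1[j] += 1.0;
          }
        }
      }
    }
    for (int i = 0; i < nt_m; ++i) phi_m += std::log(cm[i] / nt_m);
    phi_m /= nt_m;
    for (int i = 0; i < nt_m1; ++i) phi_m1 += std::log(cm1[i] / nt_m1);
    phi_m1 /= nt_m1;
    double apen = phi_m - phi_m1;
    out(0) = apen > 0.0 ? apen : 0.0;
  }
  return out;
}
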