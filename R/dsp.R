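#' Signal-processing primitives
#'
#' Minimal DSP layer used by the biomarker extractors: windowed-sinc FIR
#' band-pass design, zero-phase filtering, Hilbert envelope/phase, and Welch
#' power spectral density. All filters are linear-phase (symmetric, odd
#' length) and applied with reflection padding, so filtering commutes with
#' time reversal -- a property the waveform-shape biomarkers rely on.
#'
#' @name dsp
NULL

.fir_cache <- new.env(parent = emptyenv())

#' Design a windowed-sinc band-pass FIR filter
#'
#' Hamming-windowed sinc band-pass. The default length rule is three cycles
#' of the band's low edge, capped at one third of `n_window` so the kernel
#' always fits the 2 s analysis windows, and forced odd so the filter is
#' exactly linear-phase.
#'
#' @param low,high band edges in Hz.
#' @param fs sampling rate in Hz.
#' @param n_window length (samples) of the signals the filter will be applied
#'   to; caps the kernel length.
#' @return numeric vector of filter taps (odd length, unit DC-band gain).
#' @export
fir_bandpass <- function(low, high, fs, n_window = 2000L) {
  stopifnot(low > 0, high > low, high < fs / 2)
  key <- paste(low, high, fs, n_window, sep = "_")
  hit <- .fir_cache[[key]]
  if (!is.null(hit)) return(hit)
  taps <- min(round(3 * fs / low), floor(n_window / 3))
  taps <- max(taps, 31L)
  if (taps %% 2 == 0) taps <- taps + 1L
  m <- (taps - 1) / 2
  k <- -m:m
  sinc <- function(fc) {
    out <- 2 * fc / fs * rep(1, length(k))
    nz <- k != 0
    out[nz] <- sin(2 * pi * fc / fs * k[nz]) / (pi * k[nz])
    out
  }
  h <- sinc(high) - sinc(low)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(taps - 1)) / (taps - 1))
  h <- h * w
  # normalize gain at band center
  fc <- (low + high) / 2
  g <- sum(h * cos(2 * pi * fc / fs * k))
  h <- h / g
  .fir_cache[[key]] <- h
  h
}

#' Zero-phase band-pass filtering
#'
#' Applies a symmetric FIR band-pass with reflection padding; no phase
#' distortion is introduced, so Hilbert phases and cycle landmarks computed
#' on the output align with the input.
#'
#' @param x numeric signal.
#' @inheritParams fir_bandpass
#' @return filtered signal, same length as `x`.
#' @export
bandpass <- function(x, low, high, fs) {
  h <- fir_bandpass(low, high, fs, n_window = length(x))
  as.numeric(cpp_fir_zerophase(as.numeric(x), h))
}

#' Hilbert envelope and instantaneous phase
#'
#' Analytic signal by FFT half-spectrum doubling.
#'
#' @param x numeric signal (typically already band-passed).
#' @return list with `envelope` and `phase` (radians in (-pi, pi]).
#' @export
hilbert_transform <- function(x) {
  a <- .analytic(as.numeric(x))
  list(envelope = Mod(a), phase = Arg(a))
}

.analytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Low-pass FIR and integer decimation
#'
#' Hamming-windowed sinc low-pass (zero-phase, reflection-padded) followed
#' by taking every `factor`-th sample. Used to bring oversampled windows to
#' a rate matched to their spectral content before entropy estimation.
#'
#' @param x numeric signal.
#' @param factor integer decimation factor (1 = no-op).
#' @param fs sampling rate of `x` in Hz.
#' @return decimated signal (length `ceiling(length(x) / factor)`).
#' @export
decimate_signal <- function(x, factor, fs) {
  factor <- as.integer(factor)
  if (factor <= 1L) return(as.numeric(x))
  fc <- 0.45 * fs / factor
  key <- paste("lp", fc, fs, sep = "_")
  h <- .fir_cache[[key]]
  if (is.null(h)) {
    taps <- 101L
    m <- (taps - 1) / 2
    k <- -m:m
    h <- 2 * fc / fs * rep(1, taps)
    nz <- k != 0
    h[nz] <- sin(2 * pi * fc / fs * k[nz]) / (pi * k[nz])
    h <- h * (0.54 - 0.46 * cos(2 * pi * (0:(taps - 1)) / (taps - 1)))
    h <- h / sum(h)
    .fir_cache[[key]] <- h
  }
  y <- as.numeric(cpp_fir_zerophase(as.numeric(x), h))
  y[seq(1, length(y), by = factor)]
}

#' Welch power spectral density
#'
#' One-sided Welch PSD with Hann-windowed, mean-detrended segments.
#' Defaults match the biomarker contract: 1 s segments with 50% overlap.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param nperseg segment length in samples (default `fs`, i.e. 1 s).
#' @param overlap fractional overlap between segments (default 0.5).
#' @return list with `freq` (Hz) and `psd` (signal-units^2/Hz).
#' @export
welch_psd <- function(x, fs, nperseg = fs, overlap = 0.5) {
  nperseg <- as.integer(nperseg)
  step <- max(1L, as.integer(round(nperseg * (1 - overlap))))
  psd <- cpp_welch(as.numeric(x), fs, nperseg, step)
  list(freq = seq(0, fs / 2, length.out = nperseg %/% 2 + 1), psd = as.numeric(psd))
}

#' Integrate a PSD over a frequency band
#'
#' Rectangle-rule integral of the PSD between `low` and `high` Hz
#' (inclusive bin centers).
#'
#' @param spec list from [welch_psd()].
#' @param low,high band edges in Hz.
#' @return band power in signal-units^2.
#' @export
band_power_integral <- function(spec, low, high) {
  df <- spec$freq[2] - spec$freq[1]
  sel <- spec$freq >= low & spec$freq <= high
  sum(spec$psd[sel]) * df
}
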