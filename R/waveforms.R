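#' Synthesize a stimulus waveform
#'
#' Renders a [stimulus_spec()] to samples at rate `fs`. Conventions per
#' family:
#' * `sham` -- all zeros (no stimulation);
#' * `DC` -- constant at `amplitude`;
#' * `sinusoid` -- `sin(2 pi f t)`;
#' * `AM` -- carrier sinusoid with envelope `(1 + depth cos(2 pi f_mod t))`,
#'   peak-normalized;
#' * `chirp` -- linear frequency sweep `f0 -> f1` over the duration (phase
#'   integral of the instantaneous frequency);
#' * `chirpAM` -- carrier sinusoid amplitude-modulated by a linear-sweep
#'   envelope frequency;
#' * `FM` -- carrier with sinusoidal frequency deviation, synthesized by
#'   phase integration of `f_c + dev sin(2 pi f_mod t)`;
#' * `PAC` -- high-frequency carrier whose amplitude envelope is
#'   `(1 + depth cos(2 pi f_phase t)) / 2` (canonical phase-amplitude
#'   coupled construction), peak-normalized;
#' * `multisine` -- equal-amplitude sum of sinusoids at `freq_set`,
#'   peak-normalized;
#' * `binary` -- zero-mean pseudo-random +/-1 bit stream at `bit_rate_hz`
#'   (balanced bit sequence derived deterministically from `stim_id`).
#'
#' All non-DC waveforms are zero-mean over an integer number of periods and
#' peak-bounded by `spec$amplitude`. Deterministic: the same spec and `fs`
#' always give bit-identical samples.
#'
#' @param spec a [stimulus_spec()].
#' @param duration_s duration in seconds.
#' @param fs sampling rate in Hz; must exceed twice the highest frequency in
#'   the spec.
#' @return numeric vector of `round(duration_s * fs)` samples.
#' @export
generate_waveform <- function(spec, duration_s, fs) {
  stopifnot(inherits(spec, "stimulus_spec"), duration_s > 0, fs > 0)
  n <- round(duration_s * fs)
  t <- (0:(n - 1)) / fs
  p <- spec$params
  fmax <- suppressWarnings(max(0, unlist(p[names(p) %in%
    c("carrier_hz", "mod_hz", "f0_hz", "f1_hz", "freq_set", "bit_rate_hz",
      "pac_phase_hz", "pac_amp_hz", "dev_hz")])))
  if (fmax >= fs / 2) {
    stop("sampling rate ", fs, " Hz violates Nyquist for spec frequencies up to ",
         fmax, " Hz")
  }
  a <- spec$amplitude
  x <- switch(spec$family,
    sham = rep(0, n),
    DC = rep(a, n),
    sinusoid = a * sin(2 * pi * p$carrier_hz * t),
    AM = {
      env <- 1 + p$depth * cos(2 * pi * p$mod_hz * t)
      w <- sin(2 * pi * p$carrier_hz * t) * env
      a * w / (1 + p$depth)
    },
    chirp = {
      f_inst_phase <- p$f0_hz * t + (p$f1_hz - p$f0_hz) * t^2 / (2 * duration_s)
      a * sin(2 * pi * f_inst_phase)
    },
    chirpAM = {
      env_phase <- p$f0_hz * t + (p$f1_hz - p$f0_hz) * t^2 / (2 * duration_s)
      env <- 1 + p$depth * cos(2 * pi * env_phase)
      a * sin(2 * pi * p$carrier_hz * t) * env / (1 + p$depth)
    },
    FM = {
      # phase integration of instantaneous frequency f_c + dev*sin(2 pi f_m t)
      phase <- p$carrier_hz * t +
        p$dev_hz / (2 * pi * p$mod_hz) * (1 - cos(2 * pi * p$mod_hz * t))
      a * sin(2 * pi * phase)
    },
    PAC = {
      env <- (1 + p$depth * cos(2 * pi * p$pac_phase_hz * t)) / 2
      w <- sin(2 * pi * p$pac_amp_hz * t) * env
      a * w / max(abs(w))
    },
    multisine = {
      w <- rowSums(vapply(p$freq_set,
                          function(f) sin(2 * pi * f * t), numeric(n)))
      a * w / max(abs(w))
    },
    binary = {
      bit_len <- fs / p$bit_rate_hz
      n_bits <- ceiling(n / bit_len)
      bits <- .balanced_bits(n_bits, spec$stim_id)
      idx <- pmin(floor((0:(n - 1)) / bit_len) + 1, n_bits)
      a * bits[idx]
    },
    stop("unknown stimulus family: ", spec$family)
  )
  x
}

# Deterministic balanced +/-1 sequence: equal numbers of +1 and -1 (up to
# parity), shuffled by a small multiplicative-congruential generator keyed on
# the stimulus id. Does not touch R's global RNG.
.balanced_bits <- function(n_bits, key) {
  half <- n_bits %/% 2
  bits <- c(rep(1, n_bits - half), rep(-1, half))
  state <- (as.double(key) * 2654435761) %% 2147483647
  if (state == 0) state <- 1
  for (i in n_bits:2) {
    state <- (state * 48271) %% 2147483647
    j <- (state %% i) + 1
    tmp <- bits[i]; bits[i] <- bits[j]; bits[j] <- tmp
  }
  bits
}
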