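#' Biomarker configuration
#'
#' Band edges and estimator parameters for the 16 resting-state biomarkers.
#' The published analysis names its bands ("beta", "gamma") but not their
#' edges, the PAC estimator, the burst threshold rule, or the entropy
#' parameters; the defaults here follow the most common conventions in the
#' PD EEG literature and are all overridable.
#'
#' @param beta_band beta band edges in Hz (default 13-30).
#' @param gamma_band gamma (amplitude) band for PAC, Hz (default 50-100).
#' @param broad_band broadband range used for total power and waveform
#'   shape, Hz (default 1-45).
#' @param fit_range frequency range of the aperiodic (1/f) fit, Hz
#'   (default 2-40).
#' @param pac_bins number of phase bins of the Tort modulation index.
#' @param burst_min_s minimum burst duration in seconds (default 0.1).
#' @param burst_quantile envelope quantile defining the subject-level burst
#'   threshold (default 0.75, computed on pooled pre-stimulation windows).
#' @param entropy_m embedding dimension for ApEn/SampEn.
#' @param entropy_r tolerance as a fraction of the window SD.
#' @param entropy_decim integer decimation factor applied (with an
#'   anti-alias low-pass) before ApEn/SampEn. At 1000 Hz consecutive
#'   samples are almost perfectly correlated and m = 2 template matching
#'   mostly measures oversampling; the default 4 brings the window to
#'   250 Hz, comfortably above twice the highest analysis band edge.
#' @return list of class `biomarker_options`.
#' @export
biomarker_options <- function(beta_band = c(13, 30), gamma_band = c(50, 100),
                              broad_band = c(1, 45), fit_range = c(2, 40),
                              pac_bins = 18L, burst_min_s = 0.1,
                              burst_quantile = 0.75,
                              entropy_m = 2L, entropy_r = 0.2,
                              entropy_decim = 4L) {
  structure(list(beta_band = beta_band, gamma_band = gamma_band,
                 broad_band = broad_band, fit_range = fit_range,
                 pac_bins = as.integer(pac_bins), burst_min_s = burst_min_s,
                 burst_quantile = burst_quantile,
                 entropy_m = as.integer(entropy_m), entropy_r = entropy_r,
                 entropy_decim = as.integer(entropy_decim)),
            class = "biomarker_options")
}

#' Names of the 16 biomarkers, in canonical table order
#'
#' Order: BG-PAC; peak-trough asymmetry; rise-decay ratio; aperiodic
#' exponent and offset; burst duration, amplitude, energy; beta power and
#' relative beta power; Petrosian fractal dimension; Hjorth mobility and
#' complexity; spectral, approximate and sample entropy.
#'
#' @return character vector of length 16.
#' @export
biomarker_names <- function() {
  c("BG_PAC", "PTAsym", "RDRatio", "Exponent", "Offset",
    "ABD", "ABA", "ABE", "BetaPower", "RelBetaPower",
    "PFD", "HjMob", "HjComp", "SpecEn", "AppEn", "SampEn")
}

#' The 13 central electrodes used for biomarker averaging
#'
#' @return character vector of electrode labels.
#' @export
central_electrodes <- function() {
  c("FC5", "FC1", "FCz", "FC2", "FC6", "C3", "Cz", "C4",
    "CP5", "CP1", "CPz", "CP2", "CP6")
}

#' Segment a 9 s trial into standardized 2 s analysis windows
#'
#' Pre-stimulation is `[0, 2)` s, stimulation `[2, 4)` s; the 5 s
#' post-stimulation interval is split into four overlapping 2 s windows with
#' 1 s overlap, starting at 4, 5, 6 and 7 s. Indices are 0-based sample
#' offsets; windows are half-open.
#'
#' @param trial a `trial_recording` (see [simulate_trial()]) or any list with
#'   `data` (channels x samples matrix) and `fs`.
#' @return list with elements `pre`, `stim` (each one channels x 2s matrix)
#'   and `post` (list of four such matrices), plus `starts` (0-based sample
#'   offsets of the post windows).
#' @export
segment_trial <- function(trial) {
  fs <- trial$fs
  n_expect <- 9 * fs
  if (ncol(trial$data) != n_expect) {
    stop("trial must have exactly ", n_expect, " samples (9 s at ", fs,
         " Hz), got ", ncol(trial$data))
  }
  w <- 2 * fs
  cut <- function(start0) trial$data[, (start0 + 1):(start0 + w), drop = FALSE]
  post_starts <- c(4, 5, 6, 7) * fs
  list(pre = cut(0), stim = cut(2 * fs),
       post = lapply(post_starts, cut), starts = post_starts)
}

#' Beta and relative beta power
#'
#' Welch PSD (1 s Hann segments, 50% overlap); beta power is the integrated
#' PSD over the beta band, relative beta power its fraction of the
#' integrated 1-45 Hz power. An all-zero window yields `c(0, 0)`.
#'
#' @param window numeric vector, at least 2 s of signal.
#' @param fs sampling rate in Hz.
#' @param opts a [biomarker_options()] list.
#' @return named vector `c(BetaPower =, RelBetaPower =)`.
#' @export
band_powers <- function(window, fs, opts = biomarker_options()) {
  spec <- welch_psd(window, fs)
  bp <- band_power_integral(spec, opts$beta_band[1], opts$beta_band[2])
  tp <- band_power_integral(spec, opts$broad_band[1], opts$broad_band[2])
  c(BetaPower = bp, RelBetaPower = if (tp > 0) bp / tp else 0)
}

#' Tort modulation index (beta-gamma phase-amplitude coupling)
#'
#' Band-passes the phase and amplitude bands (zero-phase FIR), extracts the
#' Hilbert phase of the low band and envelope of the high band, bins the
#' envelope by phase, and returns the Kullback-Leibler divergence of the
#' normalized bin distribution from uniform, scaled by `log(n_bins)` so the
#' index lies in \[0, 1\].
#'
#' @inheritParams band_powers
#' @param phase_band,amp_band band edges in Hz.
#' @param n_bins number of phase bins.
#' @return modulation index in \[0, 1\].
#' @export
tort_mi <- function(window, fs, phase_band = c(13, 30), amp_band = c(50, 100),
                    n_bins = 18L) {
  ph <- hilbert_transform(bandpass(window, phase_band[1], phase_band[2], fs))$phase
  am <- hilbert_transform(bandpass(window, amp_band[1], amp_band[2], fs))$envelope
  cpp_tort_mi(ph, am, as.integer(n_bins))
}

#' Modulation index from precomputed phase/amplitude series
#'
#' Kernel behind [tort_mi()], exposed for direct testing: uniform
#' phase-binned amplitude gives 0, amplitude concentrated in one bin gives 1.
#'
#' @param phase phases in radians (-pi, pi].
#' @param amp non-negative amplitudes, same length.
#' @param n_bins number of phase bins.
#' @return modulation index in \[0, 1\].
#' @export
modulation_index <- function(phase, amp, n_bins = 18L) {
  cpp_tort_mi(as.numeric(phase), as.numeric(amp), as.integer(n_bins))
}

# Locate beta-cycle landmarks on the broadband signal. Returns a data.frame
# of alternating extrema (idx, type +1 peak / -1 trough) ordered in time.
.cycle_extrema <- function(broad, beta) {
  pos <- beta > 0
  d <- diff(as.integer(pos))
  cross <- which(d != 0)           # crossing between cross and cross+1
  if (length(cross) < 4) return(NULL)
  types <- d[cross]                # +1 rising, -1 falling
  idx <- integer(0); typ <- integer(0)
  for (k in seq_len(length(cross) - 1)) {
    seg <- (cross[k] + 1):cross[k + 1]
    if (types[k] > 0) {            # positive half-cycle -> peak
      i <- seg[which.max(broad[seg])]
      idx <- c(idx, i); typ <- c(typ, 1L)
    } else {                       # negative half-cycle -> trough
      i <- seg[which.min(broad[seg])]
      idx <- c(idx, i); typ <- c(typ, -1L)
    }
  }
  data.frame(idx = idx, type = typ)
}

#' Beta waveform-shape biomarkers
#'
#' Uses the beta-filtered signal only to locate alternating zero crossings;
#' peaks (maxima) and troughs (minima) of each half-cycle are taken on the
#' broadband (1-45 Hz) signal. Sharpness of an extremum is the mean absolute
#' second difference over a +/-5 sample neighborhood. Peak-trough asymmetry
#' is the normalized sharpness contrast; the rise-decay ratio is the log of
#' mean trough-to-peak over mean peak-to-trough duration. Time-reversing the
#' window negates `RDRatio` and preserves `PTAsym`. Fewer than 3 detected
#' cycles yields `c(0, 0)`.
#'
#' @inheritParams band_powers
#' @return named vector `c(PTAsym =, RDRatio =)`.
#' @export
waveform_shape <- function(window, fs, opts = biomarker_options()) {
  n <- length(window)
  beta <- bandpass(window, opts$beta_band[1], opts$beta_band[2], fs)
  broad <- bandpass(window, opts$broad_band[1], opts$broad_band[2], fs)
  ex <- .cycle_extrema(broad, beta)
  zero <- c(PTAsym = 0, RDRatio = 0)
  if (is.null(ex)) return(zero)
  n_peak <- sum(ex$type == 1); n_trough <- sum(ex$type == -1)
  if (n_peak < 3 || n_trough < 3) return(zero)

  sharp <- function(i) {
    s <- 1:5
    mean(abs(broad[i - s] - 2 * broad[i] + broad[i + s]))
  }
  ok <- ex$idx > 5 & ex$idx <= n - 5
  ps <- vapply(ex$idx[ok & ex$type == 1], sharp, numeric(1))
  ts <- vapply(ex$idx[ok & ex$type == -1], sharp, numeric(1))
  pt <- 0
  if (length(ps) > 0 && length(ts) > 0) {
    tot <- mean(ps) + mean(ts)
    if (tot > 0) pt <- (mean(ps) - mean(ts)) / tot
  }

  adj_type <- ex$type[-1] - ex$type[-nrow(ex)]   # +2: trough->peak (rise)
  dur <- diff(ex$idx) / fs
  rises <- dur[adj_type == 2]
  decays <- dur[adj_type == -2]
  rd <- 0
  if (length(rises) > 0 && length(decays) > 0 &&
      mean(rises) > 0 && mean(decays) > 0) {
    rd <- log(mean(rises) / mean(decays))
  }
  c(PTAsym = pt, RDRatio = rd)
}

#' Aperiodic (1/f) fit of a power spectrum
#'
#' Iterative peak-pruned least squares in log10-frequency/log10-power space:
#' an OLS line is fit, points lying more than one residual SD *above* the
#' line (oscillatory peaks) are removed, and the line is refit; two
#' prune-refit iterations. A deterministic, dependency-light approximation
#' to full spectral parameterization. `aperiodic_fit()` computes the Welch
#' PSD first; `aperiodic_fit_psd()` fits a provided spectrum.
#'
#' @inheritParams band_powers
#' @return named vector `c(Exponent =, Offset =)`: exponent is the negated
#'   log-log slope, offset the intercept at log10(f) = 0.
#' @export
aperiodic_fit <- function(window, fs, opts = biomarker_options()) {
  spec <- welch_psd(window, fs)
  aperiodic_fit_psd(spec$freq, spec$psd, fit_range = opts$fit_range)
}

#' @rdname aperiodic_fit
#' @param freq,psd spectrum to fit (Hz, signal-units^2/Hz).
#' @param fit_range frequency range of the fit in Hz.
#' @export
aperiodic_fit_psd <- function(freq, psd, fit_range = c(2, 40)) {
  sel <- freq >= fit_range[1] & freq <= fit_range[2] & psd > 0 & freq > 0
  lf <- log10(freq[sel]); lp <- log10(psd[sel])
  if (length(lf) < 3) return(c(Exponent = 0, Offset = 0))
  fit_line <- function(xx, yy) {
    mx <- mean(xx); my <- mean(yy)
    b <- sum((xx - mx) * (yy - my)) / sum((xx - mx)^2)
    c(a = my - b * mx, b = b)
  }
  ab <- fit_line(lf, lp)
  for (it in 1:2) {
    res <- lp - (ab["a"] + ab["b"] * lf)
    keep <- res <= stats::sd(res) + 1e-12
    if (sum(keep) < 3) break
    lf <- lf[keep]; lp <- lp[keep]
    ab <- fit_line(lf, lp)
  }
  c(Exponent = unname(-ab["b"]), Offset = unname(ab["a"]))
}

#' Beta burst statistics
#'
#' Beta-filters the window, takes the Hilbert envelope, and defines a burst
#' as a contiguous supra-threshold run of at least `burst_min_s` seconds.
#' The threshold is subject-level: the 75th percentile of the envelope
#' pooled over that subject's pre-stimulation windows (see
#' [burst_threshold()]), computed once per subject and channel.
#'
#' @inheritParams band_powers
#' @param threshold envelope threshold (same units as the signal); must be
#'   positive.
#' @return named vector `c(ABD =, ABA =, ABE =)`: mean burst duration (s),
#'   mean per-burst peak envelope, and mean per-burst `sum(envelope^2)/fs`.
#'   No bursts gives `c(0, 0, 0)`.
#' @export
beta_bursts <- function(window, fs, threshold, opts = biomarker_options()) {
  if (threshold <= 0) stop("burst threshold must be positive")
  env <- hilbert_transform(
    bandpass(window, opts$beta_band[1], opts$beta_band[2], fs))$envelope
  burst_stats_from_envelope(env, fs, threshold, opts$burst_min_s)
}

#' @rdname beta_bursts
#' @param env precomputed amplitude envelope.
#' @param burst_min_s minimum burst duration in seconds.
#' @export
burst_stats_from_envelope <- function(env, fs, threshold, burst_min_s = 0.1) {
  if (threshold <= 0) stop("burst threshold must be positive")
  st <- cpp_bursts(as.numeric(env), threshold, as.integer(round(burst_min_s * fs)), fs)
  c(ABD = st[1], ABA = st[2], ABE = st[3])
}

#' Subject-level beta burst threshold
#'
#' Quantile (default 75th percentile) of the beta envelope pooled across a
#' subject's pre-stimulation windows for one channel.
#'
#' @param pre_windows list of numeric pre-stimulation windows (one channel).
#' @inheritParams band_powers
#' @return scalar threshold.
#' @export
burst_threshold <- function(pre_windows, fs, opts = biomarker_options()) {
  env <- unlist(lapply(pre_windows, function(w) {
    hilbert_transform(bandpass(w, opts$beta_band[1], opts$beta_band[2], fs))$envelope
  }))
  stats::quantile(env, opts$burst_quantile, names = FALSE)
}

#' Signal-complexity biomarkers
#'
#' Petrosian fractal dimension, Hjorth mobility and complexity, spectral
#' entropy (Shannon entropy of the normalized Welch PSD scaled by the log
#' bin count), and approximate/sample entropy (embedding `m = 2`, tolerance
#' 0.2 times the window SD, Chebyshev distance). A constant window returns the
#' defined degenerate values (PFD 1, all others 0) rather than NaN.
#'
#' @inheritParams band_powers
#' @return named vector `c(PFD =, HjMob =, HjComp =, SpecEn =, AppEn =, SampEn =)`.
#' @export
complexity_suite <- function(window, fs, opts = biomarker_options()) {
  n <- length(window)
  v <- stats::var(window)
  if (v == 0) {
    return(c(PFD = 1, HjMob = 0, HjComp = 0, SpecEn = 0, AppEn = 0, SampEn = 0))
  }
  d1 <- diff(window)
  n_delta <- sum(diff(sign(d1[d1 != 0])) != 0)
  pfd <- log10(n) / (log10(n) + log10(n / (n + 0.4 * n_delta)))

  vd1 <- stats::var(d1)
  mob <- sqrt(vd1 / v)
  d2 <- diff(d1)
  mob_d <- if (vd1 > 0) sqrt(stats::var(d2) / vd1) else 0
  comp <- if (mob > 0) mob_d / mob else 0

  spec <- welch_psd(window, fs)
  p <- spec$psd
  tot <- sum(p)
  se <- 0
  if (tot > 0) {
    pr <- p[p > 0] / tot
    se <- -sum(pr * log(pr)) / log(length(p))
  }

  xd <- decimate_signal(window, opts$entropy_decim, fs)
  ent <- cpp_apen_sampen(xd, opts$entropy_m, opts$entropy_r * stats::sd(xd))
  c(PFD = pfd, HjMob = mob, HjComp = comp, SpecEn = se,
    AppEn = ent[1], SampEn = ent[2])
}

#' All 16 biomarkers for one window
#'
#' Computes the full biomarker vector in canonical order, sharing the Welch
#' PSD and band-pass filtering across estimators (hot path of the cohort
#' pipeline; the individual exported estimators are the reference
#' implementations and agree with this function exactly).
#'
#' @inheritParams band_powers
#' @param burst_thr subject-level burst threshold for this channel.
#' @return named numeric vector of length 16 (see [biomarker_names()]).
#' @export
compute_biomarkers <- function(window, fs, burst_thr, opts = biomarker_options()) {
  window <- as.numeric(window)
  n <- length(window)
  v <- stats::var(window)
  spec <- welch_psd(window, fs)

  # band powers
  bp <- band_power_integral(spec, opts$beta_band[1], opts$beta_band[2])
  tp <- band_power_integral(spec, opts$broad_band[1], opts$broad_band[2])
  relbp <- if (tp > 0) bp / tp else 0

  # aperiodic
  ap <- aperiodic_fit_psd(spec$freq, spec$psd, opts$fit_range)

  # beta-band derived: PAC phase, bursts, shape
  beta <- bandpass(window, opts$beta_band[1], opts$beta_band[2], fs)
  hb <- .analytic(beta)
  gamma <- bandpass(window, opts$gamma_band[1], opts$gamma_band[2], fs)
  genv <- Mod(.analytic(gamma))
  pac <- cpp_tort_mi(Arg(hb), genv, opts$pac_bins)

  bstats <- cpp_bursts(Mod(hb), burst_thr,
                       as.integer(round(opts$burst_min_s * fs)), fs)

  broad <- bandpass(window, opts$broad_band[1], opts$broad_band[2], fs)
  shp <- c(PTAsym = 0, RDRatio = 0)
  ex <- .cycle_extrema(broad, beta)
  if (!is.null(ex) && sum(ex$type == 1) >= 3 && sum(ex$type == -1) >= 3) {
    sharp <- function(i) {
      s <- 1:5
      mean(abs(broad[i - s] - 2 * broad[i] + broad[i + s]))
    }
    ok <- ex$idx > 5 & ex$idx <= n - 5
    ps <- vapply(ex$idx[ok & ex$type == 1], sharp, numeric(1))
    ts <- vapply(ex$idx[ok & ex$type == -1], sharp, numeric(1))
    if (length(ps) > 0 && length(ts) > 0) {
      tot <- mean(ps) + mean(ts)
      if (tot > 0) shp["PTAsym"] <- (mean(ps) - mean(ts)) / tot
    }
    adj_type <- ex$type[-1] - ex$type[-nrow(ex)]
    dur <- diff(ex$idx) / fs
    rises <- dur[adj_type == 2]; decays <- dur[adj_type == -2]
    if (length(rises) > 0 && length(decays) > 0 &&
        mean(rises) > 0 && mean(decays) > 0) {
      shp["RDRatio"] <- log(mean(rises) / mean(decays))
    }
  }

  # complexity
  if (v == 0) {
    cx <- c(PFD = 1, HjMob = 0, HjComp = 0, SpecEn = 0, AppEn = 0, SampEn = 0)
  } else {
    d1 <- diff(window)
    n_delta <- sum(diff(sign(d1[d1 != 0])) != 0)
    pfd <- log10(n) / (log10(n) + log10(n / (n + 0.4 * n_delta)))
    vd1 <- stats::var(d1)
    mob <- sqrt(vd1 / v)
    mob_d <- if (vd1 > 0) sqrt(stats::var(diff(d1)) / vd1) else 0
    comp <- if (mob > 0) mob_d / mob else 0
    ptot <- sum(spec$psd)
    se <- 0
    if (ptot > 0) {
      pr <- spec$psd[spec$psd > 0] / ptot
      se <- -sum(pr * log(pr)) / log(length(spec$psd))
    }
    xd <- decimate_signal(window, opts$entropy_decim, fs)
    ent <- cpp_apen_sampen(xd, opts$entropy_m, opts$entropy_r * stats::sd(xd))
    cx <- c(PFD = pfd, HjMob = mob, HjComp = comp, SpecEn = se,
            AppEn = ent[1], SampEn = ent[2])
  }

  out <- c(BG_PAC = pac, PTAsym = unname(shp["PTAsym"]),
           RDRatio = unname(shp["RDRatio"]),
           Exponent = unname(ap["Exponent"]), Offset = unname(ap["Offset"]),
           ABD = bstats[1], ABA = bstats[2], ABE = bstats[3],
           BetaPower = bp, RelBetaPower = relbp,
           PFD = unname(cx["PFD"]), HjMob = unname(cx["HjMob"]),
           HjComp = unname(cx["HjComp"]), SpecEn = unname(cx["SpecEn"]),
           AppEn = unname(cx["AppEn"]), SampEn = unname(cx["SampEn"]))
  out[biomarker_names()]
}

#' Extract channel-averaged trial features
#'
#' Computes all 16 biomarkers for each central channel and each of the six
#' standardized windows of a trial, averages the four post-stimulation
#' windows, then averages across channels. This is the per-trial feature
#' contract of the screening pipeline.
#'
#' @param trial a `trial_recording`.
#' @param burst_thresholds named vector of subject-level burst thresholds,
#'   one per channel (see [burst_threshold()]).
#' @param central_channels channels to average over (default the 13 central
#'   electrodes); every requested channel must exist in the trial.
#' @param opts a [biomarker_options()] list.
#' @return list of class `trial_features` with `subject_id`, `stim_id`, and
#'   named 16-vectors `pre`, `stim`, `post`.
#' @export
extract_features <- function(trial, burst_thresholds,
                             central_channels = central_electrodes(),
                             opts = biomarker_options()) {
  chn <- rownames(trial$data)
  missing <- setdiff(central_channels, chn)
  if (length(missing) > 0) {
    stop("trial is missing central channel(s): ", paste(missing, collapse = ", "))
  }
  seg <- segment_trial(trial)
  fs <- trial$fs
  nb <- length(biomarker_names())
  acc <- list(pre = numeric(nb), stim = numeric(nb), post = numeric(nb))
  for (ch in central_channels) {
    thr <- burst_thresholds[[ch]]
    acc$pre <- acc$pre + compute_biomarkers(seg$pre[ch, ], fs, thr, opts)
    acc$stim <- acc$stim + compute_biomarkers(seg$stim[ch, ], fs, thr, opts)
    pw <- rowMeans(vapply(seg$post,
      function(w) compute_biomarkers(w[ch, ], fs, thr, opts), numeric(nb)))
    acc$post <- acc$post + pw
  }
  k <- length(central_channels)
  structure(list(subject_id = trial$subject_id, stim_id = trial$stim_id,
                 pre = stats::setNames(acc$pre / k, biomarker_names()),
                 stim = stats::setNames(acc$stim / k, biomarker_names()),
                 post = stats::setNames(acc$post / k, biomarker_names())),
            class = "trial_features")
}
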