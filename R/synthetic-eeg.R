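#' Synthetic EEG cohort generator
#'
#' Generates seeded virtual subjects (healthy controls, HC, and Parkinson's
#' disease, PD) whose resting EEG carries planted group differences in the
#' biomarker domains the screening pipeline measures: beta power, beta
#' bursts, beta-gamma phase-amplitude coupling, nonsinusoidal beta waveform
#' shape, the aperiodic 1/f background, and signal complexity (via the
#' noise-to-oscillation ratio). "Effective" stimulus categories transiently
#' pull PD generator parameters toward the HC group mean during the
#' stimulation interval only.
#'
#' @name synthetic_eeg
NULL

# deterministic seed derivation; all results stay below 2^31 - 1
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master) %% 2147483647
  for (k in idx) {
    s <- (s * 48271 + as.double(k) * 8191 + 1) %% 2147483647
  }
  as.integer(s)
}

#' Default 36-channel extended 10-20 montage
#'
#' Includes the 13 central electrodes used for biomarker averaging.
#'
#' @return character vector of 36 labels.
#' @export
default_montage <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FT7", "FC5", "FC1", "FCz", "FC2", "FC6", "FT8",
    "T7", "C3", "Cz", "C4", "T8",
    "TP7", "CP5", "CP1", "CPz", "CP2", "CP6", "TP8",
    "P7", "P3", "Pz", "P4", "P8",
    "PO3", "PO4", "O1", "Oz", "O2")
}

# source-to-channel gains: oscillatory sources are strongest over the
# central strip and decay toward the periphery
.channel_gains <- function(channels) {
  mid <- c("F3", "Fz", "F4", "T7", "T8", "P3", "Pz", "P4",
           "FT7", "FT8", "TP7", "TP8")
  g <- ifelse(channels %in% central_electrodes(), 1.0,
              ifelse(channels %in% mid, 0.6, 0.3))
  stats::setNames(g, channels)
}

#' Subject generator profile
#'
#' The tunable parameters of one virtual subject's EEG generator.
#'
#' @param subject_id subject label.
#' @param group `"HC"` or `"PD"`.
#' @param aperiodic_exponent 1/f exponent chi (unitless).
#' @param aperiodic_offset log10 PSD at 1 Hz (log10 signal-units^2/Hz).
#' @param beta_amp amplitude of the 20 Hz beta source (signal units).
#' @param burst_rate beta burst arrival rate (bursts/s).
#' @param burst_mean_dur mean burst duration (s, exponential).
#' @param pac_depth modulation depth of the 65 Hz gamma envelope by beta
#'   phase, in \[0, 1\].
#' @param shape_asym nonsinusoidal warp of the beta waveform in \[-1, 1\]
#'   (0 = sinusoidal).
#' @param noise_sd white sensor noise SD (signal units).
#' @param seed subject-level seed.
#' @return list of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, group, aperiodic_exponent = 1.5,
                            aperiodic_offset = 0.5, beta_amp = 1.5,
                            burst_rate = 1.2, burst_mean_dur = 0.25,
                            pac_depth = 0.2, shape_asym = 0.05,
                            noise_sd = 1.0, seed = 1L) {
  stopifnot(group %in% c("HC", "PD"), pac_depth >= 0, burst_rate >= 0,
            burst_mean_dur >= 0)
  structure(list(subject_id = subject_id, group = group,
                 aperiodic_exponent = as.numeric(aperiodic_exponent),
                 aperiodic_offset = as.numeric(aperiodic_offset),
                 beta_amp = as.numeric(beta_amp),
                 burst_rate = as.numeric(burst_rate),
                 burst_mean_dur = as.numeric(burst_mean_dur),
                 pac_depth = as.numeric(pac_depth),
                 shape_asym = as.numeric(shape_asym),
                 noise_sd = as.numeric(noise_sd),
                 seed = as.integer(seed)),
            class = "subject_profile")
}

.profile_param_names <- function() {
  c("aperiodic_exponent", "aperiodic_offset", "beta_amp", "burst_rate",
    "burst_mean_dur", "pac_depth", "shape_asym", "noise_sd")
}

#' Group-level generator parameters
#'
#' Means and between-subject SDs of the generator parameters for each group.
#' PD differs from HC in the planted directions: higher beta amplitude,
#' longer bursts, deeper PAC, stronger waveform asymmetry, and a lower
#' noise-to-oscillation ratio (hence lower entropy). The separation was
#' calibrated once so that leave-one-subject-out classification accuracy on
#' pre-stimulation windows of the default cohort lands in the 80-90% band,
#' and then frozen.
#'
#' @return data.frame with columns `param`, `hc_mean`, `pd_mean`, `sd`.
#' @export
group_parameter_table <- function() {
  data.frame(
    param = .profile_param_names(),
    hc_mean = c(1.50, 0.50, 1.30, 1.10, 0.22, 0.12, 0.04, 1.00),
    pd_mean = c(1.50, 0.50, 1.79, 1.25, 0.34, 0.32, 0.22, 0.79),
    sd      = c(0.10, 0.08, 0.22, 0.14, 0.052, 0.068, 0.060, 0.088),
    stringsAsFactors = FALSE
  )
}

#' Mean HC generator profile (the normalization target)
#'
#' @return named numeric vector of the HC group-mean parameters.
#' @export
hc_mean_profile <- function() {
  tab <- group_parameter_table()
  stats::setNames(tab$hc_mean, tab$param)
}

#' Cohort configuration
#'
#' @param n_hc,n_pd number of healthy-control / PD virtual subjects.
#' @param n_trials trials per subject (one per stimulus).
#' @param fs sampling rate, Hz.
#' @param channel_names montage (must contain the 13 central electrodes).
#' @param trial_layout named vector `c(pre =, stim =, post =)` in seconds.
#' @param effect_map named numeric vector: effect size delta in \[0, 1\] per
#'   category id (as character names); categories absent from the map get 0.
#' @param master_seed integer master seed; all randomness derives from it.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_hc = 5L, n_pd = 5L, n_trials = 304L, fs = 1000,
                          channel_names = default_montage(),
                          trial_layout = c(pre = 2, stim = 2, post = 5),
                          effect_map = default_effect_map(),
                          master_seed = 1234L) {
  missing <- setdiff(central_electrodes(), channel_names)
  if (length(missing) > 0) {
    stop("montage is missing central electrode(s): ",
         paste(missing, collapse = ", "))
  }
  stopifnot(sum(trial_layout) == 9)  # 2 s pre / 2 s stim / 5 s post
  structure(list(n_hc = as.integer(n_hc), n_pd = as.integer(n_pd),
                 n_trials = as.integer(n_trials), fs = fs,
                 channel_names = channel_names, trial_layout = trial_layout,
                 effect_map = effect_map,
                 master_seed = as.integer(master_seed)),
            class = "cohort_config")
}

#' Default planted effect map
#'
#' Effect size delta = 0.6 for the four effective categories (11, 20, 33,
#' 36), 0 elsewhere -- the answer key that the inference layer must recover.
#'
#' @param delta planted effect size.
#' @param categories effective category ids.
#' @return named numeric vector over category ids.
#' @export
default_effect_map <- function(delta = 0.6, categories = c(11L, 20L, 33L, 36L)) {
  m <- stats::setNames(rep(0, 37), as.character(1:37))
  m[as.character(categories)] <- delta
  m
}

#' Draw the cohort's subject profiles
#'
#' Subject parameters are drawn from the group-level distributions
#' ([group_parameter_table()]) with seeds derived from the master seed.
#'
#' @param config a [cohort_config()].
#' @return list of [subject_profile()] objects (HC first, then PD).
#' @export
draw_subject_profiles <- function(config) {
  tab <- group_parameter_table()
  profiles <- list()
  idx <- 0L
  for (grp in c("HC", "PD")) {
    n <- if (grp == "HC") config$n_hc else config$n_pd
    mu <- if (grp == "HC") tab$hc_mean else tab$pd_mean
    for (i in seq_len(n)) {
      idx <- idx + 1L
      sseed <- derive_seed(config$master_seed, idx)
      old <- .Random.seed_save()
      set.seed(sseed)
      vals <- stats::rnorm(nrow(tab), mu, tab$sd)
      .Random.seed_restore(old)
      names(vals) <- tab$param
      vals["pac_depth"] <- min(max(vals["pac_depth"], 0), 1)
      vals["burst_rate"] <- max(vals["burst_rate"], 0.1)
      vals["burst_mean_dur"] <- max(vals["burst_mean_dur"], 0.05)
      vals["noise_sd"] <- max(vals["noise_sd"], 0.2)
      profiles[[idx]] <- subject_profile(
        subject_id = sprintf("%s%02d", tolower(grp), i), group = grp,
        aperiodic_exponent = vals["aperiodic_exponent"],
        aperiodic_offset = vals["aperiodic_offset"],
        beta_amp = vals["beta_amp"], burst_rate = vals["burst_rate"],
        burst_mean_dur = vals["burst_mean_dur"],
        pac_depth = vals["pac_depth"], shape_asym = vals["shape_asym"],
        noise_sd = vals["noise_sd"], seed = sseed)
    }
  }
  profiles
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# smoothed burst gate: tonic floor plus unit boxcars at Poisson arrival
# times with exponential durations, smoothed by a 100 ms Hann kernel
.burst_envelope <- function(n, fs, rate, mean_dur, tonic = 0.35) {
  dur_s <- n / fs
  n_burst <- stats::rpois(1, rate * dur_s)
  gate <- rep(0, n)
  if (n_burst > 0) {
    onset <- floor(stats::runif(n_burst, 0, n - 1)) + 1
    lens <- pmax(1, round(stats::rexp(n_burst, 1 / mean_dur) * fs))
    for (b in seq_len(n_burst)) {
      i2 <- min(n, onset[b] + lens[b] - 1)
      gate[onset[b]:i2] <- 1
    }
  }
  k <- 0.5 - 0.5 * cos(2 * pi * seq_len(round(0.1 * fs)) / (round(0.1 * fs) + 1))
  k <- k / sum(k)
  sm <- stats::filter(c(rep(gate[1], length(k)), gate, rep(gate[n], length(k))),
                      k, sides = 2)
  sm <- sm[(length(k) + 1):(length(k) + n)]
  tonic + (1 - tonic) * as.numeric(sm)
}

#' Simulate one multichannel EEG segment
#'
#' One segment = 1/f^chi background (frequency-domain amplitude shaping of
#' white noise, independent per channel) + a burst-gated, optionally
#' nonsinusoidal 20 Hz beta source + a 65 Hz gamma source whose envelope is
#' modulated by beta phase (planted PAC) + white sensor noise. Oscillatory
#' sources are shared across channels with distance-decayed gains (central
#' channels strongest); background and sensor noise are independent per
#' channel.
#'
#' @param params a [subject_profile()] or named list with the generator
#'   parameters.
#' @param n_samples segment length in samples (>= 1 s).
#' @param fs sampling rate, Hz.
#' @param seed integer seed for this segment.
#' @param channels channel labels (default the 36-channel montage).
#' @return channels x samples numeric matrix with channel rownames.
#' @export
simulate_segment <- function(params, n_samples, fs, seed,
                             channels = default_montage()) {
  stopifnot(n_samples >= fs)
  n <- as.integer(n_samples)
  nch <- length(channels)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)

  # per-channel noise streams are seeded by the channel's montage position,
  # so generating a channel subset reproduces exactly the same samples as
  # generating the full montage
  chan_idx <- match(channels, default_montage())
  chan_idx[is.na(chan_idx)] <- 37L + seq_len(sum(is.na(chan_idx)))
  white <- matrix(0, n, nch)
  noise <- matrix(0, n, nch)
  for (j in seq_len(nch)) {
    set.seed(derive_seed(seed, 1000L + chan_idx[j]))
    white[, j] <- stats::rnorm(n)
    noise[, j] <- stats::rnorm(n, sd = params$noise_sd)
  }

  # 1/f^chi background, one independent realization per channel
  chi <- params$aperiodic_exponent
  off <- params$aperiodic_offset
  freqs <- fs * (0:(n - 1)) / n
  f_fold <- pmin(freqs, fs - freqs)
  f_eff <- pmax(f_fold, 0.5)              # flatten below 0.5 Hz
  gain <- sqrt(10^off * f_eff^(-chi) * fs / 2)
  gain[1] <- 0                            # zero mean
  W <- stats::mvfft(white) * gain
  bg <- Re(stats::mvfft(W, inverse = TRUE)) / n

  # shared oscillatory sources
  set.seed(derive_seed(seed, 0L))
  t <- (0:(n - 1)) / fs
  phase0 <- stats::runif(1, 0, 2 * pi)
  phi <- 2 * pi * 20 * t + phase0
  env <- .burst_envelope(n, fs, params$burst_rate, params$burst_mean_dur)
  # nonsinusoidal beta: a second harmonic locked to the fundamental sharpens
  # peaks relative to troughs; the phase skew makes rises faster than decays
  a <- params$shape_asym
  shape <- sin(phi + a * sin(phi)) - a * cos(2 * (phi + a * sin(phi)))
  beta <- params$beta_amp * env * shape / (1 + abs(a))
  gamma_amp <- 0.6    # fixed: PAC is planted via the envelope depth, and a
                      # beta-amplitude-coupled gamma would leak beta power
                      # into the entropy contrast
  pac_env <- (1 + params$pac_depth * cos(phi)) / (1 + params$pac_depth)
  gphase0 <- stats::runif(1, 0, 2 * pi)
  gamma <- gamma_amp * pac_env * sin(2 * pi * 65 * t + gphase0)
  src <- beta + gamma

  g <- .channel_gains(channels)
  out <- t(bg + outer(src, unname(g)) + noise)
  rownames(out) <- channels
  out
}

# linear interpolation of PD parameters toward the HC mean by fraction delta
.interp_params <- function(profile, hc_mean, delta) {
  p <- profile
  for (nm in .profile_param_names()) {
    p[[nm]] <- (1 - delta) * profile[[nm]] + delta * hc_mean[[nm]]
  }
  p
}

#' Simulate one 9 s trial
#'
#' Pre- and post-stimulation intervals are generated from the subject's
#' baseline parameters; the stimulation interval from parameters linearly
#' interpolated toward the HC group mean by the effect size `delta` (PD
#' subjects only -- HC trials and sham always use `delta = 0`). Effects are
#' therefore strictly confined to the stimulation interval. Stimulation
#' artifacts are not simulated: the pipeline consumes cleaned EEG.
#'
#' @param profile a [subject_profile()].
#' @param spec the [stimulus_spec()] presented in this trial.
#' @param delta effect size in \[0, 1\].
#' @param hc_mean named vector of HC group-mean parameters
#'   (default [hc_mean_profile()]).
#' @param seed trial seed (interval sub-seeds are derived from it, so a
#'   trial's pre interval is identical whether or not the other intervals
#'   are generated).
#' @param fs sampling rate, Hz.
#' @param channels montage.
#' @param trial_layout interval durations in seconds.
#' @return list of class `trial_recording`: `subject_id`, `stim_id`, `data`
#'   (channels x 9000), `fs`, `layout`, `delta`.
#' @export
simulate_trial <- function(profile, spec, delta, hc_mean = hc_mean_profile(),
                           seed = 1L, fs = 1000,
                           channels = default_montage(),
                           trial_layout = c(pre = 2, stim = 2, post = 5)) {
  stopifnot(delta >= 0, delta <= 1)
  if (spec$family == "sham" || profile$group == "HC") delta <- 0
  stim_params <- if (delta > 0) .interp_params(profile, hc_mean, delta) else profile
  segs <- list()
  params_by_interval <- list(pre = profile, stim = stim_params, post = profile)
  for (k in seq_along(trial_layout)) {
    iv <- names(trial_layout)[k]
    segs[[iv]] <- simulate_segment(params_by_interval[[iv]],
                                   trial_layout[[k]] * fs, fs,
                                   derive_seed(seed, k), channels)
  }
  structure(list(subject_id = profile$subject_id, stim_id = spec$stim_id,
                 data = do.call(cbind, segs), fs = fs,
                 layout = trial_layout, delta = delta),
            class = "trial_recording")
}

#' Per-subject randomized trial order
#'
#' @param config a [cohort_config()].
#' @param subject_index 1-based subject index.
#' @return integer permutation of `1:n_trials`.
#' @export
trial_order <- function(config, subject_index) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(config$master_seed, 900001L, subject_index))
  sample.int(config$n_trials)
}

#' Simulate a full cohort
#'
#' Generates every subject's 304 trials in randomized order. For the default
#' cohort (10 subjects x 304 x 36 x 9000 samples) the raw data does not fit
#' in memory, so trials are either written to disk as EDF sessions
#' (`dir` given, one EDF per subject plus events and ground-truth CSVs) or
#' returned in memory (`dir = NULL`; only sensible for reduced configs).
#' Use [cohort_features()] to stream straight from the generator into
#' biomarkers without materializing raw data.
#'
#' @param config a [cohort_config()].
#' @param library stimulus library from [build_default_library()].
#' @param dir output directory for EDF sessions, or `NULL` for in-memory.
#' @return list with `profiles`, `truth` (subject_id, stim_id, delta),
#'   `orders`, and either `dir` or `trials` (nested list by subject).
#' @export
simulate_cohort <- function(config, library, dir = NULL) {
  stopifnot(length(library) >= config$n_trials)
  profiles <- draw_subject_profiles(config)
  hc_mean <- hc_mean_profile()
  cat_of <- vapply(library, function(s) s$category_id, integer(1))
  truth <- list()
  orders <- list()
  trials_out <- if (is.null(dir)) list() else NULL
  if (!is.null(dir)) dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  for (si in seq_along(profiles)) {
    prof <- profiles[[si]]
    ord <- trial_order(config, si)
    orders[[prof$subject_id]] <- ord
    subj_trials <- vector("list", config$n_trials)
    deltas <- numeric(config$n_trials)
    for (k in seq_len(config$n_trials)) {
      stim <- library[[ord[k]]]
      delta <- unname(config$effect_map[as.character(cat_of[ord[k]])])
      if (is.na(delta)) delta <- 0
      tr <- simulate_trial(prof, stim, delta, hc_mean,
                           seed = derive_seed(prof$seed, 7L, k),
                           fs = config$fs, channels = config$channel_names,
                           trial_layout = config$trial_layout)
      deltas[k] <- tr$delta
      subj_trials[[k]] <- tr
    }
    truth[[si]] <- data.frame(subject_id = prof$subject_id,
                              stim_id = vapply(subj_trials, function(x) x$stim_id, integer(1)),
                              delta = deltas, stringsAsFactors = FALSE)
    if (is.null(dir)) {
      trials_out[[prof$subject_id]] <- subj_trials
    } else {
      write_subject_session(subj_trials, prof, dir, config)
      rm(subj_trials)
    }
  }
  truth <- do.call(rbind, truth)
  out <- list(profiles = profiles, truth = truth, orders = orders)
  if (is.null(dir)) {
    out$trials <- trials_out
  } else {
    write_stimulus_library(library, file.path(dir, "stimulus_library.json"))
    utils::write.csv(truth, file.path(dir, "ground_truth.csv"), row.names = FALSE)
    out$dir <- dir
  }
  out
}
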