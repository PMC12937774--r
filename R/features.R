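#' Stream a synthetic cohort into biomarker features
#'
#' Generates each subject's trials from the seeded generator and extracts
#' channel-averaged biomarker vectors without materializing the raw cohort
#' (the full default cohort is ~8 GB of samples; per-subject streaming keeps
#' the footprint to the requested channels only). Burst thresholds are
#' computed per subject and channel from the pooled pre-stimulation beta
#' envelopes before any feature is extracted, as the burst contract
#' requires. Interval sub-seeds are derived per (subject, trial, interval),
#' so restricting `intervals` does not change the data generated for the
#' intervals that are kept.
#'
#' @param config a [cohort_config()].
#' @param library stimulus library.
#' @param intervals subset of `c("pre", "stim", "post")` to extract.
#' @param central_channels channels to average biomarkers over.
#' @param opts a [biomarker_options()] list.
#' @param subjects optional subset of subject indices to process.
#' @return data.frame: `subject_id`, `group`, `stim_id`, `delta`,
#'   `interval`, then the 16 biomarker columns in canonical order.
#' @export
cohort_features <- function(config, library, intervals = c("pre", "stim", "post"),
                            central_channels = central_electrodes(),
                            opts = biomarker_options(), subjects = NULL) {
  intervals <- match.arg(intervals, several.ok = TRUE)
  profiles <- draw_subject_profiles(config)
  if (!is.null(subjects)) profiles <- profiles[subjects]
  hc_mean <- hc_mean_profile()
  cat_of <- vapply(library, function(s) s$category_id, integer(1))
  fs <- config$fs
  nb <- length(biomarker_names())
  out <- list()

  prof_index <- if (is.null(subjects)) seq_along(profiles) else subjects
  for (pi in seq_along(profiles)) {
    prof <- profiles[[pi]]
    ord <- trial_order(config, prof_index[pi])
    nt <- config$n_trials
    gen_iv <- union("pre", intervals)   # pre always needed for thresholds
    segs <- vector("list", nt)
    deltas <- numeric(nt)
    for (k in seq_len(nt)) {
      stim <- library[[ord[k]]]
      delta <- unname(config$effect_map[as.character(cat_of[ord[k]])])
      if (is.na(delta) || stim$family == "sham" || prof$group == "HC") delta <- 0
      deltas[k] <- delta
      pars_stim <- if (delta > 0) .interp_params(prof, hc_mean, delta) else prof
      tseed <- derive_seed(prof$seed, 7L, k)
      s <- list()
      iv_names <- names(config$trial_layout)
      for (j in seq_along(iv_names)) {
        iv <- iv_names[j]
        if (!iv %in% gen_iv) next
        pars <- if (iv == "stim") pars_stim else prof
        s[[iv]] <- simulate_segment(pars, config$trial_layout[[j]] * fs, fs,
                                    derive_seed(tseed, j), central_channels)
      }
      segs[[k]] <- s
    }

    # subject/channel burst thresholds from pooled pre-stim beta envelopes
    thr <- vapply(central_channels, function(ch) {
      env <- unlist(lapply(segs, function(s) {
        hilbert_transform(bandpass(s$pre[ch, ], opts$beta_band[1],
                                   opts$beta_band[2], fs))$envelope
      }))
      stats::quantile(env, opts$burst_quantile, names = FALSE)
    }, numeric(1))

    post_offsets <- c(0, 1, 2, 3) * fs
    for (k in seq_len(nt)) {
      s <- segs[[k]]
      for (iv in intervals) {
        vec <- numeric(nb)
        for (ch in central_channels) {
          if (iv == "post") {
            pw <- vapply(post_offsets, function(o) {
              compute_biomarkers(s$post[ch, (o + 1):(o + 2 * fs)], fs,
                                 thr[[ch]], opts)
            }, numeric(nb))
            vec <- vec + rowMeans(pw)
          } else {
            vec <- vec + compute_biomarkers(s[[iv]][ch, ], fs, thr[[ch]], opts)
          }
        }
        row <- c(list(subject_id = prof$subject_id, group = prof$group,
                      stim_id = library[[ord[k]]]$stim_id, delta = deltas[k],
                      interval = iv),
                 as.list(vec / length(central_channels)))
        out[[length(out) + 1L]] <- row
      }
      segs[k] <- list(NULL)
    }
  }
  df <- data.table::rbindlist(out)
  data.table::setnames(df, c("subject_id", "group", "stim_id", "delta",
                             "interval", biomarker_names()))
  as.data.frame(df)
}

#' Per-channel biomarker values for interval comparison maps
#'
#' Computes selected biomarkers (default relative beta power and peak-trough
#' asymmetry) for every montage channel on the trials of a chosen category
#' set, keeping values per channel (no spatial averaging). Used for the
#' per-channel paired-t interval maps.
#'
#' @inheritParams cohort_features
#' @param categories category ids selecting the trial subset.
#' @param markers biomarkers to compute; subset of
#'   `c("RelBetaPower", "PTAsym")`.
#' @param channels channels to compute (default full montage).
#' @return long data.frame: `subject_id`, `group`, `stim_id`, `channel`,
#'   `interval`, one column per requested biomarker.
#' @export
cohort_channel_biomarkers <- function(config, library, categories,
                                      markers = c("RelBetaPower", "PTAsym"),
                                      channels = NULL,
                                      intervals = c("pre", "stim", "post"),
                                      opts = biomarker_options(),
                                      subjects = NULL) {
  markers <- match.arg(markers, several.ok = TRUE)
  if (is.null(channels)) channels <- config$channel_names
  profiles <- draw_subject_profiles(config)
  if (!is.null(subjects)) profiles <- profiles[subjects]
  prof_index <- if (is.null(subjects)) seq_along(profiles) else subjects
  hc_mean <- hc_mean_profile()
  cat_of <- vapply(library, function(s) s$category_id, integer(1))
  fs <- config$fs
  out <- list()

  one_window <- function(w) {
    v <- c()
    if ("RelBetaPower" %in% markers) {
      v <- c(v, RelBetaPower = unname(band_powers(w, fs, opts)["RelBetaPower"]))
    }
    if ("PTAsym" %in% markers) {
      v <- c(v, PTAsym = unname(waveform_shape(w, fs, opts)["PTAsym"]))
    }
    v
  }

  for (pi in seq_along(profiles)) {
    prof <- profiles[[pi]]
    ord <- trial_order(config, prof_index[pi])
    sel <- which(cat_of[ord] %in% categories)
    for (k in sel) {
      stim <- library[[ord[k]]]
      delta <- unname(config$effect_map[as.character(cat_of[ord[k]])])
      if (is.na(delta) || stim$family == "sham" || prof$group == "HC") delta <- 0
      pars_stim <- if (delta > 0) .interp_params(prof, hc_mean, delta) else prof
      tseed <- derive_seed(prof$seed, 7L, k)
      iv_names <- names(config$trial_layout)
      for (j in seq_along(iv_names)) {
        iv <- iv_names[j]
        if (!iv %in% intervals) next
        pars <- if (iv == "stim") pars_stim else prof
        seg <- simulate_segment(pars, config$trial_layout[[j]] * fs, fs,
                                derive_seed(tseed, j), channels)
        for (ch in channels) {
          if (iv == "post") {
            pw <- vapply(c(0, 1, 2, 3) * fs, function(o) {
              one_window(seg[ch, (o + 1):(o + 2 * fs)])
            }, numeric(length(markers)))
            vals <- rowMeans(matrix(pw, nrow = length(markers)))
            names(vals) <- markers
          } else {
            vals <- one_window(seg[ch, ])
          }
          out[[length(out) + 1L]] <- c(
            list(subject_id = prof$subject_id, group = prof$group,
                 stim_id = stim$stim_id, channel = ch, interval = iv),
            as.list(vals))
        }
      }
    }
  }
  df <- data.table::rbindlist(out)
  data.table::setnames(df, c("subject_id", "group", "stim_id", "channel",
                             "interval", markers))
  as.data.frame(df)
}
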