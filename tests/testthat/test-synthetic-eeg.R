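test_that("cohort configuration enforces the stated structure", {
  cfg <- cohort_config()
  expect_identical(cfg$n_hc, 5L)
  expect_identical(cfg$n_pd, 5L)
  expect_identical(cfg$n_trials, 304L)
  expect_identical(unname(cfg$trial_layout), c(2, 2, 5))
  expect_length(cfg$channel_names, 36)
  expect_true(all(central_electrodes() %in% cfg$channel_names))
  expect_error(cohort_config(channel_names = c("Cz", "C3")), "central")
})

test_that("simulate_segment is seeded, shaped, and leaves the global RNG alone", {
  p <- subject_profile("x", "PD")
  set.seed(123); before <- .Random.seed
  a <- simulate_segment(p, 2000, 1000, 5)
  expect_identical(.Random.seed, before)
  expect_identical(dim(a), c(36L, 2000L))
  expect_identical(rownames(a), default_montage())
  b <- simulate_segment(p, 2000, 1000, 5)
  expect_identical(a, b)
  d <- simulate_segment(p, 2000, 1000, 6)
  expect_false(identical(a, d))
  expect_error(simulate_segment(p, 500, 1000, 1), "n_samples")
})

test_that("with no oscillations the beta-band fraction matches the 1/f expectation", {
  chi <- 1.5; off <- 0.5
  f <- seq(1, 45, by = 0.5)
  target <- 10^off * pmax(f, 0.5)^-chi
  expected <- sum(target[f >= 13 & f <= 30]) / sum(target)
  rel <- vapply(1:25, function(i) {
    seg <- simulate_segment(background_profile(chi, off), 2000, 1000, i,
                            channels = "Cz")
    band_powers(seg[1, ], 1000)["RelBetaPower"]
  }, numeric(1))
  expect_equal(mean(rel), expected, tolerance = 0.15)
})

test_that("planted group contrasts point in the stated directions", {
  tab <- group_parameter_table()
  hc <- as.list(stats::setNames(tab$hc_mean, tab$param))
  pd <- as.list(stats::setNames(tab$pd_mean, tab$param))
  mean_feat <- function(pars, n = 12) {
    rowMeans(vapply(seq_len(n), function(i) {
      w <- simulate_segment(pars, 2000, 1000, i, channels = "Cz")[1, ]
      thr <- stats::quantile(hilbert_transform(
        bandpass(w, 13, 30, 1000))$envelope, 0.75)
      compute_biomarkers(w, 1000, thr)
    }, numeric(16)))
  }
  fhc <- mean_feat(hc); fpd <- mean_feat(pd)
  expect_gt(fpd["BetaPower"], fhc["BetaPower"])
  expect_gt(fpd["BG_PAC"], fhc["BG_PAC"])
  expect_gt(fpd["PTAsym"], fhc["PTAsym"])
  expect_gt(fhc["SampEn"], fpd["SampEn"])
})

test_that("effects are interpolated in the stim interval only and gated correctly", {
  prof <- subject_profile("p1", "PD", seed = 9L)
  spec <- stimulus_spec(3L, "sinusoid", list(carrier_hz = 20), 1, 6L, "x")
  sham <- stimulus_spec(304L, "sham", list(), 0, 37L, "Sham")

  t0 <- simulate_trial(prof, spec, 0, seed = 21L)
  t9 <- simulate_trial(prof, spec, 0.9, seed = 21L)
  # transience: pre and post identical, stim differs
  expect_identical(t0$data[, 1:2000], t9$data[, 1:2000])
  expect_identical(t0$data[, 4001:9000], t9$data[, 4001:9000])
  expect_false(identical(t0$data[, 2001:4000], t9$data[, 2001:4000]))

  # delta = 1 reproduces the HC mean generator exactly in the stim interval
  t1 <- simulate_trial(prof, spec, 1, seed = 21L)
  hc_prof <- prof
  for (nm in names(hc_mean_profile())) hc_prof[[nm]] <- hc_mean_profile()[[nm]]
  ref <- simulate_trial(hc_prof, spec, 0, seed = 21L)
  expect_identical(t1$data[, 2001:4000], ref$data[, 2001:4000])

  # sham and HC trials force delta to zero
  ts <- simulate_trial(prof, sham, 0.9, seed = 21L)
  expect_identical(ts$delta, 0)
  expect_identical(ts$data, t0$data)
  hcp <- subject_profile("h1", "HC", seed = 9L)
  expect_identical(simulate_trial(hcp, spec, 0.9, seed = 21L)$delta, 0)
})

test_that("mini cohort simulation is reproducible with the documented schema", {
  lib <- build_default_library()
  cfg <- cohort_config(n_hc = 1L, n_pd = 1L, n_trials = 6L, master_seed = 5L)
  a <- simulate_cohort(cfg, lib)
  expect_length(a$trials, 2)
  expect_length(a$trials[[1]], 6)
  expect_identical(dim(a$trials[[1]][[1]]$data), c(36L, 9000L))
  expect_identical(names(a$truth), c("subject_id", "stim_id", "delta"))
  expect_identical(nrow(a$truth), 12L)

  b <- simulate_cohort(cfg, lib)
  expect_identical(a$trials[[2]][[3]]$data, b$trials[[2]][[3]]$data)

  cfg2 <- cohort_config(n_hc = 1L, n_pd = 1L, n_trials = 6L, master_seed = 6L)
  c_ <- simulate_cohort(cfg2, lib)
  expect_false(identical(a$trials[[1]][[1]]$data, c_$trials[[1]][[1]]$data))
  expect_identical(dim(c_$trials[[1]][[1]]$data), dim(a$trials[[1]][[1]]$data))
  expect_identical(names(c_$truth), names(a$truth))
})

test_that("streamed features match direct per-trial extraction", {
  lib <- build_default_library()
  cfg <- cohort_config(n_hc = 1L, n_pd = 1L, n_trials = 3L, master_seed = 8L)
  chans <- c("Cz", "C3")
  feats <- cohort_features(cfg, lib, central_channels = chans)
  expect_identical(nrow(feats), 2L * 3L * 3L)
  expect_identical(names(feats)[6:21], biomarker_names())
  expect_true(all(is.finite(as.matrix(feats[, biomarker_names()]))))

  # oracle: rebuild subject 1's trials explicitly and extract directly
  sim <- simulate_cohort(cfg, lib)
  sid <- names(sim$trials)[1]
  trials <- sim$trials[[sid]]
  thr <- vapply(chans, function(ch) {
    burst_threshold(lapply(trials, function(tr) tr$data[ch, 1:2000]), cfg$fs)
  }, numeric(1))
  ft <- extract_features(trials[[2]], thr, central_channels = chans)
  got <- feats[feats$subject_id == sid & feats$stim_id == trials[[2]]$stim_id, ]
  expect_equal(unlist(got[got$interval == "pre", biomarker_names()]),
               ft$pre, tolerance = 1e-12)
  expect_equal(unlist(got[got$interval == "post", biomarker_names()]),
               ft$post, tolerance = 1e-12)
})
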