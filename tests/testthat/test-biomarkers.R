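test_that("segment_trial produces the standardized 2 s windows", {
  tr <- mini_trial()
  seg <- segment_trial(tr)
  expect_identical(seg$starts, c(4000, 5000, 6000, 7000))
  expect_identical(ncol(seg$pre), 2000L)
  expect_identical(ncol(seg$stim), 2000L)
  for (w in seg$post) expect_identical(ncol(w), 2000L)
  # stim window is data columns 2001..4000, post windows overlap by 1 s
  expect_identical(seg$stim, tr$data[, 2001:4000])
  expect_identical(seg$post[[2]], tr$data[, 5001:7000])
  bad <- tr
  bad$data <- bad$data[, 1:8999]
  expect_error(segment_trial(bad), "9000")
})

test_that("band powers match spectral oracles", {
  expect_gte(band_powers(unit_sine(20), fs_default)["RelBetaPower"], 0.99)
  expect_lte(band_powers(unit_sine(5), fs_default)["RelBetaPower"], 0.01)
  expect_identical(unname(band_powers(rep(0, 2000), fs_default)), c(0, 0))
  # flat-spectrum expectation (30-13)/(45-1)
  set.seed(7)
  rel <- replicate(40, band_powers(rnorm(2000), fs_default)["RelBetaPower"])
  expect_equal(mean(rel), (30 - 13) / (45 - 1), tolerance = 0.02 / 0.386)
})

test_that("modulation index attains its analytic extremes", {
  set.seed(1)
  ph <- runif(20000, -pi, pi)
  expect_identical(modulation_index(ph, rep(1, 20000)), 0)
  one_bin <- as.numeric(floor((ph + pi) / (2 * pi) * 18) == 7)
  expect_identical(modulation_index(ph, one_bin), 1)
  expect_identical(modulation_index(ph, rep(0, 20000)), 0)  # zero amplitude
})

test_that("tort_mi responds to generated phase-amplitude coupling", {
  mi <- function(depth) {
    mean(vapply(1:15, function(i) {
      p <- subject_profile("x", "PD", pac_depth = depth, beta_amp = 2,
                           noise_sd = 0.3)
      tort_mi(simulate_segment(p, 2000, 1000, i, channels = "Cz")[1, ], 1000)
    }, numeric(1)))
  }
  expect_gt(mi(0.9), mi(0))
})

test_that("waveform shape is symmetric for sinusoids and tracks planted asymmetry", {
  shp <- waveform_shape(unit_sine(20) + 0.05 * unit_sine(7), fs_default)
  expect_equal(unname(shp["PTAsym"]), 0, tolerance = 0.02)
  expect_equal(unname(shp["RDRatio"]), 0, tolerance = 0.02)

  pa <- vapply(1:50, function(i) {
    p <- subject_profile("x", "PD", shape_asym = 0.4, beta_amp = 3,
                         noise_sd = 0.3, aperiodic_offset = -0.5,
                         burst_rate = 2, burst_mean_dur = 0.5)
    waveform_shape(simulate_segment(p, 2000, 1000, i, channels = "Cz")[1, ],
                   1000)["PTAsym"]
  }, numeric(1))
  expect_gte(sum(pa > 0), 45)
})

test_that("time reversal negates the rise-decay ratio and preserves asymmetry", {
  set.seed(12)
  for (i in 1:5) {
    p <- subject_profile("x", "PD", shape_asym = 0.3, beta_amp = 2,
                         noise_sd = 0.5)
    w <- simulate_segment(p, 2000, 1000, i, channels = "Cz")[1, ]
    a <- waveform_shape(w, 1000)
    b <- waveform_shape(rev(w), 1000)
    expect_equal(unname(b["RDRatio"]), -unname(a["RDRatio"]), tolerance = 1e-6)
    expect_equal(unname(b["PTAsym"]), unname(a["PTAsym"]), tolerance = 1e-6)
  }
})

test_that("aperiodic fit is exact on a noiseless power law and unbiased on noise", {
  f <- seq(0, 500, by = 0.5)
  psd <- 10^1.5 * pmax(f, 0.25)^-2
  ap <- aperiodic_fit_psd(f, psd, c(2, 40))
  expect_equal(unname(ap["Exponent"]), 2, tolerance = 1e-6)
  expect_equal(unname(ap["Offset"]), 1.5, tolerance = 1e-6)

  ex <- vapply(1:20, function(i) {
    seg <- simulate_segment(background_profile(chi = 1.5), 2000, 1000, i,
                            channels = "Cz")
    aperiodic_fit(seg[1, ], 1000)["Exponent"]
  }, numeric(1))
  expect_equal(mean(ex), 1.5, tolerance = 0.2)

  set.seed(5)
  exw <- replicate(20, aperiodic_fit(rnorm(2000), fs_default)["Exponent"])
  expect_equal(mean(exw), 0, tolerance = 0.15)
})

test_that("burst statistics match run-length oracles", {
  fs <- 1000
  env <- rep(0.1, 2000)
  env[501:800] <- 1                       # one 300 ms excursion
  st <- burst_stats_from_envelope(env, fs, threshold = 0.5)
  expect_equal(unname(st["ABD"]), 0.300)
  expect_equal(unname(st["ABA"]), 1)
  expect_equal(unname(st["ABE"]), 300 / fs)

  expect_identical(unname(burst_stats_from_envelope(rep(0.1, 2000), fs, 0.5)),
                   c(0, 0, 0))

  env2 <- rep(0.1, 2000)
  env2[101:300] <- 1                      # 200 ms
  env2[1001:1400] <- 1                    # 400 ms
  st2 <- burst_stats_from_envelope(env2, fs, 0.5)
  expect_equal(unname(st2["ABD"]), 0.300)

  env3 <- rep(0.1, 2000)
  env3[101:150] <- 1                      # 50 ms: below the 100 ms minimum
  expect_identical(unname(burst_stats_from_envelope(env3, fs, 0.5)), c(0, 0, 0))

  expect_error(burst_stats_from_envelope(env, fs, 0), "positive")
  expect_error(beta_bursts(rnorm(2000), fs, -1), "positive")
})

test_that("complexity suite matches analytic oracles and orderings", {
  ramp <- seq(0, 1, length.out = 2000)
  expect_equal(unname(complexity_suite(ramp, fs_default)["PFD"]), 1)

  cx <- complexity_suite(unit_sine(10), fs_default)
  expect_equal(unname(cx["HjMob"]), 2 * pi * 10 / 1000, tolerance = 0.01)
  expect_equal(unname(cx["HjComp"]), 1, tolerance = 0.01)

  const <- complexity_suite(rep(3.7, 2000), fs_default)
  expect_identical(unname(const),
                   c(1, 0, 0, 0, 0, 0))

  set.seed(9)
  noise <- replicate(20, {
    cx <- complexity_suite(rnorm(2000), fs_default)
    c(cx["SampEn"], cx["SpecEn"], cx["AppEn"])
  })
  sine <- complexity_suite(unit_sine(10), fs_default)
  expect_gt(mean(noise[1, ]), sine["SampEn"])
  expect_gt(mean(noise[2, ]), sine["SpecEn"])
  expect_gt(mean(noise[3, ]), sine["AppEn"])
})

test_that("scale behavior: invariant, linear and quadratic biomarkers", {
  set.seed(21)
  p <- subject_profile("x", "PD", beta_amp = 2, noise_sd = 0.5)
  w <- simulate_segment(p, 2000, 1000, 4, channels = "Cz")[1, ]
  thr <- stats::quantile(
    hilbert_transform(bandpass(w, 13, 30, 1000))$envelope, 0.75)
  c_ <- 3.7
  a <- compute_biomarkers(w, 1000, thr)
  b <- compute_biomarkers(c_ * w, 1000, c_ * thr)
  invariant <- c("BG_PAC", "PTAsym", "RDRatio", "Exponent", "RelBetaPower",
                 "PFD", "HjMob", "HjComp", "SpecEn", "AppEn", "SampEn", "ABD")
  expect_equal(b[invariant], a[invariant], tolerance = 1e-6)
  expect_equal(unname(b["BetaPower"]), unname(c_^2 * a["BetaPower"]),
               tolerance = 1e-9)
  expect_equal(unname(b["ABA"]), unname(c_ * a["ABA"]), tolerance = 1e-9)
  expect_equal(unname(b["ABE"]), unname(c_^2 * a["ABE"]), tolerance = 1e-9)
  expect_equal(unname(b["Offset"]),
               unname(a["Offset"]) + 2 * log10(c_), tolerance = 1e-6)
})

test_that("compute_biomarkers agrees with the standalone estimators", {
  set.seed(30)
  p <- subject_profile("x", "PD", beta_amp = 2, noise_sd = 0.8)
  w <- simulate_segment(p, 2000, 1000, 9, channels = "Cz")[1, ]
  v <- compute_biomarkers(w, 1000, 0.5)
  expect_identical(names(v), biomarker_names())
  expect_true(all(is.finite(v)))
  expect_equal(v[c("BetaPower", "RelBetaPower")], band_powers(w, 1000))
  expect_equal(unname(v["BG_PAC"]), tort_mi(w, 1000), tolerance = 1e-9)
  expect_equal(v[c("PTAsym", "RDRatio")], waveform_shape(w, 1000))
  expect_equal(v[c("Exponent", "Offset")], aperiodic_fit(w, 1000))
  expect_equal(v[c("ABD", "ABA", "ABE")], beta_bursts(w, 1000, 0.5))
  expect_equal(v[c("PFD", "HjMob", "HjComp", "SpecEn", "AppEn", "SampEn")],
               complexity_suite(w, 1000))
})

test_that("extract_features averages channels and post windows correctly", {
  tr <- mini_trial(seed = 3L)
  # identical signal on all channels -> averaged equals single-channel
  tr_same <- tr
  tr_same$data <- matrix(rep(tr$data["Cz", ], each = nrow(tr$data)),
                         nrow = nrow(tr$data),
                         dimnames = dimnames(tr$data))
  thr <- stats::setNames(rep(0.5, 13), central_electrodes())
  ft <- extract_features(tr_same, thr)
  one <- compute_biomarkers(tr_same$data["Cz", 1:2000], tr$fs, 0.5)
  expect_equal(ft$pre, one, tolerance = 1e-12)

  # post is the unweighted mean over the 4 windows
  seg <- segment_trial(tr_same)
  post_manual <- rowMeans(vapply(seg$post, function(w)
    compute_biomarkers(w["Cz", ], tr$fs, 0.5), numeric(16)))
  expect_equal(ft$post, post_manual, tolerance = 1e-12)

  bad <- tr
  rownames(bad$data)[rownames(bad$data) == "Cz"] <- "XX"
  expect_error(extract_features(bad, thr), "Cz")
})
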