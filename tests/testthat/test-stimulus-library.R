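lib <- build_default_library()
lt <- library_table(lib)

test_that("default library satisfies every structural constraint", {
  expect_length(lib, 304)
  expect_identical(sort(lt$stim_id), 1:304)
  expect_identical(sum(lt$family == "sham"), 1L)
  expect_identical(sort(unique(lt$category_id)), 1:37)
  sizes <- table(lt$category_id)
  expect_identical(sum(sizes == 1), 2L)
  expect_identical(sum(sizes >= 2), 35L)
  labels <- lt$category_label[match(c(11L, 20L, 33L, 36L), lt$category_id)]
  expect_identical(labels, c("Sinusoidal beta 2", "Multisine MVS",
                             "FM 75 Hz carrier",
                             "Phase–Amplitude Coupling"))
})

test_that("all stimulus frequencies lie in 0-200 Hz", {
  fmax <- vapply(lib, function(s) {
    f <- unlist(s$params[names(s$params) %in%
      c("carrier_hz", "mod_hz", "f0_hz", "f1_hz", "freq_set", "bit_rate_hz",
        "pac_phase_hz", "pac_amp_hz")])
    if (length(f) == 0) 0 else max(f)
  }, numeric(1))
  expect_true(all(fmax <= 200))
  expect_true(all(vapply(lib, function(s) s$amplitude >= 0 && s$amplitude <= 1,
                         logical(1))))
})

test_that("library JSON serialization round-trips exactly", {
  path <- withr::local_tempfile(fileext = ".json")
  write_stimulus_library(lib, path)
  lib2 <- read_stimulus_library(path)
  expect_equal(lib2, lib)
})

test_that("waveform families honor their rendering contracts", {
  sham <- lib[[which(lt$family == "sham")]]
  expect_identical(generate_waveform(sham, 2, 1000), rep(0, 2000))

  # 10 Hz at 1000 Hz samples the exact peak (sample 25 = quarter period)
  sine <- stimulus_spec(900L, "sinusoid", list(carrier_hz = 10), 1, 4L, "x")
  w <- generate_waveform(sine, 2, 1000)
  expect_length(w, 2000)
  expect_equal(max(w), 1, tolerance = 1e-12)
  expect_identical(which.max(w[1:100]), 26L)

  # multisine spectral peaks (FFT oracle)
  ms <- stimulus_spec(901L, "multisine", list(freq_set = c(10, 25, 40)),
                      1, 17L, "x")
  w <- generate_waveform(ms, 2, 1000)
  mag <- Mod(stats::fft(w))[2:400]                  # 0.5 Hz bins, skip DC
  top3 <- sort(order(mag, decreasing = TRUE)[1:3] * 0.5)
  expect_equal(top3, c(10, 25, 40))

  # zero mean over integer periods for periodic families
  for (i in which(lt$family %in% c("sinusoid", "AM", "multisine", "FM", "PAC"))[
         c(1, 20, 60, 90, 120)]) {
    expect_lt(abs(mean(generate_waveform(lib[[i]], 2, 1000))), 1e-6)
  }

  # peak bound
  for (i in seq(1, 304, by = 37)) {
    expect_lte(max(abs(generate_waveform(lib[[i]], 2, 1000))),
               lib[[i]]$amplitude + 1e-9)
  }
})

test_that("waveform generation is deterministic and validates inputs", {
  b <- lt$stim_id[lt$family == "binary"][1]
  expect_identical(generate_waveform(lib[[b]], 2, 1000),
                   generate_waveform(lib[[b]], 2, 1000))
  hi <- stimulus_spec(902L, "sinusoid", list(carrier_hz = 150), 1, 9L, "x")
  expect_error(generate_waveform(hi, 1, 250), "Nyquist")
  bad <- lib[[2]]
  bad$family <- "nonsense"
  expect_error(generate_waveform(bad, 1, 1000), "unknown stimulus family")
  expect_error(stimulus_spec(1L, "nonsense", list(), 1, 1L, "x"),
               "unknown stimulus family")
})

test_that("PAC-family waveform carries more phase-amplitude coupling than a plain carrier", {
  pac <- lib[[which(lt$category_id == 36L)[3]]]
  w_pac <- generate_waveform(pac, 2, 1000)
  carrier <- stimulus_spec(903L, "sinusoid",
                           list(carrier_hz = pac$params$pac_amp_hz), 1, 8L, "x")
  w_sin <- generate_waveform(carrier, 2, 1000)
  phase_f <- pac$params$pac_phase_hz
  band <- c(max(phase_f - 4, 1), phase_f + 4)
  mi_pac <- tort_mi(w_pac, 1000, phase_band = band)
  mi_sin <- tort_mi(w_sin, 1000, phase_band = band)
  expect_gt(mi_pac, mi_sin)
})
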