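#' Stimulus specifications
#'
#' A stimulus spec describes one GVS waveform: its `stim_id` (1..304),
#' waveform `family`, named `params`, normalized `amplitude` in \[0, 1\]
#' (sub-threshold mA scaling is applied downstream by the stimulator, not
#' here), and its morphology category (`category_id` 1..37, `category_label`).
#'
#' @param stim_id integer stimulus index.
#' @param family one of `"DC"`, `"sinusoid"`, `"AM"`, `"chirp"`, `"chirpAM"`,
#'   `"FM"`, `"PAC"`, `"multisine"`, `"binary"`, `"sham"`.
#' @param params named list of waveform parameters (e.g. `carrier_hz`,
#'   `mod_hz`, `f0_hz`, `f1_hz`, `depth`, `freq_set`, `bit_rate_hz`,
#'   `pac_phase_hz`, `pac_amp_hz`).
#' @param amplitude normalized peak amplitude in \[0, 1\].
#' @param category_id integer in 1..37.
#' @param category_label category name.
#' @return an object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(stim_id, family, params = list(), amplitude = 1,
                          category_id, category_label) {
  families <- c("DC", "sinusoid", "AM", "chirp", "chirpAM", "FM", "PAC",
                "multisine", "binary", "sham")
  if (!family %in% families) {
    stop("unknown stimulus family: ", family)
  }
  stopifnot(amplitude >= 0, amplitude <= 1)
  structure(
    list(stim_id = as.integer(stim_id), family = family, params = params,
         amplitude = amplitude, category_id = as.integer(category_id),
         category_label = category_label),
    class = "stimulus_spec"
  )
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf("<stimulus %d: %s [cat %d: %s]>\n", x$stim_id, x$family,
              x$category_id, x$category_label))
  invisible(x)
}

# Category layout of the default library. The published stimulus table is not
# reproduced in the available text; this reconstruction honors every printed
# structural constraint: 304 stimuli with exactly one sham, families DC /
# sinusoid / AM / chirp / chirp-AM / FM / PAC / multisine / binary, pure
# sinusoids spanning 0.5-200 Hz, 37 morphology categories of which exactly 2
# are singletons (DC and sham), and the four named categories at ids 11, 20,
# 33 and 36.
.library_layout <- function() {
  list(
    list(id = 1L,  label = "DC",                    family = "DC",       n = 1L),
    list(id = 2L,  label = "Sinusoidal delta",      family = "sinusoid", freqs = seq(0.5, 3.5, by = 0.5)),
    list(id = 3L,  label = "Sinusoidal theta",      family = "sinusoid", freqs = seq(4, 8, by = 0.5)),
    list(id = 4L,  label = "Sinusoidal alpha 1",    family = "sinusoid", freqs = seq(8.5, 10, by = 0.5)),
    list(id = 5L,  label = "Sinusoidal alpha 2",    family = "sinusoid", freqs = seq(10.5, 12, by = 0.5)),
    list(id = 6L,  label = "Sinusoidal beta 1",     family = "sinusoid", freqs = 13:20),
    list(id = 7L,  label = "Sinusoidal gamma 1",    family = "sinusoid", freqs = c(35, 40, 45, 50, 55, 60)),
    list(id = 8L,  label = "Sinusoidal gamma 2",    family = "sinusoid", freqs = c(65, 70, 75, 80, 85, 90)),
    list(id = 9L,  label = "Sinusoidal high gamma", family = "sinusoid", freqs = c(100, 110, 120, 130, 140, 150)),
    list(id = 10L, label = "Sinusoidal very high",  family = "sinusoid", freqs = c(160, 170, 180, 190, 200)),
    list(id = 11L, label = "Sinusoidal beta 2",     family = "sinusoid", freqs = 21:30),
    list(id = 12L, label = "AM beta carrier, delta mod",  family = "AM", carrier = 20,
         mods = c(0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4, 1.25, 1.75)),
    list(id = 13L, label = "AM beta carrier, theta mod",  family = "AM", carrier = 20,
         mods = c(4.5, 5, 5.5, 6, 6.5, 7, 7.5, 8, 4.25, 4.75)),
    list(id = 14L, label = "AM gamma carrier, theta mod", family = "AM", carrier = 65,
         mods = c(4, 4.5, 5, 5.5, 6, 6.5, 7, 7.5, 8, 3.5)),
    list(id = 15L, label = "AM gamma carrier, beta mod",  family = "AM", carrier = 65,
         mods = c(13:20, 22, 25)),
    list(id = 16L, label = "AM high carrier",             family = "AM", carrier = 140,
         mods = c(1, 2, 4, 8, 13, 20, 30, 40, 6, 10)),
    list(id = 17L, label = "Multisine low",        family = "multisine",
         sets = list(c(1, 3, 5), c(2, 4, 6), c(1, 2, 4), c(3, 6, 9), c(2, 5, 8),
                     c(1, 4, 7), c(0.5, 2, 3.5), c(1.5, 3, 4.5), c(2, 6, 10), c(1, 5, 9))),
    list(id = 18L, label = "Multisine alpha-beta", family = "multisine",
         sets = list(c(9, 13, 17), c(10, 15, 20), c(8, 14, 20), c(11, 16, 21), c(9, 18, 27),
                     c(10, 20, 30), c(12, 18, 24), c(8, 16, 24), c(13, 19, 25), c(10, 17, 24))),
    list(id = 19L, label = "Multisine broadband",  family = "multisine",
         sets = list(c(5, 25, 45), c(10, 40, 70), c(5, 35, 65), c(15, 45, 75), c(20, 60, 100),
                     c(10, 50, 90), c(5, 55, 105), c(25, 75, 125), c(15, 65, 115), c(30, 90, 150))),
    list(id = 20L, label = "Multisine MVS",        family = "multisine",
         sets = list(c(0.5, 1.5, 2.5, 3.5), c(1, 2, 3, 4), c(0.5, 2, 4, 8), c(1, 3, 9, 27),
                     c(2, 4, 8, 16), c(1, 5, 13, 21), c(0.5, 4, 13, 30), c(2, 6, 18, 26),
                     c(1, 7, 13, 19), c(3, 9, 15, 21))),
    list(id = 21L, label = "Chirp slow up",   family = "chirp",
         sweeps = list(c(0.5, 4), c(0.5, 8), c(1, 6), c(1, 10), c(2, 8), c(2, 12), c(0.5, 6), c(1, 8), c(3, 9), c(2, 10))),
    list(id = 22L, label = "Chirp alpha",     family = "chirp",
         sweeps = list(c(8, 12), c(8, 13), c(9, 12), c(7, 13), c(8, 14), c(9, 13), c(10, 14), c(7, 11), c(6, 12), c(8, 11))),
    list(id = 23L, label = "Chirp beta",      family = "chirp",
         sweeps = list(c(13, 30), c(13, 20), c(20, 30), c(15, 25), c(13, 25), c(18, 30), c(14, 22), c(16, 28), c(13, 17), c(21, 29))),
    list(id = 24L, label = "Chirp gamma",     family = "chirp",
         sweeps = list(c(30, 60), c(40, 80), c(50, 100), c(60, 120), c(30, 90), c(45, 90), c(35, 70), c(55, 110))),
    list(id = 25L, label = "Chirp down",      family = "chirp",
         sweeps = list(c(30, 13), c(20, 13), c(12, 8), c(8, 4), c(30, 5), c(25, 15), c(90, 45), c(60, 30))),
    list(id = 26L, label = "Chirp-AM slow envelope",  family = "chirpAM",
         combos = list(c(20, 0.5, 4), c(20, 1, 8), c(65, 0.5, 4), c(65, 1, 8), c(40, 0.5, 6),
                       c(40, 1, 10), c(140, 0.5, 4), c(140, 1, 8))),
    list(id = 27L, label = "Chirp-AM fast envelope",  family = "chirpAM",
         combos = list(c(20, 4, 13), c(20, 8, 20), c(65, 4, 13), c(65, 8, 20), c(40, 4, 16),
                       c(40, 6, 18), c(140, 4, 13), c(140, 8, 20))),
    list(id = 28L, label = "Binary slow", family = "binary", rates = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)),
    list(id = 29L, label = "Binary mid",  family = "binary", rates = c(12, 14, 16, 18, 20, 24, 28, 32, 36, 40)),
    list(id = 30L, label = "Binary fast", family = "binary", rates = c(50, 60, 70, 80, 90, 100, 120, 140, 160, 200)),
    list(id = 31L, label = "FM 20 Hz carrier",  family = "FM", carrier = 20,
         mods = c(0.5, 1, 2, 3, 4, 5, 6, 8, 10), dev = 5),
    list(id = 32L, label = "FM 40 Hz carrier",  family = "FM", carrier = 40,
         mods = c(0.5, 1, 2, 4, 6, 8, 10, 13, 16), dev = 10),
    list(id = 33L, label = "FM 75 Hz carrier",  family = "FM", carrier = 75,
         mods = c(0.5, 1, 2, 4, 6, 8, 10, 13, 16, 20), dev = 15),
    list(id = 34L, label = "FM 140 Hz carrier", family = "FM", carrier = 140,
         mods = c(0.5, 1, 2, 4, 8, 13, 16, 20, 25), dev = 20),
    list(id = 35L, label = "PAC theta phase",   family = "PAC",
         combos = list(c(4, 65), c(5, 65), c(6, 65), c(7, 65), c(8, 65), c(4, 80), c(6, 80), c(8, 80))),
    list(id = 36L, label = "Phase–Amplitude Coupling", family = "PAC",
         combos = list(c(13, 65), c(16, 65), c(20, 65), c(24, 65), c(28, 65), c(13, 80), c(20, 80), c(28, 80), c(16, 100), c(24, 100))),
    list(id = 37L, label = "Sham", family = "sham", n = 1L)
  )
}

#' Build the default 304-stimulus GVS library
#'
#' Constructs the default waveform library: 304 stimulus specs (including
#' exactly one sham) grouped into 37 morphology categories, two of which
#' (DC and sham) are singletons, so that singleton exclusion leaves 35
#' categories for group-level inference.
#'
#' @return list of [stimulus_spec()] objects of length 304.
#' @export
build_default_library <- function() {
  layout <- .library_layout()
  specs <- list()
  sid <- 0L
  for (cat in layout) {
    add <- function(family, params) {
      sid <<- sid + 1L
      specs[[sid]] <<- stimulus_spec(sid, family, params,
                                     amplitude = if (family == "sham") 0 else 1,
                                     category_id = cat$id,
                                     category_label = cat$label)
    }
    switch(cat$family,
      DC = add("DC", list()),
      sham = add("sham", list()),
      sinusoid = for (f in cat$freqs) add("sinusoid", list(carrier_hz = f)),
      AM = for (m in cat$mods) add("AM", list(carrier_hz = cat$carrier, mod_hz = m, depth = 0.8)),
      multisine = for (s in cat$sets) add("multisine", list(freq_set = s)),
      chirp = for (sw in cat$sweeps) add("chirp", list(f0_hz = sw[1], f1_hz = sw[2])),
      chirpAM = for (co in cat$combos) add("chirpAM",
        list(f0_hz = co[2], f1_hz = co[3], carrier_hz = co[1], depth = 0.8)),
      binary = for (r in cat$rates) add("binary", list(bit_rate_hz = r)),
      FM = for (m in cat$mods) add("FM",
        list(carrier_hz = cat$carrier, mod_hz = m, dev_hz = cat$dev)),
      PAC = for (co in cat$combos) add("PAC",
        list(pac_phase_hz = co[1], pac_amp_hz = co[2], depth = 0.9))
    )
  }
  stopifnot(length(specs) == 304L)
  specs
}

#' Library grouping as a data frame
#'
#' @param library list of [stimulus_spec()] objects.
#' @return data.frame with `stim_id`, `family`, `category_id`, `category_label`.
#' @export
library_table <- function(library) {
  data.frame(
    stim_id = vapply(library, function(s) s$stim_id, integer(1)),
    family = vapply(library, function(s) s$family, character(1)),
    category_id = vapply(library, function(s) s$category_id, integer(1)),
    category_label = vapply(library, function(s) s$category_label, character(1)),
    stringsAsFactors = FALSE
  )
}

#' Write / read a stimulus library as JSON
#'
#' Serialization is lossless: `read_stimulus_library(write_stimulus_library(x))`
#' reproduces the spec list exactly (full double precision).
#'
#' @param library list of [stimulus_spec()] objects.
#' @param path JSON file path.
#' @return `write_stimulus_library`: the path, invisibly.
#' @export
write_stimulus_library <- function(library, path) {
  payload <- lapply(library, function(s) {
    list(stim_id = s$stim_id, family = s$family, params = s$params,
         amplitude = s$amplitude, category_id = s$category_id,
         category_label = s$category_label)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

#' @rdname write_stimulus_library
#' @export
read_stimulus_library <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(s) {
    params <- lapply(s$params, function(p) {
      if (is.list(p)) as.numeric(unlist(p)) else p
    })
    stimulus_spec(s$stim_id, s$family, params, s$amplitude,
                  s$category_id, s$category_label)
  })
}
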