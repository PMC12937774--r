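#' Minimal EDF writer / reader
#'
#' European Data Format: a fixed-layout ASCII header followed by data
#' records of little-endian 16-bit integers. This implementation covers the
#' continuous-recording subset the package needs (equal sampling rate across
#' channels, 1 s data records). Physical scaling per channel is chosen from
#' the data range, so round-tripping reproduces samples to within one
#' 16-bit quantization step of that range.
#'
#' @name edf
NULL

.pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

# shortest numeric rendering that (with a leading minus sign) fits the
# 8-char EDF physical-range field
.num8 <- function(x, width = 7) {
  for (fmt in c("%.6g", "%.5g", "%.4g", "%.3g", "%.2g")) {
    s <- sprintf(fmt, x)
    if (nchar(s) <= width) return(s)
  }
  sprintf("%.1g", x)
}

#' @rdname edf
#' @param data channels x samples numeric matrix with channel rownames.
#' @param fs sampling rate in Hz (integer; one data record per second).
#' @param path output file.
#' @param patient_id,recording_id free-text header fields.
#' @return `write_edf`: `path` invisibly; `read_edf`: list with `data`
#'   (channels x samples, rownames = labels), `fs`, `labels`.
#' @export
write_edf <- function(data, fs, path, patient_id = "X", recording_id = "gvscreen") {
  stopifnot(is.matrix(data), !is.null(rownames(data)))
  ns <- nrow(data)
  if (ncol(data) %% fs != 0) {
    stop("EDF writer requires a whole number of 1 s records; got ",
         ncol(data), " samples at ", fs, " Hz")
  }
  n_rec <- ncol(data) %/% fs
  pmax_ <- apply(abs(data), 1, max)
  pmax_ <- ifelse(pmax_ > 0, pmax_ * 1.001, 1)
  pm_str <- vapply(pmax_, .num8, character(1))
  pmax_ <- as.numeric(pm_str)   # use exactly what the header will carry
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(.pad(x, width), con, nchars = width, eos = NULL)
  header_bytes <- 256 + 256 * ns
  wr("0", 8); wr(patient_id, 80); wr(recording_id, 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(header_bytes, 8); wr("", 44); wr(n_rec, 8); wr("1", 8); wr(ns, 4)
  labels <- rownames(data)
  for (l in labels) wr(l, 16)
  for (i in 1:ns) wr("synthetic", 80)
  for (i in 1:ns) wr("uV", 8)
  for (i in 1:ns) wr(paste0("-", pm_str[i]), 8)
  for (i in 1:ns) wr(pm_str[i], 8)
  for (i in 1:ns) wr(dmin, 8)
  for (i in 1:ns) wr(dmax, 8)
  for (i in 1:ns) wr("", 80)
  for (i in 1:ns) wr(fs, 8)
  for (i in 1:ns) wr("", 32)

  scale <- (2 * pmax_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    block <- data[, cols, drop = FALSE]
    dig <- round((block + pmax_) / scale) + dmin
    dig <- pmin(pmax(dig, dmin), dmax)
    writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' @rdname edf
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- rd(8)
  if (version != "0") stop("malformed EDF header in ", path)
  rd(80); rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8)); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("malformed EDF header in ", path)
  labels <- vapply(1:ns, function(i) rd(16), character(1))
  for (i in 1:ns) rd(80)
  for (i in 1:ns) rd(8)
  pmin_ <- vapply(1:ns, function(i) as.numeric(rd(8)), numeric(1))
  pmax_ <- vapply(1:ns, function(i) as.numeric(rd(8)), numeric(1))
  dmin <- vapply(1:ns, function(i) as.numeric(rd(8)), numeric(1))
  dmax <- vapply(1:ns, function(i) as.numeric(rd(8)), numeric(1))
  for (i in 1:ns) rd(80)
  spr <- vapply(1:ns, function(i) as.integer(rd(8)), integer(1))
  for (i in 1:ns) rd(32)
  if (length(unique(spr)) != 1) stop("unequal per-channel rates not supported")
  fs <- spr[1] / rec_dur

  data <- matrix(0, ns, n_rec * spr[1])
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = ns * spr[1], size = 2,
                   endian = "little", signed = TRUE)
    if (length(raw) < ns * spr[1]) stop("truncated EDF data in ", path)
    block <- matrix(raw, nrow = spr[1], ncol = ns)
    cols <- ((r - 1) * spr[1] + 1):(r * spr[1])
    data[, cols] <- t((block - matrix(dmin, spr[1], ns, byrow = TRUE)) *
                        matrix(scale, spr[1], ns, byrow = TRUE) +
                        matrix(pmin_, spr[1], ns, byrow = TRUE))
  }
  rownames(data) <- labels
  list(data = data, fs = fs, labels = labels)
}

#' Write one subject's trials as an EDF session file
#'
#' Trials are concatenated in presentation order into one continuous EDF;
#' events are appended to the session-level `events.csv` (columns
#' `subject_id`, `trial_index`, `stim_id`, `onset_sample`; 0-based onsets).
#'
#' @param trials list of `trial_recording` objects in presentation order.
#' @param profile the subject's [subject_profile()].
#' @param dir session directory.
#' @param config the [cohort_config()].
#' @return path of the written EDF, invisibly.
#' @export
write_subject_session <- function(trials, profile, dir, config) {
  data <- do.call(cbind, lapply(trials, function(tr) tr$data))
  path <- file.path(dir, paste0(profile$subject_id, ".edf"))
  write_edf(data, config$fs, path,
            patient_id = paste(profile$subject_id, profile$group))
  n_per <- ncol(trials[[1]]$data)
  ev <- data.frame(subject_id = profile$subject_id,
                   trial_index = seq_along(trials),
                   stim_id = vapply(trials, function(tr) tr$stim_id, integer(1)),
                   onset_sample = (seq_along(trials) - 1) * n_per)
  ev_path <- file.path(dir, "events.csv")
  utils::write.table(ev, ev_path, sep = ",", row.names = FALSE,
                     col.names = !file.exists(ev_path),
                     append = file.exists(ev_path))
  invisible(path)
}

#' Read a session directory back into trials
#'
#' Expects one `<subject_id>.edf` per subject, a session `events.csv`, and
#' `stimulus_library.json`. Fails with the name of any missing file.
#'
#' @param dir session directory written by [simulate_cohort()].
#' @return list with `trials` (nested list: subject -> trial_recording),
#'   `events`, `library`.
#' @export
read_session <- function(dir) {
  ev_path <- file.path(dir, "events.csv")
  if (!file.exists(ev_path)) stop("missing events file: ", ev_path)
  events <- utils::read.csv(ev_path, stringsAsFactors = FALSE)
  lib_path <- file.path(dir, "stimulus_library.json")
  if (!file.exists(lib_path)) stop("missing stimulus library: ", lib_path)
  library <- read_stimulus_library(lib_path)
  trials <- list()
  for (sid in unique(events$subject_id)) {
    path <- file.path(dir, paste0(sid, ".edf"))
    if (!file.exists(path)) stop("missing EDF for subject ", sid, ": ", path)
    edf <- read_edf(path)
    ev <- events[events$subject_id == sid, ]
    n_per <- if (nrow(ev) > 1) diff(ev$onset_sample[1:2]) else ncol(edf$data)
    trials[[sid]] <- lapply(seq_len(nrow(ev)), function(k) {
      cols <- (ev$onset_sample[k] + 1):(ev$onset_sample[k] + n_per)
      structure(list(subject_id = sid, stim_id = ev$stim_id[k],
                     data = edf$data[, cols, drop = FALSE], fs = edf$fs,
                     layout = c(pre = 2, stim = 2, post = 5), delta = NA_real_),
                class = "trial_recording")
    })
  }
  list(trials = trials, events = events, library = library)
}
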