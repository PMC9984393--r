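#' Write a two-channel recording as EDF
#'
#' Minimal European Data Format writer for continuous recordings: one EEG
#' and one EMG channel, 1-second data records, 16-bit samples linearly
#' scaled between the per-channel physical extrema. Covers what the staging
#' pipeline needs; it is not a general-purpose EDF library (no annotations,
#' no discontinuous records).
#'
#' @param signals list with `eeg` and `emg` (equal-length numeric vectors,
#'   or per-epoch matrices as from [synthesize_signals()]) and `fs`
#'   (integer samples/second).
#' @param path output file path.
#' @param start_sec clock time of the first sample, seconds after midnight
#'   (stored in the header start time; default 07:00).
#' @return `path`, invisibly.
#' @export
write_edf <- function(signals, path, start_sec = 7 * 3600) {
  eeg <- signals$eeg; emg <- signals$emg; fs <- signals$fs
  if (is.matrix(eeg)) eeg <- as.vector(t(eeg))
  if (is.matrix(emg)) emg <- as.vector(t(emg))
  stopifnot(length(eeg) == length(emg), fs == round(fs), fs > 0)
  if (length(eeg) %% fs != 0) {
    stop("signal length must be a whole number of seconds")
  }
  n_rec <- length(eeg) %/% fs

  pad <- function(s, w) {
    s <- substr(as.character(s), 1, w)
    paste0(s, strrep(" ", w - nchar(s)))
  }
  phys_range <- function(x) {
    r <- max(abs(range(x)), 1e-6)
    c(-r, r)
  }
  pr_eeg <- phys_range(eeg); pr_emg <- phys_range(emg)
  dig <- c(-32768, 32767)
  to_dig <- function(x, pr) {
    as.integer(round((x - pr[1]) / (pr[2] - pr[1]) *
                       (dig[2] - dig[1]) + dig[1]))
  }

  hdr <- paste0(
    pad("0", 8), pad("synthetic mouse", 80), pad("hypnoscore", 80),
    pad("01.01.26", 8),
    pad(gsub(":", ".", format_clock(start_sec)), 8),
    pad(256 + 2 * 256, 8), pad("", 44), pad(n_rec, 8), pad("1", 8),
    pad("2", 4),
    # per-signal fields, EEG then EMG within each field block
    pad("EEG", 16), pad("EMG", 16),
    pad("synthetic", 80), pad("synthetic", 80),
    pad("uV", 8), pad("uV", 8),
    pad(formatC(pr_eeg[1], format = "g", digits = 6), 8),
    pad(formatC(pr_emg[1], format = "g", digits = 6), 8),
    pad(formatC(pr_eeg[2], format = "g", digits = 6), 8),
    pad(formatC(pr_emg[2], format = "g", digits = 6), 8),
    pad(dig[1], 8), pad(dig[1], 8),
    pad(dig[2], 8), pad(dig[2], 8),
    pad("", 80), pad("", 80),
    pad(fs, 8), pad(fs, 8),
    pad("", 32), pad("", 32))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(hdr), con)
  de <- to_dig(eeg, pr_eeg); dm <- to_dig(emg, pr_emg)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    writeBin(c(de[idx], dm[idx]), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a two-channel EDF recording
#'
#' Counterpart of [write_edf()]: reads a continuous EDF file with equal
#' samples-per-record channels and rescales 16-bit samples to physical
#' units.
#'
#' @param path EDF file path.
#' @return list with `channels` (named list of numeric vectors), `fs`
#'   (samples/second per channel), and `start_sec`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  fld <- function(w) trimws(rawToChar(readBin(con, "raw", w)))
  fld(8); fld(80); fld(80); fld(8)
  start_time <- fld(8)
  fld(8); fld(44)
  n_rec <- as.integer(fld(8))
  rec_dur <- as.numeric(fld(8))
  ns <- as.integer(fld(4))
  sig_fld <- function(w) vapply(seq_len(ns), function(i) fld(w), character(1))
  labels <- sig_fld(16); sig_fld(80); sig_fld(8)
  pmin <- as.numeric(sig_fld(8)); pmax <- as.numeric(sig_fld(8))
  dmin <- as.numeric(sig_fld(8)); dmax <- as.numeric(sig_fld(8))
  sig_fld(80)
  spr <- as.integer(sig_fld(8))
  sig_fld(32)

  out <- lapply(seq_len(ns), function(i) numeric(n_rec * spr[i]))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      raw <- readBin(con, "integer", spr[i], size = 2, signed = TRUE,
                     endian = "little")
      out[[i]][((r - 1) * spr[i] + 1):(r * spr[i])] <-
        (raw - dmin[i]) / (dmax[i] - dmin[i]) * (pmax[i] - pmin[i]) + pmin[i]
    }
  }
  names(out) <- labels
  start_sec <- clock_to_sec(gsub(".", ":", start_time, fixed = TRUE))
  list(channels = out, fs = spr / rec_dur, start_sec = start_sec)
}

#' Read an EDF recording into per-epoch matrices for staging
#'
#' @param path EDF file path with `EEG` and `EMG` channels at a common
#'   sampling rate.
#' @param epoch_s epoch length, seconds (default 4).
#' @return list with `eeg`, `emg` (epochs x samples matrices), `fs`,
#'   `epoch_s`, `start_sec`; trailing samples short of a full epoch are
#'   dropped.
#' @export
read_edf_epochs <- function(path, epoch_s = 4) {
  e <- read_edf(path)
  stopifnot(all(c("EEG", "EMG") %in% names(e$channels)))
  fs <- unname(e$fs[match("EEG", names(e$channels))])
  n_samp <- as.integer(round(fs * epoch_s))
  n_ep <- length(e$channels$EEG) %/% n_samp
  shape <- function(x) {
    matrix(x[seq_len(n_ep * n_samp)], nrow = n_ep, ncol = n_samp,
           byrow = TRUE)
  }
  list(eeg = shape(e$channels$EEG), emg = shape(e$channels$EMG),
       fs = fs, epoch_s = epoch_s, start_sec = e$start_sec)
}
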