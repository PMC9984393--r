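#' Rule set for 4-s epoch sleep staging
#'
#' The scoring rules classify each 4-s epoch from the fraction of time the
#' EEG is dominated by each frequency band, together with EMG amplitude:
#'
#' * WAKE: waveforms above 12 Hz more than 10% of the time, with high EMG;
#' * NREM: 0.5-4 Hz delta waves more than 30% of the time, frequencies
#'   above 12 Hz less than 10% of the time, with low EMG;
#' * REM: 5-10 Hz (theta-range) waves more than 20% of the time, with low
#'   EMG.
#'
#' Rules are applied in the fixed order WAKE, NREM, REM; if none fires the
#' epoch receives `fallback` (default WAKE). "Fraction of the time" is
#' operationalised as the fraction of `subwindow_s` sub-windows whose
#' dominant spectral frequency falls in the band (see
#' [compute_epoch_features()]).
#'
#' @param epoch_s epoch length, seconds (default 4).
#' @param subwindow_s sub-window length for band-dominance fractions
#'   (default 0.5; must divide `epoch_s`).
#' @param delta_band,theta_band Hz intervals (defaults `c(0.5, 4)` and
#'   `c(5, 10)`).
#' @param fast_lo lower edge of the fast band, Hz (default 12; the band is
#'   open-ended above).
#' @param wake_fast_frac fast-dominance fraction above which (with high EMG)
#'   an epoch is WAKE (default 0.10).
#' @param nrem_delta_frac delta-dominance fraction above which an epoch can
#'   be NREM (default 0.30).
#' @param nrem_fast_frac_max fast-dominance fraction that NREM must stay
#'   below (default 0.10).
#' @param rem_theta_frac theta-dominance fraction above which an epoch can
#'   be REM (default 0.20).
#' @param fallback stage assigned when no rule fires (default `"WAKE"`).
#' @return object of class `staging_rules`.
#' @export
staging_rules <- function(epoch_s = 4, subwindow_s = 0.5,
                          delta_band = c(0.5, 4), theta_band = c(5, 10),
                          fast_lo = 12,
                          wake_fast_frac = 0.10, nrem_delta_frac = 0.30,
                          nrem_fast_frac_max = 0.10, rem_theta_frac = 0.20,
                          fallback = "WAKE") {
  stopifnot(epoch_s > 0, subwindow_s > 0,
            abs(epoch_s / subwindow_s - round(epoch_s / subwindow_s)) < 1e-9,
            wake_fast_frac > 0, wake_fast_frac < 1,
            nrem_delta_frac > 0, nrem_delta_frac < 1,
            nrem_fast_frac_max > 0, nrem_fast_frac_max < 1,
            rem_theta_frac > 0, rem_theta_frac < 1,
            fallback %in% STAGES)
  structure(list(epoch_s = epoch_s, subwindow_s = subwindow_s,
                 delta_band = delta_band, theta_band = theta_band,
                 fast_lo = fast_lo,
                 wake_fast_frac = wake_fast_frac,
                 nrem_delta_frac = nrem_delta_frac,
                 nrem_fast_frac_max = nrem_fast_frac_max,
                 rem_theta_frac = rem_theta_frac,
                 fallback = fallback),
            class = "staging_rules")
}

#' Dominant frequency of each sub-window of an epoch
#'
#' Each sub-window is mean-removed, Hann-tapered, zero-padded to `pad_s`
#' seconds (frequency interpolation; at 0.5-s sub-windows the raw resolution
#' of 2 Hz would not resolve the delta band, padding to 2 s gives a 0.5 Hz
#' grid), and the dominant frequency is the argmax of the DFT magnitude
#' over positive frequencies. An all-zero sub-window has no dominant
#' frequency (`NA`).
#'
#' @param x numeric sample vector for one epoch.
#' @param fs sampling rate, Hz.
#' @param subwindow_s sub-window length, seconds.
#' @param pad_s zero-padded length, seconds (default 2).
#' @return numeric vector of dominant frequencies, one per sub-window.
#' @keywords internal
dominant_frequencies <- function(x, fs, subwindow_s, pad_s = 2) {
  m <- as.integer(round(fs * subwindow_s))
  n_sub <- length(x) %/% m
  nfft <- max(as.integer(round(fs * pad_s)), m)
  freqs <- (seq_len(nfft %/% 2)) * fs / nfft
  w <- if (m > 1) 0.5 * (1 - cos(2 * pi * (0:(m - 1)) / (m - 1))) else 1
  vapply(seq_len(n_sub), function(k) {
    seg <- x[((k - 1) * m + 1):(k * m)]
    seg <- (seg - mean(seg)) * w
    if (all(seg == 0)) return(NA_real_)
    spec <- Mod(stats::fft(c(seg, rep(0, nfft - m))))[2:(nfft %/% 2 + 1)]
    freqs[which.max(spec)]
  }, numeric(1))
}

#' Band-dominance features of one epoch
#'
#' @param eeg,emg numeric sample vectors of length `fs * rules$epoch_s`.
#' @param fs sampling rate, Hz.
#' @param rules a [staging_rules()].
#' @param emg_threshold EMG RMS threshold separating high from low muscle
#'   tone (signal units), e.g. from [calibrate_emg_threshold()].
#' @return list of class `epoch_features`: `frac_fast`, `frac_delta`,
#'   `frac_theta` (fractions of sub-windows dominated by each band),
#'   `emg_rms`, and `emg_high`.
#' @examples
#' fs <- 128
#' tt <- (0:(4 * fs - 1)) / fs
#' f <- compute_epoch_features(sin(2 * pi * 2 * tt), rnorm(4 * fs, 0, 0.1),
#'                             fs, staging_rules(), emg_threshold = 1)
#' f$frac_delta
#' @export
compute_epoch_features <- function(eeg, emg, fs, rules = staging_rules(),
                                   emg_threshold) {
  n_expect <- as.integer(round(fs * rules$epoch_s))
  if (length(eeg) != n_expect || length(emg) != n_expect) {
    stop("eeg and emg must each have fs * epoch_s = ", n_expect, " samples")
  }
  dom <- dominant_frequencies(eeg, fs, rules$subwindow_s)
  in_band <- function(f, lo, hi) !is.na(f) & f >= lo & f <= hi
  emg_rms <- sqrt(mean(emg^2))
  structure(list(
    frac_fast = mean(!is.na(dom) & dom > rules$fast_lo),
    frac_delta = mean(in_band(dom, rules$delta_band[1], rules$delta_band[2])),
    frac_theta = mean(in_band(dom, rules$theta_band[1], rules$theta_band[2])),
    emg_rms = emg_rms,
    emg_high = emg_rms > emg_threshold), class = "epoch_features")
}

#' Calibrate the EMG high/low threshold from per-epoch RMS values
#'
#' Splits log RMS values with 2-means (initialised at the sample extremes,
#' so the fit is deterministic) and returns the midpoint of the two cluster
#' centres, back-transformed to signal units. If the values are degenerate
#' (relative range below 1%) there is no high/low structure and the
#' threshold is `+Inf`: every epoch is classified low.
#'
#' @param emg_rms_per_epoch numeric vector of per-epoch EMG RMS values
#'   (length >= 10).
#' @return threshold in signal units (possibly `Inf`).
#' @export
calibrate_emg_threshold <- function(emg_rms_per_epoch) {
  x <- emg_rms_per_epoch
  if (length(x) == 0) stop("no EMG RMS values supplied")
  if (length(x) < 10) stop("need at least 10 epochs to calibrate")
  if (any(x < 0)) stop("RMS values must be non-negative")
  if ((max(x) - min(x)) <= 0.01 * mean(x)) return(Inf)
  lx <- log(pmax(x, .Machine$double.xmin))
  km <- stats::kmeans(lx, centers = matrix(c(min(lx), max(lx))))
  exp(mean(km$centers))
}

#' Stage one epoch from its features
#'
#' Applies the rules in the fixed precedence WAKE, NREM, REM (see
#' [staging_rules()]); returns the fallback stage when none fires.
#'
#' @param f an `epoch_features` list.
#' @param rules a [staging_rules()].
#' @return stage label, one of `"WAKE"`, `"NREM"`, `"REM"`.
#' @export
stage_epoch <- function(f, rules = staging_rules()) {
  if (f$frac_fast > rules$wake_fast_frac && f$emg_high) return("WAKE")
  if (f$frac_delta > rules$nrem_delta_frac &&
      f$frac_fast < rules$nrem_fast_frac_max && !f$emg_high) return("NREM")
  if (f$frac_theta > rules$rem_theta_frac && !f$emg_high) return("REM")
  rules$fallback
}

#' Stage a whole recording
#'
#' Calibrates the EMG threshold on the full recording, computes per-epoch
#' band-dominance features, and stages every epoch.
#'
#' @param signals list with `eeg` and `emg` matrices (one row per epoch) and
#'   `fs`, as produced by [synthesize_signals()] or [read_edf_epochs()].
#' @param rules a [staging_rules()].
#' @param start_sec clock anchor of the first epoch (seconds after
#'   midnight; default 07:00).
#' @return a [hypnogram()] with one label per input epoch.
#' @export
stage_recording <- function(signals, rules = staging_rules(),
                            start_sec = 7 * 3600) {
  eeg <- signals$eeg; emg <- signals$emg; fs <- signals$fs
  stopifnot(is.matrix(eeg), is.matrix(emg), all(dim(eeg) == dim(emg)))
  if (nrow(eeg) < 10) stop("need at least 10 epochs to stage a recording")
  rms <- sqrt(rowMeans(emg^2))
  thr <- calibrate_emg_threshold(rms)
  stages <- vapply(seq_len(nrow(eeg)), function(i) {
    stage_epoch(compute_epoch_features(eeg[i, ], emg[i, ], fs, rules, thr),
                rules)
  }, character(1))
  hypnogram(stages, epoch_s = rules$epoch_s, start_sec = start_sec)
}

#' Optional majority smoothing of a hypnogram
#'
#' Off by default in the pipeline; replaces each label by the majority of a
#' centred window of `width` epochs (ties keep the original label).
#'
#' @param h a [hypnogram()].
#' @param width odd window width in epochs (default 3).
#' @return smoothed [hypnogram()].
#' @export
smooth_hypnogram <- function(h, width = 3) {
  stopifnot(inherits(h, "hypnogram"), width %% 2 == 1, width >= 1)
  if (width == 1 || length(h) < width) return(h)
  half <- width %/% 2
  lab <- as.character(h)
  out <- lab
  for (i in seq_along(lab)) {
    win <- lab[max(1, i - half):min(length(lab), i + half)]
    tab <- table(win)
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1) out[i] <- top
  }
  hypnogram(out, epoch_s = attr(h, "epoch_s"),
            start_sec = attr(h, "start_sec"))
}
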