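#' Parameters for state-conditioned EEG/EMG synthesis
#'
#' Each epoch's EEG is a stage-specific dominant sinusoid (frequency drawn
#' uniformly within the stage's band, random phase) plus broadband Gaussian
#' noise; the EMG is zero-mean Gaussian noise at the stage's RMS amplitude
#' (high in wake, atonic in NREM and REM). This tonal model is deliberately
#' minimal: it realises the band-dominance structure the staging rules read
#' (delta-dominant NREM, theta-dominant REM, fast-dominant wake) without
#' 1/f background or spindles.
#'
#' @param fs sampling rate in Hz (default 256; must be at least 64 so that
#'   >12 Hz wake content is resolvable below Nyquist).
#' @param eeg_bands named list of `c(lo, hi)` Hz intervals from which each
#'   stage's dominant frequency is drawn.
#' @param eeg_amps named numeric: dominant-sinusoid amplitude per stage
#'   (arbitrary signal units).
#' @param noise_amp standard deviation of the broadband EEG noise.
#' @param emg_rms named numeric: EMG RMS per stage; wake must exceed both
#'   sleep states (sleep atonia).
#' @param seed integer seed or `NULL`.
#' @return object of class `signal_params`.
#' @export
signal_params <- function(fs = 256,
                          eeg_bands = list(WAKE = c(13, 24),
                                           NREM = c(1.5, 3.5),
                                           REM = c(5.5, 9.5)),
                          eeg_amps = c(WAKE = 1, NREM = 1.5, REM = 1),
                          noise_amp = 0.1,
                          emg_rms = c(WAKE = 1, NREM = 0.1, REM = 0.05),
                          seed = NULL) {
  stopifnot(fs >= 64, noise_amp >= 0, all(eeg_amps >= 0), all(emg_rms >= 0))
  stopifnot(all(STAGES %in% names(eeg_bands)),
            all(STAGES %in% names(eeg_amps)),
            all(STAGES %in% names(emg_rms)))
  if (!(emg_rms[["WAKE"]] > emg_rms[["NREM"]] &&
        emg_rms[["WAKE"]] > emg_rms[["REM"]])) {
    stop("WAKE EMG RMS must exceed NREM and REM EMG RMS")
  }
  structure(list(fs = fs, eeg_bands = eeg_bands, eeg_amps = eeg_amps,
                 noise_amp = noise_amp, emg_rms = emg_rms, seed = seed),
            class = "signal_params")
}

#' Synthesize per-epoch EEG and EMG from a hypnogram
#'
#' @param h a [hypnogram()].
#' @param params a [signal_params()]; `fs * epoch_s` must be an integer.
#' @return list with `eeg` and `emg` (matrices, one row per epoch,
#'   `fs * epoch_s` columns), `fs`, and `epoch_s`.
#' @examples
#' h <- hypnogram(rep(c("NREM", "WAKE"), each = 5))
#' sig <- synthesize_signals(h, signal_params(seed = 1))
#' dim(sig$eeg)
#' @export
synthesize_signals <- function(h, params = signal_params()) {
  stopifnot(inherits(h, "hypnogram"), inherits(params, "signal_params"))
  if (length(h) == 0) stop("hypnogram is empty")
  epoch_s <- attr(h, "epoch_s")
  n_samp <- params$fs * epoch_s
  if (abs(n_samp - round(n_samp)) > 1e-9) {
    stop("fs * epoch_s must be an integer number of samples")
  }
  n_samp <- as.integer(round(n_samp))
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- length(h)
  tt <- (seq_len(n_samp) - 1) / params$fs
  eeg <- matrix(0, n, n_samp)
  emg <- matrix(0, n, n_samp)
  for (i in seq_len(n)) {
    st <- as.character(h[i])
    band <- params$eeg_bands[[st]]
    f <- stats::runif(1, band[1], band[2])
    ph <- stats::runif(1, 0, 2 * pi)
    eeg[i, ] <- params$eeg_amps[[st]] * sin(2 * pi * f * tt + ph)
    if (params$noise_amp > 0) {
      eeg[i, ] <- eeg[i, ] + stats::rnorm(n_samp, 0, params$noise_amp)
    }
    emg[i, ] <- stats::rnorm(n_samp, 0, params$emg_rms[[st]])
  }
  list(eeg = eeg, emg = emg, fs = params$fs, epoch_s = epoch_s)
}

#' Parameters for PIR activity-trace simulation
#'
#' @param bin_s bin length in seconds (default 10, the native PIR bin).
#' @param false_movement_prob probability that a sleep bin registers a small
#'   nonzero movement score (sensor noise, twitches); default 0.005.
#' @param wake_score_range range of the uniform distribution of wake-bin
#'   activity scores, within \[0, 100\] (default `c(20, 100)`).
#' @param false_movement_range score range for spurious movement in sleep
#'   bins (default `c(1, 10)`).
#' @param seed integer seed or `NULL`.
#' @return object of class `pir_params`.
#' @export
pir_params <- function(bin_s = 10, false_movement_prob = 0.005,
                       wake_score_range = c(20, 100),
                       false_movement_range = c(1, 10),
                       seed = NULL) {
  stopifnot(bin_s > 0,
            false_movement_prob >= 0, false_movement_prob <= 1,
            wake_score_range[1] >= 0, wake_score_range[2] <= 100,
            wake_score_range[1] <= wake_score_range[2],
            false_movement_range[1] > 0, false_movement_range[2] <= 100)
  structure(list(bin_s = bin_s, false_movement_prob = false_movement_prob,
                 wake_score_range = wake_score_range,
                 false_movement_range = false_movement_range, seed = seed),
            class = "pir_params")
}

#' Per-bin sleep/wake state of a hypnogram on the PIR bin grid
#'
#' Each `bin_s` bin is classed sleep or wake by majority vote over the
#' hypnogram epochs it overlaps (an epoch counts if it intersects the bin);
#' ties go to wake, so bin mapping never invents sleep.
#'
#' @param h a [hypnogram()].
#' @param bin_s bin length in seconds.
#' @return logical vector, `TRUE` where the bin is asleep (NREM or REM).
#' @export
bin_sleep_state <- function(h, bin_s = 10) {
  stopifnot(inherits(h, "hypnogram"))
  epoch_s <- attr(h, "epoch_s")
  stopifnot(bin_s > 0)
  total_s <- length(h) * epoch_s
  n_bins <- floor(total_s / bin_s)
  if (n_bins < 1) stop("hypnogram shorter than one bin")
  asleep <- as.character(h) != "WAKE"
  vapply(seq_len(n_bins), function(b) {
    lo <- (b - 1) * bin_s
    hi <- b * bin_s
    idx <- seq(floor(lo / epoch_s) + 1, ceiling(hi / epoch_s))
    idx <- idx[idx <= length(h)]
    sum(asleep[idx]) > length(idx) / 2
  }, logical(1))
}

#' Simulate a PIR activity trace from a hypnogram
#'
#' Sleep bins score 0 except with probability `false_movement_prob`, when a
#' small positive score is drawn; wake bins draw integer scores from the
#' wake distribution. The true per-bin sleep state is attached so COMPASS
#' scoring can be validated against ground truth.
#'
#' @param h a [hypnogram()].
#' @param params a [pir_params()].
#' @return data frame of class `activity_trace` with columns `bin_index`,
#'   `clock_time`, `score` (integer 0-100) and `true_sleep` (logical);
#'   attributes `bin_s` and `start_sec`.
#' @examples
#' h <- hypnogram(rep(c("WAKE", "NREM"), each = 450))
#' tr <- simulate_activity_trace(h, pir_params(seed = 1))
#' head(tr)
#' @export
simulate_activity_trace <- function(h, params = pir_params()) {
  stopifnot(inherits(h, "hypnogram"), inherits(params, "pir_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  sleep <- bin_sleep_state(h, params$bin_s)
  n <- length(sleep)
  score <- integer(n)
  wake_idx <- which(!sleep)
  score[wake_idx] <- round(stats::runif(length(wake_idx),
                                        params$wake_score_range[1],
                                        params$wake_score_range[2]))
  fm <- which(sleep & stats::runif(n) < params$false_movement_prob)
  score[fm] <- round(stats::runif(length(fm),
                                  params$false_movement_range[1],
                                  params$false_movement_range[2]))
  start_sec <- attr(h, "start_sec")
  out <- data.frame(
    bin_index = seq_len(n),
    clock_time = format_clock((start_sec + (seq_len(n) - 1) * params$bin_s)),
    score = score,
    true_sleep = sleep,
    stringsAsFactors = FALSE)
  structure(out, bin_s = params$bin_s, start_sec = start_sec,
            class = c("activity_trace", "data.frame"))
}

#' Read/write activity traces as CSV
#'
#' @param trace an `activity_trace` data frame (or any data frame with
#'   columns `bin_index`, `clock_time`, `score`).
#' @param path file path.
#' @param bin_s bin length in seconds assumed on read.
#' @return `write_activity_trace` returns `path` invisibly;
#'   `read_activity_trace` returns an `activity_trace`.
#' @export
write_activity_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace)[
    intersect(c("bin_index", "clock_time", "score", "true_sleep"),
              names(trace))], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_activity_trace
#' @export
read_activity_trace <- function(path, bin_s = 10) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  start_sec <- clock_to_sec(d$clock_time[1])
  structure(d, bin_s = bin_s, start_sec = start_sec,
            class = c("activity_trace", "data.frame"))
}
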