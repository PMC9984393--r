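#' Score sleep from a PIR activity trace
#'
#' Extended behavioural inactivity is converted into sleep: maximal runs of
#' consecutive zero-score bins lasting at least `min_sleep_s` (40 s, i.e. 4
#' bins at the native 10-s resolution) are marked asleep; every other bin is
#' awake. Only exact-zero scores count as inactivity. In strict mode the run
#' must exceed 40 s instead (>= 5 bins at 10 s).
#'
#' @param trace an `activity_trace` data frame (column `score`) or a bare
#'   numeric score vector in \[0, 100\].
#' @param bin_s bin length in seconds (taken from the trace attribute when
#'   present; default 10).
#' @param min_sleep_s minimum inactivity duration counted as sleep
#'   (default 40 s).
#' @param strict if `TRUE`, require runs strictly longer than `min_sleep_s`.
#' @return logical vector, one element per bin, `TRUE` = sleep.
#' @examples
#' score_sleep(c(5, 0, 0, 0, 0, 0, 7))
#' @export
score_sleep <- function(trace, bin_s = NULL, min_sleep_s = 40,
                        strict = FALSE) {
  scores <- if (is.data.frame(trace)) trace$score else trace
  if (is.null(bin_s)) bin_s <- attr(trace, "bin_s") %||% 10
  if (length(scores) == 0) return(logical(0))
  if (any(scores < 0 | scores > 100)) {
    stop("activity scores must lie in [0, 100]")
  }
  r <- rle(scores == 0)
  long_enough <- if (strict) r$lengths * bin_s > min_sleep_s else
    r$lengths * bin_s >= min_sleep_s
  inverse.rle(list(lengths = r$lengths, values = r$values & long_enough))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Identify sleep bouts
#'
#' One bout per maximal run of sleep bins; bouts are never merged across
#' intervening wake bins.
#'
#' @param sleep_vector logical per-bin sleep vector, e.g. from
#'   [score_sleep()].
#' @param bin_s bin length in seconds (default 10).
#' @return data frame with one row per bout: `start_bin` (1-based index),
#'   `n_bins`, `duration_s`.
#' @export
detect_bouts <- function(sleep_vector, bin_s = 10) {
  stopifnot(is.logical(sleep_vector))
  r <- rle(sleep_vector)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  idx <- which(r$values)
  data.frame(start_bin = starts[idx],
             n_bins = r$lengths[idx],
             duration_s = r$lengths[idx] * bin_s)
}

#' Summary statistics of sleep bouts
#'
#' @param bouts bout data frame from [detect_bouts()] (possibly empty).
#' @return list of class `bout_stats`: `bout_count`, `mean_bout_s`,
#'   `max_bout_s`, `total_sleep_min`. With no bouts all fields are 0.
#' @export
bout_statistics <- function(bouts) {
  if (nrow(bouts) == 0) {
    return(structure(list(bout_count = 0L, mean_bout_s = 0,
                          max_bout_s = 0, total_sleep_min = 0),
                     class = "bout_stats"))
  }
  structure(list(bout_count = nrow(bouts),
                 mean_bout_s = mean(bouts$duration_s),
                 max_bout_s = max(bouts$duration_s),
                 total_sleep_min = sum(bouts$duration_s) / 60),
            class = "bout_stats")
}

#' @export
print.bout_stats <- function(x, ...) {
  cat(sprintf("%d sleep bouts: mean %.1f s, max %.0f s, total %.1f min\n",
              x$bout_count, x$mean_bout_s, x$max_bout_s, x$total_sleep_min))
  invisible(x)
}

#' Pearson validation of scored sleep against ground truth
#'
#' Product-moment correlation between the scored and true per-bin sleep
#' indicators. PIR scoring is considered valid when r exceeds 0.95 against
#' EEG/EMG-defined sleep.
#'
#' @param sleep_vector,truth_vector equal-length logical (or 0/1) vectors,
#'   length >= 2, neither constant.
#' @return Pearson correlation coefficient.
#' @export
validate_against_truth <- function(sleep_vector, truth_vector) {
  x <- as.numeric(sleep_vector); y <- as.numeric(truth_vector)
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (length(x) < 2) stop("need at least 2 bins")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Pearson correlation undefined for a constant vector")
  }
  stats::cor(x, y)
}
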