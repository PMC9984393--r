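#' Sleep stage labels
#'
#' The closed set of vigilance states used throughout the package.
#' @keywords internal
STAGES <- c("WAKE", "NREM", "REM")

#' Construct a hypnogram
#'
#' A hypnogram is an ordered sequence of vigilance-stage labels
#' (WAKE/NREM/REM) at a fixed epoch resolution, anchored to clock time so
#' that circadian summaries (hourly, light/dark) are well defined.
#'
#' @param stages character or factor vector of stage labels, each one of
#'   `"WAKE"`, `"NREM"`, `"REM"`.
#' @param epoch_s epoch length in seconds (default 4, the standard rodent
#'   scoring epoch).
#' @param start_sec clock time of the first epoch's start, in seconds after
#'   midnight (default `7 * 3600`, i.e. 07:00, lights-on in a standard
#'   12:12 cycle).
#' @return an object of class `hypnogram`: a factor with levels
#'   WAKE/NREM/REM and attributes `epoch_s` and `start_sec`.
#' @examples
#' h <- hypnogram(c("WAKE", "WAKE", "NREM", "NREM", "REM"))
#' epoch_clock_sec(h)
#' @export
hypnogram <- function(stages, epoch_s = 4, start_sec = 7 * 3600) {
  stages <- as.character(stages)
  bad <- setdiff(unique(stages), STAGES)
  if (length(bad) > 0) {
    stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  }
  if (!is.numeric(epoch_s) || length(epoch_s) != 1 || epoch_s <= 0) {
    stop("epoch_s must be a single positive number")
  }
  if (start_sec < 0 || start_sec >= 86400) {
    stop("start_sec must lie in [0, 86400)")
  }
  structure(factor(stages, levels = STAGES),
            epoch_s = epoch_s, start_sec = start_sec,
            class = c("hypnogram", "factor"))
}

#' @export
print.hypnogram <- function(x, ...) {
  n <- length(x)
  cat(sprintf("<hypnogram> %d epochs x %gs (%.2f h), start %s\n",
              n, attr(x, "epoch_s"), n * attr(x, "epoch_s") / 3600,
              format_clock(attr(x, "start_sec"))))
  print(table(factor(x, levels = STAGES)))
  invisible(x)
}

#' @export
`[.hypnogram` <- function(x, i, ...) {
  out <- NextMethod()
  attributes(out) <- c(attributes(out),
                       attributes(x)[c("epoch_s", "start_sec")])
  class(out) <- class(x)
  out
}

#' Clock time (seconds after midnight) of each epoch start
#'
#' @param h a [hypnogram()].
#' @return numeric vector, one value per epoch, wrapped modulo 24 h.
#' @export
epoch_clock_sec <- function(h) {
  stopifnot(inherits(h, "hypnogram"))
  (attr(h, "start_sec") + (seq_along(h) - 1) * attr(h, "epoch_s")) %% 86400
}

format_clock <- function(sec) {
  sec <- round(sec) %% 86400
  sprintf("%02d:%02d:%02d", sec %/% 3600, (sec %% 3600) %/% 60, sec %% 60)
}

#' Convert a hypnogram to a data frame
#'
#' @param x a [hypnogram()].
#' @param ... unused.
#' @return data frame with columns `epoch_index` (1-based), `clock_time`
#'   (HH:MM:SS) and `stage`.
#' @export
as.data.frame.hypnogram <- function(x, ...) {
  data.frame(epoch_index = seq_along(x),
             clock_time = format_clock(epoch_clock_sec(x)),
             stage = as.character(x),
             stringsAsFactors = FALSE)
}

#' Read/write hypnograms as TSV
#'
#' The on-disk form is a three-column TSV (`epoch_index`, `clock_time`,
#' `stage`); `epoch_s` and the start time are recovered from the clock-time
#' column on read.
#'
#' @param h a [hypnogram()].
#' @param path file path.
#' @return `write_hypnogram` returns `path` invisibly; `read_hypnogram`
#'   returns a [hypnogram()].
#' @export
write_hypnogram <- function(h, path) {
  utils::write.table(as.data.frame(h), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram
#' @export
read_hypnogram <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = c("integer", "character", "character"))
  secs <- clock_to_sec(d$clock_time)
  epoch_s <- if (nrow(d) > 1) (secs[2] - secs[1]) %% 86400 else 4
  hypnogram(d$stage, epoch_s = epoch_s, start_sec = secs[1])
}

clock_to_sec <- function(s) {
  p <- do.call(rbind, strsplit(s, ":", fixed = TRUE))
  as.numeric(p[, 1]) * 3600 + as.numeric(p[, 2]) * 60 + as.numeric(p[, 3])
}

#' Light/dark cycle definition
#'
#' @param lights_on_hour clock hour (0-23) when lights come on (default 7).
#' @param lights_off_hour clock hour (0-23) when lights go off (default 19);
#'   the defaults encode the standard 12:12 cycle with lights on 0700-1900.
#' @return object of class `light_cycle`.
#' @export
light_cycle <- function(lights_on_hour = 7, lights_off_hour = 19) {
  stopifnot(lights_on_hour %in% 0:23, lights_off_hour %in% 0:23)
  if (lights_on_hour == lights_off_hour) {
    stop("lights_on_hour and lights_off_hour must differ")
  }
  structure(list(lights_on_hour = lights_on_hour,
                 lights_off_hour = lights_off_hour),
            class = "light_cycle")
}

#' Is a clock hour in the light phase?
#'
#' The light phase is the half-open interval `[lights_on, lights_off)`,
#' wrapping over midnight when needed.
#'
#' @param hour integer clock hour(s), 0-23.
#' @param lc a [light_cycle()].
#' @return logical vector.
#' @export
is_light <- function(hour, lc = light_cycle()) {
  stopifnot(inherits(lc, "light_cycle"))
  on <- lc$lights_on_hour; off <- lc$lights_off_hour
  if (on < off) hour >= on & hour < off else hour >= on | hour < off
}

#' Zeitgeber hour of a clock hour
#'
#' ZT0 is lights-on; ZT12 is lights-off in a 12:12 cycle.
#'
#' @inheritParams is_light
#' @return integer vector of ZT hours, 0-23.
#' @export
zt_hour <- function(hour, lc = light_cycle()) {
  (hour - lc$lights_on_hour) %% 24
}
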