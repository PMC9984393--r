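#' Minutes per stage per hour
#'
#' Buckets a hypnogram's epochs into consecutive clock hours and reports
#' minutes spent in each stage per hour. With 4-s epochs no epoch can
#' straddle an hour boundary (4 divides 3600); this is asserted for other
#' epoch lengths. Hours with incomplete coverage (a partial first or last
#' hour) are flagged.
#'
#' @param h a [hypnogram()].
#' @param lc a [light_cycle()] used to attach ZT hours.
#' @return data frame (long form), one row per hour x stage: `hour`
#'   (sequential, 1-based from the recording start), `clock_hour` (0-23),
#'   `zt_hour` (0-23, ZT0 = lights-on), `stage`, `minutes`, `coverage_min`
#'   (minutes of recording covering that hour), `complete` (coverage == 60).
#' @examples
#' h <- hypnogram(rep("WAKE", 900))  # one hour of 4-s epochs
#' minutes_per_hour(h)
#' @export
minutes_per_hour <- function(h, lc = light_cycle()) {
  stopifnot(inherits(h, "hypnogram"))
  epoch_s <- attr(h, "epoch_s")
  start_sec <- attr(h, "start_sec")
  elapsed <- (seq_along(h) - 1) * epoch_s
  # an epoch straddling an hour boundary would make hourly bucketing lossy;
  # cannot occur at the default 4 s (4 divides 3600), asserted for the rest
  offset <- (start_sec + elapsed) %% 3600
  if (any(offset + epoch_s > 3600 + 1e-9 & offset > 1e-9)) {
    stop("epoch grid does not tile hour boundaries")
  }
  hour_seq <- ((start_sec + elapsed) %/% 3600) - (start_sec %/% 3600) + 1
  clock_hour <- ((start_sec + elapsed) %/% 3600) %% 24
  tab <- table(hour = hour_seq, stage = factor(h, levels = STAGES))
  hours <- as.integer(rownames(tab))
  ch <- vapply(hours, function(hh) clock_hour[match(hh, hour_seq)], numeric(1))
  cov_min <- rowSums(tab) * epoch_s / 60
  out <- data.frame(
    hour = rep(hours, times = 3),
    clock_hour = rep(ch, times = 3),
    zt_hour = rep(zt_hour(ch, lc), times = 3),
    stage = rep(STAGES, each = length(hours)),
    minutes = c(tab[, "WAKE"], tab[, "NREM"], tab[, "REM"]) * epoch_s / 60,
    coverage_min = rep(cov_min, times = 3))
  out$complete <- abs(out$coverage_min - 60) < 1e-9
  out[order(out$hour, match(out$stage, STAGES)), , drop = FALSE]
}

#' Aggregate an hourly summary into 12-h light/dark totals
#'
#' Sums per-hour stage minutes over the light phase (`[lights_on,
#' lights_off)`) and its complement. If the summary does not cover a full
#' 24-h day the totals are still returned, with `complete = FALSE`.
#'
#' @param hourly data frame from [minutes_per_hour()].
#' @param lc a [light_cycle()].
#' @return data frame, one row per phase x stage: `phase` (`"light"` /
#'   `"dark"`), `stage`, `minutes`, `coverage_min`, `complete`.
#' @export
aggregate_light_dark <- function(hourly, lc = light_cycle()) {
  phase <- ifelse(is_light(hourly$clock_hour, lc), "light", "dark")
  agg <- stats::aggregate(hourly$minutes,
                          by = list(phase = phase, stage = hourly$stage),
                          FUN = sum)
  names(agg)[3] <- "minutes"
  cov <- stats::aggregate(hourly$coverage_min,
                          by = list(phase = phase, stage = hourly$stage),
                          FUN = sum)
  agg$coverage_min <- cov$x
  agg$complete <- abs(agg$coverage_min - 720) < 1e-9
  agg <- agg[order(factor(agg$phase, levels = c("light", "dark")),
                   match(agg$stage, STAGES)), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Hourly sleep/wake minutes from a PIR sleep vector
#'
#' COMPASS analogue of [minutes_per_hour()]: buckets a per-bin sleep vector
#' into clock hours.
#'
#' @param sleep_vector logical per-bin sleep vector.
#' @param bin_s bin length in seconds (default 10).
#' @param start_sec clock time of the first bin (default 07:00).
#' @param lc a [light_cycle()].
#' @return data frame as in [minutes_per_hour()] with stages `"WAKE"` and
#'   `"SLEEP"`.
#' @export
sleep_minutes_per_hour <- function(sleep_vector, bin_s = 10,
                                   start_sec = 7 * 3600,
                                   lc = light_cycle()) {
  stopifnot(is.logical(sleep_vector), 3600 %% bin_s == 0)
  elapsed <- (seq_along(sleep_vector) - 1) * bin_s
  hour_seq <- ((start_sec + elapsed) %/% 3600) - (start_sec %/% 3600) + 1
  clock_hour <- ((start_sec + elapsed) %/% 3600) %% 24
  lab <- ifelse(sleep_vector, "SLEEP", "WAKE")
  tab <- table(hour = hour_seq, stage = factor(lab, c("WAKE", "SLEEP")))
  hours <- as.integer(rownames(tab))
  ch <- vapply(hours, function(hh) clock_hour[match(hh, hour_seq)], numeric(1))
  cov_min <- rowSums(tab) * bin_s / 60
  out <- data.frame(
    hour = rep(hours, times = 2),
    clock_hour = rep(ch, times = 2),
    zt_hour = rep(zt_hour(ch, lc), times = 2),
    stage = rep(c("WAKE", "SLEEP"), each = length(hours)),
    minutes = c(tab[, "WAKE"], tab[, "SLEEP"]) * bin_s / 60,
    coverage_min = rep(cov_min, times = 2))
  out$complete <- abs(out$coverage_min - 60) < 1e-9
  out[order(out$hour), , drop = FALSE]
}

#' Drinking-water drug dose
#'
#' Daily dose from volume drunk, drug concentration, and body weight:
#' `volume_ml * concentration_mg_per_ml / (body_weight_g / 1000)`. A mouse
#' drinking 5 mL/day of 0.5 mg/mL morphine at 25 g body weight receives
#' 100 mg/kg/day.
#'
#' @param volume_ml_per_day volume drunk per day, mL (>= 0).
#' @param concentration_mg_per_ml drug concentration, mg/mL (>= 0).
#' @param body_weight_g body weight, g (> 0).
#' @return dose in mg per kg body weight per day.
#' @examples
#' dose_from_intake(5, 0.5, 25)  # 100
#' @export
dose_from_intake <- function(volume_ml_per_day, concentration_mg_per_ml,
                             body_weight_g) {
  if (any(volume_ml_per_day < 0) || any(concentration_mg_per_ml < 0)) {
    stop("volume and concentration must be non-negative")
  }
  if (any(body_weight_g <= 0)) {
    stop("body_weight_g must be positive")
  }
  volume_ml_per_day * concentration_mg_per_ml / (body_weight_g / 1000)
}
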