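# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the code paths they verify.

# Run-length sleep oracle: mark every maximal zero run lasting >= min_s.
rle_sleep_oracle <- function(scores, bin_s = 10, min_s = 40) {
  n <- length(scores)
  out <- rep(FALSE, n)
  i <- 1
  while (i <= n) {
    if (scores[i] == 0) {
      j <- i
      while (j < n && scores[j + 1] == 0) j <- j + 1
      if ((j - i + 1) * bin_s >= min_s) out[i:j] <- TRUE
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  out
}

# Cell-by-cell split-plot sums-of-squares decomposition (equal or unequal
# group sizes, complete within animal), with F ratios.
ss_oracle <- function(values, group) {
  group <- factor(group)
  n <- nrow(values); tp <- ncol(values)
  gm <- mean(values)
  subj_mean <- rowMeans(values)
  time_mean <- colMeans(values)
  ss_total <- sum((values - gm)^2)
  ss_between_subj <- tp * sum((subj_mean - gm)^2)
  grp_mean <- tapply(subj_mean, group, mean)
  ng <- table(group)
  ss_group <- tp * sum(ng * (grp_mean - gm)^2)
  ss_subj <- ss_between_subj - ss_group
  ss_time <- n * sum((time_mean - gm)^2)
  cell_mean <- matrix(0, nlevels(group), tp)
  for (g in seq_len(nlevels(group))) {
    cell_mean[g, ] <- colMeans(values[group == levels(group)[g], ,
                                      drop = FALSE])
  }
  ss_cells <- sum(rep(ng, times = tp) * (cell_mean - gm)^2)
  ss_inter <- ss_cells - ss_group - ss_time
  ss_resid <- ss_total - ss_between_subj - ss_time - ss_inter
  k <- nlevels(group)
  df_g <- k - 1; df_s <- n - k
  df_t <- tp - 1; df_i <- df_g * df_t; df_r <- df_s * df_t
  list(ss = c(group = ss_group, subject = ss_subj, time = ss_time,
              interaction = ss_inter, residual = ss_resid,
              total = ss_total),
       F_group = (ss_group / df_g) / (ss_subj / df_s),
       F_time = (ss_time / df_t) / (ss_resid / df_r),
       F_interaction = (ss_inter / df_i) / (ss_resid / df_r))
}

# Textbook pooled-variance two-sample t.
pooled_t_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Globally optimal 1-D 2-means by enumerating every split of the sorted
# sample; returns the two cluster centres.
brute_2means_oracle <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  best <- NULL; best_ss <- Inf
  for (k in 1:(n - 1)) {
    c1 <- mean(xs[1:k]); c2 <- mean(xs[(k + 1):n])
    ss <- sum((xs[1:k] - c1)^2) + sum((xs[(k + 1):n] - c2)^2)
    if (ss < best_ss) { best_ss <- ss; best <- c(c1, c2) }
  }
  best
}

# Dominant frequency per sub-window by explicit DFT sums over the padded
# frequency grid (no fft call).
dominant_freq_oracle <- function(x, fs, subwindow_s = 0.5, pad_s = 2) {
  m <- round(fs * subwindow_s)
  nfft <- round(fs * pad_s)
  freqs <- (seq_len(nfft %/% 2)) * fs / nfft
  w <- 0.5 * (1 - cos(2 * pi * (0:(m - 1)) / (m - 1)))
  tt <- 0:(m - 1)
  vapply(seq_len(length(x) %/% m), function(k) {
    seg <- x[((k - 1) * m + 1):(k * m)]
    seg <- (seg - mean(seg)) * w
    if (all(seg == 0)) return(NA_real_)
    mag <- vapply(freqs, function(f) {
      Mod(sum(seg * exp(-2i * pi * f * tt / fs)))
    }, numeric(1))
    freqs[which.max(mag)]
  }, numeric(1))
}

# Per-hour per-stage minute tally by looping over epochs.
hour_tally_oracle <- function(h) {
  epoch_s <- attr(h, "epoch_s"); start <- attr(h, "start_sec")
  tal <- list()
  for (i in seq_along(h)) {
    hr <- ((start + (i - 1) * epoch_s) %/% 3600) - (start %/% 3600) + 1
    key <- paste(hr, as.character(h[i]))
    tal[[key]] <- (tal[[key]] %||% 0) + epoch_s / 60
  }
  tal
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A pure tone epoch of the given frequency.
tone_epoch <- function(freq, fs = 128, epoch_s = 4, amp = 1, phase = 0) {
  tt <- (0:(fs * epoch_s - 1)) / fs
  amp * sin(2 * pi * freq * tt + phase)
}
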