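test_that("pooled t-test reproduces hand-computed values", {
  r <- unpaired_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t, -3.674235, tolerance = 1e-6)
  expect_equal(r$df, 4)
  identical_r <- unpaired_t_test(c(2, 2, 3), c(2, 2, 3))
  expect_equal(identical_r$t, 0)
  expect_equal(identical_r$p, 1)
})

test_that("pooled t-test matches the textbook formula on random samples", {
  set.seed(51)
  for (i in 1:50) {
    x <- rnorm(sample(3:12, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(3:12, 1), mean = runif(1, -1, 1))
    r <- unpaired_t_test(x, y)
    o <- pooled_t_oracle(x, y)
    expect_equal(r$t, o$t, tolerance = 1e-10)
    expect_equal(r$df, o$df)
    expect_equal(r$p, o$p, tolerance = 1e-10)
  }
})

test_that("degenerate and undersized samples are signalled", {
  expect_equal(unpaired_t_test(c(1, 1, 1), c(1, 1))$t, 0)
  expect_error(unpaired_t_test(c(1, 1), c(2, 2)), "degenerate")
  expect_error(unpaired_t_test(1, c(1, 2)), "n >= 2")
})

test_that("one-sided and Welch variants are available", {
  x <- c(1, 2, 3, 4); y <- c(3, 4, 5, 7)
  two <- unpaired_t_test(x, y)
  less <- unpaired_t_test(x, y, alternative = "less")
  expect_equal(less$p, two$p / 2)
  w <- unpaired_t_test(x, y, welch = TRUE)
  expect_lt(w$df, two$df)  # Welch df shrink under unequal variances
})

test_that("identical constant groups give zero F for group and interaction", {
  m <- matrix(5, nrow = 6, ncol = 4)
  r <- mixed_anova(m, rep(c("ctl", "mor"), each = 3))
  expect_equal(r$F_group, 0)
  expect_equal(r$F_interaction, 0)
  expect_equal(r$p_group, 1)
})

test_that("split-plot F statistics equal the brute-force SS oracle", {
  # hand-constructed small design plus random balanced designs
  vals <- matrix(c(1, 2, 2, 3, 4, 6,
                   2, 3, 4, 6, 7, 9), nrow = 6)
  group <- rep(c("a", "b"), each = 3)
  r <- mixed_anova(vals, group)
  o <- ss_oracle(vals, group)
  expect_equal(r$F_group, o$F_group, tolerance = 1e-8)
  expect_equal(r$F_time, o$F_time, tolerance = 1e-8)
  expect_equal(r$F_interaction, o$F_interaction, tolerance = 1e-8)

  set.seed(61)
  for (i in 1:20) {
    n_per <- sample(3:6, 1); tp <- sample(2:8, 1)
    g <- rep(c("a", "b"), each = n_per)
    m <- matrix(rnorm(2 * n_per * tp, mean = rep(as.numeric(factor(g)),
                                                 times = tp)),
                nrow = 2 * n_per)
    r <- mixed_anova(m, g)
    o <- ss_oracle(m, g)
    expect_equal(r$F_group, o$F_group, tolerance = 1e-8)
    expect_equal(r$F_time, o$F_time, tolerance = 1e-8)
    expect_equal(r$F_interaction, o$F_interaction, tolerance = 1e-8)
    # conservation: SS components account for the total SS
    expect_equal(sum(r$ss), o$ss[["total"]], tolerance = 1e-8)
  }
})

test_that("unequal group sizes use the standard split-plot df", {
  set.seed(62)
  m <- matrix(rnorm(13 * 12), nrow = 13)
  r <- mixed_anova(m, rep(c("a", "b"), c(6, 7)))
  expect_equal(r$df_group, c(1, 11))
  o <- ss_oracle(m, rep(c("a", "b"), c(6, 7)))
  expect_equal(r$F_group, o$F_group, tolerance = 1e-8)
})

test_that("invalid designs are rejected", {
  m <- matrix(rnorm(12), nrow = 4)
  expect_error(mixed_anova(m, c("a", "a", "a", "b")), "2 animals per group")
  expect_error(mixed_anova(m, c("a", "a", "b")), "one group label")
  m[2, 3] <- NA
  expect_error(mixed_anova(m, c("a", "a", "b", "b")), "balanced")
  expect_error(mixed_anova(rnorm(5), rep("a", 5)), "matrix")
})

test_that("F is invariant to shifts and scales as the square of the data", {
  set.seed(63)
  m <- matrix(rnorm(8 * 5), nrow = 8)
  g <- rep(c("a", "b"), each = 4)
  r0 <- mixed_anova(m, g)
  r_shift <- mixed_anova(m + 100, g)
  expect_equal(r_shift$F_group, r0$F_group, tolerance = 1e-8)
  expect_equal(r_shift$F_interaction, r0$F_interaction, tolerance = 1e-8)
  r_scale <- mixed_anova(m * 3, g)
  expect_equal(r_scale$F_group, r0$F_group, tolerance = 1e-8)
  expect_equal(r_scale$p_time, r0$p_time, tolerance = 1e-8)
  # sums of squares scale by c^2 even though F does not
  expect_equal(r_scale$ss, r0$ss * 9, tolerance = 1e-6)
})

test_that("Greenhouse-Geisser adjustment only weakens within-subject tests", {
  set.seed(64)
  # a real time effect (so F_time > 1) with heterogeneous column variances
  # (broken sphericity); shrinking the df can only weaken the test there
  m <- matrix(rnorm(10 * 6), nrow = 10) +
    matrix(rep(c(0, 2, 0, 1, 0, 2), each = 10), nrow = 10)
  m[, 1] <- m[, 1] * 3
  g <- rep(c("a", "b"), each = 5)
  r <- mixed_anova(m, g)
  rg <- mixed_anova(m, g, gg = TRUE)
  expect_lt(rg$gg_epsilon, 1)
  expect_gte(rg$p_time, r$p_time)
  expect_equal(rg$F_time, r$F_time)  # F itself is unchanged
  expect_equal(rg$p_group, r$p_group)  # between test untouched
})

test_that("group-mean permutation statistic equals the split-plot group F", {
  set.seed(65)
  m <- matrix(rnorm(10 * 4, mean = rep(c(0, 1), each = 5)), nrow = 10)
  g <- factor(rep(c("a", "b"), each = 5))
  r <- mixed_anova(m, g)
  obs <- permutation_group_test(m, g, n_perm = 99, seed = 1)$observed
  expect_equal(obs, r$F_group, tolerance = 1e-8)
})

test_that("small designs are enumerated exhaustively", {
  set.seed(66)
  m <- matrix(rnorm(6 * 3), nrow = 6)
  g <- rep(c("a", "b"), each = 3)
  r <- permutation_group_test(m, g, n_perm = 999, seed = 2)
  expect_true(r$exhaustive)
  expect_equal(r$n_used, 20)  # choose(6, 3) relabelings
  # brute-force oracle: every assignment of 3 animals to group a
  means <- rowMeans(m)
  stats_all <- apply(combn(6, 3), 2, function(i) {
    gg <- factor(ifelse(1:6 %in% i, "a", "b"))
    ssb <- 3 * sum((tapply(means, gg, mean) - mean(means))^2)
    ssw <- sum((means - tapply(means, gg, mean)[gg])^2)
    (ssb / 1) / (ssw / 4)
  })
  expect_equal(r$p, mean(stats_all >= r$observed - 1e-12))
})

test_that("a huge group separation gives the minimal achievable p", {
  set.seed(67)
  m <- matrix(rnorm(12 * 4), nrow = 12)
  m[7:12, ] <- m[7:12, ] + 1000
  g <- rep(c("a", "b"), each = 6)
  r <- permutation_group_test(m, g, n_perm = 199, seed = 3)
  expect_false(r$exhaustive)  # choose(12, 6) = 924 > 199
  expect_equal(r$p, 1 / 200)
  expect_error(permutation_group_test(m, g, n_perm = 50), "at least 99")
})

test_that("max-T contrasts flag only time points with real separation", {
  set.seed(68)
  m <- matrix(rnorm(12 * 6), nrow = 12)
  g <- rep(c("a", "b"), each = 6)
  m[g == "b", 3] <- m[g == "b", 3] + 5  # effect at time 3 only
  res <- permutation_maxt(m, g, n_perm = 499, seed = 4)
  expect_equal(nrow(res), 6)
  expect_lt(res$p_adj[3], 0.05)
  expect_true(all(res$p_adj[-3] > 0.05))
})
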