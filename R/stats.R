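#' Unpaired two-sample t-test
#'
#' Pooled-variance (Student) t by default, matching the convention of
#' comparing two independent groups of animals; Welch available. Degenerate
#' inputs (zero pooled variance) are resolved explicitly: equal means give
#' t = 0, p = 1; unequal means with zero variance are an error.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @param welch use the Welch unequal-variance form (default `FALSE`).
#' @return list with `t`, `df`, `p`.
#' @examples
#' unpaired_t_test(c(1, 2, 3), c(4, 5, 6))
#' @export
unpaired_t_test <- function(x, y, alternative = "two.sided", welch = FALSE) {
  if (length(x) < 2 || length(y) < 2) stop("each sample needs n >= 2")
  n1 <- length(x); n2 <- length(y)
  pooled_ss <- sum((x - mean(x))^2) + sum((y - mean(y))^2)
  if (pooled_ss == 0) {
    if (mean(x) == mean(y)) {
      return(list(t = 0, df = n1 + n2 - 2, p = 1))
    }
    stop("degenerate samples: zero variance with unequal means")
  }
  ht <- stats::t.test(x, y, alternative = alternative, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Split-plot (two-way mixed-design) ANOVA
#'
#' Classical sums-of-squares decomposition for a design with one
#' between-subject factor (group) and one within-subject factor (time,
#' e.g. hour of the day): the group effect is tested against
#' subjects-within-group, time and the group-by-time interaction against the
#' subject-by-time residual. Computed with [stats::aov()] and an
#' `Error(animal)` stratum.
#'
#' @param values numeric matrix, animals in rows, time points in columns;
#'   no missing cells (each animal measured at every time point).
#' @param group group label per animal (length `nrow(values)`); at least 2
#'   animals per group. Group sizes need not be equal.
#' @param gg apply the Greenhouse-Geisser sphericity correction to the
#'   within-subject tests (default `FALSE`).
#' @return object of class `anova_result`: for each of `group`, `time`,
#'   `interaction` the F statistic, df pair and p-value, plus the full
#'   sums-of-squares table (`ss`).
#' @examples
#' set.seed(1)
#' m <- matrix(rnorm(12 * 6), nrow = 12)
#' mixed_anova(m, rep(c("ctl", "mor"), each = 6))
#' @export
mixed_anova <- function(values, group, gg = FALSE) {
  if (!is.matrix(values)) stop("values must be an animals x time matrix")
  if (anyNA(values)) stop("design must be balanced within animal (no NA)")
  n <- nrow(values); tp <- ncol(values)
  if (length(group) != n) stop("one group label per animal required")
  group <- factor(group)
  if (nlevels(group) < 2) stop("need at least 2 groups")
  if (any(table(group) < 2)) stop("need at least 2 animals per group")
  if (tp < 2) stop("need at least 2 time points")

  d <- data.frame(
    y = as.vector(values),
    animal = factor(rep(seq_len(n), times = tp)),
    time = factor(rep(seq_len(tp), each = n)),
    group = rep(group, times = tp))
  fit <- stats::aov(y ~ group * time + Error(animal), data = d)
  s <- summary(fit)
  between <- s[["Error: animal"]][[1]]
  within <- s[["Error: Within"]][[1]]
  row_of <- function(tab, name) {
    i <- match(name, trimws(rownames(tab)))
    if (is.na(i)) stop("missing ANOVA term: ", name)
    tab[i, ]
  }
  g <- row_of(between, "group"); gr <- row_of(between, "Residuals")
  tm <- row_of(within, "time"); it <- row_of(within, "group:time")
  wr <- row_of(within, "Residuals")

  eps <- 1
  if (gg) eps <- gg_epsilon(values, group)
  # F recomputed from the SS table so that a zero effect SS gives F = 0
  # exactly (aov's own ratio is 0/0 on degenerate constant data)
  ss_tol <- 1e-12 * max(sum(between[, "Sum Sq"]) + sum(within[, "Sum Sq"]), 1)
  fstat <- function(eff, res) {
    if (eff[["Sum Sq"]] <= ss_tol) return(0)
    if (res[["Sum Sq"]] <= ss_tol) return(Inf)
    (eff[["Sum Sq"]] / eff[["Df"]]) / (res[["Sum Sq"]] / res[["Df"]])
  }
  pval <- function(f, df1, df2, e = 1) {
    if (f == 0) 1 else stats::pf(f, e * df1, e * df2, lower.tail = FALSE)
  }
  F_group <- fstat(g, gr)
  F_time <- fstat(tm, wr)
  F_inter <- fstat(it, wr)
  out <- list(
    F_group = F_group,
    df_group = c(g[["Df"]], gr[["Df"]]),
    p_group = pval(F_group, g[["Df"]], gr[["Df"]]),
    F_time = F_time,
    df_time = c(tm[["Df"]], wr[["Df"]]),
    p_time = pval(F_time, tm[["Df"]], wr[["Df"]], eps),
    F_interaction = F_inter,
    df_interaction = c(it[["Df"]], wr[["Df"]]),
    p_interaction = pval(F_inter, it[["Df"]], wr[["Df"]], eps),
    gg_epsilon = if (gg) eps else NA_real_,
    ss = c(group = g[["Sum Sq"]], subject = gr[["Sum Sq"]],
           time = tm[["Sum Sq"]], interaction = it[["Sum Sq"]],
           residual = wr[["Sum Sq"]]))
  structure(out, class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  line <- function(nm, f, df, p) {
    cat(sprintf("  %-12s F(%g, %g) = %.4g, p = %.4g\n", nm, df[1], df[2], f, p))
  }
  cat("Mixed-design ANOVA (between: group; within: time)\n")
  line("group", x$F_group, x$df_group, x$p_group)
  line("time", x$F_time, x$df_time, x$p_time)
  line("group:time", x$F_interaction, x$df_interaction, x$p_interaction)
  if (!is.na(x$gg_epsilon)) {
    cat(sprintf("  Greenhouse-Geisser epsilon = %.3f (within tests adjusted)\n",
                x$gg_epsilon))
  }
  invisible(x)
}

# Greenhouse-Geisser epsilon from the pooled within-group covariance of the
# repeated measures, bounded to [1/(T-1), 1].
gg_epsilon <- function(values, group) {
  tp <- ncol(values)
  pooled <- matrix(0, tp, tp)
  dfree <- 0
  for (gl in levels(group)) {
    sub <- values[group == gl, , drop = FALSE]
    pooled <- pooled + stats::cov(sub) * (nrow(sub) - 1)
    dfree <- dfree + nrow(sub) - 1
  }
  S <- pooled / dfree
  C <- sweep(sweep(S, 1, rowMeans(S)), 2, colMeans(S)) + mean(S)
  eps <- sum(diag(C))^2 / ((tp - 1) * sum(C^2))
  min(max(eps, 1 / (tp - 1)), 1)
}

# One-way between-group F on per-animal summary values. For a balanced
# split-plot design this equals the split-plot group F computed on the full
# matrix (the between-subject stratum only sees subject means).
oneway_f <- function(means, group) {
  k <- nlevels(group)
  n <- length(means)
  gm <- mean(means)
  mg <- tapply(means, group, mean)
  ng <- tabulate(group)
  ssb <- sum(ng * (mg - gm)^2)
  ssw <- sum((means - mg[group])^2)
  if (ssw == 0) return(if (ssb == 0) 0 else Inf)
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Permutation test for a between-group effect on time-course data
#'
#' Permutes group labels across animals while keeping each animal's time
#' course intact; the test statistic is computed on per-animal time-course
#' means (for the between-subject effect this is equivalent to the
#' split-plot group F). When the number of distinct label assignments does
#' not exceed `n_perm` the null distribution is enumerated exhaustively;
#' otherwise `n_perm` random permutations are drawn and the p-value uses the
#' add-one estimator `(1 + #\{perm >= obs\}) / (1 + n_perm)`.
#'
#' @param values animals x time matrix.
#' @param group group label per animal.
#' @param statistic `"F_group"` (any number of groups) or `"mean_diff"`
#'   (absolute difference of group means; 2 groups).
#' @param n_perm number of random permutations (>= 99).
#' @param seed integer seed or `NULL`.
#' @return list with `p`, `observed`, `exhaustive` (logical), and
#'   `n_used` (number of permutations the p-value is based on).
#' @export
permutation_group_test <- function(values, group, statistic = "F_group",
                                   n_perm = 999, seed = NULL) {
  if (n_perm < 99) stop("n_perm must be at least 99")
  statistic <- match.arg(statistic, c("F_group", "mean_diff"))
  group <- factor(group)
  means <- rowMeans(as.matrix(values))
  if (statistic == "mean_diff" && nlevels(group) != 2) {
    stop("mean_diff requires exactly 2 groups")
  }
  stat_fun <- if (statistic == "F_group") {
    function(g) oneway_f(means, g)
  } else {
    function(g) abs(diff(tapply(means, g, mean)))
  }
  obs <- stat_fun(group)
  if (!is.null(seed)) set.seed(seed)
  n <- length(means)
  n_distinct <- distinct_assignments(table(group))
  if (nlevels(group) == 2 && n_distinct <= n_perm) {
    idx <- utils::combn(n, sum(group == levels(group)[1]))
    stats_all <- apply(idx, 2, function(i) {
      g <- factor(ifelse(seq_len(n) %in% i, levels(group)[1],
                         levels(group)[2]), levels = levels(group))
      stat_fun(g)
    })
    p <- mean(stats_all >= obs - 1e-12)
    return(list(p = p, observed = obs, exhaustive = TRUE,
                n_used = length(stats_all)))
  }
  perm <- replicate(n_perm, stat_fun(sample(group)))
  p <- (1 + sum(perm >= obs - 1e-12)) / (1 + n_perm)
  list(p = p, observed = obs, exhaustive = FALSE, n_used = n_perm)
}

distinct_assignments <- function(counts) {
  exp(lgamma(sum(counts) + 1) - sum(lgamma(counts + 1)))
}

#' Per-time-point permutation contrasts with max-T family-wise control
#'
#' For each time point computes the pooled-variance t statistic between the
#' two groups, and adjusts across time points by the permutation
#' distribution of the maximum absolute t (labels permuted across animals,
#' time courses kept intact).
#'
#' @param values animals x time matrix.
#' @param group two-level group label per animal.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed or `NULL`.
#' @return data frame with one row per time point: `time`, `t`, `p_adj`.
#' @export
permutation_maxt <- function(values, group, n_perm = 999, seed = NULL) {
  group <- factor(group)
  if (nlevels(group) != 2) stop("max-T contrasts require exactly 2 groups")
  values <- as.matrix(values)
  tstats <- function(g) {
    i1 <- g == levels(group)[1]
    vapply(seq_len(ncol(values)), function(j) {
      x <- values[i1, j]; y <- values[!i1, j]
      sp <- sqrt(((length(x) - 1) * stats::var(x) +
                    (length(y) - 1) * stats::var(y)) /
                   (length(x) + length(y) - 2))
      if (sp == 0) return(0)
      (mean(x) - mean(y)) / (sp * sqrt(1 / length(x) + 1 / length(y)))
    }, numeric(1))
  }
  obs <- tstats(group)
  if (!is.null(seed)) set.seed(seed)
  max_null <- replicate(n_perm, max(abs(tstats(sample(group)))))
  p_adj <- vapply(abs(obs), function(tj) {
    (1 + sum(max_null >= tj - 1e-12)) / (1 + n_perm)
  }, numeric(1))
  data.frame(time = seq_len(ncol(values)), t = obs, p_adj = p_adj)
}
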