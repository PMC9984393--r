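#' Default stage-transition matrices per light phase and condition
#'
#' Row-stochastic 3x3 matrices over (WAKE, NREM, REM) at 4-s epoch
#' resolution. The defaults encode, per phase and treatment condition, the
#' qualitative sleep architecture of group-housed laboratory mice:
#'
#' * `light` (rest phase, all conditions): wake occupancy ~0.42, NREM ~0.51,
#'   REM ~0.07, with NREM bouts of a few minutes;
#' * `dark` / `control`: wake occupancy ~0.65 (mice are nocturnal);
#' * `dark` / `morphine`: strongly elevated wake persistence, occupancy
#'   ~0.85, emulating the near-continuous dark-cycle wakefulness seen under
#'   chronic oral morphine.
#'
#' REM is entered only from NREM (standard rodent physiology); direct
#' WAKE-to-REM transitions are zero and rejected by validation unless
#' `allow_wake_to_rem = TRUE` in [hypnogram_params()].
#'
#' @return nested list: `matrices[[phase]][[condition]]` with phases
#'   `light`/`dark` and conditions `control`/`morphine`.
#' @export
default_transition_matrices <- function() {
  m <- function(v) {
    matrix(v, nrow = 3, byrow = TRUE, dimnames = list(STAGES, STAGES))
  }
  light <- m(c(0.960, 0.040, 0.000,
               0.025, 0.967, 0.008,
               0.060, 0.000, 0.940))
  dark_control <- m(c(0.980, 0.020, 0.000,
                      0.035, 0.957, 0.008,
                      0.060, 0.000, 0.940))
  dark_morphine <- m(c(0.990, 0.010, 0.000,
                       0.050, 0.943, 0.007,
                       0.070, 0.000, 0.930))
  list(light = list(control = light, morphine = light),
       dark = list(control = dark_control, morphine = dark_morphine))
}

#' Parameters for hypnogram simulation
#'
#' @param duration_h recording length in hours (default 24).
#' @param epoch_s epoch length in seconds (default 4).
#' @param transition_matrices nested list `[[phase]][[condition]]` of 3x3
#'   row-stochastic matrices over (WAKE, NREM, REM); default
#'   [default_transition_matrices()].
#' @param intervention_window optional transient intervention (e.g. a
#'   chemogenetic-inhibition window after a CNO injection): a list with
#'   `start_hour` (clock hour), `duration_h`, and `matrix` (3x3 replacement
#'   matrix used while the window is active). Default `NULL`.
#' @param allow_wake_to_rem permit direct WAKE-to-REM transitions
#'   (default `FALSE`; rodents enter REM from NREM).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return object of class `hypnogram_params`.
#' @export
hypnogram_params <- function(duration_h = 24, epoch_s = 4,
                             transition_matrices = default_transition_matrices(),
                             intervention_window = NULL,
                             allow_wake_to_rem = FALSE,
                             seed = NULL) {
  stopifnot(duration_h > 0, epoch_s > 0)
  if ((duration_h * 3600) %% epoch_s != 0) {
    stop("duration_h * 3600 must be divisible by epoch_s")
  }
  for (phase in names(transition_matrices)) {
    for (cond in names(transition_matrices[[phase]])) {
      validate_transition_matrix(transition_matrices[[phase]][[cond]],
                                 allow_wake_to_rem,
                                 sprintf("(%s, %s)", phase, cond))
    }
  }
  if (!is.null(intervention_window)) {
    stopifnot(is.list(intervention_window),
              all(c("start_hour", "duration_h", "matrix") %in%
                    names(intervention_window)))
    validate_transition_matrix(intervention_window$matrix, allow_wake_to_rem,
                               "(intervention)")
  }
  structure(list(duration_h = duration_h, epoch_s = epoch_s,
                 transition_matrices = transition_matrices,
                 intervention_window = intervention_window,
                 allow_wake_to_rem = allow_wake_to_rem, seed = seed),
            class = "hypnogram_params")
}

validate_transition_matrix <- function(P, allow_wake_to_rem = FALSE,
                                       label = "") {
  if (!is.matrix(P) || !all(dim(P) == c(3, 3))) {
    stop("transition matrix ", label, " must be 3x3")
  }
  if (any(P < 0)) stop("transition matrix ", label, " has negative entries")
  if (any(abs(rowSums(P) - 1) > 1e-12)) {
    stop("transition matrix ", label, " rows must sum to 1 (within 1e-12)")
  }
  if (!allow_wake_to_rem && P[1, 3] > 0) {
    stop("transition matrix ", label,
         " allows WAKE -> REM; set allow_wake_to_rem = TRUE to permit")
  }
  invisible(P)
}

#' Stationary distribution of a stochastic matrix
#'
#' Solves pi = pi P with sum(pi) = 1 by linear solve. Requires a unique
#' stationary distribution (irreducible chain).
#'
#' @param P row-stochastic square matrix.
#' @return numeric vector summing to 1.
#' @export
stationary_distribution <- function(P) {
  n <- nrow(P)
  A <- t(diag(n) - P)
  A[n, ] <- 1
  b <- c(rep(0, n - 1), 1)
  pi <- tryCatch(solve(A, b), error = function(e) {
    stop("stationary distribution is not unique (reducible chain)")
  })
  pmax(pi, 0) / sum(pmax(pi, 0))
}

#' Simulate a hypnogram from phase-switching Markov chains
#'
#' At each epoch the active transition matrix is chosen from the clock time:
#' the light-phase matrix or dark-phase matrix for `condition`, overridden by
#' the intervention matrix while the intervention window is active. The first
#' epoch's state is drawn from the stationary distribution of the initially
#' active matrix.
#'
#' @param params a [hypnogram_params()].
#' @param condition condition label; must index a matrix in both phases of
#'   `params$transition_matrices`.
#' @param lc a [light_cycle()].
#' @param start_sec clock time of the first epoch (seconds after midnight;
#'   default lights-on).
#' @return a [hypnogram()].
#' @examples
#' h <- simulate_hypnogram(hypnogram_params(duration_h = 2, seed = 1),
#'                         condition = "morphine")
#' table(h)
#' @export
simulate_hypnogram <- function(params, condition = "control",
                               lc = light_cycle(),
                               start_sec = lc$lights_on_hour * 3600) {
  stopifnot(inherits(params, "hypnogram_params"))
  tm <- params$transition_matrices
  for (phase in c("light", "dark")) {
    if (is.null(tm[[phase]][[condition]])) {
      stop("no transition matrix for (", phase, ", ", condition, ")")
    }
  }
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- as.integer(params$duration_h * 3600 / params$epoch_s)
  secs <- (start_sec + (seq_len(n) - 1) * params$epoch_s) %% 86400
  hours <- secs %/% 3600
  phase_key <- ifelse(is_light(hours, lc), "light", "dark")
  in_window <- rep(FALSE, n)
  iw <- params$intervention_window
  if (!is.null(iw)) {
    rel <- (secs - iw$start_hour * 3600) %% 86400
    in_window <- rel < iw$duration_h * 3600
  }
  states <- integer(n)
  P0 <- if (in_window[1]) iw$matrix else tm[[phase_key[1]]][[condition]]
  states[1] <- sample.int(3, 1, prob = stationary_distribution(P0))
  u <- stats::runif(n)  # one draw per epoch keeps the trajectory reproducible
  for (i in seq_len(n - 1)) {
    P <- if (in_window[i + 1]) iw$matrix else tm[[phase_key[i + 1]]][[condition]]
    states[i + 1] <- findInterval(u[i + 1], cumsum(P[states[i], ]),
                                  left.open = TRUE) + 1L
  }
  hypnogram(STAGES[states], epoch_s = params$epoch_s, start_sec = start_sec)
}

#' Simulate a cohort of animals under one condition
#'
#' Convenience wrapper: one 24-h (by default) hypnogram per animal, with
#' per-animal seeds derived from `seed` so the cohort is reproducible as a
#' whole.
#'
#' @param n_animals number of animals.
#' @param condition condition label (must have matrices in `params`).
#' @param params a [hypnogram_params()]; its `seed` field is ignored in
#'   favour of the derived per-animal seeds.
#' @param lc a [light_cycle()].
#' @param seed integer base seed.
#' @return list of [hypnogram()]s, one per animal.
#' @export
simulate_cohort <- function(n_animals, condition = "control",
                            params = hypnogram_params(), lc = light_cycle(),
                            seed = 1) {
  lapply(seq_len(n_animals), function(i) {
    p <- params
    p$seed <- (seed * 1000L + i) %% .Machine$integer.max
    simulate_hypnogram(p, condition, lc)
  })
}
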