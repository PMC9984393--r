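---
title: "Methods: rule-based sleep staging, PIR sleep scoring and circadian summaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based sleep staging, PIR sleep scoring and circadian summaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypnoscore)
```

# What this package computes

`hypnoscore` analyses rodent sleep across the 12:12 light/dark cycle in
five connected pieces:

1. a **synthetic-data generator** — hypnograms from phase-switching Markov
   chains, state-conditioned EEG/EMG signals, and passive-infrared (PIR)
   activity traces;
2. **rule-based EEG/EMG staging** of 4-s epochs into Wake/NREM/REM;
3. **PIR ("COMPASS") sleep scoring** by the 40-s inactivity rule, with
   sleep-bout analytics and Pearson validation against ground truth;
4. **circadian summaries** — minutes per stage per hour, 12-h light/dark
   totals, drinking-water dose arithmetic;
5. **group statistics** — pooled t-tests, split-plot mixed ANOVA, and
   permutation alternatives.

Because raw EEG/PIR recordings of the kind this pipeline targets are large
and rarely shareable, the generator is a first-class module: every
downstream stage is exercised and validated on synthetic data whose
statistical structure matches what the analysis assumes.

# The generative model

## Hypnograms

A hypnogram is a first-order Markov chain over the states
$\{W, N, R\}$ (wake, NREM, REM) at 4-s epoch resolution. The transition
matrix in force at any epoch is selected by clock time: one matrix for the
light phase, one per treatment condition for the dark phase, optionally
overridden by an *intervention window* (emulating a transient
chemogenetic-inhibition effect after a CNO injection early in the dark
phase). The first state is drawn from the stationary distribution of the
initially active matrix. One uniform variate is drawn per epoch, so two
simulations with the same seed share their random stream epoch-for-epoch
even when their matrices differ — matched-seed comparisons of intervention
scenarios are exact outside the altered window.

The defaults encode qualitative rodent sleep architecture rather than any
published table (none exists for this design); they were fixed once, from
physiological plausibility:

```{r stationary}
tm <- default_transition_matrices()
round(rbind(
  light          = stationary_distribution(tm$light$control),
  dark_control   = stationary_distribution(tm$dark$control),
  dark_morphine  = stationary_distribution(tm$dark$morphine)), 3)
```

* light phase: wake ≈ 42%, REM ≈ 7% of time, NREM bouts of a few minutes —
  typical for mice at rest;
* dark phase, control: wake ≈ 65% (mice are nocturnal);
* dark phase, chronic morphine: wake ≈ 84%, with long wake bouts (mean
  wake run $1/(1-0.99) = 100$ epochs ≈ 6.7 min), emulating near-continuous
  drug-induced dark-cycle wakefulness;
* REM is entered only from NREM (standard rodent physiology); a
  constructor flag relaxes this;
* the default intervention window (used in the tests) starts at 20:00 —
  one hour after lights-off — lasts 4 h, and substitutes the control dark
  matrix for the morphine one, emulating inhibition of the wake-promoting
  circuit for the expected duration of CNO action.

Matrices are validated on construction: rows must sum to 1 within
$10^{-12}$, entries must be non-negative, and $P(W\to R)$ must be zero
unless explicitly allowed.

## EEG/EMG signals

Each epoch's EEG is a single stage-specific sinusoid plus white noise: the
tone frequency is drawn uniformly from the stage's band (NREM 1.5–3.5 Hz
inside the 0.5–4 Hz delta band; REM 5.5–9.5 Hz inside 5–10 Hz; wake
13–24 Hz above 12 Hz), with random phase. The EMG is zero-mean Gaussian
noise at a stage-specific RMS (default 1.0 wake, 0.1 NREM, 0.05 REM —
muscle atonia in sleep). This **tonal model is a deliberate
simplification**: it realises exactly the band-dominance structure the
staging rules read, and nothing else. It does not emulate 1/f background,
spindles, artifacts, or gradual state transitions, so staging performance
on it bounds what the rules can do when their assumptions hold; it says
nothing about robustness to realistic EEG microstructure.

## PIR activity traces

The hypnogram is projected onto the 10-s PIR bin grid: a bin is asleep if
a strict majority of the epochs it overlaps are asleep, with ties going to
wake (the mapping never invents sleep). Sleep bins score 0 except with a
small *false-movement probability* (default 0.005) of a small positive
score; wake bins draw integer scores uniformly from 20–100. The default
false-movement rate and wake-score range were fixed with the rest of the
generator defaults.

# Staging rules

Each 4-s epoch is classified from its band-dominance fractions and EMG
amplitude, in fixed rule order:

* **WAKE** — fast (>12 Hz) dominance more than 10% of the time *and* high
  EMG;
* **NREM** — delta (0.5–4 Hz) dominance more than 30% of the time, fast
  dominance less than 10%, *and* low EMG;
* **REM** — 5–10 Hz dominance more than 20% of the time *and* low EMG;
* otherwise the **fallback** stage, WAKE by default (configurable). In the
  lab workflow such epochs would be resolved by a human scorer; an
  automated pipeline needs a documented default, and wake is the
  conservative choice (it never inflates sleep).

"X% of the time" is operationalised as the fraction of 0.5-s sub-windows
whose *dominant spectral frequency* (argmax of the DFT magnitude after
mean removal and Hann tapering) falls in the band. This is the closest
literal reading of "waveforms ... % of the time" we could defend; whether
the original scoring software thresholds FFT *power* fractions instead is
not documented, so the operationalisation is a package choice, stated, not
asserted as anyone else's. Two numerical details matter:

* at 0.5 s a raw DFT bin is 2 Hz wide — too coarse for the 0.5–4 Hz delta
  band — so sub-windows are zero-padded to 2 s, giving a 0.5 Hz frequency
  grid;
* an all-zero sub-window has no dominant frequency and counts toward no
  band (an all-zero epoch therefore has all fractions 0 and falls through
  to the fallback stage; it is not an error).

The 5–10 Hz REM band is named `theta` in the code; descriptions of this
rule set sometimes label it "delta", but 5–10 Hz in rodents is the theta
range.

The EMG high/low threshold is calibrated per recording: 2-means on log
RMS (deterministically initialised at the sample extremes), threshold =
midpoint of the cluster centres. If the RMS values span less than 1%
relative range the split is meaningless and the threshold is $+\infty$
(everything low). Calibrating on log values makes the threshold scale with
the data, so staging is invariant to a common EMG gain factor; band
fractions are argmax-based and hence invariant to EEG amplitude scaling.

No temporal smoothing or contextual rules (e.g. forbidding W→R) are
applied by default; `smooth_hypnogram()` provides an optional majority
filter, off by default, because the recovery tests need the raw rule
output.

# PIR sleep scoring

Maximal runs of consecutive *exactly zero* bins lasting **at least 40 s**
(4 bins) are sleep; everything else is wake. Two readings of "40 s" are
possible — "inactivity greater than 40 s" versus "convert 40 s of
inactivity into sleep" — and the package resolves the conflict as
$\ge 40$ s, since the conversion phrasing names 40 s itself as sleep;
`strict = TRUE` gives the $> 40$ s reading. No epsilon tolerance is
applied to "zero" (the score definition makes 0 exact), and bouts are
never merged across a single active bin. Bout statistics are count,
arithmetic mean duration, maximum duration, and total sleep minutes; an
empty bout list reports zeros.

# Circadian summaries

Hourly summaries count epochs per stage per clock hour (4-s epochs cannot
straddle an hour boundary since 4 divides 3600; other epoch lengths are
asserted to tile hours). Partial first/last hours are flagged with their
actual coverage rather than silently rescaled. Light/dark totals sum
hours over `[lights_on, lights_off)` and its complement; both clock-hour
and zeitgeber-time (ZT0 = lights-on) labels are carried so either
reporting convention is available — post-hoc windows like "last 6 h of the
dark phase" are ZT-anchored in some labs and clock-anchored in others, and
the summaries support both without re-aggregation.

Dose arithmetic is exact:
$\mathrm{dose} = V \cdot c \,/\, (m/1000)$ mg/kg/day for volume $V$
(mL/day), concentration $c$ (mg/mL) and body weight $m$ (g).

# Statistics

* **Unpaired t-test**: pooled-variance Student t by default (the
  convention in the animal literature this pipeline serves), two-sided;
  Welch and one-sided variants available. Zero pooled variance with equal
  means returns $t = 0, p = 1$; with unequal means it is an explicit
  error rather than an infinite statistic. (Published post-hoc values of
  the form $t = 1.72$, df 17, $P = 0.042$ are only consistent with a
  one-sided test; the package defaults to two-sided and leaves one-sided
  to the `alternative` argument.)
* **Split-plot mixed ANOVA** (`mixed_anova`): between-subject factor
  group, within-subject factor time; group is tested against
  subjects-within-group, time and group×time against the subject×time
  residual. Computed via `stats::aov` with an `Error(animal)` stratum; F
  ratios are recomputed from the sums of squares so that a zero effect SS
  gives F = 0 exactly even on degenerate constant data. Greenhouse–
  Geisser correction is available (`gg = TRUE`) but off by default — the
  conventional reports this mirrors do not apply it. Group sizes may be
  unequal (complete within animal is required); df follow the standard
  decomposition, e.g. two groups of 6 and 7 give a group test on
  $(1, 11)$ df.
* **Permutation tests**: group labels are permuted across animals with
  time courses kept intact. The statistic is the between-group F on
  per-animal time-course means, which equals the split-plot group F (the
  between-subject stratum only sees subject means) and keeps the loop
  cheap. With $\binom{n}{n_1}$ distinct assignments at or below `n_perm`
  the null is enumerated exhaustively; otherwise `n_perm` draws are used
  with the add-one estimator $p = (1 + \#\{T^* \ge T\})/(1 + n_\mathrm{perm})$,
  which is valid (never anti-conservative) by construction. Per-time-point
  contrasts use max-T family-wise adjustment (`permutation_maxt`) instead
  of a parametric post-hoc: it controls FWER without reproducing any
  proprietary software's post-hoc conventions.

# What the tests do and do not show

The test suite validates every operation against independent oracles
(run-length encoding for sleep scoring, brute-force sums of squares for
the ANOVA, explicit-sum DFT argmax for the features, exhaustive 1-D
2-means for the EMG calibration), checks conservation laws (hourly minutes
sum to 60, light+dark = 24 h, bout totals = sleep-bin totals), calibration
(type-I error of the group test ≈ 0.05 over 500 null replicates;
permutation p uniform under the null), and the scenario structure
(morphine raises dark-cycle wake; the intervention window lowers it only
within its own hours). Typical problem sizes are 24-h single-animal
simulations (21,600 epochs), cohorts of 8–13 animals, 300–450-epoch
staging recordings, and 50–100 seed replicates — sizes chosen to make
Monte-Carlo assertions stable.

Passing on synthetic data shows the *pipeline logic* is correct under the
generator's assumptions. It does not show that the staging rules agree
with a human scorer on real EEG (tonal signals have no ambiguous epochs),
nor that PIR scoring reaches its validation correlation on real mice
(where quiet wake is the main confound; the generator's false-movement
model makes sleep→wake errors rare and wake→sleep errors impossible, which
is optimistic about immobile wake).

# Known limitations

* The generator's transition matrices are calibrated to qualitative
  patterns, not to any published hour-by-hour table; simulated effect
  sizes are not expected to match published F statistics.
* The EDF writer/reader covers exactly the two-channel continuous layout
  the pipeline produces; it is not a general EDF(+) implementation.
* Spectral-power (band power over time) analyses are out of scope by
  design; the features are dominance fractions only.
* Three-way designs (e.g. DREADD × drug × day) are not implemented; the
  split-plot model covers the two-factor analyses, and the permutation
  machinery the contrasts.
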