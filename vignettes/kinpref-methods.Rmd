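---
title: "Quantifying kin-directed mate and social preference: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying kin-directed mate and social preference: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinpref)
```

## The scientific problem

Animals are classically expected to avoid mating with close kin because
inbred offspring suffer fitness costs, yet kin affiliation outside the
sexual context can be beneficial, and the two pressures interact. kinpref
implements a complete analysis pipeline for testing kin-directed sexual and
social preference in small freshwater fish (guppies are the motivating
system) across three complementary designs:

1. **Dichotomous mate choice**: a focal fish in the main compartment of a
   three-compartment tank chooses between a related and an unrelated
   opposite-sex stimulus, and preference is read from time spent in the
   5 cm association zone in front of each stimulus compartment.
2. **Free-swimming mate choice**: eight fish (two families, both sexes and
   mating statuses) interact in a 36 cm circular arena; sexual behaviours
   are scored per actor-recipient pair and spatial associations are taken
   from tracked centroid trajectories.
3. **Same-sex social arenas**: eight same-sex fish (one sibling pair plus
   six unrelated) interact; associations measure nonsexual kin affiliation.

The central statistic is the strength of preference

$$\mathrm{SOP} = \frac{T_R - T_{UR}}{T_R + T_{UR}} \in [-1, 1],$$

where $T_R$ and $T_{UR}$ are times associated with the related and the
unrelated option. $+1$ is exclusive kin preference, $-1$ exclusive kin
avoidance, $0$ no bias. When $T_R + T_{UR} = 0$ the score is undefined and
the trial is flagged and excluded listwise from downstream fits — never
coerced to zero, which would fabricate an unbiased preference.

## Association detection

Two fish are associated at a frame when both centroids are valid and their
Euclidean distance is at most the threshold radius. The default radius is
two mean body lengths, `derive_threshold(1.76, 2)` = 3.52 cm, a deliberately
strict criterion for close-range interaction (four body lengths is a common
looser shoal-membership rule and is available via the `multiplier`
argument). Design choices:

* The boundary is inclusive (`distance <= radius`). The distinction is
  measure-zero for continuous trajectories and an inclusive rule makes exact
  geometric tests possible.
* Frames where either centroid is missing are removed from both the
  numerator and denominator of that dyad, so tracking loss cannot bias
  association shares.
* Total association time is accumulated frame-wise; no minimum bout length
  or gap merging is applied by default. A bout extractor
  (`association_bouts()`) with both filters exists for descriptive use.

## Zone occupancy and the informed-choice window

Zone membership is centroid-in-rectangle, boundary-inclusive on the tank
wall and half-open against the neutral region; sides map to
related/unrelated through the randomised stimulus-side assignment. The
coordinate frame (origin at the lower-left of the main compartment, 0-based
frames, time = frame / frame rate) is the package's own convention, as is
the treatment of missing frames (interpolate runs of at most 5 frames,
exclude longer gaps for the affected individual).

Informed choice (IC) re-scores a trial using only frames from the later of
the two first zone entries onward, so the focal has seen both options.
Trials where a zone is never visited, or where the second visit leaves a
window shorter than `min_window_s` (default 60 s — long enough for a
handful of zone visits at the default switching rate, short enough to
retain late-but-informative trials), are flagged for exclusion rather than
scored. Interval SOPs default to successive thirds of the trial; the edges
are configurable because no canonical interval scheme exists.

In free-swimming arenas the SOP uses summed association durations with the
related versus unrelated partner sets (2 vs 2 opposite-sex fish in the
mixed design; 1 sibling vs 6 unrelated in the same-sex design). Raw sums
are the default, which preserves the 1-vs-6 group-size asymmetry of the
same-sex design: under uniform association the expected score is
$(t - 6t)/(t + 6t) = -5/7$, not 0. A `per_capita` flag normalises by set
size for readers who prefer a symmetric null; it is off by default because
the raw-sum definition is the one the headline analyses use.

## The inference layer

* **Mixed models** are fitted with glmmTMB: Gaussian LMMs for SOP scores
  (family-of-origin random intercept) and log-link negative-binomial GLMMs
  for behaviour counts and association frame counts (arena random
  intercept; behaviour type as an additional random intercept in the pooled
  models). The NB family is parameterised by mean and dispersion to absorb
  the overdispersion typical of behavioural counts.
* **Stepwise interaction pruning** starts from all interactions up to the
  configured order and repeatedly drops the least significant currently
  droppable interaction (per-term Wald p at or above 0.05, marginality
  respected) until only significant interactions or main effects remain.
  Main effects are never dropped. For the dyadic association models the
  starting order is two: the dyad design makes several three-way cells
  structurally empty (a related female-female pair is always one virgin and
  one experienced sibling), so a three-way interaction is inestimable.
* **Per-predictor chi-square tests** (`likelihood_ratio_anova()`) follow
  the type-II marginality convention: a predictor is tested by
  likelihood-ratio comparison of models that both exclude interactions
  involving it. This serves two purposes: it is the multi-level-predictor
  test feeding Tukey post-hoc contrasts (via emmeans, familywise-adjusted,
  link scale), and it is the calibrated marginal test of a main effect in
  the occasional replicate where noise lets an interaction survive pruning
  — the conditional coefficient in such a model is not a test of the
  marginal effect, and simulation shows that treating it as one inflates
  the type-I error of the selection-plus-test procedure.
* **BH-FDR** (`bh_fdr()`) is implemented from the step-up definition
  (sort, $\mathrm{adj}_{(i)} = \min_{j \ge i} m\,p_{(j)}/j$, cap at 1) and is
  applied within explicitly declared families: one predictor across the
  models of a results section (e.g. the relatedness terms of the four
  female behaviour models). Adjustment always uses unrounded raw p-values.
  The association-duration models of the mixed-sex and same-sex experiments
  form a single declared family per predictor, spanning the two
  experiments; `run_all()` computes that joint adjustment.
* Classical pieces — the one-sample t-test of mean SOP against 0, Wilcoxon
  rank-sum comparisons of stimulus traits, Spearman rank consistency of
  per-individual SOPs across experiments (mid-rank ties, pairwise deletion
  of undefined scores) — wrap the corresponding stats routines and return
  tidy one-row tables.

## The synthetic-data generator

The package ships generators that emulate the statistical structure the
analysis assumes, so every stage is testable end-to-end without the
original recordings. They emulate structure, not guppy biomechanics.

**Zone trials** are a stationary three-state process (related zone /
unrelated zone / neutral) sampled at frame resolution: each frame the state
is redrawn from the stationary distribution
$(p_{\mathrm{zone}} b,\; p_{\mathrm{zone}}(1-b),\; 1-p_{\mathrm{zone}})$
with a probability calibrated so actual state changes occur at the
requested switching rate (default 4 per minute, a plausible visit tempo
over a 30-minute trial). Because the chain starts at stationarity, the
expected SOP of a trial is exactly $2b - 1$ at any duration, which gives the
estimator-recovery tests a closed-form truth. A `delay_s` field keeps slow
explorers in the neutral region before zone use begins; the default
scenario uses it for the one trial whose informed-choice window is
unusably short.

**Arena trajectories** are biased correlated random walks in a reflecting
circular arena: per frame, each fish's heading is the persistence-weighted
previous heading plus a social pull toward the others plus wrapped-Gaussian
angular noise, with speeds drawn from a truncated normal. The angular-noise
spread is derived from the persistence parameter
($\sigma = \sqrt{-2\log\rho}$) so the asocial heading autocorrelation
matches it. The social pull is the attraction-weighted resultant of unit
vectors toward the other fish, direction-normalised with a saturating
(tanh) magnitude: full normalisation would erase the dependence of
association time on the attraction weight, which the monotonicity checks
require, while an unbounded resultant would let crowded arenas override
persistence entirely. The boundary reflects specularly (preserves speed).
No frame rate, speed or turning statistics are reported for the original
recordings; the defaults (10 frames/s, 5 ± 2 cm/s) are stated as plausible
for adult guppies in a 36 cm arena and are not claimed to match real
kinematics. The attraction scale was set once from a dose-response sweep so
that dyads associate for a realistic few minutes per 30-minute trial at the
default (0.02 uniform in mixed arenas; 0.03 females / 0.005 males in
same-sex arenas, reproducing the strong observed female-male contrast in
association).

**Behaviour counts** per aggregation cell are negative-binomial with a
log-linear mean (relatedness and mating-status log rate ratios, arena
random intercept) — exactly the model family the inference layer fits, so
parameter-recovery tests are meaningful. The default per-cell base rates
(orienting 20, approaching 12, gliding 3; pursuing 30, sigmoid 10, mating
3) follow the usual abundance ordering of these courtship behaviours, with
dispersion 2 and arena SD 0.3 giving visible overdispersion. In the
pipeline the simulated cell counts are expanded into actor/recipient
events and re-aggregated through the event pathway, so the aggregation
module is exercised end-to-end and must reproduce the cells exactly.

The default scenario reproduces the study frame: 24 families of 4 (96
fish), 96 choice trials with 7 acclimation breaches (3 virgin males, 2
experienced males, 2 experienced females) and one late explorer (89
analyzed, 88 informed-choice), 12 mixed-sex arenas of 8, 12 same-sex
arenas of 8, stimulus trait differences drawn so mean absolute differences
match the measured cohort (1.96 mm / 1.06 mm body length in females/males,
via $\mathrm{E}|X| = \sigma\sqrt{2/\pi}$), and zone shares of 68%
(females) and 58% (males). All preference effects default to null. An
optional per-fish latent kin preference (SD, cross-experiment sharing
fraction, arena gain) induces cross-experiment consistency when switched
on.

What the generator does **not** emulate: visual fields, courtship
sequences, posture, identity-tracking errors beyond missing centroids, or
any mechanistic link between behaviour counts and trajectories (events and
movements are simulated independently). Passing tests therefore certify
the measurement and inference chain, not a behavioural model of fish.

## Determinism and numerical choices

Every simulator takes an explicit integer seed; a run's master seed spawns
per-stage and per-trial streams deterministically (`spawn_seeds()`), so a
`run_config` plus seed reproduces every table byte-for-byte, and each
written CSV carries the configuration hash and seed in a comment line.
Other numerics: interpolation fills only interior gaps (no extrapolation);
zone membership uses strict half-open inner boundaries so a centroid is
never in two zones; undefined SOPs and non-converged fits are excluded
listwise with counts retained in the ledgers; glmmTMB convergence problems
are surfaced as flags and warnings, never silently ignored.

## Problem sizes used by the test suite

The packaged tests run the full 96-trial choice cohort but shorten
recordings and replicate counts where the check is statistical rather than
structural: zone trials of 5-10 simulated minutes (1,000 replicates for
estimator recovery at three bias levels), 500-frame arenas for the 50
brute-force oracle comparisons, 200 replicate fits for the null-calibration
and effect-recovery checks, and 4-arena pipelines for the determinism
check. These sizes were chosen so Monte-Carlo error stays well inside the
3-standard-error tolerances the tests assert.

## Known limitations

* The zone process is a Markov chain, not mechanistic swimming: visit
  durations are geometric, and spatial continuity between zone and neutral
  frames is not modelled. Only occupancy totals and visit order feed the
  analysis, so this is sufficient for the statistics but unsuitable for
  kinematic questions.
* The same-sex SOP inherits the 1-vs-6 asymmetry of its definition;
  cross-experiment correlations mix scores with different nulls. This
  mirrors the published definition; the per-capita flag exists for
  sensitivity analyses.
* Wald z-tests at 12 arenas are only asymptotically exact; the simulation
  suite bounds the realised type-I error, but small-cluster corrections are
  out of scope.
* The breach and late-explorer exclusions are scenario metadata, not
  detected from trajectories; a barrier-crossing detector would require
  video, which the package deliberately does not touch.
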