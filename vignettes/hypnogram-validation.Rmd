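---
title: "Validating wearable sleep staging against PSG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating wearable sleep staging against PSG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypnomatch)
```

## The problem

Consumer sleep trackers estimate sleep stages from wrist motion and, in some
devices, cardiorespiratory signals, and report the night as a hypnogram over
a coarse alphabet: Wake–Light–Deep ("type II" devices) or
Wake–REM–Light–Deep ("type I"). Polysomnography (PSG), scored by physicians
into the five AASM stages (Wake, N1, N2, N3, REM), is the clinical ground
truth. Summary agreement statistics — overall accuracy, a single kappa —
flatter devices, because most of the night is sleep: a tracker that scores
everything as Light sleep is right most of the time while being useless
about *when* stages change. `hypnomatch` implements a validation pipeline
that keeps the chronology: aggregate wake–sleep features are compared
per night, and stage-*transition* agreement is scored epoch by epoch with a
localized mismatch index (LMI).

## Pipeline

1. **Synchronization** (`synchronize()`). Both hypnograms are placed on the
   PSG's 30-s epoch grid using the two recordings' clock start times and
   truncated to the overlapping interval. Epochs are indexed from 0 and span
   half-open intervals `[start + i·dur, start + (i+1)·dur)`. Offsets that
   are not a whole number of epochs are rounded to the nearest epoch; a
   partial final epoch is truncated. Start times less than 12 h apart on the
   clock are treated as the same night, so recordings may cross midnight.
   Hypnograms with different epoch durations are first resampled to the
   coarser one — majority label per block, ties to the earlier epoch —
   which preserves stage dwell without inventing stages.

2. **Interrater gating** (`fleiss_kappa()`, `interrater_gate()`). When
   several raters scored the PSG, Fleiss' kappa
   $\kappa = (\bar P - \bar P_e)/(1 - \bar P_e)$ measures chance-corrected
   epoch-level agreement. Hypnograms with $\kappa < 0.8$ are flagged for
   joint revision; the boundary value 0.8 passes. If every rating falls in
   one category, $\bar P_e = 1$: total agreement is reported as
   $\kappa = 1$, disagreement in that degenerate case is an error rather
   than a number.

3. **AASM categorization** (`categorize_psg()`). PSG stages are mapped to
   the device alphabet before any pairwise metric: N1 and N2 are Light for
   both device types; N3 is Deep; REM stays REM for type I devices and is
   counted as Deep for type II devices. The wake/sleep partition is
   untouched, so wake–sleep features are categorization-invariant.

4. **Features** (`extract_features()`). Per night and scorer: sleep onset
   SO (first non-Wake epoch), sleep period time SPT (onset to last sleep
   epoch), total sleep time TST with light/deep/REM components
   (TST = TLST + TDST + TRST), sleep efficiency SE = 100·TST/SPT,
   wakefulness after sleep onset WASO = SPT − TST + WAS, and stage
   percentages PLS/PDS/PRS of TST.

5. **Localized mismatch index** (`lmi_sequence()`). Stages are encoded
   Wake = 1, Light = 2, Deep = 4 and first-differenced; the transition set
   *A* collects the epoch boundaries where at least one scorer changes
   stage; the index at a boundary is the product of the two deltas. The six
   legal three-stage transitions (W–L, W–D, L–D, L–W, D–L, D–W) have deltas
   1, 3, 2, −1, −2, −3, so the diagonal values 1, 4, 9 certify that both
   scorers saw the same transition, and every off-diagonal value identifies
   a specific disagreement. Each member of *A* is classified correct
   wake / correct sleep / incorrect wake / incorrect sleep, and the class
   rates (percent of |*A*|) summarize the night.

6. **Statistical comparison** (`paired_feature_test()`, `confusion()`,
   `cohort_report()`). Features are compared across nights with a paired
   test — paired t when the Shapiro–Wilk test at α = 0.05 does not reject
   normality of the differences, Wilcoxon signed-rank otherwise — plus the
   signed paired effect size mean(diff)/sd(diff). Epoch-by-epoch confusion
   gives per-stage sensitivity and specificity and overall accuracy.
   With several devices, each feature gets a ranking by descending p-value
   (larger p = harder to distinguish from PSG), ties broken by smaller
   absolute effect.

## Design choices where the design was open

**Transition classes from the delta pair, not the product.** The published
grouping for three-stage devices assigns products {1, 9} to correct wake,
{4} to correct sleep, {3, −4} to incorrect sleep and the remaining values
{2, 6, −1, −2, −3, −6, −9} to incorrect wake. We classify from the ordered
delta pair with a rule that reproduces that grouping exactly (verified
exhaustively over all 36 cells in the tests): equal deltas are correct,
wake/sleep according to whether the transition touches Wake; otherwise the
disagreement is *incorrect sleep* when neither delta touches Wake, or when
both touch Wake with the same sign (the scorers agree the subject crossed
the wake–sleep boundary and only disagree about the depth, e.g. W–L vs
W–D); every other disagreement is *incorrect wake*. The pair-based rule
matters for four-stage (type I) devices, where no single REM integer code
keeps all products distinct — the delta pair stays unambiguous as long as
wake-involving and sleep-only delta magnitudes do not collide, which the
constructor enforces (default REM code 8, giving delta magnitudes
{1, 2, 3, 4, 6, 7}).

**One-sided transitions.** Boundaries where exactly one scorer transitions
are in *A* by its definition and have product 0. They are missed or
spurious transitions, i.e. disagreements, and are classified incorrect,
with the wake/sleep subclass taken from the scorer that moved.

**Rates over |A|.** All class rates are percentages of the transition set,
not of all epochs, so the four classes always sum to 100% and
correct + incorrect = 100%.

**Feature conventions.** SPT counts the last sleep epoch's full duration
(a closed span of epochs); a pure clock difference between onset and last
sleep epoch would silently drop one epoch from every night. The WAS term of
WASO is 0 unless a lights-on time is supplied, since hypnogram-only input
does not record lights-off/on events; with `lights_on`, WAS is the wake
time scored between the last sleep epoch and that clock time. SO is
reported as a clock time, a 0-based epoch index, and minutes from recording
start; statistical comparisons use the minutes scale, which subtracts
cleanly across midnight. For statistical tests the effect size is signed
paired Cohen's d with differences taken device − PSG.

**Degenerate inputs.** An all-Wake hypnogram raises a distinct no-sleep
condition rather than returning feature values; an empty transition set
makes rates an error, not 0/0; all-zero paired differences report the
degenerate no-difference result with p = 1.

## The simulator: what it emulates, and what it does not

`sim_scenario()` / `simulate_pair()` generate paired nights with known
ground truth, standing in for overnight recordings (which are not shipped
with the package). The PSG is a first-order Markov chain over the five AASM
stages at 30-s epochs, 960 epochs (8 h) by default, started awake. The
default transition matrix (`default_psg_transitions()`) uses sticky stages
(self-transition 0.70–0.90, i.e. dwell times of minutes) with sleep entered
via N1/N2, giving a plausible adult stage mix of roughly 5–10% wake,
~50% light, ~20% N3 and ~20% REM across the night. The device channel
applies, in order: a constant scoring lag (each stage reported k epochs
late), per-epoch mislabeling (a uniform rate, or a full row-stochastic
confusion matrix over the device alphabet), and epoch dropout refilled by
holding the previous reported stage, as consumer firmware does. Every draw
is governed by one integer seed (device draws use seed + 1; night k of a
cohort uses master seed + k), so runs are bit-reproducible.

The simulator is deliberately minimal: a first-order chain has geometric
dwell times, no ultradian REM cycling, no time-of-night non-stationarity,
and the error channel is epoch-independent. Passing tests therefore
demonstrate that the *metrics* are computed correctly and recover planted
error rates — they are not evidence about how any real device scores real
sleep, and dwell-time realism is a parameterization default, not a claim.

## Problem sizes and numerical notes

The test suite runs nights of 240–960 epochs, a 50,000-epoch chain for the
stationary-distribution check, 30-night cohorts for error-rate recovery
(binomial 3σ bands), and 1000 replicates at n = 30 nights for the type-I
calibration of the paired test suite (expected rejection 5% ± 1.5%). Stage
percentages and rates are exact rational arithmetic on epoch counts, so
equality tolerances in the tests are at machine precision except where a
quantity is genuinely stochastic. Fleiss' kappa guards the
$\bar P_e \to 1$ limit with a square-root-of-machine-epsilon margin.

## Known limitations

* Binary EDF ingestion is not implemented; annotation tracks are read from
  a plain-text `onset,duration,stage` export instead.
* Lagged-transition credit (matching transitions offset by ±k epochs) is
  intentionally absent: the index is a strict per-boundary product.
* The published four-stage (type I) index table is not reproduced anywhere
  in the available sources; four-stage classification is defined by the
  delta-pair rule above.
* No multiple-testing correction is applied across features by default.

## A worked example

```{r example}
s <- sim_scenario(n_epochs = 960, mislabel = 0.2, seed = 7)
night <- simulate_pair(s)
rep <- compare_night(night$psg, night$device, run_config("II"))
rep
rep$lmi$rates$correct          # percent of transition epochs agreed
rep$confusion$accuracy         # epoch-by-epoch accuracy, ~ 100 * (1 - 0.2)
head(as.data.frame(rep$lmi))   # chronological per-transition record
```
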