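# hypnomatch

Validation of wearable sleep-tracker hypnograms against polysomnography
(PSG) ground truth.

Consumer sleep trackers report the night as a hypnogram over a coarse stage
alphabet — Wake–Light–Deep ("type II" devices) or Wake–REM–Light–Deep
("type I") — while PSG is scored by physicians into the five AASM stages
(Wake, N1, N2, N3, REM). Because most of the night is sleep, whole-night
agreement statistics overestimate how well a tracker follows the *dynamics*
of sleep: a device that never leaves "Light" still gets high accuracy.
`hypnomatch` is for sleep researchers and device developers who need a
benchmark that keeps the chronology.

## What it computes

* **Synchronization and epoching** — paired hypnograms aligned by clock
  time on the PSG's 30-s epoch grid (`read_hypnogram`, `synchronize`).
* **AASM-based categorization** — PSG stages mapped to the device alphabet:
  N1/N2 → Light, N3 → Deep, and REM → Deep for type II devices or kept as
  REM for type I (`categorize_psg`).
* **Interrater gating** — Fleiss' kappa
  `κ = (P̄ − P̄ₑ)/(1 − P̄ₑ)` over multiple PSG raters with a κ ≥ 0.8 gate
  (`fleiss_kappa`, `interrater_gate`).
* **Wake–sleep features** — SO, SPT, TST (= TLST + TDST + TRST),
  SE = 100·TST/SPT, WASO = SPT − TST + WAS, and stage percentages
  PLS/PDS/PRS (`extract_features`).
* **Localized mismatch index (LMI)** — stages encoded Wake = 1, Light = 2,
  Deep = 4; at every epoch boundary where at least one scorer changes stage
  (the transition set *A*), the index is the product of the two scorers'
  first differences, LMIᵢ = ΔY\_Wᵢ · ΔY\_Pᵢ. The six legal transitions have
  deltas 1, 3, 2, −1, −2, −3, so 1, 4, 9 certify an exactly reproduced
  transition and every other value names a specific disagreement, grouped
  into correct wake {1, 9}, correct sleep {4}, incorrect sleep {3, −4} and
  incorrect wake (the rest) (`lmi_sequence`, `classify_lmi`,
  `summarize_rates`).
* **Epoch-by-epoch confusion** — per-stage sensitivity/specificity and
  overall accuracy (`confusion`).
* **Paired cohort statistics** — per-feature paired t or Wilcoxon
  signed-rank (chosen by Shapiro–Wilk on the differences), signed paired
  effect size, and per-feature device rankings (`paired_feature_test`,
  `cohort_report`).
* **Synthetic nights** — a first-order Markov PSG simulator with a
  controllable device-error channel (mislabeling, scoring lag, dropout) and
  exact ground-truth bookkeeping, so every metric has a closed-loop test
  (`sim_scenario`, `simulate_pair`, `simulate_cohort`).

## Worked example

Simulate an 8-h night (960 epochs of 30 s) scored by a type II device with
a 20% uniform mislabel rate, and compare it with its own PSG ground truth:

```r
library(hypnomatch)
s <- sim_scenario(n_epochs = 960, mislabel = 0.2, seed = 7)
night <- simulate_pair(s)
rep <- compare_night(night$psg, night$device, run_config("II"))
rep
#> <night_report> 960 epochs, accuracy 79.38%, correct transitions 15.50%
rep$confusion
#> <confusion_summary> 960 epochs, accuracy 79.38%
#>              Wake Light  Deep
#> sensitivity 86.05 80.11 77.54
#> specificity 89.75 88.73 90.27
rep$features_device
#> <sleep_features>
#>   SO 22:33:30 (epoch 7, 3.5 min)  SPT 476.5 min  TST 414.5 min
#>   SE 87.0%  WASO 62.0 min  PLS 58.1%  PDS 41.9%  PRS -
head(as.data.frame(rep$lmi), 3)
#>   epoch delta_psg delta_device lmi           class
#> 1     6         1            1   1    correct_wake
#> 2    10         0            2   0 incorrect_sleep
#> 3    11         0           -2   0 incorrect_sleep
```

Reading the numbers: the planted 20% mislabel rate reappears as the 79.4%
epoch accuracy, but the transition-level view is far harsher — only 15.5%
of the 387 boundaries where either scorer changed stage agree, because
random mislabeling creates many spurious one-sided transitions (the
`lmi = 0` rows: the device transitioned, the PSG did not). The device's
feature set also shows the inflation of WASO (62 vs 18 min for the PSG
scorer) that epoch noise produces. This gap between respectable accuracy
and poor transition agreement is exactly what the localized index is
designed to expose.

## Command line

```sh
inst/cli/hypnomatch compare  --psg psg.csv --device dev.csv --device-type II --out out/
inst/cli/hypnomatch simulate --scenario inst/extdata/default_scenario.yaml --out data/ --seed 1
inst/cli/hypnomatch cohort   --manifest data/manifest.csv --out out/
```

The CLI is a thin wrapper over the package functions; results are identical
to direct library calls. See the vignette
(`vignettes/hypnogram-validation.Rmd`) for the model, design decisions and
simulator limitations.
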