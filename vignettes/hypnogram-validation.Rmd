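---
title: "Validating a consumer sleep tracker against polysomnography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating a consumer sleep tracker against polysomnography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Wrist-worn consumer trackers estimate sleep from movement and heart rate and
report a hypnogram in 1-minute epochs over four stages (wake, light, deep,
REM). The clinical reference, polysomnography (PSG), is manually scored in
30-second epochs over the five AASM stages (W, N1, N2, N3, REM). Validating
a tracker therefore requires three things before any statistics can be
computed: a common epoch grid, a common stage vocabulary, and a common
analysis window. `hypnoval` implements that harmonization and the two
standard layers of comparison used in consumer-sleep-technology evaluation
frameworks:

* **epoch level** — 2-way (sleep/wake) and 4-way (wake/light/deep/REM)
  confusion matrices with accuracy, sensitivity of sleep detection,
  specificity of wake detection, and Cohen's chance-corrected kappa;
* **parameter level** — per-night summary parameters (TST, WASO, SOL, SE,
  stage minutes, awakenings) compared with normality-gated paired tests,
  paired Cohen's *d*, and Bland–Altman limits of agreement.

Because raw per-night recordings of validation studies are rarely published,
the package also ships a synthetic cohort generator with a known
ground-truth error structure, so every stage of the pipeline is testable and
parameter recovery can be demonstrated end to end.

## Harmonization rules

1. **Grid.** Device minutes are split into two 30-s epochs sharing the
   stage (`split_epochs`), conserving total and per-stage duration exactly.
2. **Vocabulary.** PSG stages are merged onto the device's classes
   (`merge_stages`): N1 and N2 collapse into *light*; W→wake, N3→deep,
   REM→REM. The merge is one-way; light sleep is never expanded back into
   N1/N2.
3. **Window.** Analysis is restricted to time in bed (TIB), the
   lights-off → lights-on interval. Devices only report between their
   detected sleep onset and offset, so in-window time not covered by the
   export is scored as wake (`pad_device_wake`). Lights markers that do not
   fall on a 30-s boundary are snapped *outward* (lights-off floors,
   lights-on ceils): widening the window can add a wake epoch but never
   discards scored sleep.
4. **Pairing.** The two 30-s series are paired by absolute timestamp
   (`align_pair`). Grids offset by a non-multiple of 30 s are an error, not
   silently resampled — a sub-epoch offset indicates a synchronization fault
   that resampling would hide. Pairs with an `UNSCORED` member are deleted
   pairwise with a logged count; imputation is out of scope.

## Sleep parameter definitions

With sleep epochs = {light, deep, REM} inside the TIB window:

| parameter | definition | unit |
|---|---|---|
| TIB | lights-on − lights-off | min |
| SOL | lights-off → first sleep epoch | min |
| TSPD | first sleep epoch → end of last sleep epoch | min |
| TST | total sleep-epoch time | min |
| WASO | wake strictly inside the sleep period | min |
| SE | 100 × TST / TIB | % |
| awake | TIB − TST | min |
| awakenings | wake bouts > 5.0 min inside the sleep period | count |

Three definitional choices deserve comment, because published tables rarely
print their formulas:

* **WASO ends at the final sleep epoch.** Terminal wake is excluded. This
  is forced by the identity TSPD = TST + WASO, which published parameter
  tables satisfy exactly for both methods; counting terminal wake would
  break it.
* **The awakening threshold is strict.** "> 5 min" means a bout of exactly
  ten 30-s epochs (5.0 min) does not count; eleven epochs (5.5 min) does.
* **awake = TIB − TST**, i.e. all wake inside TIB including SOL and
  terminal wake. Published cohort means are ambiguous between this and
  SOL + WASO (the two candidates differ by bouts outside the sleep period);
  neither reproduces every printed mean exactly, so the package uses the
  definition that is self-consistent with its other identities. SE uses the
  standard 100 × TST/TIB; note that a cohort's mean SE is a mean of ratios
  and cannot be recovered from mean TST and mean TIB.

These choices make TST = light + deep + REM and TSPD = TST + WASO exact
identities on *every* computed record, and both are enforced by
property-style tests.

## Epoch agreement: pooled versus per-participant

Validation papers mix two summaries that are numerically different:
*pooled* metrics computed on the cellwise sum of all participants' confusion
matrices, and the *mean (SD)* of per-participant metrics. For the packaged
reference counts the pooled 2-way kappa is ≈ 0.28 while the per-participant
mean is ≈ 0.22 — both are correct answers to different questions (epoch-level
versus night-level agreement). `cohort_agreement` computes and labels both;
nothing in the package silently prefers one.

Kappa is `(p_o − p_e)/(1 − p_e)` with `p_e` the usual product of marginals.
Degenerate matrices (a single occupied class, `p_e = 1`) are reported as 1
when observed agreement is perfect and 0 otherwise, with a flag — standard
packages disagree here, so the convention is explicit. Ordinal kappa labels
use the conventional bins (slight/fair/moderate/substantial/almost perfect);
since the published bin edges are stated to two decimals (0.20 / 0.21, …),
boundaries are placed at 0.205, 0.405, 0.605, 0.805 so that values printed
as 0.20 and 0.21 land in adjacent bins. Per-class 4-way metrics are reported
as *both* recall (row-wise) and PPV (column-wise), because published
"per-stage agreement" figures mix the two families; neither is privileged.

## Parameter statistics

* **Test choice.** Differences (reference − device) are tested with the
  paired two-tailed *t* test when Shapiro–Wilk does not reject normality at
  α = 0.05, otherwise with the Wilcoxon **signed-rank** test. Validation
  papers sometimes name the unpaired "Mann–Whitney" test here, but the
  design is paired; the signed-rank test is the coherent nonparametric
  choice. Its *z* statistic uses the normal approximation with tie
  correction and continuity correction (checked against `stats::wilcox.test`
  in the tests). Constant differences (Shapiro–Wilk undefined) route to the
  Wilcoxon branch with a flag.
* **Effect size.** Paired Cohen's *d* = mean(diff)/SD(diff) with the sample
  (n−1) SD throughout. The n−1 convention is confirmed by published tables
  in which the printed *d* equals printed bias / printed SD to printed
  precision for most parameters; rows where the printed numbers are
  internally inconsistent are documented and not asserted.
* **Bland–Altman.** bias = mean(ref − dev); limits = bias ± 1.96 SD; the
  95% CI of the bias uses the *t* distribution. Positive bias means the
  device *under*estimates. The exceedance count uses strict inequality.
* **No multiplicity correction** is applied by default, matching standard
  practice in this literature; `p.adjust` can be applied to the comparison
  table by the user.

## The synthetic cohort generator

The generator's purpose is testability with known truth, not physiological
realism.

* **PSG model.** A first-order Markov chain over the five AASM stages at
  30-s steps, started in wake at lights-off, with TIB drawn from a normal
  (mean 443.58, SD 44.98 min) truncated at 240 min and rounded to whole
  minutes. First-order dynamics are the minimal structure with controllable
  stage occupancy and bout lengths. Group presets (`psg_preset`): the
  sleep-disorder preset has higher wake-entry rates and lower N3 occupancy.
  Preset entries were calibrated once against the finite-horizon expected
  occupancies (matrix powers of the transition matrix, horizon = mean TIB)
  so that expected stage minutes land near a clinical validation cohort's
  means — total TST ≈ 345 min and deep sleep ≈ 73 vs ≈ 51 min for the
  no-disorder vs disorder presets. These are calibration targets, not
  asserted equalities; tests compare the simulation against the *chain's
  own* analytic expectation, which is exact.
* **Device model.** The true hypnogram is merged to four stages and
  coarsened to 1-minute frames by majority vote (ties to the earlier epoch —
  for two 30-s epochs this is the first epoch's stage). Each frame emits a
  device stage from the row of a 4×4 emission matrix
  P(device | reference); the default is the row-normalised pooled 4-way
  confusion of a real tracker, so default cohorts reproduce the qualitative
  findings (sleep sensitivity ≫ wake specificity, negative TST bias, REM
  called light). The record is truncated to start at the first emitted
  sleep frame, emulating exports that begin at detected sleep onset.
* **Quantization caveat.** Minute framing is lossy whenever a stage run
  ends mid-frame: the frame takes one stage, the reference keeps both. With
  the calibrated presets ≈ 3% of epochs sit in such mixed frames, so even a
  noiseless device (identity emission) yields kappa slightly below 1
  through the full pipeline. The noiseless test therefore uses a
  frame-aligned truth (stages constant within each minute), where kappa is
  exactly 1; and emission recovery (`estimate_emission`) cross-tabulates
  device frames against the *frame-majority* labels the emission was
  actually applied to, dropping each record's first frame (whose emission is
  conditioned on being sleep by the truncation rule) — an unbiased
  estimator, unlike the pipeline's 30-s pooled confusion.
* **What the generator does not emulate:** ultradian cycle timing, REM
  latency structure, inter-night within-subject correlation, device clock
  drift, and missing data from device failures. Passing recovery tests
  demonstrates the *pipeline's* correctness, not device performance on real
  nights.

## File formats and numerical conventions

EDF+ annotation files carry stages as standard texts (`Sleep stage W`,
`Sleep stage N1`, …). The 4-stage vocabulary's merged light class has no
standard text; files use the dedicated text `Sleep stage L` with the
vocabulary tagged in the recording-identification header field, so
round-trips are lossless and no pretended N1/N2 detail is written. Gaps
between annotations become `UNSCORED` epochs (device exports omit pre-sleep
time by design); overlapping stage annotations are an error. The epoch
duration is implied by the annotations (GCD of stage durations). Timestamps
are stored at 1-s precision; epochs are half-open `[onset, onset + d)`.
Device CSVs use a package-defined dialect (`timestamp_iso8601,stage`)
because vendor apps do not publish a schema; an adapter hook accepts other
layouts.

## Problem sizes used by the test suite

The suite checks the sleep-parameter path against a brute-force per-epoch
oracle on 1,000 random nights, agreement metrics against a naive counting
oracle on 500 random pair series, generator occupancy against the exact
finite-horizon expectation over 400 nights per preset, Bland–Altman recovery
over 200 replicates of 45-night cohorts, and emission recovery on one
45-night cohort; the whole suite runs in under two minutes on one CPU.

## Known limitations

* No signal-level processing: the package consumes scored hypnograms, never
  raw EEG/EMG/accelerometry.
* No offset correction between the two devices' clocks is applied by
  default; grids must agree modulo 30 s.
* Kappa confidence intervals and prevalence-adjusted variants are out of
  scope, as is regression-based (proportional-bias) Bland–Altman.
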