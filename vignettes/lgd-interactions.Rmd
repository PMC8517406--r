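---
title: "Measuring local-by-global auditory novelty interactions in intracranial EEG"
author: "lgdint authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring local-by-global auditory novelty interactions in intracranial EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lgdint)
```

## The scientific problem

Auditory cortex tracks novelty at more than one time scale. In the
local/global deviant (LGD) paradigm, each trial is a quintuple of 100 ms
vowels (/a/ or /i/) with 50 ms gaps: the first four vowels are identical and
the fifth either repeats them (local standard, LS) or differs (local
deviant, LD). Across a sequence, one quintuple is frequent (global standard,
GS) and the other rare (global deviant, GD; the behavioral target). Crossing
the two factors yields four conditions — LSGS, LDGS, LSGD, LDGD — and the
question this package quantifies is whether the two novelty systems
*interact* at a recording site:

$$
L \times G = (\mathrm{LDGD} - \mathrm{LSGD}) - (\mathrm{LDGS} - \mathrm{LSGS})
$$

computed on trial-averaged high-gamma (70–150 Hz) power. A **positive**
interaction means the "double surprise" LDGD response exceeds LSGD beyond
what the LD main effect predicts; a **negative** interaction means the
reverse. Because the contrast is a difference of differences, the response
measure must be non-negative for its sign to be interpretable — hence power
(µV²), never voltage or dB.

The pipeline covers the full path from a continuous multichannel recording
plus a trial events table to: per-site interaction waveforms, cluster-based
permutation significance, site classification by interaction sign, regional
prevalence/latency summaries across arousal states (awake W, sedated S,
unresponsive U), and signal-detection behavioral metrics for the GD target
task.

## The measurement chain and its assumptions

1. **Resampling** to the 1000 Hz analysis rate (anti-alias FIR, then cubic
   spline onto the target grid). Assumes in-band content below 450 Hz is
   what matters; verified by amplitude preservation of a 100 Hz probe to
   within 1%.
2. **Line-noise suppression** by least-squares regression of sine/cosine
   components at the line frequency (default 60 Hz, fundamental only;
   harmonics opt-in) in 30 s chunks. Each chunk loses only 2 degrees of
   freedom per harmonic, so broadband content is preserved to well under
   1 dB while a stationary line component is removed essentially completely.
   The method assumes the line is locally sinusoidal with slowly drifting
   amplitude/phase; the chunk length is the knob trading drift tracking
   against broadband absorption (expected relative RMS absorption is
   $\sqrt{2H/n_{\text{chunk}}}$ for $H$ harmonics).
3. **High-gamma bandpass**: 300th-order Hamming-window FIR, 70–150 Hz,
   applied forward–backward. The zero-phase choice matters: onset latencies
   are a reported quantity, and a single-pass filter would shift them by the
   group delay (150 ms). A single-pass variant with explicit delay
   compensation is available (`zero_phase = FALSE`).
4. **Artifact rejection**: per site, mean and SD of the band-filtered
   voltage are computed once over the whole block; a trial is excluded if
   any sample in its epoch window (−600 to +800 ms around the 5th-vowel
   onset) deviates more than 5 SD from the block mean. We screen epoch
   samples only — deflections between trials cannot contaminate a trial
   average and are ignored.
5. **Power envelope**: square, then 50 ms centered running average (window
   shrinks at the series edges; the edges lie outside the 0–800 ms test
   window at the chosen epoch span, so truncation never touches the
   statistics).
6. **Epoching**: one row per *test* trial (habituation excluded), t = 0 at
   the 5th-vowel onset; all windows are half-open `[start, end)` and time
   t ms maps to sample `floor(t * fs / 1000)`.

## The interaction statistic and its null

Condition means use unmasked test trials only. The reported waveform is the
difference-of-differences, baseline-corrected by subtracting its own mean
over `[-600, 0)` ms — the half-open window excludes the t = 0 sample, which
is already response territory. Baseline correction applies to the *reported*
waveform; the test statistic below is computed on trials directly, where an
additive constant cancels in the contrast anyway.

Significance over 0–800 ms uses a cluster-based permutation test:

* **Pointwise t**: the 2×2 interaction contrast divided by its pooled-SD
  standard error, $t = \hat{c} / (s_p \sqrt{\sum_c 1/n_c})$ with
  $df = N - 4$. The paradigm is heavily unbalanced (within a four-sequence
  block: 144/144/36/36 trials), which the $1/n_c$ weights absorb. This
  pooled-contrast t is exactly the interaction coefficient t of a saturated
  two-factor linear model, and the test suite cross-checks it against
  `lm()` to 1e-10. A Welch-style variant was considered and rejected as the
  default: the permutation scheme assumes exchangeability under the null,
  which the pooled statistic matches.
* **Cluster formation**: threshold at the two-tailed 1% tail of Student's
  T(df), i.e. the 0.995 quantile (we read "1st percentile tail of the
  two-tailed distribution" as two-tailed α = 0.01; configurable). Maximal
  runs of suprathreshold points of one sign form clusters; the cluster
  statistic is the sum of t values in the run.
* **Monte Carlo null**: condition labels are reshuffled across trials
  (group sizes preserved) 10,000 times by default; each partition's largest
  absolute cluster statistic enters one pooled two-sided null (positive and
  negative maxima are not split by sign — the alternative is available via
  the observed-side comparison if needed, but one two-sided family is the
  default because a single "largest cluster statistic" per partition is
  collected). Cluster p-values use the $(1+k)/(1+n)$ convention so p is
  never 0, and the permutation loop runs in compiled code with R's RNG, so
  results are bit-reproducible given a seed.
* **Classification**: a site exhibits a positive (negative) interaction iff
  it has at least one significant (p < 0.05) cluster of that sign; a site
  may be both. Onset latency per sign is the start of the first significant
  cluster.

Multiple comparisons across time are controlled by the max-statistic; across
sites no further correction is applied (prevalence is reported per-site at
α = 0.05).

## The synthetic-data generator

The study's raw recordings are not redistributable, so the generator is the
package's ground-truth-bearing input. Per site it emulates:

* **1/f background** (spectral shaping of white Gaussian noise, power
  exponent 1.0) at `noise_sd` = 3 µV, plus a 60 Hz line component
  (`line_amp` = 2 µV, random phase).
* **Vowel-locked gamma bursts**: a 110 Hz carrier (band center) under a
  100 ms Hann envelope at every vowel onset, amplitude `base_amplitude` =
  1 µV. Only the 5th-vowel burst is condition-modulated: ×`ld_gain` (1.3)
  on LD trials, ×`gd_gain` (1.2) on GD trials. These defaults put evoked
  bursts at roughly the band-limited background level — a realistic evoked
  high-gamma signal-to-noise ratio for responsive sites, and one that keeps
  ordinary responses safely inside the 5 SD artifact criterion.
* **The injected interaction**: a second carrier at 130 Hz whose squared,
  smoothed envelope adds exactly `abs(interaction_amp)` µV² over
  `[effect_onset, effect_onset + effect_duration]` after the 5th vowel, on
  LDGD trials for positive amplitudes and LSGD for negative. The 20 Hz beat
  between the two carriers is nulled *exactly* by the 50 ms running-average
  window (a 20 Hz cosine integrates to zero over 50 ms), so injected power
  is additive — which is what makes the injection a clean ground truth for
  the difference-of-differences.
* **Arousal attenuation**: per-state multipliers (W = 1, S = 0.4, U = 0.1)
  scale the deviance gains (their excess over 1) and the interaction
  amplitude, emulating the progressive suppression of novelty responses
  under sedation and unresponsiveness.
* **Behavior**: targets are pressed with condition-specific hit
  probabilities (defaults LDGD 0.85 vs LSGD 0.60) at
  `5th-vowel onset + max(rt_floor, N(rt_mean, rt_sd))`; the default RT means
  (420 ms LDGD, 516 ms LSGD) reproduce the double-surprise advantage in the
  grand median RTs. Non-targets false-alarm at 2% per trial.
* Optional rare high-amplitude transients (1% of trials in the demo config)
  exercise the artifact-rejection rule, and every injected effect is written
  to a ground-truth JSON sidecar for parameter-recovery tests.

What the generator does **not** emulate: evoked low-frequency potentials,
cross-site covariance, non-stationary background (drowsiness spindles,
epileptiform activity), burst latency jitter, or any biophysical cortical
model. Passing tests therefore demonstrate that the *analysis* recovers
known effect structure from signals with realistic spectra and SNR — not
that it is robust to every pathology of clinical recordings.

"Noise floor" in the recovery conditions means the SD of the high-gamma
power envelope over the baseline window, pooled across trials and time
(`power_noise_floor()`): it is the measurement noise an injected power
increment competes against.

## Paradigm bookkeeping choices

The test-trial order within a sequence is "pseudorandom"; the package's
reading is a uniform draw over arrangements with **no two GD trials
adjacent** (deviant runs would let expectation build differently). This is a
documented choice, recorded in the events config, and can be disabled
(`no_adjacent_gd = FALSE`). Recorded task instructions are represented only
as a configurable silent gap before each sequence. All schedule times are
integer milliseconds; onset-to-onset intervals are Gaussian (mean 1500 ms,
SD 10 ms).

## Behavioral scoring

A press counts as a hit only between the 5th-vowel onset of a target and the
onset of the following trial; a press inside a non-target trial's span is a
false alarm on that trial. One press is assigned to at most one trial, and a
press on a target before its 5th vowel cannot be a hit (the trial stays a
miss unless a later press lands in the window). These rules slightly
undercount detections and bias RTs fast, which is accepted as part of the
scoring definition.

Sensitivity is $d' = Z(\text{hit rate}) - Z(\text{false-alarm rate})$.
Extreme rates (0 or 1) are replaced by $1/(2n)$ and $1 - 1/(2n)$ before the
quantile transform; with `correct_extremes = FALSE` such blocks are flagged
undefined instead, so that blocks without hits can be reported descriptively
rather than numerically. Group inference uses one-tailed Wilcoxon
signed-rank tests across subjects for hit rate and d′ (alternative:
LDGD > LSGD), per-subject two-sided rank-sum tests on hit RTs, and
Benjamini–Hochberg adjustment applied jointly across all of these reported
p-values — that family (2 signed-rank + one rank-sum per subject) is the
package's documented FDR family.

## Regional summaries

ROI assignment is table-driven: the electrode TSV carries each site's ROI
and ROI group, because real assignments require subject-specific anatomy and
physiology that cannot be recomputed here. A deliberately crude MNI-box
assigner (`synthetic_mni_box_roi()`) exists for synthetic data only and is
labeled as such. Left-hemisphere MNI x coordinates are sign-flipped once
(guarded against double application) to pool hemispheres in right-hemisphere
space. Prevalence is the percentage of classified, non-excluded sites in an
ROI group with at least one significant cluster of the given sign in the
given state; sites significant for both signs count once in each sign's
row. Display rounding is 3 significant figures; computations keep full
precision.

The package ships a transcription of the reference regional tables as
regression fixtures. Three percentage cells of the interaction-count table
are internally inconsistent with their own printed counts (STG negative-W,
posterior-STG negative-S, IFG negative-S); the fixture flags them, and the
tests assert the arithmetic recomputed from the counts for those cells
rather than the discrepant printed values.

## Validation problem sizes

The shipped validation suite uses sizes chosen to make its statistical
claims meaningful while keeping a full run comfortably interactive:

* Type-I calibration: 500 independent null sites, 40 trials per condition,
  1000 permutations each; site-level false-positive rate must land in
  [3%, 8%] at nominal α = 0.05.
* Exact-oracle agreement: 2-trials-per-condition instances, where the full
  permutation null is enumerable ($8!/(2!)^4 = 2520$ partitions); Monte
  Carlo p must match the exact p within ±0.02.
* Parameter recovery: 100 replicates per sign of a two-sequence block
  (72 GS + 18 GD per sequence, so 72/72/18/18 trials across the four
  conditions), injected effect at onset 150 ms, duration 200 ms, amplitude
  5× the power noise floor, 500 permutations per replicate; ≥95% detection
  with the correct sign and median recovered onset within [100, 200] ms
  (the 50 ms smoother and the threshold crossing blur onsets by design).

## Known limitations

* The permutation engine assumes trial exchangeability under the null; slow
  within-block drifts that correlate with condition order would violate it.
* Onset latency inherits the smoothing kernel's blur and the cluster
  threshold's conservatism; latencies are comparable within this pipeline
  but not absolute physiological onsets.
* The plain-text recording container is convenient and portable but not
  space-efficient; for large datasets users should keep recordings in their
  native acquisition format and construct `continuous_recording` objects in
  memory.
* With 18 GD trials per sequence, d′ and hit-rate estimates per block are
  coarse; the group tests are rank-based for exactly that reason.
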