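---
title: "Methods: accommodative step-response analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: accommodative step-response analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accomstep)
```

This vignette is the package's own account of its science: the processing
and inference chain, the synthetic-data model behind the tests, the
numerical choices, and what the validation studies do and do not show.

## The measurement and its two metrics

Dynamic photorefraction samples the refractive state of both eyes at
50 Hz while a participant steps accommodation between a 1 m target (1 D
demand) and a 40 cm target (2.5 D demand) — a 1.5 D step. Each of the
seven Maddox cue conditions (`BDP`, `BD-p`, `BP-d`, `DP-b`, `B-dp`,
`D-bp`, `P-bd`) contributes one session of interleaved far-to-near
("focus") and near-to-far ("defocus") movements, 5 s each, with a
randomized 0.5–2 s onset delay inside each movement window to defeat
anticipation.

Accommodation is modeled in the field as a dual-mode controller: a
preprogrammed open-loop pulse that launches the response, and a
closed-loop feedback phase that settles it on the demand. The two
per-movement metrics separate these components:

* **peak velocity** (D/s) — the extremum of the differentiated response,
  indexing the preprogrammed pulse;
* **final amplitude** (D) — the mean of the last 0.5 s (25 samples) of
  the baseline-aligned position, indexing feedback closure; divided by
  the 1.5 D demand it is the response **gain**.

## Processing chain and its fixed order

`interpolate → filter → calibrate → align → segment → differentiate`

1. **Eye substitution.** Accommodation is consensual, so a sample missing
   in one eye is copied from the other (`substitute_eye()`); samples
   missing in both eyes stay missing.
2. **File rejection** (`apply_rejection()`), judged on the repaired
   signal: ≥ 25 % combined missingness, fewer than 750 valid samples
   (15 s), or a gap of ≥ 225 consecutive samples (4.5 s) rejects the
   file. All three thresholds follow the stated wording literally
   (inclusive ≥ for the first and third, strict < for the second) and are
   configurable. The nominal 7500-sample session length is reported as a
   completeness ratio, not used for rejection. A switch
   (`presubstitution = TRUE`) evaluates the rules before repair, in which
   case a sample with *either* eye missing counts as compromised.
3. **Gap interpolation** (`interpolate_short_gaps()`): linear between
   flanking valid samples, nearest-value fill at the edges; the original
   mask is kept so that movement windows with > 10 % interpolated samples
   can be flagged.
4. **Filtering** (`lowpass_filter()`): 5th-order Butterworth, 20 Hz
   cut-off, applied forward–backward so the filter is zero-phase and
   cannot bias peak-velocity timing. Two consequences are documented
   rather than hidden: the effective response is $|H|^2$, so the cut-off
   sits at −6 dB (a 20 Hz tone leaves with half its amplitude), and the
   whole recording is filtered *before* segmentation so the 5-s windows
   carry no filter edge transients.
5. **Calibration**: multiplication by the per-recording scalar from the
   file header (default 1.0). Photorefraction slopes vary between
   individuals; the per-participant lens-calibration experiment is out of
   scope, so the factor is configuration, not estimation.
6. **Segmentation and alignment** (`segment_movements()`): one 5-s
   window per logged event, baseline-aligned by subtracting its first
   sample; windows running past end-of-file are dropped with a warning
   count.
7. **Differentiation** (`compute_velocity()`): central differences
   (exact for quadratics) with one-sided differences at the window edges.

The two eyes are averaged after substitution; the analysis signal is the
mean of OD and OS. Group-average curves (`align_at_peak_velocity()`)
shift each trace so its peak-velocity sample maps to a common index
before averaging — with randomized onsets, naive time-locked averaging
would smear the group response.

## Outlier policy and inference

Movement validity flags operationalise exclusions whose original
operational definitions are not stated; the defaults are deliberate
conventions, all configurable via `validity_thresholds()`:
`NON_RESPONSE` below 0.2 D of final amplitude on a 1.5 D step, `NOISE`
above 25 D/s anywhere in the velocity trace, `ARTIFACT` above 10 %
gap-interpolated samples in the window.

Two outlier levels follow:

* **intra-participant**: a single-pass 2-SD rule per
  participant × cue × direction cell, applied independently to PV and FA
  (a movement can be an outlier for one metric and not the other); mean
  and sample SD are computed once, `sd = 0` flags nothing, and cells with
  fewer than 3 movements skip the rule with a warning;
* **inter-participant**: 1.5 × IQR labeling of participant-level values
  per cue, with quartiles by linear interpolation of order statistics
  (`quantile(type = 7)`), applied inside `main_effect_workflow()` before
  inference.

Inference per metric × direction stratum runs on participant-level
magnitudes: Levene (classical mean-centered; Brown–Forsythe optional) and
per-group Shapiro–Wilk record the assumption report; the main effect uses
the tie-corrected Kruskal–Wallis statistic with the chi-square
approximation on $k-1$ degrees of freedom (appropriate at these group
sizes; the exact permutation distribution appears only as a test oracle);
if significant at $\alpha = 0.05$, Dwass–Steel–Critchlow–Fligner all-pairs
comparisons follow. Each DSCF pair mid-ranks the pooled values,
standardizes the rank sum by its exact tie-corrected permutation moments,
scales by $\sqrt2$, and refers $|W|$ to the studentized-range distribution
$q(k, \infty)$, which controls the familywise error over all
$\binom{7}{2} = 21$ comparisons. Degenerate cases return explicit
conventions rather than errors: all-tied pools give $W = 0$, $p = 1$ with
a `degenerate` flag; an all-identical Kruskal–Wallis pool returns $H = 0$,
$p = 1$.

## The synthetic-data generator

No recordings are distributed with the study, so the generator *is* the
test bed. It emulates the design exactly where the design is stated, and
uses labeled conventions elsewhere.

**Stated by the design** (and fixed as defaults): 50 Hz sampling; 5-s
movements; 30 movements per binocular cue session and 60 per monocular
cue, focus/defocus interleaved; 1.5 D steps; onset delays uniform in
0.5–2 s; per-cue final-amplitude gain targets
`BDP 0.97, BD-p 0.97, BP-d 0.80, B-dp 0.71, DP-b 0.60, D-bp 0.55,
P-bd 0.33` (the two near-unity and the lowest value are calibrated to the
qualitative descriptions "closest to the 1.5 D target" and "about
0.5 D").

**Package conventions** (no stated values exist; chosen once to look
physiologic and documented here):

* response form: a single first-order exponential,
  $x(t) = \text{baseline} \pm A\,(1 - e^{-(t-t_0)/\tau})$, the minimal
  form consistent with the published single-participant morphology; its
  theoretical peak velocity is $A/\tau$ at onset. An optional boxcar
  velocity pulse (`pulse_height`, `pulse_width`) is available for
  dual-mode experiments and off by default (note it shifts the settled
  level by `pulse_height * pulse_width`);
* $\tau \sim U(0.20, 0.35)$ s per movement, spanning peak velocities of
  roughly 4–8 D/s at 1.5 D amplitude;
* per-movement amplitude jitter: SD 0.05 D around the cue target;
* measurement noise: white Gaussian, SD 0.1 D per sample and eye;
* defocus movements are sign-flipped focus movements with an
  independently configurable gain table (defaults equal);
* blink/dropout artifacts: per-sample gap start probability $10^{-3}$
  per eye, geometric lengths with mean 12 samples (~0.24 s);
* layout: each movement occupies one contiguous 5-s slot with the onset
  delay inside it, so a 30-movement session is exactly 150 s
  (7500 samples), matching the nominal session length; the refraction
  state carries over between slots as in a continuous recording;
* seeds: master seed → per-recording → per-artifact streams through a
  multiplicative hash (`derive_seed()`), so identical configurations
  produce byte-identical cohort files.

**What the generator does not emulate** — and therefore what passing
tests cannot show about real data: instrument-specific noise spectra and
slow drift, pupil-size dependence of the photorefraction slope, actual
blink kinematics (gaps are clean excisions), latency differences between
cue conditions, participant-level heterogeneity of gain or dynamics
(between-participant variance is measurement-driven under the defaults),
and any vergence trace. Conclusions about the *pipeline* transfer;
conclusions about *physiology* do not.

## Numerical choices

* **Filter edges.** Forward–backward filtering with zero initial
  conditions produces large transients on signals with nonzero baseline
  (~0.24 D on a constant, measured during development). `lowpass_filter()`
  therefore demeans, pads both ends with odd reflection (≥ 50 samples),
  filters, trims and restores the mean: constants pass through to
  machine precision and edge residuals drop to ~$10^{-6}$–$10^{-5}$ D.
* **Peak-velocity attenuation.** The exponential response has a velocity
  discontinuity at onset; discrete central differences plus the 20 Hz
  zero-phase filter recover 0.87–0.94 of the theoretical $A/\tau$ over
  $\tau \in [0.20, 0.35]$ and worst-case onset phase (0.917 at
  $\tau = 0.25$ with on-grid onset). The validation studies therefore
  check PV to within 10 % and treat FA, which is insensitive to the
  corner, to $10^{-6}$ D on noiseless input.
* **Noiseless FA recovery** is measured on movements interior to a
  recording; the first and last windows touch the recording edge, where
  reflection padding leaves a ~$2 \times 10^{-6}$ D residual.
* **FA recovery coverage** is assessed per cue *and direction stratum*,
  with the pooled movement-level standard error and without the 2-SD
  trim. Three reasons, each measured: adjacent slots alternate direction
  and share boundary samples through the single-sample baseline
  reference, which correlates opposite-direction FA magnitudes (lag-1
  correlation ≈ 0.06) and deflates a direction-pooled SE; within a
  stratum movement FAs are independent (mean off-diagonal correlation
  ≈ −0.001); and the trimmed mean is a different estimand whose
  small-cell trimming inflates sampling variance relative to the
  trimmed-sample SE. A participant-level SE at $n = 20$ would turn a
  2-SE check into a ~94 %-coverage $t(19)$ interval by construction.
* **Ties** everywhere use mid-ranks; quartiles use linear interpolation
  of order statistics; all inclusive/exclusive threshold choices follow
  the stated wording and are asserted at their boundary values in the
  test suite.
* **Type-I control** of the Kruskal–Wallis stage is studied at the
  participant-summary level (7 groups × 20 iid values per replicate):
  the test consumes only participant-level values, so simulating full
  signal cohorts for 1000 replicates would add cost, not information.

## Validation studies and problem sizes

The test suite runs three simulation studies, sized to exercise the
study design while keeping a default test run in minutes:

* *recovery/ordering*: 100 replicate cohorts of 20 participants × 7 cues
  at 0.1 D noise (`fa_recovery_study()`); per cue × direction the pooled
  mean FA is compared with `gain × 1.5 D` at ± 2 SE, and per replicate
  the focus-FA group means must preserve the partition
  `{BDP, BD-p} > {BP-d, B-dp, DP-b, D-bp} > {P-bd}` and a significant
  main effect. A 2-SE interval has ~95.4 % nominal coverage, so the
  observed rate is expected to fluctuate around 0.95 between seeds —
  calibration runs of 200–300 replicates per stratum gave z-SD
  0.94–0.99.
* *Type-I*: 1000 null replicates (`kw_null_study()`), expecting a
  rejection rate near 0.05.
* *oracle equivalence*: exhaustive enumeration (1680 assignments for
  Kruskal–Wallis on 3 × 3; all 70 rank-sum splits per DSCF pair at
  4 + 4) — exact, not sampled.

## Known limitations

* The DSCF reference distribution uses $q(k, \infty)$; for very small
  groups the familywise control is approximate (its moments, however,
  are the exact permutation moments even under ties).
* The chi-square approximation to the Kruskal–Wallis null is used
  throughout; with 7 groups of ≥ 20 it is accurate, but the package does
  not provide exact permutation p-values outside the test oracles.
* `shapiro_wilk()` delegates to the host implementation of Royston's
  approximation; it gates workflow branching only.
* Peak velocity on noisy traces is biased upward by the extremum over
  250 velocity samples; the bias is common to all cue conditions and
  does not affect FA, but absolute PV values from noisy recordings
  should be read with that in mind.
* The recording dialect is the package's own plain-text CSV; proprietary
  instrument formats are not parsed.
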