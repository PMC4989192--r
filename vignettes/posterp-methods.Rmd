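---
title: "Post-error adjustment analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Post-error adjustment analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posterp)
```

# The scientific problem

After committing an error, people adjust: responses slow down (post-error
slowing, PES) and accuracy improves (post-error improvement of accuracy,
PIA). In an equiprobable visual Go/No-go task the error of interest is the
false alarm (FA) — a button press to a No-go stimulus. The
electrophysiological question is what happens *before* the next stimulus:
does the brain change its preparatory set after an error? Two slow
pre-stimulus ERP components index preparation: the prefrontal negativity
(pN), a slow negative ramp over prefrontal sites (Fp1/Fp2) linked to
top-down attentional/inhibitory control, and the Bereitschaftspotential
(BP), a slow central negativity (C1/Cz/C2) generated largely by the
supplementary motor area and indexing motor readiness. The analysis this
package implements compares trials that follow an FA (post-error) with
trials that follow a correct response (post-correct), together with the
visual P1 (PO8) and N1 (PO7) components, behavioral summaries (conditional
FA rates, median RTs, PES, PIA), signal-detection measures, and the
inferential layer (repeated-measures ANOVAs, Bonferroni post-hocs, paired
t-tests, Pearson correlations).

Because no human dataset ships with the package, a first-class synthetic
cohort generator produces event logs and continuous EEG with known ground
truth, so every stage of the pipeline is verifiable end to end.

# The task and behavioral model

`task_config()` encodes the design: 10 blocks of 80 trials, four stimulus
identities at p = 0.25 each (two Go, two No-go — 400/400 exactly, balanced
within block), 260 ms stimulus duration, SOA uniform on 1000–2000 ms,
EEG at 250 Hz.

`behavior_profile()` is a first-order sequential response model:

* On a No-go trial, P(FA) depends on the previous trial's outcome:
  0.111 after a correct trial, 0.0404 after an FA (the condition-mean
  calibration of the generator).
* Hit RTs are log-normal, parameterized by the median (408 ms pre-error,
  445 ms after an FA; FA RTs have median 395 ms) with a multiplicative
  spread chosen so the RT standard deviation is about 65 ms. A log-normal
  family was chosen because RTs are right-skewed and the analysis
  summarizes them by medians, which the median parameterization makes
  exact: the injected PES is the difference of medians, 37 ms.
* Misses occur at a small default rate of 0.01. No miss rate is part of
  the calibration targets; the non-zero default exists so the
  signal-detection ceiling-correction path (hit rate 1 → 1 − 1/(2N)) is
  exercised in realistic cohorts. It is a stated guess, not a calibrated
  value.
* The first trial of a block has no predecessor and uses the
  after-correct parameters; sequential context never crosses block
  boundaries (blocks are separated by rest).

A button press is attributed to the most recent stimulus if it falls
100–1000 ms after that onset. Since the SOA is at least 1000 ms this
assignment is unambiguous.

# The EEG forward model

`render_recording()` is linear: recording = noise + sum over trials of each
applicable component template at its lock time. Templates
(`component_template()`, defaults in `default_templates()`) are triangular
time courses projected through per-channel gains and scaled by the trial's
sequential condition:

| component | lock | channels (weights) | time course | condition scaling |
|---|---|---|---|---|
| pN | stimulus | Fp1 (0.86), Fp2 (1.14) | ramp −600 → 0 ms, peak −2.8 µV, decay by +50 ms | post-error × 2.143 |
| BP | stimulus | C1, Cz, C2 (1) | ramp −500 → 0 ms, peak −3.6 µV, decay by +50 ms | post-error × 0.444 |
| P1 | stimulus | PO8 (1), PO7 (0.4) | 60–110–170 ms, +4 µV | none |
| N1 | stimulus | PO7 (1), PO8 (0.4) | 90–160–230 ms, −4 µV | none |
| Ne | response | Cz (1), C1/C2 (0.8), Fp (0.3) | 0–80–200 ms, −2.5 µV | error trials only |
| Pe | response | Cz (0.8), C1/C2 (0.7), Fp (0.4), PO (0.5) | 120–300–560 ms, +2.5 µV | error trials only |

Because the preparatory ramps are linear from their onset to stimulus
onset, the analysis-window mean (pN over −600–0 ms, BP over −500–0 ms)
equals half the peak in closed form: −1.4 µV (pN) and −1.8 µV (BP) in the
post-correct condition, matching the condition means the generator is
calibrated to, with post-error gains 2.143 (= 3.0/1.4) and 0.444
(= 0.8/1.8).

**Why the fast post-stimulus decay and the modest, charge-balanced Ne/Pe.**
The analysis baseline is the first 200 ms of the epoch (−1100 to −900 ms),
which unavoidably overlaps late activity of the *previous* trial. Averaged
over the 1000 ms SOA jitter, a previous-trial waveform contributes its
time-integral, smeared by a trapezoidal lag density. Two consequences
drive the template defaults:

1. Activity common to both conditions (the previous trial's own pN/BP and
   its decay) cancels in condition *differences* but not in amplitude
   *ratios*: a common baseline offset δ turns a true gain g into the
   measured (g·b − δ)/(b − δ). The dominant term in δ is the previous
   ramp's post-stimulus decay tail; ending the decay 50 ms after stimulus
   onset (preparation resolves into the stimulus-evoked response) keeps
   the deterministic ratio error at about +6% (pN) and −10% (BP), inside
   the ±15% recovery tolerance the generator is designed to meet.
   Noiseless wide-SOA simulations (where no neighboring activity enters
   the epoch) recover the gains to numeric precision, which separates
   this smearing effect from any pipeline error.
2. Error-related potentials exist only on the trials *preceding*
   post-error trials, so their smear is a genuine condition difference.
   With a roughly charge-balanced biphasic Ne/Pe pair (areas −0.25 and
   +0.25 µV·s at Cz) the jitter-smeared net contribution to the
   pre-stimulus windows is below 0.04 µV — visible in the error-locked
   averages, negligible in the preparatory measures. Real Ne/Pe
   complexes are often larger and not charge-balanced; on real data this
   leakage is exactly why the package also implements the control
   segmentations (response-locked and previous-stimulus-locked frames
   with a −1500/−1300 ms or 100 ms pre-stimulus baseline, and the
   expanded −2000/+900 ms frame).

The noise model is 1/f background (frequency-domain synthesis, DC-free,
default SD 10 µV, exponent 1; the shaped component is synthesized on a
half-rate grid and linearly upsampled, since its spectral mass lies far
below the half-rate Nyquist and the analysis band ends at 25 Hz), a 10 Hz
alpha sinusoid with random per-channel phase (4 µV), and epoch-level
artifact excursions: with probability 0.05
per trial a 200 ms half-sine of ±200 µV is added at a random time inside
that trial's epoch. The artifact amplitude is required to exceed the
±120 µV rejection threshold so injected artifacts are rejectable by
design. Volume conduction, ocular physiology and 50 Hz line noise are out
of scope (line noise is removed at acquisition in the recording setup this
emulates).

Between-subject structure (`profile_jitter()`) perturbs probabilities, RT
medians, an overall ERP scale (SD 0.3) and the two condition gains
(SD 0.25 for pN, 0.08 for BP), truncated to valid ranges. A subject's
expected post-error BP amplitude additionally shifts their post-error RT
median by +100 ms/µV, so a smaller (less negative) BP means slower
post-error responses; this generative coupling is what the BP–RT Pearson
correlations recover with r ≈ 0.4–0.5. Simulated between-subject spread is
deliberately cleaner than published human cohorts (where per-condition SDs
are several µV); passing recovery tests therefore demonstrates pipeline
correctness under the modeled variability, not expected effect sizes or
power on real recordings.

# The analysis pipeline

Per subject (`analyze_subject()`):

1. **Trial classification** (`classify_trials()`): hits, misses, correct
   rejections, FAs; post-error = previous same-block trial was an FA;
   post-correct = previous was a hit or correct rejection; pre-error =
   next trial is an FA (a trial can be pre-error and carry a post flag).
   Trials after a miss carry neither post flag — a miss is neither a
   correct response nor an FA, so those trials are ambiguous under the
   condition definitions.
2. **Behavioral summary**: conditional FA rates, RT medians, PES
   (positive = slowing), PIA (positive = improvement), and
   `sdt_metrics()` with the 0 → 1/(2N), 1 → 1 − 1/(2N) correction applied
   symmetrically to both rates (the ceiling rule is stated for the hit
   side; the floor rule mirrors it on the FA side).
3. **Evoked construction** (`build_condition_evokeds()`): stimulus-locked
   epochs from −1100 to +900 ms (501 samples at 250 Hz; Go and No-go
   pooled, as the preparatory and early visual components do not
   distinguish them), per-epoch ±120 µV rejection ("exceeding" read
   strictly: an epoch peaking at exactly 120 µV is retained), pointwise
   averaging, 4th-order zero-phase Butterworth low-pass at 25 Hz applied
   to averages only (two passes preserve component latencies and double
   the 24 dB/octave roll-off), then baseline correction over the epoch's
   initial 200 ms. Epochs that would cross the recording edge are dropped
   with a count; epochs neighboring a rejected trial are *not* excluded
   (the SOA jitter decorrelates neighbor activity). A condition with no
   surviving epochs is reported absent, with a reason, never fabricated.
4. **Component quantification** (`measure_components()`): fixed windows —
   pN mean amplitude at Fp1/Fp2 over −600–0 ms, BP at C1/Cz/C2 over
   −500–0 ms, P1 positive peak at PO8 in 60–160 ms, N1 negative peak at
   PO7 in 100–220 ms (peak search windows are package defaults, stated as
   such, and configurable). Data-driven window discovery is available as
   an optional mode: `samplewise_paired_ttest()` across subjects plus
   `select_window()`, which operationalizes "consistently significant" as
   the longest run of consecutive p < α samples lasting at least 40 ms
   (10 samples at 250 Hz) — a standard guard against isolated-sample false
   positives. Fixed-window quantification never depends on the discovery
   heuristic.

Per cohort (`analyze_cohort()` → `build_report()`): subjects enter the
group statistics only with at least one FA and at least 20 artifact-free
FA epochs (inclusive boundary). The report carries the inclusion ledger,
behavioral tables and paired t-tests (PIA, PES, FA-RT comparisons),
group signal-detection means, the two Condition × Site repeated-measures
ANOVAs (pN over Fp1/Fp2; BP over C1/Cz/C2), Bonferroni site post-hocs
within each condition (the multiplier is the whole family of site pairs
across both conditions), paired t-tests for P1/N1 amplitude and latency,
Pearson correlations between post-error amplitudes and the post-error
median hit RT (medians, because the behavioral summary is median-based),
and percent-change effect sizes computed on magnitudes (so "a 56%
reduction" of a negative-going component reads naturally).

# Numerical and statistical choices

* **ANOVA**: classical within-subject partitioning via
  `aov(y ~ A*B + Error(subject/(A*B)))`; each effect is tested against its
  own subject-by-effect interaction. No sphericity correction by default,
  matching integer degrees of freedom such as F(2, 70) for a 3-level site
  factor at n = 36; a Greenhouse–Geisser adjustment is available behind
  `gg_correction = TRUE`. Degenerate inputs: zero effect variance gives
  F = 0, p = 1; zero error variance with non-zero effect gives F = ∞,
  p = 0; incomplete designs are a hard error (no silent imputation). The
  implementation is cross-checked in the tests against a hand-computed
  sum-of-squares decomposition frozen before the build, and F = t² holds
  for 2-level factors.
* **Paired t / correlation**: base `t.test` / `cor.test`; zero-variance
  differences return a signed infinite t with p = 0, flagged.
* **Peaks**: ties break toward the earliest sample; an extremum on a
  search-window edge warns about possible monotonicity.
* **Timing**: sample k of an epoch starting at `start_ms` lies at
  `start_ms + k/rate`; the lock event falls exactly on sample
  `round(−start_ms/1000 × rate)`. Window membership is inclusive at both
  edges with a 1e-6 ms guard against floating-point drift.
* **Determinism**: all randomness flows from one master seed;
  per-subject and per-replicate seeds are drawn from it, so cohorts,
  reports and manifests are bit-reproducible.

# Calibration studies and their sizes

`recover_parameters()` simulates replicate cohorts and compares recovered
quantities with the generator's closed-form injections. The shipped
configuration of the main study is 20 replicates of 36 subjects on the
8-channel analysis montage — large enough that Monte-Carlo error on the
recovered means (≈2% on the gain ratios, ≈1.4 ms on PES) is well below
the tolerances being checked, and small enough to run on a laptop in
minutes. FA-rate recovery uses the unweighted mean of per-subject rates
(the estimator a mean-percentage group summary corresponds to); weighting
by trial count would be biased because error-prone subjects contribute
fewer post-correct trials by construction. The recovered PES carries a
small intrinsic negative bias (≈1–2 ms): pre-error hits can themselves be
post-error trials (an error–hit–error sequence), which drags the pre-error
median slightly toward the post-error one. This is a property of the
condition definitions, not of the estimator, and stays well inside the
±5 ms recovery band.

Null calibration re-runs the pipeline with all condition gains equal, RT
medians equalized, and the response-locked error templates removed
(`null_effect_config()`, 200 replicates of 12 subjects on a 2-channel
montage). The Ne/Pe templates must be removed for a *null* calibration:
their jitter-smeared tail is a genuine post-error/post-correct difference,
so leaving them in would measure the leakage, not the test's
false-positive rate. The rm-ANOVA Condition effect then rejects at the
nominal 5% within binomial tolerance.

# Known limitations

* The forward model is a template-plus-noise abstraction: no volume
  conduction, no ocular or myogenic artifact physiology, no trial-to-trial
  latency jitter of components, and stationary noise. Recovery results
  quantify pipeline correctness, not expected performance on human data.
* The epoch-initial baseline inherits previous-trial activity by
  construction; with realistic (larger, unbalanced) error potentials the
  amplitude *ratios* on real data would be biased in the way quantified
  above, while condition differences and their tests remain clean. The
  control segmentation schemes exist to assess this on any given dataset.
* Percent change is undefined across sign-discordant condition means and
  is flagged rather than forced.
* The d′/C analysis assumes per-subject rates averaged at the group level.
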