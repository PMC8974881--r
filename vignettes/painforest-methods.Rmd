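---
title: "Multimodal discrimination of noxious and non-noxious stimulation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal discrimination of noxious and non-noxious stimulation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(painforest)
```

## The problem

Infants cannot report pain, so clinical research quantifies it through the
responses a noxious event (here, a clinically required heel lance) evokes
across several modalities: facial grimacing, heart-rate acceleration,
oxygen-desaturation episodes, limb reflex withdrawal measured by EMG, and a
stereotyped noxious-evoked potential at the vertex EEG electrode roughly
400–700 ms after the stimulus. Each modality can also be summarised by
several competing measures (for facial activity, three action durations;
for heart rate, a 4 × 6 grid of windowed change statistics; and so on).
Two questions follow naturally: does combining measures *within* a modality
improve discrimination of noxious from non-noxious stimulation, and does
combining *modalities* improve it beyond any single one?

`painforest` frames both questions as supervised classification: each
infant contributes up to two stimulus-locked observations — one after a
real heel lance (noxious) and one after a control release of the same
device without skin contact — and a classifier is asked to tell the two
apart from extracted physiological measures. Discrimination accuracy and
ROC area then quantify how informative a measure set is.

## The classifier: a subject-bootstrapped random forest

The centrepiece is `subject_rf()`, a random forest written from scratch
because the paired design breaks two assumptions of off-the-shelf
implementations:

* **Bagging unit.** Each tree's bootstrap draws S subjects with replacement
  from the S distinct subjects; a subject drawn k times contributes *all*
  of its observations k times. The two paired observations of an infant are
  therefore always jointly in-bag or jointly out-of-bag.
* **Out-of-bag honesty.** An observation's OOB prediction aggregates only
  trees whose bag excludes its *subject*. Without this, the paired
  observation of the same infant could sit in a tree's training set while
  its twin is "held out", and OOB accuracy would be optimistic. With
  subject-level bags the probability that a given subject is out of bag for
  a tree is (1 − 1/S)^S → e⁻¹ ≈ 0.368, which the package checks.
* **Missing data.** Real multimodal cohorts lose whole modalities to
  artifacts, and the training set deliberately retains such subjects.
  Each tree imputes missing features with the medians of its own in-bag
  rows, computed at fit time and stored for prediction, so no out-of-bag
  information leaks into a tree and test-time imputation is deterministic.
  Surrogate splits were considered and rejected: median imputation is
  simpler, transparent, and adequate for whole-modality missingness.

Trees are otherwise classical: Gini impurity splits evaluated at midpoints
between consecutive distinct feature values, per-node feature subsampling
of size `mtry` (default ⌈√p⌉), growth to purity with minimum leaf size 1
and no pruning. Ties in the split search are resolved by feature order and
then by the lower threshold, and a 0.5 vote fraction is labelled control
(flagged as a tie), so fits and predictions are bit-reproducible from a
single seed. Defaults of 1000 trees and ⌈√p⌉ features per node follow
common practice; both are arguments and are echoed in every report.

## Signal measures

All windows are half-open `[a, b)` and expressed in seconds relative to
stimulus onset, so every measure is invariant to the sampling rate up to
discretisation (tested at 500 vs 1000 Hz).

* **EEG.** Traces are band-passed 0.5–70 Hz (4th-order Butterworth, applied
  forward and backward for zero phase) with a Q = 30 biquad notch at
  50 Hz, epoched to [−0.5, 1.0) s and baseline-corrected to the
  prestimulus mean. Two automated magnitudes are computed. `EEGt` projects
  a canonical biphasic template onto the trial over 400–700 ms after Woody
  alignment (the integer-sample shift in ±100 ms maximising normalised
  cross-correlation with the template; ties go to the smallest, then the
  negative, shift). The projection coefficient ⟨x, T⟩/⟨T, T⟩ is linear and
  sign-preserving. `EEGa` is the automated peak-to-peak amplitude: maximum
  over [450, 650) ms minus minimum over [350, 450) ms after Woody
  alignment to the cohort-average noxious epoch — computed from the
  training split only, so no test-set information enters the reference.
* **The template.** No canonical waveform is distributed with infant EEG
  systems, so the package constructs one: a difference of two Gaussians
  (negative lobe at 400 ms, SD 25 ms; positive lobe at 530 ms, SD 45 ms;
  weights set for a 5:7 extrema ratio) refined by power iteration under
  the analysis band-pass until it is a fixed point of the filter
  (eigenvalue ≈ 0.999), then unit-energy normalised. The refinement
  matters: a template containing energy below the 0.5 Hz high-pass edge
  would lose ~7% of its projected magnitude to the filter chain, biasing
  every `EEGt` value downward. A template derived from filtered recordings
  — as validated evoked-response templates are in practice — lives in the
  passband by construction, and the fixed-point refinement reproduces that
  property exactly; closed-loop recovery error of an injected amplitude is
  ~0.3%.
* **EMG.** Both legs' traces are band-passed 10–500 Hz with 50 Hz notch
  harmonics (the upper edge is capped at 0.95 × Nyquist with a logged
  warning when the sampling rate cannot carry it) and epoched to
  [−2, 14.5) s. `RMS` averages root-mean-square over the four 250 ms
  windows of the first post-stimulus second. Reflex `DUR`/`AMP` come from
  a threshold detector: threshold = mean + 3 SD of 250 ms-window RMS over
  the baseline; onset = first supra-threshold window (50 ms steps) starting
  within the first second — reflex withdrawal is short-latency, and an
  unbounded onset scan over 14+ s of 285 overlapping windows would cross a
  3-SD threshold by chance in roughly half of burst-free traces, whereas
  the bounded scan keeps the false-onset rate under 10%; offset = first
  window beginning ≥ 4 consecutive sub-threshold windows, searched to the
  epoch end. A burst without an identifiable offset is flagged and its
  duration/amplitude treated as missing, mirroring how unresolvable reflex
  endpoints are excluded in practice. All five constants are arguments.
* **Heart rate.** Beat times become a per-second bpm series (60 divided by
  the mean RR interval ending in the trailing 5 s window, `NA` when the
  window is empty). From it — and analogously from the raw saturation
  series — the 4 × 6 grid: {mean change, extreme change, and both
  normalised by the prestimulus SD} × windows {5, 10, 15, 20, 25, 30} s,
  against a [−15, 0) s baseline. The extreme is the maximum for heart rate
  and the minimum for saturation. Normalised measures are missing when the
  prestimulus SD is zero — the honest choice, and the forest tolerates
  missingness anyway. The per-second series (not raw RR) feeds the grid,
  since it is the only series the measure definitions reference; the
  saturation baseline mirrors the heart-rate convention (15 s).
* **Facial activity** enters as scored durations (brow bulge, eye squeeze,
  nasolabial furrow, each in [0, 30] s); video scoring itself is a manual
  process out of scope here, so durations are consumed (or simulated)
  directly.

In total 59 measures per observation: 3 facial + 24 heart rate +
24 saturation + 2 EEG + 6 EMG.

## The synthetic cohort generator

No public dataset carries these recordings, so `simulate_cohort()`
generates cohorts with the statistical structure the analysis assumes, and
is itself first-class, tested code.

* Each subject has a latent lognormal **responsiveness** factor (mean 1,
  log-SD 0.7) shared across modalities and between its two conditions.
  This single factor induces the between-modality correlation observed in
  real cohorts and, through its wide spread, the clinically familiar
  phenomenon of infants who barely respond in any modality.
* The noxious observation adds: a template-shaped EEG deflection of
  amplitude 10 µV × responsiveness at a latency jittered uniformly within
  ±50 ms; a shared-onset EMG burst on both legs (burst-noise SD
  1.2 µV × responsiveness ipsilaterally, half that contralaterally; onset
  uniform in [0.05, 0.5] s, duration 0.8–2.5 s, raised-cosine edges); a
  heart-rate rise of 6.5 bpm × responsiveness peaking near 12 s; an
  oxygen-saturation dip of 2.5 percentage points × responsiveness with
  ~5 s lag occurring in 35% of noxious trials; and Gamma-distributed
  facial durations (shape 2) with mean 1 + 2.5 × responsiveness s,
  truncated to the 30 s scoring window. Control observations realise the
  same baseline processes with all effect contributions at zero.
* Baselines: white EEG noise (SD 4 µV) and EMG noise (SD 2 µV) band-limited
  by the downstream filters; heart rate 140 bpm with smooth AR(1)
  variability (SD 4 bpm, 5 s correlation time), converted to strictly
  increasing beat times by time-rescaling the instantaneous rate;
  saturation 97% with AR(1) noise (SD 0.6); baseline grimacing of mean 1 s.
* These effect sizes were set once so that single-measure discriminability
  on a large synthetic cohort lands where multimodal infant studies report
  it — facial and ipsilateral EMG strongest (AUC ≈ 0.83–0.85), heart rate
  and EEG template moderate (≈ 0.79–0.81), contralateral EMG ≈ 0.71 and
  saturation weakest (≈ 0.60) — and then frozen. They are a realism
  choice, not a fit to any particular dataset.
* **Missingness** removes whole modalities from individual observations
  independently (default 5% per modality), emulating per-modality artifact
  loss while leaving enough fully complete subjects to form a held-out
  test set of the size the experiment drivers default to.
* One top-level seed spawns independent per-subject, per-modality
  substreams, so a subject's signals are bit-reproducible regardless of
  cohort size or simulation order.

What the generator does **not** emulate: 1/f EEG background and real
artifact morphology (noise is filter-band-limited white), ECG
contamination of EMG, movement artifacts, oximeter quantisation, or any
dependence of the response on gestational age (ages are drawn uniformly
over 34–43 weeks and independent of responsiveness). Passing tests
therefore demonstrate internal consistency of the pipeline and the
statistical machinery under a plausible data-generating process — not
clinical performance on real recordings.

## Experiments

`run_within_modality()` reproduces the measure-comparison design: per
modality it fits a forest per single measure plus the combined model where
one exists (facial, each EMG leg), ranks models by OOB accuracy then AUC,
and compares each against the modality's reference model (the combined
model, else the best single measure) with the mid-P McNemar test on common
observations and DeLong's test on paired OOB scores.

`run_multimodal()` trains the full model — nasolabial furrow, heart-rate
maximum change over 15 s, saturation minimum change over 30 s, EEG
template magnitude, and both legs' reflex RMS — on training subjects with
at least three modalities, reports OOB metrics overall and stratified by
gestational age (term ≥ 37 weeks vs preterm, Yates-corrected chi-square),
and validates the full model, the six single-measure models, and the
behavioural + physiological subset on the held-out test set. Test subjects
are chosen, in subject order, among those with every modality present and
every measure extractable in both conditions — a reflex without an
identifiable endpoint counts as an artifact — mirroring how a balanced,
artifact-free validation set is assembled in practice; train/test subject
sets are disjoint by construction and by test.

## Evaluation statistics

Wilson score intervals (no continuity correction) accompany accuracy,
sensitivity and specificity. ROC curves enumerate distinct score
thresholds; the trapezoidal AUC equals the Mann–Whitney statistic with
ties counted ½ (verified against exhaustive pair counting). The AUC
confidence interval is a percentile bootstrap with 2000 resamples drawn at
the *subject* level, so paired observations move together — the
resampling unit is a design decision exposed to the user, and percentile
(rather than BCa) bounds are the simplest method consistent with a plain
2000-fold bootstrap. Degenerate resamples that lose a class are redrawn
and counted. Paired model comparisons use the two-sided mid-P McNemar test
(discordant counts referred to Binomial(n, ½) with half weight on the
observed count) and DeLong's structural-component test for correlated
AUCs. Chance comparisons use the exact binomial test
(sum-of-smaller-probabilities two-sided rule, via `binom.test`), and the
term/preterm accuracy comparison a Yates-corrected 2 × 2 chi-square (via
`chisq.test`, with a small-expected-cell flag); Spearman correlations use
mid-rank ties, pairwise-complete observations, and a t-approximation
p-value (adequate above n ≈ 10; pairs with fewer than 3 complete rows are
left missing).

## Numerical choices and degenerate inputs

Filter transients are handled by generating traces longer than the epochs
cut from them. Woody alignment translates samples and discards edges
rather than wrapping; epochs are validated to cover the search window at
the maximal shift. Zero-variance baselines make normalised measures
missing rather than infinite. The split search requires a strictly
positive impurity decrease, so constant features yield leaves, not
arbitrary splits. An observation with zero eligible OOB trees raises an
error naming the remedy (more trees) instead of returning a silent `NA`.
All serialization (cohorts, feature tables, fitted forests, reports) is
plain text with 17-significant-digit numbers, making every round trip
bit-exact and every rerun byte-identical given the same seed.

## Problem sizes

The test suite runs the generator at 250 Hz EEG/EMG sampling (every window
is defined in seconds, so rates are interchangeable; the default remains
500 Hz) with cohorts of 16–120 subjects, and the acceptance checks use the
study-scale design: a 109-subject cohort split 77 train / 32 test at 1000
trees for the flagship experiment, twenty 90-subject replicates at 500
trees for the multimodal-versus-subset comparison, 2000 null simulations
for test calibration and 500 nested replicates for bootstrap coverage.
These sizes were chosen as the smallest at which the quantities of
interest are stable.

## Known limitations

The forest offers no variable-importance measures, regression mode or
proximity matrices; the generator produces exactly one observation per
condition per subject; only the Cz channel is modelled; composite clinical
scores (e.g. PIPP-R) are not computed. The burst detector is a documented
re-specification — published reflex-quantification algorithms differ in
details that their original descriptions leave unstated — and its
constants, like every other tunable here, are exposed and echoed in
output metadata rather than presented as canonical values. EEG magnitudes
are in the internal units of the synthetic template and are not comparable
to microvolt values reported from validated clinical templates.
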