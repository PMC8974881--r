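# painforest

Multimodal discrimination of noxious from non-noxious stimulation in
infants, with a random forest that bootstraps subjects instead of
observations.

## The problem

Newborns cannot report pain. Research practice therefore records the
responses a clinically required heel lance evokes across several
modalities — facial grimacing, heart rate, oxygen saturation, limb reflex
withdrawal (EMG) and noxious-evoked brain activity (EEG at Cz) — and asks
which measures, alone or combined, best distinguish the noxious event from
a non-noxious control release of the same lancing device. `painforest`
implements that analysis end to end for anyone who wants to run it on
stimulus-locked multimodal recordings or study its statistical behaviour
on simulated cohorts:

* a **synthetic cohort generator** producing paired noxious/control
  multimodal recordings with a shared per-subject responsiveness factor,
  latency-jittered evoked potentials, reflex bursts, heart-rate rises,
  occasional saturation dips, facial-action durations and per-modality
  missingness (`simulate_cohort()`, `write_cohort()`/`read_cohort()`);
* **signal feature extraction**: zero-phase band-pass + mains-notch
  filtering, epoching, Woody latency alignment, evoked-potential template
  projection and automated peak-to-peak amplitude, EMG reflex
  RMS/duration/amplitude via a documented burst detector, per-second heart
  rate from beat times, and the 4 × 6 windowed change grids for heart rate
  and saturation — 59 named measures per observation
  (`extract_features()`);
* the **subject-bootstrapped random forest**: Gini trees grown to purity
  with per-node feature subsampling, subject-level bags so paired
  observations never straddle a bag boundary, per-tree in-bag median
  imputation for missing modalities, and honest out-of-bag scoring
  (`subject_rf()`, with `print`/`summary`/`predict`/`plot` methods and
  exact JSON serialization);
* the **companion statistics**: Wilson score intervals, ROC/AUC with
  subject-level bootstrap confidence intervals, two-sided mid-P McNemar
  tests, DeLong's test for correlated AUCs, exact binomial chance
  comparisons, Yates-corrected chi-square stratification, and
  pairwise-complete Spearman correlation matrices;
* **experiment drivers** reproducing the two study designs — the
  within-modality measure comparison and the multimodal train/validate
  experiment — plus deterministic report files and a small CLI
  (`run_within_modality()`, `run_multimodal()`, `report()`,
  `inst/scripts/painforest-cli.R`).

## The model in brief

Each of S subjects contributes paired observations (noxious, control).
Every tree of the forest draws S subjects with replacement; a subject drawn
k times contributes all its observations k times. Splits minimise Gini
impurity 1 − Σ pᵢ²; trees grow to purity with mtry = ⌈√p⌉ features per
node. An observation's out-of-bag score is the noxious-vote fraction over
the trees whose bag excludes its *subject* — the probability a subject is
out of bag is (1 − 1/S)^S ≈ e⁻¹ — so OOB performance is an honest estimate
despite the pairing. The EEG measure `EEGt` is the least-squares projection
⟨x, T⟩/⟨T, T⟩ of a unit-energy biphasic template T onto the trial over
400–700 ms after Woody alignment within ±100 ms.

## Worked example

Simulate a 60-subject cohort, hold out 16 complete subjects, train the
multimodal forest and validate it:

```r
library(painforest)
cfg <- experiment_config(
  cohort = cohort_config(n_subjects = 60, seed = 7),
  n_test = 16, n_trees = 500, n_boot = 1000, seed = 7)
res <- run_multimodal(cfg)
print(res)
```

```
Multimodal experiment: 44 training / 16 test subjects
Training (out-of-bag):
  accuracy    0.875 (0.790-0.929)
  sensitivity 0.841 (0.706-0.921)
  specificity 0.909 (0.788-0.964)
  AUC         0.945 (0.903-0.980)   (n = 88)
Term vs preterm accuracy: chi-square 0.000, p = 1
Test set:
         model  n accuracy       auc p_mcnemar_vs_full p_delong_vs_full
1         full 32  0.87500 0.9179688                NA               NA
2           NF 32  0.71875 0.8496094      0.1459960937     4.079156e-01
3    hr_max_15 32  0.59375 0.6269531      0.0063476563     2.794328e-03
4   sat_min_30 32  0.62500 0.7265625      0.0224609375     4.276313e-02
5         EEGt 32  0.75000 0.8359375      0.2265625000     2.837929e-01
6         RMSi 32  0.68750 0.7539062      0.0390625000     3.268756e-02
7         RMSc 32  0.50000 0.5058594      0.0009765625     3.367147e-05
8 behav_physio 32  0.84375 0.8203125      0.6875000000     2.118318e-01
```

Reading it: the training block gives out-of-bag accuracy, sensitivity and
specificity with 95% Wilson intervals and the AUC with its subject-level
bootstrap interval. The test block scores the full six-measure model, each
single-measure model, and the behavioural + physiological subset
(nasolabial furrow + heart rate + saturation) on the 32 held-out
observations; the last two columns compare each model's accuracy (mid-P
McNemar) and AUC (DeLong) against the full model. Here the full model's
test AUC (0.92) exceeds every single-modality AUC — significantly so for
heart rate, saturation and both EMG legs — which is the multimodal claim
the package exists to examine. `report(res, "out/")` writes the same
content as a byte-reproducible JSON report plus CSV tables, ROC point
files and a plain-text summary. (Accuracy values in the example are exact
multiples of 1/32; your numbers will differ with other seeds.)

The measure-comparison experiment is one call away
(`run_within_modality(cfg)`), and single pieces are exported for direct
use: `make_template()`, `bandpass_notch_filter()`, `woody_align()`,
`template_magnitude()`, `emg_burst_metrics()`, `heart_rate_series()`,
`windowed_change_features()`, `wilson_interval()`, `mcnemar_midp()`,
`delong_paired_test()`, `bootstrap_auc_ci()`, `spearman_matrix()`.

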