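# ghpat

Goldner–Harary graph-pattern (GHPat) feature engineering for two-class EEG
classification.

EEG is an accessible screening signal for dementia: Alzheimer's disease
shifts band power (delta/theta and gamma up, alpha/beta down) but no single
spectral marker is reliable, so automated models extract many features and
let validation decide. `ghpat` implements a complete, lightweight,
self-organized pipeline of that kind for multichannel EEG records with
subject identifiers and binary labels (1 = disease, 2 = control):

1. **GHPat textural features.** Each 15-s segment (7500 samples at 500 Hz)
   is scanned with overlapping 11-sample blocks `P1..P11`, one value per
   node of the Goldner–Harary graph. Seven directed subgraphs (8 directed
   edges each) compete to encode every block: the one whose node-set mean is
   closest to the whole-signal mean wins, its edges `(s, t)` produce bits
   `1[P_s − P_t ≥ 0]`, and the 8-bit codes fill a 256-bin histogram:

   `code = Σ_q bit_q · 2^(q−1)`, `feature = hist(codes, 0..255)`.

2. **Multilevel fusion.** A seven-level symlet-4 low-pass wavelet cascade
   feeds the same extractor plus 14 statistical moments per band:
   (256 + 14) × 8 = **2160** features per segment per channel.

3. **INCA selection.** NCA ranks the features; prefixes of size 50–550 are
   scored by 10-fold kNN misclassification; the best prefix wins.

4. **Classification.** Weighted kNN (k = 10, Manhattan distance,
   squared-inverse votes) under leave-one-subject-out cross-validation,
   per channel.

5. **Fusion.** Iterative majority voting over the accuracy-sorted channel
   results (n = 3..20 → 18 voted vectors for a 20-channel montage) and a
   greedy pick of the most accurate of all 38 candidates.

A seeded synthetic-cohort generator (band-limited noise with class-dependent
band gains and per-subject random effects) makes every stage testable
without any EEG download. See `vignettes/ghpat-methods.Rmd` for the model
details, parameter conventions and known limitations — including the fact
that the fusion stage is label-dependent model selection.

## Worked example

```r
library(ghpat)

cohort <- generate_cohort(synthetic_cohort_config(
  n_subjects_per_class = 4, segments_per_subject = 2,
  n_channels = 4, band_gain_effect = 1, seed = 7))

fit <- ghpat_pipeline(cohort$records, cohort$labels, cohort$subject_ids,
                      ghpat_config(seed = 3))
summary(fit)
#> GHPat self-organized classification fit
#>   channels: 4   segments: 16   CV: loso   ablation case: 5
#>   candidates: 4 channel-wise + 2 voted = 6
#>   ultimate result: Fp1  accuracy 100.00%  gm 100.00%
#>
#> channel-wise accuracies (%):
#> Fp1 Fp2  F3  F4
#> 100 100 100 100
#>
#> voted accuracies (%):
#>  n3  n4
#> 100 100
#>
#> ultimate result metrics:
#> TP 8  TN 8  FP 0  FN 0
#> accuracy 100.00%  gm 100.00%  precision 100.00%  recall 100.00%
#> F1 100.00%  kappa 100.00%  AUC 100.00%
```

Each channel is modelled independently (here the four channels of an
8-subject, 16-segment synthetic cohort with a strong ×2 band-power class
effect, which every channel separates perfectly under LOSO); the greedy
step returns the first of the tied perfect candidates (channel `Fp1`), and
the metrics block refers to that fused ("ultimate") prediction vector.

Lower-level entry points mirror the stages: `ghpat_transform()`,
`mdwt_lowpass()`, `statistical_features()`, `extract_segment_features()`,
`nca_rank()` / `inca_select()`, `knn_classify()` / `loso_cv()`,
`imv_vote()` / `greedy_best()` / `region_average()`.

## Command line

```sh
Rscript inst/cli/ghpat.R synth   --out cohort --subjects-per-class 4 --segments 2 --channels 4 --seed 7
Rscript inst/cli/ghpat.R run-all --input cohort --out results --seed 3
```

Subcommands `extract`, `select`, `classify`, `fuse` expose the intermediate
stages (feature tables, selection JSON, prediction CSVs); `--ablation-case`
switches the per-band extractor (GHPat only / moments only / both / classic
1-D LBP / full model) and `--cv kfold10` replaces LOSO by stratified
ten-fold CV.

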