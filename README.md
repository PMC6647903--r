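# drscore

Weakly supervised outcome prediction from breast-cancer tissue-microarray
(TMA) spot images. The package turns one H&E-stained spot image per patient
into a continuous **digital risk score (DRS)** and a low/high DRS group,
using only survival follow-up as supervision — no cell- or tissue-level
annotation anywhere — and ships the survival-analysis and rater-agreement
layer used to evaluate such a score. Because clinical cohorts of this kind
are not redistributable, a synthetic cohort generator with a known, tunable
image→hazard signal makes every stage testable end to end.

## The method

For a spot image *I* the pipeline computes:

1. **Tissue foreground.** Grayscale (channel mean) → Gaussian smoothing
   (truncation radius 15 px, σ = 5) → the transform
   *I*<sub>t</sub> = (ln(1 − *I*<sub>g</sub>) + 2e)/(2e) → Otsu thresholding
   (256 bins) → removal of connected components < 12,500 px. A spot is
   analysed only if its foreground area strictly exceeds 0.02 mm².
2. **Local descriptors.** A dense grid (stride 16 px) of 512-dimensional
   descriptors from a pluggable extractor — a pretrained CNN used as a
   frozen feature extractor in production, a deterministic multi-scale
   filter bank (`fixture_extractor()`) in tests — keeping only descriptors
   whose cell centre lies in the foreground.
3. **Improved Fisher vector encoding.** PCA 512 → 16; diagonal-covariance
   GMM with K = 64 components fitted to a class-balanced subsample of
   4 × 10⁶ descriptors; per-component mean and variance gradients
   G<sub>μ<sub>k</sub></sub> = (1/N√w<sub>k</sub>) Σᵢ γ<sub>k</sub>(xᵢ)(xᵢ−μ<sub>k</sub>)/σ<sub>k</sub>,
   G<sub>σ<sub>k</sub></sub> = (1/N√(2w<sub>k</sub>)) Σᵢ γ<sub>k</sub>(xᵢ)[((xᵢ−μ<sub>k</sub>)/σ<sub>k</sub>)² − 1];
   signed square root and L2 normalisation; PCA 2048 → 48.
4. **Classification.** Linear SVM on the 48-dim features. Labels: *high* =
   breast-cancer death before 10 years, *low* = never died of breast cancer
   during follow-up; breast-cancer deaths at ≥ 10 years are indeterminate
   and excluded. The DRS is the signed hyperplane distance; DRS group is
   high iff the score is strictly positive.
5. **Evaluation.** Kaplan–Meier (Greenwood SE, log–log CIs) and log-rank by
   DRS group for disease-specific and overall survival; uni-/multivariate
   Cox models (Efron ties, Wald CIs, Schoenfeld proportionality check);
   Harrell's C-index with a percentile-bootstrap CI; ROC AUC; and, for
   pathologist panels, majority-vote visual scores, percent agreement and
   Cohen's κ.

See `vignettes/drscore-methods.Rmd` for every numerical convention and the
design rationale.

## Worked example

Simulate a cohort with a strong texture-linked hazard (β = 1), train on a
2/3 split, evaluate on the rest:

```r
library(drscore)

cfg <- cohort_config(n_patients = 150, image_size = 256,
                     effect_size_beta = 1.0, baseline_rate = 0.04, seed = 2)
cohort <- generate_cohort(cfg)
split  <- split_cohort(cohort$clinical$patient_id, 2/3, seed = 2)
params <- drs_params(pre_components = 16, K = 8, post_components = 16,
                     subsample_total = 5000, min_area_mm2 = 2e-4, seed = 2)

fit <- drs_train(cohort, cohort$clinical, params, split$train)
#> <drs_fit> trained on 88/100 spots (0 area-excluded, 12 indeterminate),
#>           train AUC 0.865
ev <- drs_evaluate(fit, cohort, cohort$clinical, split$test)
#> <drs_evaluation> 50 scored (0 excluded), AUC 0.819
#>   log-rank (DSS) p = 5.896e-05; C-index 0.714 (0.622-0.796)
cox_table(ev$cox_univariate)
#>            term     coef       hr hr_lower95 hr_upper95      p_value
#> 1 drs_grouphigh 1.816298 6.149051   2.256689     16.755 0.0003831539
```

Reading the output: 12 of the 100 training patients died of breast cancer
beyond the 10-year label horizon and are excluded from supervision; on the
50 held-out patients the DRS ranks outcome-derived labels with AUC 0.82;
patients the model calls high-risk die of breast cancer ~6× faster (HR 6.1),
and the DRS grouping alone concordance-orders 71% of usable patient pairs.
Ten-year disease-specific survival in this run is 87% in the low group
versus 28% in the high group.

A file-based workflow (PNG images + CSV tables in, TSV/JSON out) is
available via `run_train()` / `run_evaluate()`, and as a command line:

```sh
Rscript inst/cli/drs_pipeline.R simulate --out cohort/ --n 120 --beta 1.0
Rscript inst/cli/drs_pipeline.R train --images cohort/images \
    --clinical cohort/clinical.csv --out models/ --k 16 --min-area-mm2 7e-4
Rscript inst/cli/drs_pipeline.R evaluate --models models/drs_models.json \
    --images cohort/images --clinical cohort/clinical.csv --out eval/
```

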