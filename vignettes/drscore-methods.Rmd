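---
title: "Digital risk scoring of TMA spot images: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital risk scoring of TMA spot images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

`drscore` implements a weakly supervised pipeline that predicts breast-cancer
outcome from a single haematoxylin–eosin-stained tissue-microarray (TMA) spot
image per patient. No cell- or tissue-level annotation is used anywhere:
supervision comes purely from follow-up records. The pipeline produces a
continuous *digital risk score* (DRS) per patient and a dichotomised low/high
DRS group, which is then evaluated with standard survival statistics and
compared with pathologists' visual risk scores.

The stages are:

1. **Foreground segmentation** — find the tissue disc in the spot image and
   apply a physical spot-area inclusion criterion.
2. **Local descriptors** — dense grid of fixed (not trained) convolutional
   descriptors, restricted to the foreground.
3. **Improved Fisher vector (IFV) encoding** — PCA compression of
   descriptors, a diagonal-covariance Gaussian mixture model, Fisher-gradient
   pooling into one fixed-length vector per spot, and a second PCA.
4. **Linear SVM** — trained on outcome-derived labels; its signed distance to
   the hyperplane is the DRS.
5. **Evaluation** — Kaplan–Meier/log-rank, Cox models, Harrell's C-index,
   ROC AUC, and inter-rater agreement statistics.

## Foreground segmentation

The spot image is averaged over colour channels (unweighted mean), smoothed
with a normalised Gaussian and passed through the logarithmic transform

$$I_t = \frac{\ln(1 - I_g) + 2e}{2e},$$

where $I_g$ is the smoothed grayscale image and $e$ is Euler's number. The
transform maps white ($I_g \to 1$) towards 0 and dark tissue towards 1, and
stretches the bright end of the histogram where the tissue/background
boundary lives. Otsu's method then thresholds $I_t$, and connected
components smaller than 12,500 pixels are removed.

Numerical choices the formula itself leaves open:

* **Gaussian parameterisation.** The smoothing is defined by a *truncation
  radius* of 15 px; we take $\sigma = \text{radius}/3$ (the usual
  three-sigma support convention), a 31×31 kernel normalised to unit sum,
  and replicate-padding at the borders. Both $\sigma$ and the radius are
  arguments of `gaussian_smooth()`.
* **Clamp.** $I_g$ is clamped at $1 - e^{-2e}$ before the logarithm. The
  $(x + 2e)/2e$ form normalises $\ln(1-I_g)$ from $[-2e, 0]$ onto $[0, 1]$;
  the clamp realises exactly that range and removes the singularity at pure
  white. The anchors $I_t(0) = 1$ and $I_t(1 - e^{-2e}) = 0$ are asserted in
  the tests, as is strict monotone decrease.
* **Otsu details.** 256-bin histogram spanning the data range; the threshold
  maximises between-class variance; ties are broken toward the lower
  threshold; pixels strictly *above* the threshold are foreground (tissue is
  dark in $I_g$, hence high in $I_t$). A constant image has no separable
  classes and yields an empty mask with a warning.
* **Connectivity.** Components are 8-connected: tissue fragments are dense
  and 4-connectivity would split diagonal bridges. The 12,500-px minimum is
  strict ("smaller than"), so a component of exactly 12,500 px survives.
* **Area criterion.** A spot enters the analysis only if its foreground area
  strictly exceeds 0.02 mm². The comparison is done in mm² — at
  0.22 µm/px, 0.02 mm² is ≈ 413,223 px, and the often-quoted round figure of
  400,000 px is treated as an illustration, not the operative constant. The
  mm² form also scales correctly for the smaller synthetic spots (below).

## Local descriptors

The descriptor stage is a *contract* (`descriptor_extractor`): any function
that maps an H×W image to a `ceil(H/stride)` × `ceil(W/stride)` grid of
D-dimensional vectors with deterministic cell centres. A pretrained CNN used
as a frozen feature extractor fits this contract (D = 512 channels, stride
16 matching the downsampling of a 16-layer VGG-style network's last
convolutional layer), but the package deliberately ships no network weights:
tests and experiments run on `fixture_extractor()`, a deterministic
multi-scale filter bank with the same interface —

* oriented first-derivative and Laplacian-of-Gaussian filters at three
  scales ($\sigma$ = 1, 1.8 and 3.2 px, truncated at 2.5σ) on each colour
  channel (27 band-pass responses);
* absolute-value rectification and mean pooling over each 16×16 grid cell;
* a fixed, seeded random projection to D = 512 followed by half-wave
  rectification.

The discrete second-derivative kernels are re-centred to exact zero DC gain,
so a constant image produces exactly zero descriptors — a property the test
suite exploits as a closed-form oracle. Because the filters are applied
convolutionally with replicate borders and pooling is aligned to the
absolute pixel grid, translating an image by one full stride shifts the
descriptor grid by exactly one cell (up to border cells).

Descriptors whose cell centre falls outside the foreground mask are
discarded (centre-in-mask rule — the simplest order-independent assignment
of grid cells to mask pixels).

## IFV encoding

Descriptors are compressed by PCA from 512 to 16 dimensions, and a
64-component diagonal-covariance GMM is fitted to a class-balanced random
subsample (4×10⁶ descriptors at full scale; half from low-risk spots, half
from high-risk). With posteriors $\gamma_k(x_i)$, the per-component
gradients are

$$G_{\mu_k} = \frac{1}{N\sqrt{w_k}} \sum_i \gamma_k(x_i)\,
  \frac{x_i - \mu_k}{\sigma_k}, \qquad
G_{\sigma_k} = \frac{1}{N\sqrt{2 w_k}} \sum_i \gamma_k(x_i)
  \left[\left(\frac{x_i - \mu_k}{\sigma_k}\right)^2 - 1\right],$$

concatenated over $k$ (2Kd = 2048 values), followed by the signed square
root $\mathrm{sign}(z)\sqrt{|z|}$ and global L2 normalisation — the
"improved" part of the encoding. An all-zero vector is passed through
unchanged. A second PCA compresses the 2048-dim IFVs to 48 features; it is
fitted on training-set IFVs only, so no test-set information leaks into the
encoder.

GMM numerical policy (none of which the encoding formulas fix): k-means++
initialisation from the seed; EM convergence when the mean log-likelihood
gain per point falls below 1e-5, capped at 200 iterations; per-dimension
variance floor of 1e-4 × the sample variance; a component whose
responsibility mass collapses is re-seeded at the worst-modelled point and
EM continues. PCA components carry a fixed sign convention (the
largest-magnitude loading is positive) so that serialised models are
reproducible. Neither PCA whitens by default; whitening is a flag.

## Labels and the classifier

Training labels come from follow-up alone: **high** = died of breast cancer
strictly before 10 years; **low** = never died of breast cancer during
follow-up (alive at last contact, or death from another cause at any time).
A breast-cancer death at ≥ 10 years satisfies neither rule; such records are
labelled *indeterminate*, excluded from supervision, and counted in the
training report. The two printed rules cannot be made exhaustive without
guessing, so exclusion-with-warning is the only assumption-free policy.

The classifier is a linear soft-margin SVM (hinge loss, L2 regularisation),
high coded +1. The DRS is the signed distance $w\cdot x + b$; the DRS group
is high iff the score is strictly positive — a score of exactly zero goes to
the favourable (low) group. The margin parameter defaults to 1.0 and can
optionally be selected by stratified 5-fold cross-validated AUC over
$10^{-2} \dots 10^2$. No feature standardisation is applied beyond the
encoder's PCA.

## Survival and agreement statistics

* **Endpoints.** Disease-specific survival (DSS): event = breast-cancer
  death; other deaths and patients alive at last contact are censored at
  their follow-up time. Overall survival (OS): event = death of any cause.
* **Kaplan–Meier** with Greenwood standard errors and 95% CIs on the
  complementary log-log scale, clipped to [0, 1]; 10-year survival is the
  right-continuous step-function value.
* **Cox models** use Efron handling of ties (Breslow by flag), Wald CIs and
  p-values. Constant covariates are rejected; monotone-likelihood fits are
  flagged as errors. Proportionality is checked by the Schoenfeld-residual
  slope test (`survival::cox.zph`) at α = 0.05 — the mechanism by which a
  non-proportional covariate (such as ER status) is dropped from a
  multivariate model.
* **Harrell's C-index** is computed by explicit pair enumeration: usable
  pairs are those whose shorter observed time is an event *and* whose times
  differ; score ties count 1/2. Note that `survival::concordance` treats an
  event and a censoring at the same observed time as comparable and so can
  differ slightly on tied data; the classic definition is used here, and the
  two agree exactly on tie-free data (asserted in the tests). The C-index of
  the binary DRS grouping is computed on the 0/1 group indicator. Its 95% CI
  is a percentile bootstrap over patients (2000 resamples by default); no
  closed-form CI is attempted.
* **Model comparison** between nested Cox fits is a likelihood-ratio test,
  2·Δlogℓ against χ² with df = parameter difference. A comparison of two
  *non-nested* univariate models (e.g. DRS vs visual score) has no standard
  LRT; the package provides the nested form only and the combined
  multivariate fit for the non-nested question.
* **Rater agreement.** A spot is excluded if *any* rater marks it not
  evaluable; the visual risk score is the majority vote of an odd number of
  raters (an even panel is a configuration error — no tie rule exists).
  *Percent agreement* defaults to the unanimous reading (all raters agree);
  a pairwise-average mode exists. For three near-independent binary raters
  the unanimous rate tends to 2/2³ = 25%, far below any plausible pairwise
  average, which is why the unanimous reading is the default interpretation
  of low printed agreement values. Cohen's κ uses marginal-product expected
  agreement and the large-sample normal test of κ = 0.

## The synthetic cohort generator

Real spot images and follow-up data of this kind are not redistributable, so
the package ships a generator with a *known, tunable image→hazard* signal:

* **Images.** A jittered circular "tissue" disc (pink matrix colour) on a
  near-white background, filled with dark nucleus-like elliptical blobs;
  per-pixel Gaussian colour noise. The expected blob count interpolates
  between 150 and 600 (per 512-px spot, scaled with image area) through a
  logistic function of the latent score — the texture statistic is trivially
  verifiable by connected-component counting on the generator's own
  pre-noise blob mask.
* **Survival.** Breast-cancer death time ~ Exponential(rate
  `baseline_rate`·exp(β·z)); competing other-cause death ~
  Exponential(`other_cause_rate`); administrative censoring at 16 years
  (matching a cohort whose median follow-up approaches that horizon). The
  observed time is the minimum of the three. The exponential form is a
  stand-in — the real cohort's hazard and censoring distributions are
  unknown — and is the simplest model matching the DSS/OS censoring
  semantics; a Weibull extension would slot into the same interface.
* **Latent score.** Binary by default (z = ±1 with equal probability),
  mirroring low/high supervision; a continuous standard-normal mode supports
  coefficient-recovery experiments.
* **Defaults** (chosen once, as study conditions): β = log(2.1)/2, so the
  hazard ratio between the binary classes is 2.1 — the magnitude of risk
  separation the DRS grouping is meant to carry; baseline rate 0.04/y at
  z = 0; other-cause rate 0.02/y. Whole cohorts are pure functions of
  (config, seed): per-patient child seeds are derived arithmetically, so
  images can be regenerated lazily instead of stored.
* **Scale.** Synthetic spots default to 512 px — about 1/5 of the linear
  size of a real 0.6 mm core at 0.22 µm/px — keeping one spot's full
  pipeline under ~0.3 s. The physical pixel size is kept at 0.22 µm, so the
  synthetic disc (~0.007 mm²) would fail the clinical 0.02 mm² criterion;
  synthetic runs therefore use an area-scaled criterion (7×10⁻⁴ mm², ~30% of
  the disc), which exercises the same strict-inequality logic.

What the generator does *not* emulate: realistic H&E appearance (stain
variation, nuclei chromatin texture, stroma/epithelium architecture),
scanner artefacts, folds or pen marks, multi-core layouts, or realistic
censoring patterns. Passing tests therefore demonstrate that the pipeline's
machinery recovers a texture-linked hazard signal under controlled
conditions — not that it would reach any particular performance on clinical
images.

## Experiment sizes used by the test suite

The packaged experiments are scaled so the whole suite runs on one CPU in
well under half an hour:

* End-to-end signal recovery: 5 cohorts of n = 400 (512-px spots), strong
  texture effect (β = 1.5, baseline 0.03/y — chosen so that, with the label
  rules above, about 90% of high-label patients are truly high-class and the
  achievable label AUC comfortably exceeds 0.8), 10⁴-descriptor subsample,
  K = 16, 16 → 48 PCA dims, 2/3-1/3 split. Median held-out AUC > 0.8, median
  log-rank p < 0.05.
* Null calibration: 20 cohorts of n = 400 (64-px spots) with β = 0 and a
  50/50 split, giving ~200 test patients per run — enough resolution for the
  held-out AUC to land in [0.4, 0.6] in ≥ 18/20 runs when the truth is
  chance; the bootstrapped C-index CI must cover 0.5 equally often.
  Log-rank size is checked on 1000 image-free cohorts (n = 100).
* Parameter recovery: Cox coefficient within 3 SE of log 2 at n = 1000;
  GMM means within 0.1 on separated mixtures at n = 5000.
* Oracle equivalence: IFV vs a naive two-loop reference (≤ 1e-8), Otsu vs
  exhaustive threshold search, C-index vs O(n²) enumeration, Kaplan–Meier vs
  hand product-limit, log-rank vs a 10⁴-permutation reference.

The same end-to-end experiment, at one seed, is what
`scripts/acceptance.R` re-runs from scratch.

## Known limitations

* The fixture extractor is a filter bank, not a learned network; it shares
  the extractor contract but not the representation power of a pretrained
  CNN. An external CNN adapter can be plugged in through
  `descriptor_extractor()` without touching the rest of the pipeline.
* The exponential survival model cannot express non-proportional hazards,
  cure fractions, or informative censoring.
* One spot per patient is assumed throughout; pooling of multiple cores per
  patient is out of scope.
* The evaluation layer implements generic association tests only; it does
  not model pathologists' tissue-entity grading scales beyond opaque
  categorical covariates.

## A minimal session

```{r}
library(drscore)

cfg <- cohort_config(n_patients = 120, image_size = 256, seed = 1)
cohort <- generate_cohort(cfg)
split <- split_cohort(cohort$clinical$patient_id, 2/3, seed = 1)

params <- drs_params(pre_components = 16, K = 8, post_components = 16,
                     subsample_total = 5000, min_area_mm2 = 2e-4, seed = 1)
fit <- drs_train(cohort, cohort$clinical, params, split$train)
ev  <- drs_evaluate(fit, cohort, cohort$clinical, split$test)
ev
```
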