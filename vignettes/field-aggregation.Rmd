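---
title: "Methods: pixel-to-field aggregation for single-image crop classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pixel-to-field aggregation for single-image crop classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fieldagg)
```

## The problem

In many agricultural regions only one or two cloud-free satellite scenes
are available per season, so crop classification must work from a single
multispectral image. Pixel-wise classifiers are the workhorse, but the
decision unit is the agricultural field: a connected pixel set known a
priori to carry one crop. `fieldagg` implements the stage that most
pipelines improvise — collapsing per-pixel class probabilities
`p(k | x_i)` into one label per field — together with the feature
generation, class balancing and evaluation machinery around it.

## Aggregation strategies

Three strategies are implemented over a field `F` with `N` classes.

**Majority voting** assigns each pixel its argmax class and takes the mode.
It is robust but discards confidence: three pixels at (0.55, 0.45) outvote
two at (0.01, 0.99) even though the latter carry far more information
(`bayesian_vote()` reverses that example, `majority_vote()` does not — this
is tested).

**Average voting** scores each class by the arithmetic mean probability.
It uses the full vectors but treats pixels as replicate measurements:
binary pixels at 0.6, 0.7, 0.8 average to 0.7, below the strongest pixel.

**Bayesian log-odds aggregation** treats pixels as conditionally
independent evidence given the field's class. For each class, one-vs-rest:

$$I(k) = \sum_{i \in F} \log\frac{1 - p(k \mid x_i)}{p(k \mid x_i)},
\qquad c = \arg\max_k \frac{1}{1 + e^{I(k)}} = \arg\min_k I(k).$$

Summing log-odds multiplies odds, so the 0.6/0.7/0.8 example combines to
`(.6·.7·.8)/(.6·.7·.8 + .4·.3·.2) = 14/15 ≈ 0.933`: independent positives
reinforce. A single pixel reproduces its own probabilities exactly.

### Numerical choices

- Probabilities are clipped to `[ε, 1−ε]` with `ε = 1e-9` before the logs,
  so hard 0/1 outputs of tree ensembles stay finite. `ε` is configurable in
  `(0, 0.5)`.
- The label is computed as `argmin I(k)`, algebraically identical to the
  sigmoid argmax but immune to overflow when `|I|` is large (hundreds of
  pixels drive `I` to ±10²–10³).
- One-vs-rest confidences do not sum to one across classes; they are
  reported unnormalized by default (the argmax is unaffected), with a
  `renormalize` flag for display.
- Ties — equal vote counts or exactly equal confidences — resolve to the
  lowest catalog index and set a `tie` flag, making results deterministic
  and auditable. Input probability rows must sum to 1 within `1e-6`.

### Smoothing

Saturated predictions (`p ≈ 1`) make single pixels dictate the field. The
smoothing map

$$\hat p_\alpha(k \mid x_i) = \alpha\, p(k \mid x_i) +
\frac{1-\alpha}{N-1}\bigl(1 - p(k \mid x_i)\bigr)$$

shrinks toward the uniform vector; it preserves the simplex exactly
(`α + (1−α) = 1`), is the identity at `α = 1`, and preserves each pixel's
argmax whenever `α > 1/N` (below `1/N` it *inverts* ranks — the reason
`tune_alpha()` exists and the package never defaults below that bound for
its 7-class settings). For 7-class problems, grid search on validation
fields typically lands in the 0.3–0.4 band; `0.35` is used as the
benchmark's smoothed setting. Smoothing applies to the Bayesian route by
default; averaging is unaffected by any rank-preserving shrinkage, since
the mean of smoothed vectors is the smoothed mean.

## Features

The 13 Sentinel-2-style bands (B01–B08, B8A, B09–B12, assumed already on a
common 10 m grid, bands of coarser native resolution having been
bilinearly resampled upstream) are extended with NDVI, two-band EVI, NDRE
(red-edge role = B06) and MSAVI. Indices are always computed on raw
bottom-of-atmosphere reflectance, *then* the 17-channel stack is
standardized per channel over valid pixels — ratio indices on standardized
values are meaningless, and a test asserts the two orders differ. MSAVI
uses the canonical closed form
`(2·NIR + 1 − sqrt((2·NIR+1)² − 8·(NIR − Red)))/2`. Division-by-zero
pixels get fill value 0 and an invalid flag. Normalization statistics are
returned so a training scene's `μ_j, σ_j` can be reused on inference
scenes (`apply_normalization()`), preventing leakage; whether statistics
should be global or per tile is an open question in the source material —
per-scene statistics are the package's choice.

## Class balancing

Smallholder landscapes are heavily imbalanced (the reference distribution
spans 789 fields for the largest class to 2 for the smallest; classes that
cannot support pixel training — here `Dates` and the `Intercrop`
vineyard/pecan mixture — are dropped, leaving 7). The balancing verbs
operate on pixel tibbles after the field-level split, with field
provenance retained, so validation fields never leak into training:

- `random_oversample()` — with-replacement copies up to the majority count;
- `random_undersample()` — without-replacement subset down to the minority
  count;
- `smote_oversample()` — synthetic points `x_base + λ(x_corr − x_base)`,
  `λ ~ U(0,1)`, `x_corr` among the `k = 5` nearest same-class neighbors
  (Euclidean, the original SMOTE convention); provenance
  `(base, corr, λ)` is stored so segment membership is auditable;
- `class_weights()` — `w_y = total/(n_classes · count_y)`, normalized
  inverse frequency (the count-weighted mean weight is 1). The weight
  formula is not prescribed by the source material; this normalization is
  the package's choice and is exposed so alternatives can be tested.
  Weights feed `weighted_loss()` and the classifiers' native weighting
  (case weights for the forest, instance weights for boosting; kNN has no
  such mechanism and the benchmark skips that cell).

Balancing targets (majority count for ROS/SMOTE, minority for RUS) follow
the standard convention. All three verbs are deterministic under a seed.

## The synthetic landscape generator

The generator emulates the *structure* of a smallholder survey scene, not
its radiometry: disjoint contiguous fields grown by seeded random region
growing (4-connectivity) on a bare-soil background; field sizes
`max(5, round(N(150, 45)))` pixels at 10 m — the 150-pixel mean matching a
0.015 km² average field; class labels drawn from the reference 7-class
imbalance; pixel spectra = class prototype + i.i.d. `N(0, 0.02)` per band,
with prototypes built as vegetation/soil endmember mixtures plus small
class-specific NIR/SWIR offsets. A grid sized for 55% field cover keeps
region growth from jamming.

Per-pixel probabilities come from a Dirichlet confusion model: for a pixel
of true class `t`, concentrations are 1 everywhere and `1 + 2/τ` on `t`.
`τ = 0` gives exact one-hot truth (all aggregators then score 100%, a
tested degenerate case); `τ → ∞` approaches the flat Dirichlet and chance
accuracy `1/N`. Pixels are independent given the field class — exactly the
regime the log-odds rule assumes. The ordering experiment in the test
suite uses `τ = 10`, chosen once as the weakly-informative regime
(per-pixel argmax accuracy ≈ 0.19 against a 1/7 ≈ 0.14 chance level)
where aggregation strategy genuinely matters: with strongly informative
pixels every strategy saturates at 100% on 150-pixel fields and nothing
can be compared. At that setting, over 50 seeded replicates of 300-field
landscapes, field-level OA orders Bayesian > averaging > majority, and all
field-level scores far exceed pixel-level OA.

What passing these tests does *not* show: real classifier errors are
spatially correlated (shadows, edges, registration), violating conditional
independence and eroding — though in practice not reversing — the
log-odds advantage; real spectra have texture, illumination gradients and
mixed boundary pixels the generator omits. The generator validates the
algebra and the orderings under the stated model, not radiative realism.

## Augmentation

The training-time augmentation for 100×100 tiles applies, in order:
reflect-pad by 50 px per side (reflect-101, edge not duplicated), rotate
by `U(−60, 60)` degrees, scale by `U(0.75, 1)`, shift by `U(−20, 20)` px
per axis, center-crop back to 100×100. Image channels are warped
bilinearly; label rasters use order-0 interpolation, so no label value can
be invented (tested). The warps are a single composed affine transform
executed by `EBImage::affine()`. Identity parameters reproduce the input
exactly on labels and to interpolation tolerance on channels.

## Evaluation and benchmark

`overall_accuracy()` (percent) and `macro_f1()` (unweighted mean of
per-class F1; classes absent from both sides excluded, zero
precision+recall contributes 0) are validated exactly against an
independent confusion-matrix oracle. The benchmark grid crosses
{ROS, RUS, SMOTE, weighting} × {kNN, RF, GB} × {none, majority, average,
Bayesian (α = 1 and 0.35)}, skipping kNN × weighting, with a 70/30
field-stratified split (the split ratio is not prescribed by the source
material; 70/30 is the package's default). Defaults are sized for a
single CPU: 120-field scenes, 25 training pixels sampled per field, 100
trees, 30 boosting rounds, k = 10 — hyperparameters are exposed in
`benchmark_config()` and are deliberately modest defaults, not tuned
values. Test-suite runs use smaller scenes still (20–60 fields) except for
the 50×300-field ordering experiment.

## Known limitations

- No geospatial CRS handling: rasters are plain pixel grids with a
  resolution tag (multi-frame TIFF + JSON sidecar on disk); co-registration
  is assumed done upstream.
- The Bayesian rule uses a uniform class prior; field-frequency priors
  would be a one-line extension of `I(k)` but are deliberately omitted to
  keep the evidence combination assumption-minimal.
- Conditional independence across pixels is an idealization; see the
  generator section.
- The U-Net branch of single-image classification is out of scope; only
  the weighted loss it would consume is provided.
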