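---
title: "Methods: uncertainty priority maps and fixation-weighting analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: uncertainty priority maps and fixation-weighting analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazepriority)
```

## The model

`gazepriority` treats gaze prediction as the evaluation of *priority
maps*: non-negative rasters, aligned to an image, whose value at a pixel
expresses how strongly that location should attract overt attention. The
package's central map quantifies **object-recognition uncertainty**. The
premise is that an object proposal for which many learned categories
compete is an unresolved perceptual hypothesis, and attention is deployed
to resolve it.

Concretely, detector output for an image is a set of proposal boxes, each
with a vector of per-category confidences. Preprocessing applies a
confidence filter (a proposal survives if its best score reaches
`th_conf`; sub-threshold category entries are pruned) and class-agnostic
greedy non-maximum suppression, so that each surviving proposal stands
for one physical object. The competing count $f_b$ of a surviving
proposal is the number of categories at or above `th_conf`. The map is

$$\mathrm{UC} = \sum_{b=1}^{B} G(B_{center},\sigma)\,\frac{f_b}{\max_B f_b},$$

a sum of per-proposal Gaussians weighted by relative competing counts.
The same machinery supports the information-theoretic reading: with
$P_{unique}(b) = 1 - f_b/\sum_b f_b$ the probability that box $b$ houses
a single uniquely recognized object, $-\log_{10} P_{unique}$ ranks boxes
exactly as the weights do.

Two alternative formulations probe whether the specific form matters.
The *label-entropy* map replaces the count weight with the Shannon
entropy of the above-threshold confidence vector; the *pixel-wise* map
skips NMS entirely, counts at each pixel the number of enclosing boxes,
and smooths the count raster. Centre-bias and target maps complete the
factor set; bottom-up saliency enters only through an adapter for
precomputed rasters (plus a deliberately simple centre-surround contrast
stand-in used by the tests — it is not a saliency model and is labelled
accordingly).

## Parameters

| Parameter | Default | Role |
|---|---|---|
| `th_conf` | 0.02 | proposal/category confidence threshold |
| `th_nms` | 0.30 | IoU above which a lower-ranked box is suppressed (strict `>`) |
| `sigma` (UC, entropy maps) | $h_b/4$ per box | SD of each proposal's Gaussian, pixels |
| `sigma_c` (centre bias) | $h_{im}/3$ | SD of the centred Gaussian, pixels |
| target confidence | 0.9 (TP), 0.02 (TA) | strict cut-off on the target-category score |
| pixel-wise smoothing | window $h_{im}/4$, SD = window/4 | truncated Gaussian kernel |
| FDM smoothing | $h_{im}/24$ | roughly one degree of visual angle at common eye-tracking geometries |
| patch grid | 8 × 6 | 48 scene patches for the GLMM design |
| fixation ordinals | 1–9 | per-index analyses |
| histogram matching | 256 bins | empirical-quantile specification |

Where the construction leaves a choice open, the package fixes it once
and exposes it as an argument:

* **Per-proposal Gaussian SD.** No SD is prescribed for the
  uncertainty/entropy Gaussians. We default to $h_b/4$ — one quarter of
  the box height — for consistency with the target-map convention, and
  accept a fixed global SD via `sigma =` a number.
* **Peak versus mass normalization.** Per-proposal Gaussians are
  *peak*-normalized (amplitude 1) before weighting, so a weight is
  directly the map value at an isolated proposal's centre. Mass
  normalization would down-weight large objects relative to small ones;
  peak normalization keeps the weights interpretable as peak priorities.
* **Entropy weights.** Raw detector confidences need not sum to 1, so
  the above-threshold vector is renormalized before
  $-\sum w_p \log w_p$ (`renormalize = FALSE` uses raw scores). The
  logarithm is base 10 so that $k$ equally confident categories give
  weight $\log_{10} k$, on the same scale as the self-information
  numbers; `log_base` changes it.
* **NMS details.** Suppression is class-agnostic (the aim is one box per
  physical object, not per category; `per_category = TRUE` restores the
  detection-benchmark behaviour), uses strict inequality IoU > `th_nms`
  (a box at exactly the threshold survives), and breaks score ties by
  input order, which keeps the operation deterministic and seed-free.
* **Centre-bias amplitude.** The $1/(\sigma_c\sqrt{2\pi})$ factor is
  retained as written even though min-max normalization later cancels
  it: constructors build the defining formula, normalization is a
  separate, explicit step.
* **Target-map construction.** The target Gaussian is built on a square
  of side $h_{im}$ with SD $h_{im}/4$ and bilinearly resampled to the
  box extent, so its anisotropy follows the box aspect ratio; resampling
  to the original size is exactly the identity, so a square box of side
  $h_{im}$ reduces to the unresampled Gaussian.

## Evaluation pipeline

NSS standardizes a map to zero mean and unit *population* SD over pixels
and averages at fixated pixels; a constant map is defined to score 0
(with a warning) rather than error, so batch evaluation proceeds. NSS is
invariant under positive affine transforms of the map, which the tests
assert.

The GLMM analysis follows a fixed preprocessing order: priority maps are
histogram-matched to the per-image fixation-density map, averaged over
the 8 × 6 patch grid, and each feature column is then min-max normalized
to [0, 1] across the whole observation table. The order matters —
normalizing before patch averaging would rescale within images rather
than across the design — and is therefore enforced in
`patch_feature_table()` rather than left to callers. Histogram matching
uses one reference FDM per image (not a pooled task-level reference).
Remainder pixels of a non-divisible image go to the last grid row and
column.

The observation table has exactly $n_{image} \times n_{subjects} \times
48$ rows: every subject-image pair contributes all 48 patches, with an
all-zero response when that trial has no fixation of the given ordinal;
the per-ordinal *instance* counts (trials that do reach the ordinal) are
reported alongside and normalized to sum to 1 over ordinals. A "new
fixation" is each successive recorded fixation, indexed from 1; returns
to previously fixated patches still count.

One logistic mixed model is fitted per fixation ordinal with all
features entered jointly — each z-statistic then measures that map's
*unique* contribution. The phrase could also be read as one model per
feature, so `mode = "per_feature"` provides that variant. Random
intercepts default to scene type (plus target category for search
designs); groupings with fewer than two levels are dropped with a
warning, and with no usable grouping the fit reduces to ordinary
logistic regression, which doubles as the test oracle. Fits use
`lme4::glmer` with `nAGQ = 0` (penalized-likelihood approximation) by
default: on tables of ~10^5 rows it is several-fold faster than the
Laplace approximation and, for the variance components that arise here
(near zero), coefficients agree with the ordinary logistic fit to
well below the reporting precision; `nagq = 1` restores Laplace.

Weight tables clamp negative z-statistics to zero before row
normalization — a signed normalization would make rows with negative
entries uninterpretable as weights — but raw z, standard errors, raw and
Bonferroni-adjusted p-values (across features × ordinals) are always
retained in the companion statistics table. A row with no positive z
falls back to uniform weights with a warning. Rank-deficient designs
(identical feature columns, aliased coefficients) are errors, not silent
drops; non-convergence and separation are surfaced as warnings and
recorded on the result.

## The synthetic cohort

The generators exist so every stage is testable without eye-tracking
data, and they define the study conditions used throughout the tests:

* scenes of 5 integer boxes (sides 10–24 px) on 60 × 80 px images —
  that size makes each of the 48 grid patches exactly 10 × 10 px;
* detector output with one proposal per object whose above-threshold
  category count equals a requested competition level (cycling 1–4),
  plus sub-threshold nuisance scores to exercise filtering;
* scanpaths of 9 fixations per subject, 10 subjects per image, drawn
  i.i.d. from $(1-\varepsilon)\sum_i w_i\, m_i/\!\sum m_i +
  \varepsilon\,\mathrm{uniform}$ with $\varepsilon = 0.05$. The floor
  keeps the sampling density strictly positive so the logistic models
  never see perfectly separable data.

The weight-recovery experiment ties everything together: 200 images × 10
subjects per run, mixture weights (0.6, 0.3, 0.1) over the uncertainty
map, centre bias, and a target map, recovered by the full
FDM → histogram-match → patch-means → GLMM → weight-table pipeline; the
Monte-Carlo check repeats this over 20 seeds and asks that the recovered
per-row z-ordering match the generating order in at least 90% of rows.
These sizes were chosen as the smallest at which the three z-statistics
separate cleanly (roughly 40, 8, and 5 SDs); all are arguments, so
larger cohorts are one call away.

What the simulator deliberately does not model: sequential scanpath
structure (saccade-length priors, inhibition of return, the centre-start
of real trials), fixation durations, detector miscalibration beyond
uniform score noise, and any dependence of the mixture weights on the
fixation ordinal. Passing the recovery test therefore shows that the
pipeline correctly estimates *stationary* map weightings from i.i.d.
samples — it does not certify behaviour on serially dependent human
scanpaths, where per-ordinal weight differences are exactly what the
analysis is meant to reveal.

## Numerical conventions and degenerate inputs

* Pixels are 0-based with origin top-left; pixel (row $r$, col $c$)
  covers $[c, c+1) \times [r, r+1)$ and all Gaussians are evaluated at
  pixel centres $(c+0.5, r+0.5)$. Boxes are half-open $[x, x+w) \times
  [y, y+h)$, so IoU on integer boxes equals the covered-pixel-count
  ratio. A pixel belongs to a box if its centre does.
* Gaussians are evaluated over the full image (no truncation) except
  the pixel-wise smoothing kernel, whose window is the stated size
  rounded to odd; mass clipped at image borders is simply lost (no
  renormalization), matching the summed-formula definition.
* Boxes are clipped to the image on read; proposals entirely outside
  are dropped with a warning. Zero-proposal images yield all-zero maps
  with a warning rather than an error so batch runs proceed.
* Min-max normalization maps a constant raster to all zeros (warning);
  histogram matching against a constant reference returns that
  constant; both preserve pixel rank order up to ties.
* All generator randomness flows through explicit integer seeds
  (`withr::with_seed`), making every synthetic artifact, including
  serialized files, bit-reproducible.

## Limitations

The package consumes detector output; it does not run a detector, and
the quality of the uncertainty map is bounded by the calibration of the
supplied confidences. Bottom-up saliency is adapter-only. Dataset-scale
findings about human gaze (which factor dominates which task, and by how
much) require real detector output and real fixations; the tests here
validate the machinery — formulas, design matrices, estimators — under
known synthetic truth, at desk scale.
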