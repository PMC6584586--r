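---
title: "Validating voxel-based morphometry pipelines with synthetic phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating voxel-based morphometry pipelines with synthetic phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Voxel-based morphometry (VBM) detects local anatomical change by spatially
normalizing every subject to a common template, taking the log of the
Jacobian determinant of each subject's deformation field as a map of local
volume change, and testing those maps voxelwise between groups. The result
depends heavily on choices buried inside the registration engine — the
gradient step size and the regularization applied to the update and total
deformation fields — and on the template-building strategy. Because real
studies have no voxel-level ground truth, these choices are usually made by
intuition.

`morphoval` provides ground truth. It simulates cohorts of labeled
brain-like volumes, induces a *known* volume change in chosen structures by
warping each image with a mask-driven diffeomorphism (a morphological
phantom), runs a complete minimal VBM pipeline, and scores how well the
induced change is recovered. Because every stage is seeded and synthetic,
the whole framework runs on a desk in minutes and is exactly reproducible.

## Pipeline model

The pipeline mirrors a standard small-animal VBM workflow:

1. **Masking.** A brain mask is extracted by Otsu thresholding on a 256-bin
   histogram followed by a small sequence of morphological operations with
   a spherical element (parameters: number of operations `n_ops`, radius in
   voxels). The literature describes this stage only as "a series of
   eroding, dilating, and closing"; we fix the sequence as alternating
   erode/dilate starting with an erosion, a balancing dilation when
   `n_ops` is odd, one closing, then largest 26-connected component and
   hole filling. An unbalanced literal alternation would net-erode the mask
   by one element radius, which contradicts the intent of a denoising pass,
   so the balanced form is used.
2. **Linear alignment.** Centre-of-mass plus principal-axes initialization
   refined by a 12-parameter gradient-based mean-squares minimization.
   Principal axes are replaced by the identity rotation when the intensity
   covariance is near-isotropic (axes are undefined there).
3. **Template construction (MDT).** An affine average seeds an iterative
   template: each iteration registers every cohort member to the current
   template, averages the warped images (appearance), and applies the
   voxelwise mean of the inverse warps, scaled by `shape_update_step`
   (default 0.25), to the average (shape). Default 6 iterations, the first
   3 on a 2x downsampled grid. The shape update drives the template toward
   the cohort's mean geometry, which is what makes it minimally biased.
4. **Re-registration.** Every subject — including subjects that did not
   contribute to the template — is freshly registered to the final MDT, and
   the log-Jacobian map of its to-MDT warp is the quantity analyzed.
5. **Statistics.** Maps are smoothed with a 3-voxel-sigma Gaussian; the
   analysis mask is the template brain mask eroded by the smoothing radius;
   two one-tailed pooled-variance t-tests (atrophy and hypertrophy
   directions) give p-maps, unstandardized effect maps (mean log-Jacobian
   difference), and Benjamini-Hochberg q-maps computed separately per tail.
   A seeded permutation test over group labels is available as a
   nonparametric alternative.

### The registration engine

The engine is a greedy multi-resolution diffeomorphic method exposing the
three knobs whose interplay the framework is designed to study:

* `step` — each iteration's update field is normalized so its largest
  displacement equals `min(step, 0.4)` voxels. The 0.4-voxel cap keeps
  every increment invertible, so the composed total field stays
  diffeomorphic by construction.
* `reg_update` ("RegU") — Gaussian sigma, in voxels, applied to each
  update field (fluid-like regularization).
* `reg_total` ("RegT") — Gaussian sigma applied to the accumulated total
  field after each composition (elastic-like regularization).

The update force is the mean-squares gradient `(F - M∘φ)·∇(M∘φ)` or a
local normalized cross-correlation gradient over a cubic window (radius 4
by default). Three pyramid levels (strides 4/2/1, pre-smoothing sigmas
2/1/0) with at most 100 iterations each and a relative-improvement
stopping rule (1e-8 over a 20-iteration window) are the defaults at the
64^3 scale this package targets. The moving image is histogram-matched to
the fixed image when their intensity ranges differ by more than 10%.

Deliberate simplifications, documented as the package's largest fidelity
gaps with respect to full symmetric normalization (SyN) tooling:

* forward and inverse fields come from two independent greedy runs rather
  than a midpoint-symmetric optimization; the fixed-point `invert_field()`
  is available when an exact inverse is required;
* regularizer strengths are interpreted as Gaussian *sigmas* in voxels (a
  single consistent convention; relative orderings of swept values are
  preserved);
* the mean-squares metric is the default for the synthetic study, where
  all images share one contrast model. The local-correlation metric is
  implemented and tested, and matters for multi-site or multi-contrast
  data rather than for these fixtures.

## Phantom induction

For each subject, the binary masks of the structures to be altered are
dilated or eroded by a spherical element (one voxel in the default study),
the original and edited masks are merged, and the original is
diffeomorphically registered to the target with parameters (0.5, 3, 1) and
the mean-squares metric — strong total-field regularization is appropriate
because the desired change is a pure local expansion/contraction. Both
masks are pre-smoothed with sigma 0.5 voxels so the binary-image metric has
gradient support at the interface; the measured truth still comes from the
produced field, not from the smoothed inputs. The warp is applied to every
contrast with linear interpolation (labels: nearest-neighbour), and the
induced change is measured as the mean Jacobian of the original-to-target
warp over each original mask. Because the integral of a Jacobian over a
region is the volume of its image, this mean tracks the voxel-count volume
ratio of the edit — the package's central oracle, tested at 15% relative
tolerance.

## Evaluation metrics

With the cohort-average induced change ΔV_sim as target:

* **Distance from target** |Δd| = |ΔV_sim − ΔV_impl| with
  ΔV_impl = (exp(mean effect over the structure) − 1)·100%.
* **Sensitivity index** d' = (μ_S − μ_N)/sqrt(σ²_S + σ²_N) between the
  structure's *inner shell* (signal) and its *leakage region* (noise: the
  2-voxel dilation shell around the structure, minus the structure and any
  other altered structure, clipped to the brain mask). The inner shell is
  the erosion-depth shell whose volume best matches the leakage volume.
  For atrophy structures the effect map is negated first.
* **ROC AUC and TPR@p=0.05** over p-value thresholds: TPR is the fraction
  of structure voxels significant at the threshold, FPR the fraction of
  in-mask brain voxels outside it; the area uses the trapezoidal rule (it
  equals the Mann-Whitney concordance with tie half-credit, which the
  tests assert exactly).
* **Dice coefficients** between atlas labels propagated through the
  pipeline (atlas → template → subject) and the generator's ground-truth
  subject labels.

Parameter sets are ranked per metric (competition ranking for ties; |Δd|
and runtime low-is-better, the rest high-is-better); the phantom average is
the mean of the per-structure metric ranks, and the combined ranking
averages the Dice rank, the runtime rank and the phantom average.

## The synthetic cohort

Each subject is the mirror-symmetric base atlas — an ellipsoidal shell
(semi-axes 27x23x19 voxels at 64^3) containing bilateral
hippocampus-like (9x10x8), caudate-putamen-like (6.5x7.5x7) and
ventricle-like (2x4x3) structures, with distinct per-structure means in
two contrasts ("FA"-like, which drives registration, and "DWI"-like, used
for masking) — deformed by a random diffeomorphism and jittered by a small
random affine. The diffeomorphism is white noise smoothed with a
4-voxel-sigma Gaussian, scaled to a 1.5-voxel maximum displacement, and
exponentiated by 6 scaling-and-squaring steps; the affine jitter is up to
±1 voxel translation, ±2° rotation and ±2% per-axis scale. Intensity noise
is additive Gaussian (sigma 0.02) — fixed-specimen MR has high SNR and the
pipeline's statistics assume roughly Gaussian residuals, so Rician noise
would add complexity without changing what the framework can test.
Generation is a pure function of the spec and its seed, and every
generating warp is verified to have strictly positive Jacobian (amplitude
is halved and redrawn in the rare failing case).

Structure sizes were chosen up front from a smoothing-retention budget: a
one-voxel erosion of the hippocampus-like structure induces a volume
change of about −30%, and with 3-voxel-sigma smoothing the mean effect
over a structure of semi-axes ~9 voxels retains roughly 75–85% of the
log-Jacobian signal, keeping the implied change within a few percentage
points of the simulated one. Much smaller structures would make |Δd|
dominated by smoothing dilution rather than by registration quality — the
quantity the framework is actually probing.

What the generator does *not* emulate: cortical folding, realistic DTI
tensor contrast, Rician noise, intensity nonuniformity, or
partial-volume effects. Passing the phantom study therefore demonstrates
that the pipeline machinery recovers known geometric change under
idealized imaging, not that any parameter set is optimal for a particular
scanner or species.

## Numerical choices and degenerate inputs

* Out-of-grid resampling returns 0 (background); brains are padded inside
  the grid by construction.
* Jacobians use central differences in the interior, one-sided at faces;
  log-Jacobians clamp determinants at 1e-6 before the log.
* Zero pooled variance in the t-test yields t = 0, p = 0.5 at equal means
  and p clamped to 1e-300 at unequal means; p/q maps carry sentinel 1
  outside the analysis mask.
* Permutation tests switch to exhaustive enumeration (identity included,
  `p = #(stat ≥ obs)/n_assign`) whenever the number of distinct label
  assignments does not exceed the requested permutation count.
* The inner-shell volume match ties to the smaller erosion depth; a
  structure smaller than its target volume is returned whole.
* FDR is computed separately for each tail's p-map, matching the practice
  of reporting atrophy and hypertrophy q-maps separately.
* ROC curves default to p-value thresholds; q-based curves can be built by
  passing a q-map.
* Label volumes are always resampled with nearest-neighbour interpolation.

## Problem sizes

The default study — and the package's own acceptance checks — use 64^3
grids with 5 control subjects and their 5 phantom counterparts, 6 template
iterations (3 downsampled), and at most 100 registration iterations per
pyramid level. These sizes were chosen so a complete study runs in minutes
on one core while the induced changes remain an order of magnitude larger
than the inter-subject variability, the same separation a well-powered
small-animal study would aim for. The directional probe comparing RegT
values runs on a further scaled-down cohort (48^3, 4 subjects per group):
it asserts only an ordering with tolerance, which needs less statistical
power than the absolute recovery thresholds.

One consequence of the greedy engine worth knowing when interpreting
phantom truths: the per-iteration total-field smoothing spreads a little
displacement far from the mask interface, so the raw mask-registration
field is not local. The phantom model is a local expansion/contraction,
so `induce_warp()` windows the field with a smooth envelope that is 1 on
the edited structures (where the truth is measured) and decays to zero a
few voxels beyond their 2-voxel leakage shells; both windowed fields are
verified to remain diffeomorphic.

## Known limitations

* The greedy engine is not numerically equivalent to full SyN; absolute
  metric values will differ from ANTs-based pipelines even where relative
  parameter orderings agree.
* Two-group contrasts only; covariates in the predictors table are carried
  but not modeled.
* Runtime-based rankings are hardware-dependent and are never part of the
  package's asserted results.
* Bias-field correction and multi-contrast mask fusion are out of scope.
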