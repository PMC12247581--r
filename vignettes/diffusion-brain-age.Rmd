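---
title: "Dual-guidance diffusion regression for brain age: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-guidance diffusion regression for brain age: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Brain age is the biological age a model infers from a structural T1-weighted
MRI scan of a healthy brain. The gap between predicted brain age and
chronological age is a candidate biomarker of atypical development and
neurodegeneration. `diffage` implements a denoising-diffusion probabilistic
model (DDPM) for *scalar regression* of age from 2D axial brain slices,
together with the surrounding pipeline: intensity preprocessing and
percentile slice selection, multi-slice ensembling with outlier exclusion,
and the downstream brain-age-gap statistics (volumetric group comparisons,
longitudinal rate categorisation, optional age-bias correction).

Because real multi-site MRI cannot be redistributed with a package, `diffage`
ships a synthetic phantom generator in which age is encoded geometrically.
Every component of the method is therefore exercisable and testable end to
end at desk scale.

## The regression diffusion model

The response is the age normalised to $y_0 \in [-1, 1]$ over configurable
bounds (default 3-30 years). The forward process corrupts $y_0$ over $T$
steps with a linear variance schedule $\beta_1 = 10^{-4}, \dots, \beta_T =
0.02$:

$$y_t = \sqrt{\bar\alpha_t}\, y_0 + \sqrt{1 - \bar\alpha_t}\, \epsilon,
\qquad \bar\alpha_t = \prod_{s \le t} (1 - \beta_s), \quad
\epsilon \sim N(0, 1).$$

A conditional denoiser $\epsilon_\theta(\rho(x), y_t, \hat y^g, \hat y^l, t)$
predicts the injected noise from the image embedding $\rho(x)$, the noised
response, two guidance priors, and a sinusoidal timestep embedding, ending in
a single-output fully connected layer. Training minimises

$$\mathcal L_{\text{diff}} = \mathcal L_e +
\tfrac12\left(\mathcal L_{\text{MMD}}^g + \mathcal L_{\text{MMD}}^l\right),$$

where $\mathcal L_e = \lVert \epsilon - \epsilon_\theta(\cdot) \rVert^2$
(batch mean) and the two regularisers are maximum-mean-discrepancy distances
between batches of noise predictions — conditioned on the global prior alone
and on the local prior alone — and standard-normal reference draws.
Timesteps are drawn uniformly on $[1, T]$ per training example.

At inference the standard ancestral DDPM reverse chain runs from $y_T \sim
N(0,1)$:

$$y_{t-1} = \frac{1}{\sqrt{\alpha_t}}\left(y_t -
\frac{\beta_t}{\sqrt{1-\bar\alpha_t}}\,\epsilon_\theta(\cdot)\right) +
\sigma_t z, \qquad \sigma_t^2 = \beta_t,\; z = 0 \text{ at } t = 1,$$

and `n_draws` independent chains (default 4) are averaged before mapping
back to years. With a null noise predictor and the stochastic term disabled
the chain has the closed form $y_0 = y_T / \sqrt{\bar\alpha_T}$, which the
test suite verifies to $10^{-9}$.

### Dual-granularity conditional guidance

Two auxiliary predictors condition every diffusion step:

* **Global prior** $\hat y^g$: the slice passes through a small
  convolutional encoder $\tau_g$ whose final $1 \times 1$ linear convolution
  produces a saliency map; $\hat y^g$ is the arithmetic mean of all map
  responses.
* **Local prior** $\hat y^l$: the $k$ highest saliency responses (greedy
  selection with non-maximum suppression at radius `patch_size/2`, ties
  broken in row-major scan order) are mapped back to image patches, encoded
  by a local encoder $\tau_l$, pooled by gated attention
  $a_k = \mathrm{softmax}_k\!\left(w^\top(\tanh(V h_k) \odot \sigma(U h_k))\right)$,
  and passed through a linear head.

Both priors are regressed onto the true normalised age with a mean-squared
error loss added to the joint objective (weight 1, configurable).

### Design choices in the open

Several aspects of this architecture are genuinely open design territory; the
package's choices are:

* **Joint training with detached priors.** The guidance encoders train
  jointly with the diffusion model, but $\hat y^g, \hat y^l$ enter the
  denoiser as detached inputs: the diffusion losses update the image encoder
  and denoiser only, the guidance MSE updates the guidance streams only.
  This avoids a separate pre-training stage while keeping each stream's
  objective unambiguous; the finite-difference gradient checks in the test
  suite validate exactly this factorisation.
* **Vector-input denoiser.** For a scalar response the denoiser is a
  multilayer perceptron over $[\rho(x), y_t, \hat y^g, \hat y^l,
  \text{emb}(t)]$; a spatial U-Net has no natural scalar analogue, and the
  stated single-output fully connected layer is retained as the final layer.
* **Conditional MMD inputs.** Each MMD term uses the batch of noise
  predictions obtained with that prior occupying both conditioning slots;
  the estimator is the biased V-statistic with a Gaussian kernel (always
  non-negative), bandwidth from the median pairwise-distance heuristic,
  treated as a constant during backpropagation.
* **Networks from scratch.** No neural-network library is a dependency: the
  encoders are small stride-2 residual convolutional networks implemented as
  im2col index gathers plus BLAS matrix products, with hand-written backward
  passes and Adam. The desk profile uses widths 8/16/32 for $\rho$ (a
  width-reduced residual encoder) and 8/16 for $\tau_g$ and $\tau_l$.
* **Early stopping** uses patience 50 on a validation loss computed with a
  fixed noising draw so epochs are comparable; the desk profile's epoch cap
  (12) is what actually ends desk-scale runs, and the best-validation
  checkpoint is returned either way.
* **Optimiser**: Adam, learning rate 2e-3, batch 128 in the desk profile.

## Preprocessing

Volumes are trilinearly rescaled to 1 mm isotropic spacing (preserving
physical extent to within a voxel per axis), thresholded by Otsu's method on
a 256-bin histogram to zero the background, median-filtered with a 3x3x3
kernel, and scaled to $[0, 1]$ by dividing the foreground by its maximum.
Anchoring the scale at the zero background (rather than min-max on the
foreground) keeps re-normalisation from shifting an already normalised
volume; exact idempotence additionally requires the input to be a fixed
point of the median filter (true for flat-interface volumes; curved
compartment boundaries can flip single border voxels on a second pass, which
is a property of median filtering itself).

Axial slices with at least 1% non-zero voxels (inclusive, counted after
background removal) are valid; five percentile slices (25, 37.5, 50, 62.5,
75 by default) are chosen from the valid list by nearest rank on positions,
`valid[round(p/100 * (n-1)) + 1]` with round-half-up. Registration, skull
stripping, and N4 bias-field correction are external tools in this pipeline
and appear as pass-through hooks whose execution status is recorded in the
provenance log.

## Ensembling

Per-subject consensus over slice models: plain averaging, or the
outlier-exclusion rule — compute the mean $m$ and *sample* (n-1) standard
deviation $s$ of the slice predictions, exclude predictions with
$|p - m| > s$ (strict inequality, single pass), and average the rest. With
this convention at least one prediction always survives, and $s = 0$
excludes nothing.

## Brain-age-gap statistics

* Gap = predicted age − chronological age.
* Accuracy: MAE and the 25th/75th percentiles of absolute error
  (linear-interpolation percentile convention).
* Outlier grouping: within (integer-year age bin x sex) strata, subjects more
  than 1 sample SD above (below) the stratum mean prediction are Older
  (Younger); strata smaller than 3 default to Average with a warning.
* Group comparisons: two-sided Mann-Whitney U tests per measure, sex, and
  group pair against the Average group, Bonferroni-corrected at
  $\alpha / (\text{measures} \times \text{sexes} \times \text{pairs})$
  (0.05/16 = 0.003125 in the standard design); Cohen's d with pooled sample
  SD. The comparison count is a formula, not a constant, so reduced designs
  adjust automatically.
* Longitudinal: per-interval rates $\Delta\text{value}/\Delta\text{age}$,
  subject rate = mean of interval rates; Accelerated/Decelerated when the
  brain-age rate is more than 1 cohort SD above/below the cohort mean;
  Stable-vs-Accelerated and Stable-vs-Decelerated Mann-Whitney tests per
  measure at $\alpha/8$ (P < 0.00625, i.e. the P < 0.006 threshold of the
  four-measure design).
* Age-bias correction (off by default): fit gap $= a\,\text{age} + b$ on a
  disjoint fit set, subtract the fitted line from predictions.

## The synthetic phantom generator

A phantom is a nested-ellipsoid volume: a CSF-filled "ventricle" core whose
radius grows linearly with age, a white-matter shell, and a cortical
grey-matter band whose thickness shrinks linearly with age, inside an
ellipsoidal brain on a 32^3 grid (1 mm voxels in the NIfTI header), plus
additive Gaussian intensity noise (SD 0.02) clipped at zero. Linear radius
and thickness maps keep the analytic voxel-count oracle trivial; the tests
compare compartment counts against direct evaluation of the defining radius
inequalities. Ages are sampled uniformly over the configured range,
emulating age-flattened training stratification.

The volumetric-table generator plants standardized mean differences per
measure and group; the planted shift is $d \times \mathrm{SD}_{\text{total}}$
with the age-trend variance included in $\mathrm{SD}_{\text{total}}$, so a
pooled-SD Cohen's d recovers the planted value. The longitudinal generator
gives each subject a per-year brain-age rate $1 + N(0, \tau)$; planted
Accelerated/Decelerated subjects have their rate *pinned* at $1 \pm c\tau$
(replacing, not adding to, the subject-level deviation). With an additive
shift on top of subject-level spread, a mean + 1 SD threshold cannot reach
high sensitivity for a +2 SD shift even in the infinite-sample limit
(the maximum is about 84% as the planted fraction goes to zero), so the
pinned form is the construction under which the categorisation rule is
meaningfully testable; measurement noise on predictions (SD 0.1 years per
visit) keeps the recovery non-trivial.

**What the phantoms do and do not show.** The geometric age encoding is
strictly monotone and noise is i.i.d. Gaussian; real T1w MRI has scanner and
site effects, registration error, biological heterogeneity, and a much
weaker, non-monotone image-age relationship. Passing the desk-scale recovery
tests demonstrates that the machinery — schedule, guidance, losses,
sampling, ensembling, statistics — is implemented correctly and can learn a
known mapping; it says nothing about accuracy on real scans.

## Problem sizes and numerical tolerances

The desk-profile study conditions used by the tests and the acceptance
script: 2000 training / 200 validation / 200 test phantoms per seed, one
model per percentile slice (five models), T = 100, three seeds with majority
voting for the stochastic end-to-end checks. Deterministic oracles are held
to 1e-12 (schedule products, kernel sums), closed forms to 1e-9, Monte-Carlo
moments to 1% at 1e5 draws, and planted-effect recoveries to the stated
simulation tolerances. All randomness flows from explicit integer seeds;
training and prediction are bit-reproducible in single-threaded BLAS mode.

## Known limitations

* The desk profile is a faithful scale-down, not the full-size model: a
  width-reduced encoder instead of an 18-layer residual network at full
  width, T = 100 instead of 1000, 32^2 slices instead of full-resolution MRI.
* The phantom generator does not simulate MRI contrast physics, bias fields,
  or registration error (deliberate non-goals).
* Centile normalisation of volumetrics (normative growth charts) is consumed
  as input columns when present, never computed.
* `rescale_isotropic` uses trilinear interpolation; high-frequency content
  beyond the Nyquist limit of the target grid will alias as in any linear
  resampler.
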