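---
title: "Generating 3D brain morphology by deforming a learned template"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating 3D brain morphology by deforming a learned template}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Most generative models for 3D structural brain MRI synthesize intensity
volumes directly. Much of the biologically meaningful variation between
individual brains, however, is geometric: regions grow, shrink and fold.
`morphdiff` therefore models the *deformation* of a shared anatomy rather
than the image itself. It assumes every volume `x` is a warped copy of a
template `x_bar`,

    x = v o x_bar,     v = Id + u,

where `u` is a dense 3-channel displacement field in voxel units and `Id`
the identity sampling grid. Modeling the distribution of images reduces to
modeling the distribution of displacement fields induced by the template.

Training is in two stages, following the latent-diffusion recipe with the
autoencoder replaced by a registration network:

**Stage 1** jointly learns three networks. A template decoder produces
the template volume as a learnable full-resolution base image plus an
additive modulation decoded from a small input vector (learnable in the
unconditional model; the normalized condition vector `(age/100, sex)` in
the conditional variant) — the learnable-atlas construction of
conditional template learning. The base image trains with a 10x
learning-rate multiplier: it is a direct per-voxel parameter, not a conv
output, and would otherwise lag the rest of the model. An encoder sees the image and the current template
concatenated along the channel axis and produces a variational latent `z`
(8 channels at 1/8 resolution: three stride-2 levels). A deformation
decoder maps `z` to the displacement field that warps the template onto
the image through a differentiable trilinear grid sampler. The loss is a
registration objective:

    L = L1(warp(x_bar, u), x)
        + alpha * mean_p |u(p)|^2 + beta * mean_p |grad u(p)|^2
        + kl_weight * KL(q(z|x) || N(0, 1))
        + adversarial_weight * LSGAN generator term.

Defaults are `alpha = 5`, `beta = 1`, `kl_weight = 1e-7`,
`adversarial_weight = 0.005`, with a 3-layer strided patch critic judging
the deformed template against real volumes under a least-squares GAN
objective. The tiny KL weight exists only to prevent the latent variance
from growing without bound; it is not meant to make the latent prior
match closely.

**Stage 2** freezes stage 1 and trains a time-conditioned denoiser on the
encoded latents (epsilon-prediction DDPM): latents are corrupted as
`z_t = sqrt(abar_t) z_0 + sqrt(1 - abar_t) eps` and a small 3D UNet with a
sinusoidal time embedding learns to predict `eps` from `(z_t, t, c)`. The
condition `c` enters through single-head cross-attention over two learned
condition tokens at the coarse UNet levels. Generation samples a latent by
reverse diffusion (ancestral or DDIM), decodes it to a displacement field,
and warps the template; in the conditional variant the condition channels
appended to `z` are rebuilt deterministically from the requested `c`
rather than denoised, so generation stays consistent with the latent
layout seen in training.

## Design choices on open points

Several details are deliberate package decisions where the underlying
method leaves room:

* **Norm convention and units in the regularizer.** `R(u)` uses means
  over voxels (sum over channels and derivative directions), so `alpha`
  and `beta` are resolution-independent. `displacement_regularizer()`
  reports voxel-unit values by default; inside the training objective the
  field is first rescaled to grid-sampler coordinates (half grid extent
  = 1, the convention of the standard differentiable-warp stacks), which
  is the scale the default `alpha = 5`, `beta = 1` are calibrated for.
  On voxel units those weights would suppress all useful deformation: a
  two-voxel boundary shift would cost roughly a hundred times its
  similarity gain.
* **Displacement, not velocity.** The field is applied directly as
  `v = Id + u`; there is no scaling-and-squaring integration, and no
  diffeomorphism guarantee. `jacobian_determinant()` reports folding
  instead.
* **Finite differences.** Forward differences with a replicated edge (the
  last slice contributes a zero difference), the common choice in
  learning-based registration.
* **Zero-initialized heads.** The final layers of both the field head and
  the diffusion UNet output are zero-initialized, so stage 1 starts
  exactly at the identity deformation and a fresh denoiser predicts zero
  noise (unit loss against unit Gaussian targets). This makes early
  training stable and gives clean analytic baselines for tests.
* **Half-resolution heads with a full-resolution refinement.** The field
  and template are predicted at half the grid resolution, upsampled
  trilinearly, and passed through one cheap full-resolution 3x3x3
  convolution. Fields and templates are smooth at half resolution, so
  this removes the expensive full-resolution convolutions from the inner
  loop, while the refinement layer restores thin bright structures
  (phantom ventricles span only a few voxels) that plain trilinear
  upsampling dilutes.
* **Log-variance clamp and posterior sharpening.** The encoder's
  log-variance is clamped to [-10, 10]. Because the KL weight is tiny,
  reconstruction pressure sharpens the posterior until many latent
  elements sit at the lower clamp — an effectively deterministic encoder,
  the expected regime for KL-regularized latent-diffusion autoencoders.
  The clamp keeps that collapse numerically bounded; the penalty's real
  job, preventing variance blow-up, is what the tests assert.
* **Out-of-bounds sampling** replicates the border by default (a `zeros`
  option exists); phantom anatomy never reaches the boundary, so the two
  differ only in pathological cases.
* **Noise schedule.** Linear betas 1e-4 to 2e-2 over `T = 100` steps in
  the desk preset (`T = 1000` in the reference-scale preset), the standard
  DDPM convention; the schedule kind, step count and samplers are
  configurable. Latents are standardized by a single scalar (1/SD of the
  training latents) before diffusion and unscaled after sampling.
* **Sampled latents for stage 2.** The diffusion model trains on the
  reparameterized latent draw (a `mean` export is available in
  `stage1_config`), matching common latent-diffusion practice.
* **Condition encoding.** Age is divided by 100, sex is a 0/1 scalar;
  the same map feeds the template decoder, the appended latent channels
  and the cross-attention tokens, and it is trivially invertible.
* **Classifier-free guidance is deliberately absent**; conditioning flows
  only through cross-attention and, in the conditional variant, the
  appended channels and conditional template.

## The phantom generator

Real training data for this class of model is tens of thousands of
registered, skull-stripped T1-weighted volumes; none ships with the
package. The phantom module generates a stand-in cohort whose morphology
varies the way the model cares about:

* concentric "head", "brain" ellipsoids with two lateral subregions and a
  central "ventricle", painted in order into a label map (inner regions
  overwrite outer ones);
* region radii vary linearly with normalized age and with sex; the
  default ventricle grows strongly with age (base semi-axes 0.08-0.10 of
  the grid, +0.08 per normalized-age unit), which mirrors the
  best-established ageing signal in brain morphometry and makes age
  recoverable from volume alone;
* the outer boundary carries a sinusoidal radial perturbation whose phase
  depends on sex — a purely morphological, folding-like sex signal;
* intensities per region are distinct (0.25/0.55/0.75/0.40/0.95 against
  background 0), so thresholding at intensity midpoints recovers the
  exact label map of a noiseless, unsmoothed phantom; generated images
  are segmented the same way (`threshold_segment()`), standing in for a
  learned segmenter;
* Gaussian smoothing (0.6 voxels) and additive Gaussian noise (SD 0.02)
  are applied to the image only; labels stay exact.

Effect sizes are free parameters of the phantom world, chosen once and
generously so that recovery analyses are well-powered at desk scale. What
phantoms do *not* emulate: MRI physics (bias fields, k-space artifacts),
true cortical topology, registration error, and the long-tailed anatomy
of real cohorts. A pass on phantoms therefore demonstrates that the
machinery — warping, joint template learning, latent diffusion,
conditioning, the metric suite — is correct and recovers planted
morphological signal; it does not certify image realism on clinical data.

## Problem sizes and presets

The package's standard study runs on the `desk32` preset: 200 phantoms at
32^3, 30 stage-1 epochs (Adam, lr 1e-3, batch 8, decade-balanced age
sampling), 2000 stage-2 steps (T = 100), and 50 generated samples with
ages evenly spaced on [5, 95] and alternating sex. The reproduction
script (`scripts/acceptance.R`) runs the same pipeline with a 15-epoch
stage 1 — the measured properties stabilize within the first dozen
epochs — so a full from-scratch rerun stays comfortably inside a
laptop-scale session. Channel widths are
desk-scale (encoder 8/16/16, decoder 16/12/12, UNet 24/32); the
`reference_full` preset records the reference-scale shapes (160x192x176
grids, UNet 384/512/512, T = 1000, lr 1e-4) and is not meant to be run on
a laptop. The structural commitments — three downsampling levels, 8
latent channels, 3-channel field output, cross-attention placement — are
identical across presets.

```{r}
library(morphdiff)
spec <- phantom_spec()
cohort <- make_cohort(spec, 200, seed = 101)
ae <- train_autoencoder(cohort, stage1_config(conditional = TRUE, seed = 1))
enc <- encode_cohort(ae, cohort, seed = 11)
dm <- train_diffusion(enc$latents, enc$conditions, stage2_config(seed = 12))
samples <- generate(ae, dm, condition(70, 1), n = 5, seed = 33)
```

## Evaluation protocol

`evaluate_cohorts()` (and the `evaluate` CLI subcommand) reproduces the
reference evaluation design at phantom scale:

* **MS-SSIM diversity**: mean multi-scale SSIM over 1000 random sample
  pairs; higher means less diverse. On 32^3 grids only 2 of the standard
  5 scales fit the 11-voxel Gaussian window; the weights are renormalized
  and the scale count recorded.
* **Condition adherence**: small 3D CNN age regressor and sex classifier
  trained on the real cohort, applied to generated samples; reported as
  age MAE (overall and per requested-age decade) and sex accuracy.
* **Regional-volume effect sizes**: absolute Cohen's d (classical pooled-SD
  two-sample form) per region between real ground-truth label volumes and
  threshold-segmented generated volumes; zero-pooled-SD regions are
  flagged, not dropped.
* **Frechet distance** over a pluggable feature embedding; the bundled
  extractor is the penultimate (global-average-pooled) layer of the
  phantom-trained age predictor, so the metric runs fully offline. An
  ImageNet-style backbone can be plugged in by supplying its features.

## Known limitations

* Networks are plain 3D conv stacks sized for CPUs; no attention in
  stage 1, no multi-resolution field pyramid.
* The warp is resolution-preserving and non-invertible; analyses that
  need inverse deformations (e.g., template-space statistics of real
  images) are out of scope.
* The threshold segmenter assumes the generated intensities stay close to
  the phantom palette; a model that drifts far from it would need the
  learned-segmenter route instead.
* Determinism is exact for fixed seeds on a given BLAS; bit-exactness
  across different BLAS builds is not guaranteed.
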