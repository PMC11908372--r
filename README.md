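# morphdiff

Generative modeling of 3D brain morphology by deforming a learned
template, for researchers who study how anatomy varies with attributes
such as age and sex and who want condition-specific synthetic cohorts
whose *shape* statistics are right, not just their voxel intensities.

## The model

Direct intensity-space generators (GANs, plain latent diffusion) can miss
the geometric detail that carries most inter-individual variation in
neuroimaging. `morphdiff` instead assumes every volume is a warped copy of
a learned template,

    x = v ∘ x̄,    v = Id + u,

and models the distribution of displacement fields `u`. Two stages:

1. **Deformation autoencoder with a learned template.** A template
   decoder produces `x̄` (optionally conditioned on `(age/100, sex)`); an
   encoder maps the channel-concatenated `(x, x̄)` to a variational latent
   `z` (8 channels, 1/8 resolution); a deformation decoder maps `z` to
   `u`; a differentiable trilinear warp applies `v = Id + u` to `x̄`. All
   three are trained jointly on a registration loss

       L1(v ∘ x̄, x) + α·mean‖u‖² + β·mean‖∇u‖² + 1e-7·KL + 0.005·LSGAN,

   with α = 5, β = 1, and a 3-layer strided patch critic.

2. **Conditional latent diffusion.** An ε-prediction DDPM over the
   stage-1 latents, with `(age, sex)` injected by cross-attention over
   learned condition tokens. Sampling a latent, decoding it to a field,
   and warping the template yields a novel anatomy for a requested
   condition.

Everything runs on CPU: the 3D conv stacks, the warp and its gradients
are implemented in Rcpp/RcppArmadillo with hand-derived backward passes.

Because no imaging cohort ships with the package, a phantom module
generates synthetic "brain" cohorts — concentric ellipsoid anatomy with
ground-truth labels whose ventricles grow with age and whose outer
boundary folds with a sex-dependent phase — so the full pipeline trains,
generates and evaluates end to end offline. See the methods vignette
(`vignettes/deformation-diffusion.Rmd`) for the model, the phantom
design, and every numerical decision.

## Worked example

```r
library(morphdiff)

spec   <- phantom_spec()                           # 32^3 phantom anatomy
cohort <- make_cohort(spec, 200, seed = 101)       # ages 5-100, sexes 50/50

ae <- train_autoencoder(cohort, stage1_config(conditional = TRUE, seed = 1))
ae
#> <morph_autoencoder 32x32x32 (conditional), 30 epochs, similarity 0.1883 -> 0.0141>

enc <- encode_cohort(ae, cohort, seed = 11)
dm  <- train_diffusion(enc$latents, enc$conditions, stage2_config(seed = 12))
dm
#> <morph_diffusion latent 8x4x4x4, T=100, 2000 steps, loss 0.942 -> 0.165>

# 5 synthetic 70-year-old female anatomies
samples <- generate(ae, dm, condition(70, 1), n = 5, seed = 33)
sum(threshold_segment(samples[[1]]$volume, spec) == 5L)   # ventricle voxels
#> [1] 300
```

The printed similarity line says the deformed template matches images
~13x better than at the start of training; the diffusion loss falls from
the unit-Gaussian baseline (~1.0) as the denoiser learns the latent
distribution; and the ventricle voxel count of a generated 70-year-old
(300) sits far above what the same pipeline generates at the young end of
the age range (~87 voxels at age 5), i.e. the requested age shows up in
the generated morphology.

The command-line front end chains the same steps
(`inst/cli/morphdiff.R`): `make-data`, `train-ae`, `train-dm`,
`generate`, `evaluate`, `export-template`, each taking `--config`,
`--seed`, `--preset` and `--set key=value` overrides, reading and writing
NIfTI volumes plus TSV manifests.

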