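# fodgan

Generative modelling of 4D fibre-orientation-distribution (FOD) volumes with
an alpha-Wasserstein GAN, in R.

## The problem

Diffusion-MRI pipelines estimate, in every voxel, a *fibre orientation
distribution* — a spherical function describing the angular density of white
matter axons — represented by real even-order spherical-harmonic (SH)
coefficients (order `lmax = 6` gives 28 coefficients per voxel, so a whole
brain is a 4D array `28 x 128 x 128 x 64`). Sharing such data is restricted
by privacy; synthetic cohorts that preserve the anatomy and the fibre
geometry would let methods development proceed without patient data.

`fodgan` implements the full modelling and validation chain for this
problem, for researchers in diffusion MRI and medical image synthesis:

* **SH data model** (`sh_basis`, `sh_image`): real even-order orthonormal
  basis, channels ordered by `l` then `m` ascending (phase-free associated
  Legendre convention), evaluation/fitting on the sphere, coefficient
  rotation by sample-and-refit, cropping with 0-based inclusive slice
  ranges, trilinear regridding, 4D NIfTI I/O.
* **Synthetic phantoms** (`make_phantom`, `make_cohort`,
  `make_toy_connectome`): seeded brain-like FOD phantoms with smooth
  crossing fibre bundles encoded as rotated single-fibre SH lobes, an
  isotropic ventricle, ground-truth tract masks, streamlines, and
  block-structured toy connectomes — every downstream module is testable
  without any data download.
* **Augmentation** (`augment_cohort`): each volume plus four slightly
  rotated copies (one per principal axis and one triple rotation, angles
  `N(0, 1°)`), with true SH reorientation; 965 subjects become 4825.
* **Networks** (`fullscale_generator_spec`, ..., `build_network`): declarative
  layer tables for the four sub-networks — generator/decoder (transposed
  conv + nearest-neighbour-upsampling conv blocks, tanh output),
  discriminator and encoder (six strided 3D convolutions), code
  discriminator (three linear layers) — instantiated at full scale
  symbolically and at desk scale concretely by a self-contained 3D
  convolutional engine (im2col/GEMM kernels in RcppArmadillo, batch norm,
  Adam, reverse-mode gradients; optional single-precision convolutions).
* **Training** (`train`): the hybrid objective

  ```
  L_GE = -<D(x_dec)> - <D(x_syn)> - <CD(z_e)> + lambda <||x_real - x_dec||_L1>
  L_D  =  <D(x_dec)> + <D(x_syn)> - 2 <D(x_train)> + kappa * phi_D
  L_CD =  <CD(z_e)> - <CD(z_r)> + kappa * phi_CD
  ```

  with per-sample gradient-penalty interpolants, `lambda = 50000`,
  `kappa = 10`, Adam at learning rate 1e-4, batch size 6, and the per-epoch
  schedule 1 encoder / 2 generator / 4 discriminator / 1 code-discriminator
  steps. Training is seeded, logged, checkpointed, and bit-compatibly
  resumable.
* **Generation** (`generate_fods`): seeded latent sampling, denormalization
  to FOD units, NIfTI output with a JSON manifest.
* **Validation metrics** (`dice`, `pairwise_ssd`, `channel_histograms`,
  `normalize_connectome`, `global_efficiency`, `mantel`,
  `resample_streamline`, `afd_map`, `along_tract_profile`,
  `streamlines_to_mask`, `cohort_compare`): the quantitative comparison
  suite for synthetic-vs-real cohorts.

## Worked example

```r
library(fodgan)

# a seeded cohort of 20 brain-like FOD phantoms on a 32 x 32 x 16 grid
spec   <- phantom_spec(grid_dims = c(32, 32, 16), voxel_size = c(5, 5, 10),
                       lmax = 6, seed = 11)
cohort <- make_cohort(20, spec)

# train a desk-scale model (channels / 50, latent 64) for 200 epochs
cfg   <- train_config(epochs = 200,
                      scale = model_scale(c(32, 32, 16), 1/50, latent_dim = 64),
                      seed = 4, eval_every = 50)
state <- train(cfg, cohort, val_cohort = make_cohort(4, spec, seed = 900))
lg <- training_log(state)
lg[!is.na(lg$val_l1), c("epoch", "val_l1")][c(1, 2, 4, 5), ]
#>     epoch    val_l1
#> 1       1 213898.22
#> 50     50  99782.57
#> 150   150  58277.78
#> 200   200  51110.26

# the held-out reconstruction L1 fell 4-fold; now sample new FODs
synth <- generate_fods(state, 16, seed = 77)
ssd <- pairwise_ssd(synth)
round(c(mean = ssd$mean, sd = ssd$sd), 1)
#>   mean     sd
#> 3119.1 5918.4
```

The held-out reconstruction error (`val_l1`, the mean per-volume sum of
absolute coefficient differences in normalized units) drops monotonically
across the logged epochs, and all 16 generated volumes are pairwise
distinct (`all(ssd$values > 0)`), the no-mode-collapse probe. The validation metrics compare synthetic and
reference cohorts; for example, connectomes are normalized to total weight 2
before computing weighted global efficiency:

```r
C <- make_toy_connectome(116, seed = 9)
global_efficiency(normalize_connectome(C))
#> [1] 0.0004680974
```

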