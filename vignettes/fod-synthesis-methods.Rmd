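---
title: "Methods: generative modelling of FOD volumes with an alpha-Wasserstein GAN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: generative modelling of FOD volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions, and numerical choices
behind `fodgan`, in the spirit of a methods section: what is computed, under
which assumptions, with which defaults, and where the edges are.

## The data model

A fibre orientation distribution (FOD) is an antipodally symmetric spherical
function per voxel, stored as real even-order spherical-harmonic (SH)
coefficients. `fodgan` fixes the following convention:

* orders `l = 0, 2, ..., lmax`; `(lmax+1)(lmax+2)/2` channels
  (28 at `lmax = 6`);
* channels ordered by `l` ascending, then `m = -l ... l` ascending;
* real orthonormal basis: `m = 0` gives `N(l,0) P_l^0(cos theta)`;
  `m > 0` gives `sqrt(2) N(l,m) P_l^m(cos theta) cos(m phi)`; `m < 0` the
  matching sine term; associated Legendre functions are evaluated by the
  standard diagonal/upward recurrences *without* the Condon–Shortley phase.

Orthonormality means the spherical integral of the FOD is
`sqrt(4*pi) * c_0`, which is the simplified apparent-fibre-density (AFD)
map offered by `afd_map()`. Full fixel-wise AFD requires FOD lobe
segmentation, which this package does not perform; `along_tract_profile()`
accepts any externally computed scalar map in its place.

`sh_image` stores coefficients channel-first (`[n_coeff, nx, ny, nz]`) with
voxel sizes in mm and no full affine: the pipeline never needs world-space
registration, only voxel geometry. World coordinates put the corner of the
first voxel at the origin; voxel centres sit at `(i + 0.5) * voxel_size` for
0-based index `i`.

### Rotation of SH coefficients

`rotate_sh()` uses sample-and-refit: the rotated function is evaluated on a
512-point Fibonacci sphere sampling (≥ 4x oversampling of the 28
coefficients) and re-fitted by least squares. Rotations act unitarily within
each order, so the per-order coefficient norms are preserved; the tests
assert this (tolerance 1e-6) together with composition
(`R2 after R1 = R2 %*% R1`) and isotropic-channel invariance. A Wigner-matrix
recursion would be faster at scale but is not needed at these orders, and the
band-norm property test guards the simpler route.

### Cropping and regridding

Slice ranges are 0-based inclusive: keeping slices 10–137 retains
`137 - 10 + 1 = 128` slices. This matches the whole-brain trim of the
native `145 x 174 x 145` grid at 1.25 mm (sagittal 10–137, frontal 7–171,
axial 2–129 → `128 x 165 x 128`), which, regridded to `128 x 128 x 64`,
yields the anisotropic working voxel of `1.25 x 1.61 x 2.5` mm. Regridding
preserves the physical extent (`new_size = old_size * old_dims /
new_dims`) and interpolates each channel trilinearly at the new voxel
centres with edge clamping, so constant images are exactly preserved. The
upstream tool that performed this step in the original pipeline does not
document its kernel; trilinear is the conventional choice.

## The synthetic phantom generator

`make_phantom()` emulates the features of whole-brain FOD training data that
the networks must learn, not its intensity statistics:

* an ellipsoidal brain support (background exactly zero);
* 1–4 smooth fibre bundles: quadratic Bézier centrelines carrying an
  axially symmetric single-fibre lobe aligned with the local tangent;
  crossing voxels sum their lobes;
* an isotropic "ventricle" ellipsoid carrying only the `l = 0` channel;
* per-subject geometric jitter (`N(0, jitter_sd^2)` mm on control points
  and the ventricle centre, default 0.5 mm) to mimic inter-subject
  variability, and optional coefficient noise (default 0: clean geometry).

The single-fibre lobe is `(d . t)^lmax` — exactly band-limited at the
phantom's `lmax`, hence non-negative up to fit round-off and free of
truncation ringing; the amplitude-non-negativity invariant is tested with a
2% allowance. The default desk-scale grid is `16 x 16 x 8` at 2 mm with
`lmax` 2 or 6 selectable; the default bundle radius is 18% of the smallest
grid extent so the built-in geometries fit any grid. Seeding is explicit:
subject `i` of a cohort uses child seed `seed + i`, so cohorts are
reproducible per subject and independent of cohort size. What passing tests
on these phantoms do *not* show: performance on real FOD contrast, real
noise spectra, or real anatomical variability.

`make_toy_connectome()` produces the block-diagonal community structure that
whole-brain structural connectomes display (dense blocks separated by
sparser off-block connections): edge probability `1.5 * density` in-block
(capped at 1) versus `0.5 * density` across blocks, uniform weights with
means 1.0 and 0.4.

## Augmentation

The training pool is expanded 5x: the original plus one small random
rotation about each principal axis plus one triple rotation
(`Rz %*% Ry %*% Rx`), all angles `N(0, 1 degree)`. Rotation resamples the
spatial grid trilinearly about the grid centre (zero-padding outside — at 1
degree the boundary effect is negligible) and, by default, reorients the SH
coefficients with the same rotation so fibre orientations follow the
anatomy; a flag disables reorientation because the original description is
ambiguous about whether coefficients were reoriented or only the grid
resampled. Reorientation is the physically correct default.

## Networks

The four sub-networks are built from declarative layer tables:

* **Generator/decoder** — a transposed 3D convolution lifts the latent
  vector (5000 at full scale) as channels on a `1^3` grid onto the coarse
  grid `dims / (32, 32, 16)`; four blocks of nearest-neighbour x2 upsampling
  + 3^3 convolution + batch norm + ReLU reduce channels
  3200 → 1600 → 800 → 400 → 200; a final `(2, 2, 1)` upsample + convolution
  emits the 28 SH channels through tanh. Output `28 x 128 x 128 x 64`.
* **Discriminator** — six strided convolutions (28 → 125 → 250 → 500 → 1000
  → 2000 → 1), kernel 4 stride 2 except layer 5 (`(4,4,3)`/`(2,2,1)`) and
  the final collapsing kernel; leaky-ReLU slope 0.2 then 0.05; batch norm in
  layers 2–5 only. Kept as printed even though gradient-penalty practice
  often omits batch norm in the critic; a flag disables it.
* **Encoder** — identical to the discriminator except the last layer emits
  the latent dimension. The encoder is deterministic — no mean/log-variance
  split; Gaussian structure of the codes is enforced adversarially by the
  code discriminator.
* **Code discriminator** — linear 5000 → 4096 → 4096 → 1 with batch norm and
  leaky-ReLU (slope 0.2) after the first two layers.

Where the tables are silent we use the conventional choices: conv → batch
norm → activation ordering; latent entering as channels on a `1^3` grid;
fan-in-scaled normal initialisation. Shape traces are validated symbolically
at construction for every spec, including full scale (no parameter
allocation: the full-scale generator holds ~1.2e9 parameters).
`scale_spec()` produces desk-scale variants by multiplying internal channel
counts (floor 2) and swapping the latent, preserving the topology; spatial
dims must be divisible by `(32, 32, 16)`.

### The network engine

No deep-learning framework is used: forward and reverse-mode passes are
implemented in the package, with im2col + GEMM convolution kernels
(RcppArmadillo), nearest-neighbour upsampling, training/eval-mode batch
normalisation (momentum 0.1, eps 1e-5, biased variance throughout), and
Adam (framework-default betas 0.9/0.999). Backpropagation is verified
against central-difference numeric gradients for every layer kind, including
batch norm and the transposed convolution, in the test suite.

Convolutions optionally run in single precision (`precision = "single"`,
the default for `train()`), the conventional training precision for this
model family; parameters, batch norm and the optimiser stay in double. In
single-precision mode tanh uses the degree-13/6 rational minimax
approximation standard in deep-learning runtimes (max abs error ~3e-7).

## Training objective and schedule

With batch means `< >`, decoded batch `x_dec = G(E(x_train))`, synthetic
batch `x_syn = G(z_r)`:

* `L_GE = -<D(x_dec)> - <D(x_syn)> - <CD(z_e)> + lambda <||x_train - x_dec||_L1>`
  (the `CD(z_r)` term is absent: G and E cannot influence it). The L1 norm
  is the sum of absolute differences over all voxels and channels of one
  sample.
* `L_D = <D(x_dec)> + <D(x_syn)> - 2 <D(x_train)> + kappa * phi_D`, with
  `phi_D` the gradient penalty at `alpha x_train + (1-alpha) x_syn` and
  `beta x_train + (1-beta) x_dec`, per-sample `alpha, beta ~ U(0,1)`.
* `L_CD = <CD(z_e)> - <CD(z_r)> + kappa * phi_CD` at
  `gamma z_e + (1-gamma) z_r`.

Defaults: `lambda = 50000` (the large reconstruction weight that suppresses
mode collapse by pushing the model toward a VAE), `kappa = 10`, Adam lr
1e-4, batch 6. One epoch is one schedule iteration on freshly drawn batches
— at full scale, 37,000 epochs of batch 6 cannot be full passes over 4825
subjects, so "epoch" here means one iteration of: recompute `L_GE` and step
E once and G twice (same batch, loss recomputed before each step; each step
evaluates only the loss terms that carry gradients for the network being
stepped — the value is identical), then four discriminator updates on fresh
batches, then one code-discriminator update. The optimiser-step ledger after
`k` epochs is exactly `E:k, G:2k, D:4k, CD:k`, which the tests assert.

Numerical choices worth knowing:

* **Gradient-penalty parameter gradients.** The penalty involves
  `grad_x D(x)`, so its parameter gradient is a second derivative. It is
  computed as a directional (Hessian-vector) derivative along the normalised
  input gradient, by a symmetric/one-sided finite difference of the
  first-order backward pass (step scaled to a 1e-4 relative perturbation).
  For piecewise-linear critics (leaky-ReLU networks) this is exact; batch
  norm makes it approximate to O(eps). Per-sample input gradients are taken
  from one batched reverse pass, so batch-norm coupling across the batch is
  included, as it is in standard autograd implementations. In the training
  loop both interpolant families are evaluated in one batched critic pass
  (their batch-norm statistics are pooled there); the exported
  `gradient_penalty_d()` evaluates the two terms separately.
* **Intensity normalisation.** The generator ends in tanh, so training data
  are divided per channel by the cohort-wide maximum absolute coefficient;
  the constants are stored in the checkpoint sidecar and inverted on
  generation. Out-of-range values at application time are clipped with a
  reported count.
* **Reconstruction weight at reduced scale.** The L1 term scales with the
  voxel count, so `train_config(scale_lambda = TRUE)` (default) multiplies
  `lambda` by `prod(dims) / prod(c(128, 128, 64))`, keeping the
  reconstruction/adversarial balance of the full-scale setting (e.g.
  `lambda_eff ≈ 781` at `32 x 32 x 16`).
* **Held-out reconstruction metric.** Logged with batch statistics over the
  held-out cohort rather than running averages: at desk scale the running
  averages lag the rapidly moving batch statistics and would measure
  normalisation drift, not reconstruction. Running statistics are left
  untouched by evaluation.
* **Failure handling.** A non-finite loss aborts with a checkpoint and a
  diagnostic rather than propagating NaNs.
* **Determinism.** All randomness flows from the config seed through R's
  RNG; checkpoints store the RNG state, so resuming reproduces the
  uninterrupted run bit-exactly. Single-precision kernels are deterministic
  on a given platform.

## Desk-scale study conditions

The bundled demonstration trains at `32 x 32 x 16` voxels, channel
multiplier 1/50 (the generator runs 64 → 32 → 16 → 8 → 4 → 28 channels),
latent 64, batch 6, 200 epochs, on 20 phantoms with 4 held-out — about 15
minutes on one CPU core. This is the configuration exercised by the
acceptance tests: held-out reconstruction L1 must fall relative to epoch 1,
and 16 generated samples must be pairwise distinct (the mode-collapse
probe). Full-scale training (latent 5000, `128 x 128 x 64`, 37,000 epochs)
requires data-centre GPUs and is out of scope; the full-scale architecture
is still constructed and shape-checked symbolically.

## Validation metrics

* **Dice** `2|A∩B| / (|A|+|B|)` on equal-grid binary masks; both-empty is an
  error, not 0/0.
* **Pairwise SSD**: sums of voxelwise squared coefficient differences over
  all unordered pairs; quantifies cohort variation.
* **Connectome normalisation**: scale to total weight 2 (each connection
  counted twice in the symmetric matrix), removing global streamline-weight
  bias before network measures.
* **Weighted global efficiency**: edge lengths `1/weight` (the
  brain-connectivity-toolbox convention), Dijkstra shortest paths via
  igraph, mean of `1/d` over ordered pairs, disconnected pairs contributing
  0; cross-checked against a Floyd–Warshall oracle on 100 random graphs.
* **Mantel test**: Pearson (default; Spearman by flag) correlation of
  upper-triangle entries, p by node-label permutations with the add-one
  estimator `(count + 1) / (n_perm + 1)`, default 9999 permutations;
  null calibration is tested (rejection rate at alpha = 0.05 within
  [0.02, 0.09] over 200 replicates).
* **Streamline machinery**: arc-length resampling to 100 equidistant points
  (endpoints exact); trilinear along-tract profiling with mean/sd across
  streamlines; rasterization to 1 mm binary masks by exact 3D voxel
  traversal (DDA) rather than vertex binning — point-dropping produces
  discontinuous masks at coarse step sizes, the failure mode that motivates
  segment traversal.
* **Cohort comparison**: within-synthetic / within-validation / cross-pair
  distributions for pairwise statistics, and a two-sided
  Wilcoxon–Mann–Whitney rank-sum p (via `stats::wilcox.test`) for
  per-subject statistics.

## Known limitations

* Phantoms are geometric caricatures; no claim is made about matching real
  FOD intensity statistics, noise, or anatomy beyond crossing-bundle
  structure and compartment layout.
* AFD is the whole-FOD spherical integral, not fixel-wise AFD.
* Tractography, streamline weighting, bundle segmentation and atlas
  registration are external to this package: `streamline_set` and
  `connectome` objects are consumed, not estimated, here (the phantom
  generator produces synthetic stand-ins).
* The full-scale model is instantiated only symbolically; training at full
  scale is out of scope.
* Whether the critic should retain batch normalisation under a gradient
  penalty is debatable; the printed architecture keeps it, and so does the
  default here (`batch_norm_d = FALSE` to disable).
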