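Package: fodgan
Title: Synthesis of Fibre Orientation Distribution Volumes with an
    Alpha-Wasserstein GAN
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Generative modelling of 4D fibre-orientation-distribution (FOD)
    volumes from diffusion MRI. Implements the real even-order spherical
    harmonic data model with rotation, cropping, regridding and NIfTI I/O; a
    seeded synthetic FOD phantom generator with ground-truth tract masks,
    streamlines and toy connectomes; rotation-based training-pool
    augmentation; the four alpha-WGAN sub-networks (generator/decoder,
    discriminator, encoder, code discriminator) built from declarative layer
    tables with a self-contained 3D convolutional network engine; the hybrid
    adversarial/reconstruction training objective with Wasserstein gradient
    penalties and its per-epoch update schedule; sampling of synthetic FOD
    cohorts from a trained generator; and a quantitative validation suite
    (Sorensen-Dice tract overlap, pairwise squared differences, channel
    histograms, connectome normalization, weighted global efficiency, Mantel
    permutation tests, streamline rasterization and along-tract fibre-density
    profiling).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pracma,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
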