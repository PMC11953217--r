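# Sampling synthetic FOD cohorts from a trained generator.

#' Draw a batch of latent vectors
#'
#' Independent standard-normal entries, deterministic per seed.
#'
#' @param n Number of samples.
#' @param dim Latent dimension.
#' @param seed Integer seed.
#' @return `dim x n` matrix.
#' @export
sample_latent <- function(n, dim, seed = 1) {
  stopifnot(n >= 1, dim >= 1)
  set.seed(as.integer(seed))
  matrix(rnorm(dim * n), dim, n)
}

#' Generate synthetic FOD volumes from a trained generator
#'
#' Latents are drawn from a standard normal, pushed through the generator in
#' evaluation mode (running batch-norm statistics), denormalized back to FOD
#' coefficient units, and optionally written as 4D NIfTI files with a JSON
#' manifest recording the seed and file names.
#'
#' @param state A trained `fod_gan_state` (or a checkpoint directory).
#' @param n Number of volumes to generate.
#' @param seed Integer seed for the latent draws.
#' @param out_dir Optional output directory; when given, files
#'   `fod_synth_0001.nii.gz`, ... and `manifest.json` are written.
#' @param latent_dim Expected latent dimension; generation refuses a
#'   mismatch with the checkpoint.
#' @param batch Generator batch size used while sampling.
#' @return List of [sh_image()]; when `out_dir` is given, file paths are
#'   attached as the `paths` attribute.
#' @export
generate_fods <- function(state, n, seed = 1, out_dir = NULL,
                          latent_dim = NULL, batch = 8) {
  if (is.character(state)) state <- load_checkpoint(state)
  stopifnot(inherits(state, "fod_gan_state"), n >= 1)
  g_latent <- state$config$scale$latent_dim
  if (!is.null(latent_dim) && latent_dim != g_latent)
    stop("requested latent dimension ", latent_dim,
         " does not match the checkpoint's generator latent ", g_latent)
  z <- sample_latent(n, g_latent, seed)
  voxel_size <- c(1.25, 1.61, 2.5) * c(128, 128, 64) / state$config$scale$dims
  imgs <- vector("list", n)
  i <- 1L
  while (i <= n) {
    j <- min(n, i + batch - 1L)
    y <- net_forward(state$G, z[, i:j, drop = FALSE], train = FALSE)$y
    for (k in seq_len(j - i + 1L)) {
      coeffs <- y[, , , , k] * state$constants
      dim(coeffs) <- dim(y)[1:4]
      imgs[[i + k - 1L]] <- sh_image(coeffs, voxel_size)
    }
    i <- j + 1L
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- file.path(out_dir, sprintf("fod_synth_%04d.nii.gz", seq_len(n)))
    for (k in seq_len(n)) write_fod(imgs[[k]], paths[k])
    jsonlite::write_json(
      list(seed = seed, n = n, latent_dim = g_latent,
           files = basename(paths)),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
    attr(imgs, "paths") <- paths
  }
  imgs
}
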