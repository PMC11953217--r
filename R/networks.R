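# Declarative layer tables for the four alpha-WGAN sub-networks, shape
# tracing, and desk-scale reduction of the full-resolution architecture.

layer_spec <- function(kind, in_channels, out_channels,
                       kernel = c(1, 1, 1), stride = c(1, 1, 1),
                       padding = c(0, 0, 0), batch_norm = FALSE,
                       activation = "none", slope = 0,
                       upsample = NULL) {
  kind <- match.arg(kind, c("conv3d", "tconv3d", "linear"))
  if (in_channels < 1 || out_channels < 1) stop("channel counts must be positive")
  if (slope < 0) stop("activation slope must be >= 0")
  activation <- match.arg(activation, c("none", "relu", "leaky_relu", "tanh"))
  rep3 <- function(v) {v <- as.integer(v); if (length(v) == 1) rep(v, 3) else v}
  structure(list(kind = kind, in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 kernel = rep3(kernel), stride = rep3(stride),
                 padding = rep3(padding), batch_norm = batch_norm,
                 activation = activation, slope = slope,
                 upsample = if (is.null(upsample)) NULL else rep3(upsample)),
            class = "layer_spec")
}

net_spec <- function(role, layers, latent_dim, input_kind, input_shape,
                     output_shape) {
  spec <- structure(list(role = role, layers = layers,
                         latent_dim = as.integer(latent_dim),
                         input_kind = input_kind,
                         input_shape = as.integer(input_shape),
                         output_shape = as.integer(output_shape)),
                    class = "net_spec")
  for (i in seq_along(layers)[-1]) {
    if (layers[[i]]$in_channels != layers[[i - 1]]$out_channels)
      stop("layer ", i, " input channels (", layers[[i]]$in_channels,
           ") do not chain with layer ", i - 1, " output (",
           layers[[i - 1]]$out_channels, ")")
  }
  tr <- trace_shapes(spec)   # validates closure on the output contract
  attr(spec, "trace") <- tr
  spec
}

#' @export
print.net_spec <- function(x, ...) {
  cat(sprintf("%s: %d layers, latent %d, input (%s) -> output (%s)\n",
              x$role, length(x$layers), x$latent_dim,
              paste(x$input_shape, collapse = ","),
              paste(x$output_shape, collapse = ",")))
  invisible(x)
}

#' Forward shape trace of a network specification
#'
#' Walks the declarative layer list symbolically (no parameters are
#' allocated) and returns the `(channels, x, y, z)` shape after every layer,
#' verifying that the trace closes on the spec's output contract.
#'
#' @param spec A `net_spec` as returned by [fullscale_generator_spec()] and
#'   friends.
#' @return List of integer shape vectors, one per layer.
#' @export
trace_shapes <- function(spec) {
  shape <- spec$input_shape
  if (spec$input_kind == "latent") shape <- c(spec$latent_dim, 1L, 1L, 1L)
  if (spec$input_kind == "vector") shape <- c(shape, 1L, 1L, 1L)
  out <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    if (shape[1] != l$in_channels)
      stop("layer ", i, ": expected ", l$in_channels, " input channels, got ",
           shape[1])
    sp <- shape[2:4]
    if (!is.null(l$upsample)) sp <- sp * l$upsample
    sp <- switch(l$kind,
      conv3d = {
        o <- (sp + 2 * l$padding - l$kernel) %/% l$stride + 1L
        if (any((sp + 2 * l$padding - l$kernel) %% l$stride != 0))
          warning("layer ", i, ": stride does not tile the input exactly")
        o
      },
      tconv3d = (sp - 1L) * l$stride - 2L * l$padding + l$kernel,
      linear = sp)
    if (any(sp < 1)) stop("layer ", i, ": non-positive spatial size (",
                          paste(sp, collapse = ","), ")")
    shape <- as.integer(c(l$out_channels, sp))
    out[[i]] <- shape
  }
  expect <- spec$output_shape
  if (length(expect) == 1) expect <- c(expect, 1L, 1L, 1L)
  if (!all(shape == expect))
    stop("shape trace (", paste(shape, collapse = ","),
         ") does not close on the output contract (",
         paste(expect, collapse = ","), ")")
  out
}

# spatial reduction factors of the convolutional backbone: the generator
# lifts the latent onto dims / c(32, 32, 16) and upsamples back
.downs_factor <- c(32L, 32L, 16L)

#' Declarative architecture of the generator/decoder
#'
#' Six blocks: a 3D transposed convolution lifting the latent vector onto a
#' coarse grid (batch norm, leaky ReLU slope 0.1), four blocks of nearest-
#' neighbour x2 upsampling followed by a 3x3x3 convolution with batch norm
#' and ReLU, and a final block upsampling by (2, 2, 1) into a 3x3x3
#' convolution with tanh output.  At full scale the channel sequence is
#' 3200, 1600, 800, 400, 200 down to the 28 SH coefficient channels and the
#' output volume is 28 x 128 x 128 x 64.
#'
#' @param dims Output spatial dimensions (divisible by 32, 32, 16).
#' @param latent_dim Latent dimension (5000 at full scale).
#' @param n_coeff Number of SH coefficient output channels.
#' @param channels Internal channel sequence (length 5).
#' @return A `net_spec`.
#' @export
fullscale_generator_spec <- function(dims = c(128, 128, 64), latent_dim = 5000,
                                 n_coeff = 28,
                                 channels = c(3200, 1600, 800, 400, 200)) {
  dims <- check_scale_dims(dims)
  k1 <- as.integer(dims / .downs_factor)
  layers <- list(
    layer_spec("tconv3d", latent_dim, channels[1], kernel = k1, stride = 1,
               padding = 0, batch_norm = TRUE, activation = "leaky_relu",
               slope = 0.1))
  for (i in 1:4)
    layers[[i + 1]] <- layer_spec("conv3d", channels[i], channels[i + 1],
                                  kernel = 3, stride = 1, padding = 1,
                                  batch_norm = TRUE, activation = "relu",
                                  upsample = c(2, 2, 2))
  layers[[6]] <- layer_spec("conv3d", channels[5], n_coeff, kernel = 3,
                            stride = 1, padding = 1, batch_norm = FALSE,
                            activation = "tanh", upsample = c(2, 2, 1))
  net_spec("generator", layers, latent_dim, input_kind = "latent",
           input_shape = latent_dim, output_shape = c(n_coeff, dims))
}

# shared six-layer convolutional backbone of discriminator and encoder
conv_backbone <- function(dims, in_channels, out_final, channels,
                          batch_norm = TRUE) {
  layers <- list(
    layer_spec("conv3d", in_channels, channels[1], kernel = 4, stride = 2,
               padding = 1, batch_norm = FALSE, activation = "leaky_relu",
               slope = 0.2))
  for (i in 1:3)
    layers[[i + 1]] <- layer_spec("conv3d", channels[i], channels[i + 1],
                                  kernel = 4, stride = 2, padding = 1,
                                  batch_norm = batch_norm,
                                  activation = "leaky_relu", slope = 0.05)
  layers[[5]] <- layer_spec("conv3d", channels[4], channels[5],
                            kernel = c(4, 4, 3), stride = c(2, 2, 1),
                            padding = 1, batch_norm = batch_norm,
                            activation = "leaky_relu", slope = 0.05)
  # final kernel collapses whatever spatial extent remains after layer 5
  sp <- dims
  for (l in layers) sp <- (sp + 2L * l$padding - l$kernel) %/% l$stride + 1L
  layers[[6]] <- layer_spec("conv3d", channels[5], out_final, kernel = sp,
                            stride = 1, padding = 0, batch_norm = FALSE,
                            activation = "none")
  layers
}

#' Declarative architecture of the discriminator (critic)
#'
#' Six 3D convolutional layers with leaky-ReLU activations (slope 0.2 in
#' layer 1, 0.05 elsewhere) and batch normalisation in layers 2-5 only; at
#' full scale channels run 28, 125, 250, 500, 1000, 2000 and the final 4^3
#' convolution emits one real number per input volume.
#'
#' @param dims Input spatial dimensions (divisible by 32, 32, 16).
#' @param n_coeff Number of SH input channels.
#' @param channels Internal channel sequence (length 5).
#' @param batch_norm Keep batch normalisation in layers 2-5 (the printed
#'   architecture); set `FALSE` for the batch-norm-free critic preferred by
#'   much of the gradient-penalty literature.
#' @return A `net_spec`.
#' @export
fullscale_discriminator_spec <- function(dims = c(128, 128, 64), n_coeff = 28,
                                     channels = c(125, 250, 500, 1000, 2000),
                                     batch_norm = TRUE) {
  dims <- check_scale_dims(dims)
  net_spec("discriminator",
           conv_backbone(dims, n_coeff, 1L, channels, batch_norm),
           latent_dim = 1L, input_kind = "image",
           input_shape = c(n_coeff, dims), output_shape = 1L)
}

#' Declarative architecture of the encoder
#'
#' Identical to [fullscale_discriminator_spec()] except that the final layer
#' emits `latent_dim` channels (5000 at full scale), projecting an FOD
#' volume deterministically into the latent space.
#'
#' @inheritParams fullscale_discriminator_spec
#' @param latent_dim Latent dimension.
#' @return A `net_spec`.
#' @export
fullscale_encoder_spec <- function(dims = c(128, 128, 64), latent_dim = 5000,
                               n_coeff = 28,
                               channels = c(125, 250, 500, 1000, 2000),
                               batch_norm = TRUE) {
  dims <- check_scale_dims(dims)
  net_spec("encoder",
           conv_backbone(dims, n_coeff, latent_dim, channels, batch_norm),
           latent_dim = latent_dim, input_kind = "image",
           input_shape = c(n_coeff, dims), output_shape = latent_dim)
}

#' Declarative architecture of the code discriminator
#'
#' Three linear layers on latent vectors: `latent -> 4096 -> 4096 -> 1`,
#' with batch normalisation and leaky ReLU (slope 0.2) after layers one and
#' two.
#'
#' @param latent_dim Latent dimension.
#' @param hidden Hidden width (4096 at full scale).
#' @return A `net_spec`.
#' @export
fullscale_code_discriminator_spec <- function(latent_dim = 5000, hidden = 4096) {
  layers <- list(
    layer_spec("linear", latent_dim, hidden, batch_norm = TRUE,
               activation = "leaky_relu", slope = 0.2),
    layer_spec("linear", hidden, hidden, batch_norm = TRUE,
               activation = "leaky_relu", slope = 0.2),
    layer_spec("linear", hidden, 1L))
  net_spec("code_discriminator", layers, latent_dim, input_kind = "vector",
           input_shape = latent_dim, output_shape = 1L)
}

check_scale_dims <- function(dims) {
  dims <- as.integer(dims)
  if (length(dims) != 3 || any(dims < 1)) stop("dims must be 3 positive integers")
  if (any(dims %% .downs_factor != 0))
    stop("spatial dims (", paste(dims, collapse = ","),
         ") must be divisible by (", paste(.downs_factor, collapse = ","),
         "), the product of the network's down/upsampling factors")
  dims
}

#' Desk-scale instantiation parameters
#'
#' @param dims Spatial dimensions, divisible by `(32, 32, 16)`.
#' @param multiplier Channel multiplier in `(0, 1]`; internal channel counts
#'   are scaled and rounded with a floor of 2.
#' @param latent_dim Replacement latent dimension.
#' @return An object of class `model_scale`.
#' @export
model_scale <- function(dims = c(32, 32, 16), multiplier = 1 / 50,
                        latent_dim = 64) {
  dims <- check_scale_dims(dims)
  if (multiplier <= 0 || multiplier > 1)
    stop("multiplier must be in (0, 1]")
  structure(list(dims = dims, multiplier = multiplier,
                 latent_dim = as.integer(latent_dim)),
            class = "model_scale")
}

scale_channels <- function(channels, multiplier) {
  pmax(2L, as.integer(round(channels * multiplier)))
}

#' Scale a full-resolution network spec down to desk scale
#'
#' Internal channel counts are multiplied (floor 2), the latent dimension is
#' replaced, and the spatial contract is rebuilt at the scaled dimensions;
#' the layer topology (kinds, kernels, strides, normalisation, activations)
#' is preserved.  With `multiplier = 1` at full dimensions the spec is
#' returned unchanged.
#'
#' @param spec A `net_spec` from one of the `fullscale_*_spec()` constructors.
#' @param scale A [model_scale()].
#' @return The scaled `net_spec`.
#' @export
scale_spec <- function(spec, scale) {
  stopifnot(inherits(spec, "net_spec"), inherits(scale, "model_scale"))
  ch <- function(idx) vapply(spec$layers[idx], function(l) l$out_channels, 1L)
  switch(spec$role,
    generator = fullscale_generator_spec(
      dims = scale$dims, latent_dim = scale$latent_dim,
      n_coeff = spec$layers[[6]]$out_channels,
      channels = scale_channels(ch(1:5), scale$multiplier)),
    discriminator = fullscale_discriminator_spec(
      dims = scale$dims, n_coeff = spec$layers[[1]]$in_channels,
      channels = scale_channels(ch(1:5), scale$multiplier),
      batch_norm = spec$layers[[2]]$batch_norm),
    encoder = fullscale_encoder_spec(
      dims = scale$dims, latent_dim = scale$latent_dim,
      n_coeff = spec$layers[[1]]$in_channels,
      channels = scale_channels(ch(1:5), scale$multiplier),
      batch_norm = spec$layers[[2]]$batch_norm),
    code_discriminator = fullscale_code_discriminator_spec(
      latent_dim = scale$latent_dim,
      hidden = scale_channels(spec$layers[[1]]$out_channels,
                              scale$multiplier)),
    stop("unknown network role: ", spec$role))
}

#' Parameter count of a network spec (no allocation)
#'
#' @param spec A `net_spec`.
#' @return Total number of trainable parameters (weights, biases, batch-norm
#'   scales and shifts).
#' @export
n_params <- function(spec) {
  stopifnot(inherits(spec, "net_spec"))
  sum(vapply(spec$layers, function(l) {
    w <- if (l$kind == "linear") l$in_channels * l$out_channels
         else prod(c(l$in_channels, l$out_channels, l$kernel))
    w + l$out_channels + if (l$batch_norm) 2 * l$out_channels else 0
  }, numeric(1)))
}
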