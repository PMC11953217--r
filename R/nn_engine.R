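# Self-contained network engine: parameter initialisation, forward pass with
# activation caching, reverse-mode backward pass (parameter and/or input
# gradients), and Adam.  Activation tensors are [C, X, Y, Z, N] arrays;
# linear layers operate on [features, N] matrices.

.bn_eps <- 1e-5
.bn_momentum <- 0.1

#' Build a network from a declarative spec
#'
#' Parameters are initialised with fan-in-scaled normal weights
#' (`sd = sqrt(2 / fan_in)`) and zero biases, reproducibly from the seed.
#'
#' @param spec A `net_spec`.
#' @param seed Integer seed for the initialisation draws.
#' @param precision `"double"` (default) or `"single"`: arithmetic precision
#'   of the convolution kernels.  Parameters and all other layers stay in
#'   double precision; single precision is the conventional training
#'   precision for this model family and roughly halves CPU time.
#' @return An object of class `fod_network`.
#' @export
build_network <- function(spec, seed = 1,
                          precision = c("double", "single")) {
  stopifnot(inherits(spec, "net_spec"))
  precision <- match.arg(precision)
  set.seed(as.integer(seed))
  layers <- lapply(spec$layers, function(l) {
    p <- list(spec = l)
    if (l$kind == "linear") {
      fan_in <- l$in_channels
      p$W <- matrix(rnorm(l$out_channels * l$in_channels,
                          sd = sqrt(2 / fan_in)),
                    l$out_channels, l$in_channels)
    } else if (l$kind == "conv3d") {
      fan_in <- l$in_channels * prod(l$kernel)
      p$W <- array(rnorm(l$out_channels * fan_in, sd = sqrt(2 / fan_in)),
                   dim = c(l$out_channels, l$in_channels, l$kernel))
    } else {  # tconv3d: weight layout [Cin, Cout, k]
      fan_in <- l$in_channels * prod(l$kernel)
      p$W <- array(rnorm(l$out_channels * fan_in, sd = sqrt(2 / fan_in)),
                   dim = c(l$in_channels, l$out_channels, l$kernel))
    }
    p$b <- numeric(l$out_channels)
    if (l$batch_norm) {
      p$gamma <- rep(1, l$out_channels)
      p$beta <- numeric(l$out_channels)
      p$run_mean <- numeric(l$out_channels)
      p$run_var <- rep(1, l$out_channels)
    }
    p
  })
  structure(list(spec = spec, layers = layers, seed = as.integer(seed),
                 precision = precision),
            class = "fod_network")
}

#' @export
print.fod_network <- function(x, ...) {
  cat(sprintf("fod_network (%s): %d layers, %s parameters\n",
              x$spec$role, length(x$layers),
              format(n_params(x$spec), big.mark = ",")))
  invisible(x)
}

# reshape network input to the canonical 5D / matrix form
canon_input <- function(net, x) {
  kind <- net$spec$input_kind
  if (kind == "image") {
    if (length(dim(x)) == 4) dim(x) <- c(dim(x), 1L)
    return(x)
  }
  # latent / vector input: accept a vector or [features, N] matrix
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  array(x, dim = c(nrow(x), 1L, 1L, 1L, ncol(x)))
}

bn_forward <- function(p, x, train) {
  C <- dim(x)[1]
  M <- length(x) / C
  xm <- matrix(x, C, M)
  if (train) {
    mu <- rowMeans(xm)
    v <- rowMeans((xm - mu)^2)
    p$run_mean <- (1 - .bn_momentum) * p$run_mean + .bn_momentum * mu
    p$run_var <- (1 - .bn_momentum) * p$run_var + .bn_momentum * v
  } else {
    mu <- p$run_mean
    v <- p$run_var
  }
  invstd <- 1 / sqrt(v + .bn_eps)
  xhat <- (xm - mu) * invstd
  y <- p$gamma * xhat + p$beta
  dim(y) <- dim(x)
  list(y = y, xhat = xhat, invstd = invstd, p = p)
}

bn_backward <- function(p, cache, dy) {
  C <- length(p$gamma)
  M <- length(dy) / C
  dym <- matrix(dy, C, M)
  dgamma <- rowSums(dym * cache$xhat)
  dbeta <- rowSums(dym)
  dxhat <- dym * p$gamma
  dx <- (p$gamma * cache$invstd / M) *
    (M * dxhat - rowSums(dxhat) - cache$xhat * rowSums(dxhat * cache$xhat))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

.act_code <- c(none = 0L, relu = 1L, leaky_relu = 2L, tanh = 3L)

act_forward <- function(kind, slope, x, single = FALSE) {
  if (kind == "none") return(x)
  cpp_act_fwd(x, .act_code[[kind]], slope, single)
}

act_backward <- function(kind, slope, x_pre, y, dy) {
  if (kind == "none") return(dy)
  # tanh backward uses the output, (leaky) relu the pre-activation sign
  cpp_act_bwd(if (kind == "tanh") y else x_pre, dy, .act_code[[kind]], slope)
}

#' Forward pass through a network
#'
#' @param net A [build_network()] result.
#' @param x Input: `[C, X, Y, Z]` or `[C, X, Y, Z, N]` array for image
#'   networks, a `[features, N]` matrix (or vector) for latent/vector
#'   networks.
#' @param train Use batch statistics in batch-norm layers and update running
#'   statistics (`TRUE`), or use running statistics (`FALSE`).
#' @param keep_cache Keep per-layer activations for a backward pass.
#' @return List with `y` (output: `[C, ...]` array for 4D outputs, a numeric
#'   vector of length N for scalar outputs, or a `[features, N]` matrix),
#'   `cache` (if requested) and `net` (with updated running statistics).
#' @export
net_forward <- function(net, x, train = TRUE, keep_cache = FALSE) {
  x <- canon_input(net, x)
  single <- identical(net$precision, "single")
  caches <- if (keep_cache) vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    p <- net$layers[[i]]
    l <- p$spec
    cache <- list(x_in = if (keep_cache) x)
    if (!is.null(l$upsample) && any(l$upsample != 1)) {
      x <- cpp_upsample_nn_fwd(x, dim(x), l$upsample)
    }
    if (keep_cache) cache$x_conv <- x
    if (l$kind == "linear") {
      C <- dim(x)[1]; N <- dim(x)[5]
      xm <- matrix(x, C, N)
      x <- array(p$W %*% xm + p$b, dim = c(l$out_channels, 1L, 1L, 1L, N))
    } else if (l$kind == "conv3d") {
      Wm <- p$W
      dim(Wm) <- c(l$out_channels, l$in_channels * prod(l$kernel))
      x <- cpp_conv3d_fwd(x, dim(x), Wm, p$b, l$kernel, l$stride, l$padding,
                          single)
    } else {
      x <- cpp_tconv3d_fwd(x, dim(x), p$W, dim(p$W), p$b, l$stride, l$padding)
    }
    if (l$batch_norm) {
      bn <- bn_forward(p, x, train)
      net$layers[[i]] <- bn$p
      if (keep_cache) {
        cache$bn_xhat <- bn$xhat
        cache$bn_invstd <- bn$invstd
      }
      x <- bn$y
    }
    if (keep_cache) cache$pre_act <- x
    x <- act_forward(l$activation, l$slope, x, single)
    if (keep_cache) {
      cache$y <- x
      caches[[i]] <- cache
    }
  }
  y <- x
  d <- dim(y)
  if (all(d[1:4] == 1)) y <- as.numeric(y)            # scalar critic output
  else if (all(d[2:4] == 1)) y <- matrix(y, d[1], d[5])  # vector output
  list(y = y, cache = caches, net = net)
}

#' Backward pass (reverse-mode) through a cached forward pass
#'
#' @param net The network used in the forward pass.
#' @param cache `cache` from [net_forward()] with `keep_cache = TRUE`.
#' @param dy Gradient of the loss with respect to the network output, in the
#'   same shape as the returned `y` (a length-N vector for scalar outputs).
#' @param want_params Compute parameter gradients.
#' @param want_input Compute the gradient with respect to the network input.
#' @return List with `dx` (input gradient, canonical 5D shape or
#'   `[features, N]` matrix for latent inputs) and `grads` (per-layer lists
#'   with `W`, `b` and, for batch-norm layers, `gamma`, `beta`).
#' @export
net_backward <- function(net, cache, dy, want_params = TRUE,
                         want_input = TRUE) {
  n_layers <- length(net$layers)
  single <- identical(net$precision, "single")
  grads <- vector("list", n_layers)
  last_y <- cache[[n_layers]]$y
  dy <- array(dy, dim = dim(last_y))
  for (i in rev(seq_len(n_layers))) {
    p <- net$layers[[i]]
    l <- p$spec
    cc <- cache[[i]]
    dy <- act_backward(l$activation, l$slope, cc$pre_act, cc$y, dy)
    if (l$batch_norm) {
      bn <- bn_backward(p, list(xhat = cc$bn_xhat, invstd = cc$bn_invstd), dy)
      g <- list(gamma = bn$dgamma, beta = bn$dbeta)
      dy <- array(bn$dx, dim = dim(dy))
    } else g <- list()
    need_dx <- want_input || i > 1
    if (l$kind == "linear") {
      C <- dim(cc$x_conv)[1]; N <- dim(cc$x_conv)[5]
      xm <- matrix(cc$x_conv, C, N)
      dym <- matrix(dy, l$out_channels, N)
      if (want_params) {
        g$W <- dym %*% t(xm)
        g$b <- rowSums(dym)
      }
      if (need_dx) dy <- array(t(p$W) %*% dym, dim = dim(cc$x_conv))
    } else if (l$kind == "conv3d") {
      Wm <- p$W
      dim(Wm) <- c(l$out_channels, l$in_channels * prod(l$kernel))
      bw <- cpp_conv3d_bwd(cc$x_conv, dim(cc$x_conv), Wm, dy,
                           l$kernel, l$stride, l$padding,
                           need_dx, want_params, single)
      if (want_params) {
        g$W <- array(bw$dW, dim = dim(p$W))
        g$b <- bw$db
      }
      if (need_dx) dy <- bw$dx
    } else {
      bw <- cpp_tconv3d_bwd(cc$x_conv, dim(cc$x_conv), p$W, dim(p$W), dy,
                            l$stride, l$padding, need_dx, want_params)
      if (want_params) {
        g$W <- bw$dW
        g$b <- bw$db
      }
      if (need_dx) dy <- bw$dx
    }
    if (need_dx && !is.null(l$upsample) && any(l$upsample != 1)) {
      dy <- cpp_upsample_nn_bwd(dy, dim(dy), l$upsample)
    }
    grads[[i]] <- if (want_params) g
  }
  dx <- NULL
  if (want_input) {
    dx <- dy
    if (net$spec$input_kind != "image") dx <- matrix(dx, dim(dx)[1], dim(dx)[5])
  }
  list(dx = dx, grads = grads)
}

# --- Adam ------------------------------------------------------------------

.param_names <- c("W", "b", "gamma", "beta")

adam_init <- function(net) {
  list(t = 0L,
       m = lapply(net$layers, function(p)
         lapply(p[intersect(.param_names, names(p))], function(v) v * 0)),
       v = lapply(net$layers, function(p)
         lapply(p[intersect(.param_names, names(p))], function(v) v * 0)))
}

#' One Adam update of a network from a gradient list
#'
#' Standard Adam with bias correction; the defaults are the framework
#' defaults (`beta1 = 0.9`, `beta2 = 0.999`, `eps = 1e-8`).
#'
#' @param net A `fod_network`.
#' @param grads `grads` from [net_backward()].
#' @param state Optimizer state from a previous call, or `NULL` to start.
#' @param lr Learning rate.
#' @param beta1,beta2,eps Adam moment decay rates and stabiliser.
#' @return List with updated `net` and `state`.
#' @export
adam_step <- function(net, grads, state = NULL, lr = 1e-4,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.null(state)) state <- adam_init(net)
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(net$layers)) {
    gi <- grads[[i]]
    if (is.null(gi)) next
    for (nm in intersect(.param_names, names(gi))) {
      g <- gi[[nm]]
      m <- beta1 * state$m[[i]][[nm]] + (1 - beta1) * g
      v <- beta2 * state$v[[i]][[nm]] + (1 - beta2) * g * g
      state$m[[i]][[nm]] <- m
      state$v[[i]][[nm]] <- v
      net$layers[[i]][[nm]] <- net$layers[[i]][[nm]] -
        lr * (m / bc1) / (sqrt(v / bc2) + eps)
    }
  }
  list(net = net, state = state)
}
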