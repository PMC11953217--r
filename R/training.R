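# The hybrid adversarial/reconstruction objective and its per-epoch update
# schedule.  Loss functions are exposed generically (any critic that can be
# evaluated and differentiated with respect to its input), so they can be
# verified against scalar hand computations; the training loop applies them
# to the built networks.

# --- batch utilities -------------------------------------------------------

flatten_batch <- function(x) {
  if (is.matrix(x)) return(list(mat = x, dims = dim(x)))
  d <- dim(x)
  list(mat = matrix(x, prod(d[-length(d)]), d[length(d)]), dims = d)
}

unflatten_batch <- function(mat, dims) {
  if (length(dims) == 2) return(matrix(mat, dims[1], dims[2]))
  array(mat, dim = dims)
}

batch_size_of <- function(x) {
  d <- dim(x)
  if (is.null(d)) 1L else d[length(d)]
}

slice_sample <- function(x, n) {
  f <- flatten_batch(x)
  v <- f$mat[, n]
  if (length(f$dims) > 2) dim(v) <- f$dims[-length(f$dims)]
  v
}

# per-sample convex combination w * a + (1 - w) * b
mix_batch <- function(a, b, w) {
  cpp_mix_batch(a, b, w)
}

# --- generic critic interface ----------------------------------------------

#' Evaluate a critic on a batch
#'
#' A critic is either a built [build_network()] with scalar output, a plain
#' function mapping one sample to one real number, or a
#' `list(f = function, grad = function)` supplying an analytic input
#' gradient.
#'
#' @param critic The critic.
#' @param x Batch: `[.., N]` array or `[features, N]` matrix.
#' @return Numeric vector of length N.
#' @export
critic_value <- function(critic, x) {
  if (inherits(critic, "fod_network"))
    return(net_forward(critic, x, train = TRUE)$y)
  f <- if (is.function(critic)) critic else critic$f
  vapply(seq_len(batch_size_of(x)), function(n) f(slice_sample(x, n)),
         numeric(1))
}

#' Gradient of a critic with respect to its input batch
#'
#' For networks this is a reverse-mode pass; for function critics the
#' analytic `grad` is used when supplied, otherwise a central finite
#' difference (intended for small test inputs only).
#'
#' @inheritParams critic_value
#' @return Array/matrix of the same shape as `x`.
#' @export
critic_input_grad <- function(critic, x) {
  if (inherits(critic, "fod_network")) {
    fw <- net_forward(critic, x, train = TRUE, keep_cache = TRUE)
    bw <- net_backward(fw$net, fw$cache, rep(1, length(fw$y)),
                       want_params = FALSE, want_input = TRUE)
    g <- bw$dx
    if (is.matrix(x) && !is.matrix(g)) g <- matrix(g, nrow(x), ncol(x))
    if (!is.matrix(x)) dim(g) <- dim(x)
    return(g)
  }
  g_fun <- if (is.list(critic) && !is.null(critic$grad)) critic$grad else NULL
  f <- if (is.function(critic)) critic else critic$f
  fx <- flatten_batch(x)
  out <- fx$mat * 0
  for (n in seq_len(ncol(fx$mat))) {
    s <- slice_sample(x, n)
    if (!is.null(g_fun)) {
      out[, n] <- as.numeric(g_fun(s))
    } else {
      if (length(s) > 10000)
        stop("finite-difference critic gradient is for small test inputs; ",
             "supply an analytic grad or a network")
      h <- 1e-6 * (1 + max(abs(s)))
      for (j in seq_along(s)) {
        sp <- s; sm <- s
        sp[j] <- sp[j] + h; sm[j] <- sm[j] - h
        out[j, n] <- (f(sp) - f(sm)) / (2 * h)
      }
    }
  }
  unflatten_batch(out, fx$dims)
}

# --- loss functions --------------------------------------------------------

check_bundle <- function(bundle, need) {
  miss <- setdiff(need, names(bundle))
  if (length(miss)) stop("bundle is missing: ", paste(miss, collapse = ", "))
  ns <- vapply(bundle[need], batch_size_of, 1L)
  if (length(unique(ns)) != 1) stop("bundle batch sizes disagree")
  invisible(ns[1])
}

#' Generator/encoder loss
#'
#' `L_GE = -<D(x_dec)> - <D(x_syn)> - <CD(z_e)> + lambda <||x_real -
#' x_dec||_L1>`, where angle brackets are batch means and the L1 norm is the
#' sum of absolute coefficient differences over all voxels and channels of
#' one sample.  The `CD(z_r)` term is absent because neither the generator
#' nor the encoder influences it.
#'
#' @param bundle List with `x_real`, `x_dec`, `x_syn`, `z_e` batches.
#' @param D,CD Critics (see [critic_value()]).
#' @param lambda Weight of the reconstruction term (50000 at full scale).
#' @return Scalar loss.
#' @export
loss_ge <- function(bundle, D, CD, lambda) {
  check_bundle(bundle, c("x_real", "x_dec", "x_syn", "z_e"))
  l1 <- colSums(abs(flatten_batch(bundle$x_real)$mat -
                    flatten_batch(bundle$x_dec)$mat))
  -mean(critic_value(D, bundle$x_dec)) -
    mean(critic_value(D, bundle$x_syn)) -
    mean(critic_value(CD, bundle$z_e)) +
    lambda * mean(l1)
}

#' Wasserstein gradient penalty of a critic
#'
#' `<(||grad_xhat critic(xhat)||_2 - 1)^2>` at per-sample convex
#' interpolants `xhat_n = w_n a_n + (1 - w_n) b_n` with `w_n ~ U(0, 1)`.
#'
#' @param critic A critic (see [critic_value()]).
#' @param a,b Batches to interpolate between.
#' @param mix Optional vector of per-sample mixing weights in `[0, 1]`;
#'   drawn uniformly when missing.
#' @return Scalar penalty.
#' @export
gradient_penalty <- function(critic, a, b, mix = NULL) {
  N <- batch_size_of(a)
  if (is.null(mix)) mix <- runif(N)
  if (any(mix < 0 | mix > 1)) stop("mix weights must lie in [0, 1]")
  xhat <- mix_batch(a, b, mix)
  g <- flatten_batch(critic_input_grad(critic, xhat))$mat
  gn <- sqrt(colSums(g^2))
  mean((gn - 1)^2)
}

#' Discriminator gradient penalty (both interpolant families)
#'
#' `phi_D` evaluates the penalty at `xhat = alpha x_train + (1 - alpha)
#' x_syn` and at `xtilde = beta x_train + (1 - beta) x_dec`, with
#' independent per-sample `alpha`, `beta`.
#'
#' @param D The critic.
#' @param x_train,x_syn,x_dec Batches.
#' @param alpha,beta Optional per-sample mixing weights.
#' @return Scalar penalty (sum of the two terms).
#' @export
gradient_penalty_d <- function(D, x_train, x_syn, x_dec,
                               alpha = NULL, beta = NULL) {
  gradient_penalty(D, x_train, x_syn, alpha) +
    gradient_penalty(D, x_train, x_dec, beta)
}

#' Discriminator and code-discriminator losses
#'
#' `L_D = <D(x_dec)> + <D(x_syn)> - 2 <D(x_train)> + kappa phi_D` and
#' `L_CD = <CD(z_e)> - <CD(z_r)> + kappa phi_CD`, with `phi_CD` evaluated at
#' `zhat = gamma z_e + (1 - gamma) z_r`.
#'
#' @param bundle List with `x_train` (alias `x_real`), `x_syn`, `x_dec`
#'   (for `loss_d`) or `z_e`, `z_r` (for `loss_cd`).
#' @param D,CD Critics.
#' @param kappa Gradient-penalty weight (10 at full scale).
#' @param alpha,beta,gamma Optional per-sample interpolation weights.
#' @return Scalar loss.
#' @export
loss_d <- function(bundle, D, kappa, alpha = NULL, beta = NULL) {
  if (is.null(bundle$x_train)) bundle$x_train <- bundle$x_real
  check_bundle(bundle, c("x_train", "x_syn", "x_dec"))
  adv <- mean(critic_value(D, bundle$x_dec)) +
    mean(critic_value(D, bundle$x_syn)) -
    2 * mean(critic_value(D, bundle$x_train))
  pen <- if (kappa != 0)
    gradient_penalty_d(D, bundle$x_train, bundle$x_syn, bundle$x_dec,
                       alpha, beta) else 0
  adv + kappa * pen
}

#' @rdname loss_d
#' @export
loss_cd <- function(bundle, CD, kappa, gamma = NULL) {
  check_bundle(bundle, c("z_e", "z_r"))
  adv <- mean(critic_value(CD, bundle$z_e)) -
    mean(critic_value(CD, bundle$z_r))
  pen <- if (kappa != 0)
    gradient_penalty(CD, bundle$z_e, bundle$z_r, gamma) else 0
  adv + kappa * pen
}

# --- intensity normalization ----------------------------------------------

#' Per-channel intensity normalization into the generator's tanh range
#'
#' The generator ends in a tanh, so training data are mapped affinely into
#' `[-1, 1]` by dividing each SH channel by a per-channel scale (the
#' cohort-wide maximum absolute coefficient).  The mapping is invertible;
#' values outside the calibrated range are clipped with a reported count.
#'
#' @param cohort List of [sh_image()] used to calibrate the scales.
#' @return Numeric vector of strictly positive per-channel scales.
#' @export
fit_normalization <- function(cohort) {
  scales <- Reduce(pmax, lapply(cohort, function(img)
    apply(abs(img$coefficients), 1, max)))
  scales[scales == 0] <- 1
  scales
}

#' @rdname fit_normalization
#' @param img An [sh_image()].
#' @param constants Per-channel scales from `fit_normalization`.
#' @export
normalize_intensity <- function(img, constants) {
  stopifnot(inherits(img, "sh_image"))
  if (any(constants <= 0)) stop("normalization scales must be positive")
  x <- img$coefficients / constants
  n_clip <- sum(x < -1 | x > 1)
  if (n_clip > 0) {
    message(n_clip, " coefficient(s) outside the calibrated range were clipped")
    x <- pmin(pmax(x, -1), 1)
  }
  sh_image(x, img$voxel_size, img$basis)
}

#' @rdname fit_normalization
#' @export
denormalize_intensity <- function(img, constants) {
  stopifnot(inherits(img, "sh_image"))
  sh_image(img$coefficients * constants, img$voxel_size, img$basis)
}

# --- training configuration -------------------------------------------------

#' Training configuration
#'
#' Defaults follow the full-scale recipe: Adam at learning rate 1e-4 for all
#' four networks, batch size 6, reconstruction weight `lambda_l1 = 50000`,
#' gradient-penalty weight `kappa_gp = 10`, and the per-epoch schedule of 1
#' encoder, 2 generator, 4 discriminator and 1 code-discriminator optimiser
#' steps.  An epoch is one schedule iteration on freshly drawn batches.
#'
#' @param epochs Number of epochs.
#' @param scale A [model_scale()] controlling dimensions, channel multiplier
#'   and latent size.
#' @param lr Learning rate.
#' @param batch_size Batch size.
#' @param lambda_l1 Reconstruction weight.  At reduced spatial scale the
#'   voxelwise L1 sum shrinks with the voxel count; `scale_lambda = TRUE`
#'   rescales lambda by the voxel-count ratio so the reconstruction /
#'   adversarial balance matches the full-scale setting.
#' @param kappa_gp Gradient-penalty weight.
#' @param n_coeff Number of SH channels of the data.
#' @param seed Root seed for initialisation and all training randomness.
#' @param scale_lambda Rescale `lambda_l1` by the voxel-count ratio.
#' @param batch_norm_d Keep batch norm in the discriminator/encoder.
#' @param precision Convolution arithmetic: `"single"` (default, the
#'   conventional training precision, about twice as fast on CPU) or
#'   `"double"`.
#' @param eval_every Evaluate held-out reconstruction every this many epochs
#'   (0 = never).
#' @param checkpoint_every Write a checkpoint every this many epochs when a
#'   checkpoint directory is given (0 = only at the end).
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs, scale = model_scale(), lr = 1e-4,
                         batch_size = 6, lambda_l1 = 50000, kappa_gp = 10,
                         n_coeff = 28, seed = 1, scale_lambda = TRUE,
                         batch_norm_d = TRUE, eval_every = 1,
                         checkpoint_every = 0,
                         precision = c("single", "double")) {
  stopifnot(epochs >= 0, lr > 0, batch_size >= 1, lambda_l1 >= 0,
            kappa_gp >= 0)
  precision <- match.arg(precision)
  lambda_eff <- lambda_l1
  if (scale_lambda)
    lambda_eff <- lambda_l1 * prod(scale$dims) / prod(c(128, 128, 64))
  structure(list(epochs = as.integer(epochs), scale = scale, lr = lr,
                 batch_size = as.integer(batch_size),
                 lambda_l1 = lambda_l1, lambda_eff = lambda_eff,
                 kappa_gp = kappa_gp, n_coeff = as.integer(n_coeff),
                 seed = as.integer(seed), batch_norm_d = batch_norm_d,
                 precision = precision,
                 eval_every = as.integer(eval_every),
                 checkpoint_every = as.integer(checkpoint_every),
                 steps_per_epoch = c(E = 1L, G = 2L, D = 4L, CD = 1L)),
            class = "train_config")
}

# --- gradient plumbing ------------------------------------------------------

add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (i in seq_along(b)) {
    if (is.null(b[[i]])) next
    for (nm in names(b[[i]]))
      a[[i]][[nm]] <- if (is.null(a[[i]][[nm]])) b[[i]][[nm]]
                      else a[[i]][[nm]] + b[[i]][[nm]]
  }
  a
}

scale_grads <- function(g, s) {
  lapply(g, function(layer) if (is.null(layer)) NULL
         else lapply(layer, function(v) v * s))
}

# Parameter gradients of the gradient penalty via a central-difference
# directional derivative: for r_n = grad_x sum_m D_m at sample n,
# d/dtheta (||r_n|| - 1)^2 = 2 (||r_n|| - 1) d/dtheta (u_n . r_n) with
# u_n = r_n / ||r_n|| held fixed, and u_n . r_n is the derivative of the
# critic output along u_n, evaluated by a symmetric difference.  Exact for
# piecewise-linear critics; O(eps^2) otherwise.
gp_eval <- function(D, a, b, mix) {
  N <- length(mix)
  xhat <- mix_batch(a, b, mix)
  fw <- net_forward(D, xhat, train = TRUE, keep_cache = TRUE)
  bw <- net_backward(fw$net, fw$cache, rep(1, length(fw$y)),
                     want_params = TRUE, want_input = TRUE)
  gn <- cpp_col_norms(bw$dx, N)
  value <- mean((gn - 1)^2)
  coef <- ifelse(gn > 1e-12, 2 * (gn - 1) / (N * gn), 0)
  V <- cpp_scale_cols(bw$dx, coef)
  vnorm <- sqrt(sum(cpp_col_norms(V, N)^2))
  if (vnorm < 1e-14) return(list(value = value, grads = NULL, net = fw$net))
  eps <- 1e-4 * max(1, sqrt(sum(cpp_col_norms(xhat, N)^2))) / vnorm
  xp <- cpp_axpy(xhat, V, eps)
  dim(xp) <- dim(xhat)
  fp <- net_forward(fw$net, xp, train = TRUE, keep_cache = TRUE)
  gp <- net_backward(fp$net, fp$cache, rep(1, N), want_params = TRUE,
                     want_input = FALSE)$grads
  grads <- add_grads(scale_grads(gp, 1 / eps),
                     scale_grads(bw$grads, -1 / eps))
  list(value = value, grads = grads, net = fp$net)
}

# loss + parameter gradients of L_GE for the current batch.  `need` selects
# the network about to be stepped: the x_syn path carries no encoder
# gradient and the CD(z_e) path no generator gradient, so each variant
# evaluates only the terms whose gradients it uses (the full loss value is
# identical and recomputed from scratch in both).
ge_eval <- function(state, x_train, z_r, need = c("G", "E")) {
  need <- match.arg(need)
  cfg <- state$config
  N <- batch_size_of(x_train)
  fe <- net_forward(state$E, x_train, train = TRUE, keep_cache = need == "E")
  state$E <- fe$net
  z_e <- fe$y
  fd_ <- net_forward(state$G, z_e, train = TRUE, keep_cache = TRUE)
  state$G <- fd_$net
  x_dec <- fd_$y
  fs <- net_forward(state$G, z_r, train = TRUE, keep_cache = need == "G")
  state$G <- fs$net
  x_syn <- fs$y
  dd <- net_forward(state$D, x_dec, train = TRUE, keep_cache = TRUE)
  state$D <- dd$net
  ds <- net_forward(state$D, x_syn, train = TRUE, keep_cache = need == "G")
  state$D <- ds$net
  fc <- net_forward(state$CD, z_e, train = TRUE, keep_cache = need == "E")
  state$CD <- fc$net

  l1 <- cpp_l1_cols(x_train, x_dec, N)
  loss <- -mean(dd$y) - mean(ds$y) - mean(fc$y) + cfg$lambda_eff * mean(l1)

  neg <- rep(-1 / N, N)
  dx_dec <- net_backward(dd$net, dd$cache, neg, want_params = FALSE,
                         want_input = TRUE)$dx
  dx_dec <- cpp_add_sign(dx_dec, x_dec, x_train, cfg$lambda_eff / N)

  if (need == "G") {
    dx_syn <- net_backward(ds$net, ds$cache, neg, want_params = FALSE,
                           want_input = TRUE)$dx
    bd <- net_backward(fd_$net, fd_$cache, dx_dec, want_params = TRUE,
                       want_input = FALSE)
    bs <- net_backward(fs$net, fs$cache, dx_syn, want_params = TRUE,
                       want_input = FALSE)
    return(list(state = state, loss = loss,
                g_G = add_grads(bd$grads, bs$grads), l1 = mean(l1)))
  }
  dz_cd <- net_backward(fc$net, fc$cache, neg, want_params = FALSE,
                        want_input = TRUE)$dx
  bd <- net_backward(fd_$net, fd_$cache, dx_dec, want_params = FALSE,
                     want_input = TRUE)
  dz_e <- bd$dx + dz_cd
  g_E <- net_backward(fe$net, fe$cache, dz_e, want_params = TRUE,
                      want_input = FALSE)$grads
  list(state = state, loss = loss, g_E = g_E, l1 = mean(l1))
}

# loss + parameter gradients of L_D for a fresh batch
d_eval <- function(state, x_train, z_r) {
  cfg <- state$config
  N <- batch_size_of(x_train)
  fe <- net_forward(state$E, x_train, train = TRUE)
  state$E <- fe$net
  fd_ <- net_forward(state$G, fe$y, train = TRUE)
  state$G <- fd_$net
  x_dec <- fd_$y
  fs <- net_forward(state$G, z_r, train = TRUE)
  state$G <- fs$net
  x_syn <- fs$y

  acc <- NULL
  adv <- 0
  for (term in list(list(x = x_dec, w = 1), list(x = x_syn, w = 1),
                    list(x = x_train, w = -2))) {
    fw <- net_forward(state$D, term$x, train = TRUE, keep_cache = TRUE)
    state$D <- fw$net
    adv <- adv + term$w * mean(fw$y)
    bw <- net_backward(fw$net, fw$cache, rep(term$w / N, N),
                       want_params = TRUE, want_input = FALSE)
    acc <- add_grads(acc, bw$grads)
  }
  pen <- 0
  if (cfg$kappa_gp != 0) {
    # both interpolant families (anchored at x_train against x_syn and
    # x_dec) in one batched critic pass
    d5 <- dim(x_train)
    d5[5] <- 2L * N
    both_train <- cpp_cat_batch(x_train, x_train)
    dim(both_train) <- d5
    both_gen <- cpp_cat_batch(x_syn, x_dec)
    dim(both_gen) <- d5
    g <- gp_eval(state$D, both_train, both_gen, runif(2 * N))
    state$D <- g$net
    pen <- 2 * g$value   # gp_eval averages over 2N samples; phi_D sums terms
    if (!is.null(g$grads))
      acc <- add_grads(acc, scale_grads(g$grads, 2 * cfg$kappa_gp))
  }
  list(state = state, loss = adv + cfg$kappa_gp * pen, g_D = acc)
}

# loss + parameter gradients of L_CD for a fresh batch
cd_eval <- function(state, x_train, z_r) {
  cfg <- state$config
  N <- batch_size_of(x_train)
  fe <- net_forward(state$E, x_train, train = TRUE)
  state$E <- fe$net
  z_e <- fe$y
  acc <- NULL
  adv <- 0
  for (term in list(list(z = z_e, w = 1), list(z = z_r, w = -1))) {
    fw <- net_forward(state$CD, term$z, train = TRUE, keep_cache = TRUE)
    state$CD <- fw$net
    adv <- adv + term$w * mean(fw$y)
    bw <- net_backward(fw$net, fw$cache, rep(term$w / N, N),
                       want_params = TRUE, want_input = FALSE)
    acc <- add_grads(acc, bw$grads)
  }
  pen <- 0
  if (cfg$kappa_gp != 0) {
    g <- gp_eval(state$CD, z_e, z_r, runif(N))
    state$CD <- g$net
    pen <- g$value
    if (!is.null(g$grads))
      acc <- add_grads(acc, scale_grads(g$grads, cfg$kappa_gp))
  }
  list(state = state, loss = adv + cfg$kappa_gp * pen, g_CD = acc)
}

draw_batch <- function(state) {
  cfg <- state$config
  n <- dim(state$data)[5]
  idx <- sample.int(n, cfg$batch_size, replace = cfg$batch_size > n)
  x <- state$data[, , , , idx, drop = FALSE]
  z <- matrix(rnorm(cfg$scale$latent_dim * cfg$batch_size),
              cfg$scale$latent_dim, cfg$batch_size)
  list(x = x, z = z)
}

#' One epoch of the update schedule
#'
#' Recomputes `L_GE` and steps the encoder once and the generator twice on
#' the same batch, then performs four discriminator updates on fresh
#' batches, then one code-discriminator update.  All randomness comes from
#' the ambient RNG stream seeded by [train()].
#'
#' @param state Training state from [train()] internals.
#' @return Updated state with loss log and step counters advanced.
#' @export
epoch_step <- function(state) {
  cfg <- state$config
  batch <- draw_batch(state)
  loss_ge_val <- NA_real_
  for (who in c("E", "G", "G")) {
    r <- ge_eval(state, batch$x, batch$z, need = who)
    state <- r$state
    loss_ge_val <- r$loss
    if (!is.finite(r$loss)) return(abort_nonfinite(state, "L_GE", r$loss))
    if (who == "E") {
      st <- adam_step(state$E, r$g_E, state$opt$E, lr = cfg$lr)
      state$E <- st$net; state$opt$E <- st$state
      state$steps["E"] <- state$steps["E"] + 1L
    } else {
      st <- adam_step(state$G, r$g_G, state$opt$G, lr = cfg$lr)
      state$G <- st$net; state$opt$G <- st$state
      state$steps["G"] <- state$steps["G"] + 1L
    }
  }
  loss_d_val <- numeric(4)
  for (k in 1:4) {
    b <- draw_batch(state)
    r <- d_eval(state, b$x, b$z)
    state <- r$state
    loss_d_val[k] <- r$loss
    if (!is.finite(r$loss)) return(abort_nonfinite(state, "L_D", r$loss))
    st <- adam_step(state$D, r$g_D, state$opt$D, lr = cfg$lr)
    state$D <- st$net; state$opt$D <- st$state
    state$steps["D"] <- state$steps["D"] + 1L
  }
  b <- draw_batch(state)
  r <- cd_eval(state, b$x, b$z)
  state <- r$state
  if (!is.finite(r$loss)) return(abort_nonfinite(state, "L_CD", r$loss))
  st <- adam_step(state$CD, r$g_CD, state$opt$CD, lr = cfg$lr)
  state$CD <- st$net; state$opt$CD <- st$state
  state$steps["CD"] <- state$steps["CD"] + 1L

  state$epoch <- state$epoch + 1L
  state$log[[length(state$log) + 1]] <-
    data.frame(epoch = state$epoch, loss_ge = loss_ge_val,
               loss_d = mean(loss_d_val), loss_cd = r$loss,
               val_l1 = NA_real_)
  state
}

abort_nonfinite <- function(state, which, value) {
  if (!is.null(state$checkpoint_dir)) save_checkpoint(state)
  stop("non-finite ", which, " (", value, ") at epoch ", state$epoch + 1L,
       if (!is.null(state$checkpoint_dir))
         paste0("; checkpoint written to ", state$checkpoint_dir))
}

# mean held-out reconstruction L1 (normalized intensity domain).  Batch
# statistics over the held-out cohort are used for normalisation layers —
# at desk scale the running averages lag the rapidly moving batch
# statistics, and batch mode measures the encoder/decoder pair as trained.
# Running statistics are left untouched.
heldout_l1 <- function(state, val_data) {
  z <- net_forward(state$E, val_data, train = TRUE)$y
  dec <- net_forward(state$G, z, train = TRUE)$y
  mean(cpp_l1_cols(val_data, dec, dim(val_data)[5]))
}

cohort_to_array <- function(cohort, constants) {
  arrs <- lapply(cohort, function(img)
    pmin(pmax(img$coefficients / constants, -1), 1))
  d <- dim(arrs[[1]])
  out <- array(0, dim = c(d, length(arrs)))
  for (i in seq_along(arrs)) out[, , , , i] <- arrs[[i]]
  out
}

#' Train the four networks
#'
#' Builds generator, discriminator, encoder and code discriminator at the
#' configured scale, calibrates intensity normalization from the training
#' cohort, and runs the per-epoch update schedule with seeded, resumable
#' randomness.  Losses are logged each epoch; held-out reconstruction L1 is
#' logged at epoch 1 and every `eval_every` epochs when a validation cohort
#' is supplied.
#'
#' @param config A [train_config()].
#' @param cohort Non-empty list of [sh_image()] training volumes.
#' @param val_cohort Optional list of held-out [sh_image()].
#' @param checkpoint_dir Optional directory for checkpoints.
#' @param resume_from Optional checkpoint directory to resume from; training
#'   continues bit-compatibly to `config$epochs`.
#' @param verbose Print a progress line every 10 epochs.
#' @return The trained state (class `fod_gan_state`) containing the four
#'   networks, optimizer states, normalization constants, step counters and
#'   the loss log (as a data frame under `$log_df` via [training_log()]).
#' @export
train <- function(config, cohort, val_cohort = NULL, checkpoint_dir = NULL,
                  resume_from = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "train_config"), length(cohort) >= 1)
  if (!is.null(resume_from)) {
    state <- load_checkpoint(resume_from)
    state$config <- config
    state$checkpoint_dir <- checkpoint_dir
    assign(".Random.seed", state$rng, envir = globalenv())
  } else {
    set.seed(config$seed)
    constants <- fit_normalization(cohort)
    scale <- config$scale
    specs <- list(
      G = scale_spec(fullscale_generator_spec(n_coeff = config$n_coeff), scale),
      D = scale_spec(fullscale_discriminator_spec(n_coeff = config$n_coeff,
                                              batch_norm = config$batch_norm_d),
                     scale),
      E = scale_spec(fullscale_encoder_spec(n_coeff = config$n_coeff,
                                        batch_norm = config$batch_norm_d),
                     scale),
      CD = scale_spec(fullscale_code_discriminator_spec(), scale))
    state <- structure(list(
      config = config, constants = constants,
      data = cohort_to_array(cohort, constants),
      G = build_network(specs$G, config$seed + 1L, config$precision),
      D = build_network(specs$D, config$seed + 2L, config$precision),
      E = build_network(specs$E, config$seed + 3L, config$precision),
      CD = build_network(specs$CD, config$seed + 4L, config$precision),
      opt = list(G = NULL, D = NULL, E = NULL, CD = NULL),
      steps = c(E = 0L, G = 0L, D = 0L, CD = 0L),
      epoch = 0L, log = list(), checkpoint_dir = checkpoint_dir),
      class = "fod_gan_state")
    set.seed(config$seed + 1000L)  # training stream, distinct from init
  }
  val_data <- if (!is.null(val_cohort))
    cohort_to_array(val_cohort, state$constants)
  while (state$epoch < config$epochs) {
    state <- epoch_step(state)
    if (!is.null(val_data) && config$eval_every > 0 &&
        (state$epoch == 1L || state$epoch %% config$eval_every == 0L ||
         state$epoch == config$epochs)) {
      state$log[[length(state$log)]]$val_l1 <- heldout_l1(state, val_data)
    }
    if (verbose && state$epoch %% 10L == 0L) {
      last <- state$log[[length(state$log)]]
      cat(sprintf("epoch %d: L_GE %.4g, L_D %.4g, L_CD %.4g\n",
                  last$epoch, last$loss_ge, last$loss_d, last$loss_cd))
    }
    if (!is.null(checkpoint_dir) && config$checkpoint_every > 0 &&
        state$epoch %% config$checkpoint_every == 0L)
      save_checkpoint(state)
  }
  if (!is.null(checkpoint_dir)) save_checkpoint(state)
  state
}

#' Loss log of a trained state as a data frame
#'
#' @param state A `fod_gan_state`.
#' @return Data frame with one row per epoch: the three losses and, where
#'   evaluated, the held-out reconstruction L1.
#' @export
training_log <- function(state) {
  do.call(rbind, state$log)
}

#' Save / load a training checkpoint
#'
#' The full state (networks, optimizer moments, RNG stream, normalization
#' constants, log) is serialized, alongside a human-readable JSON sidecar
#' with the architecture summary, seed and normalization scales.  Resuming
#' from a checkpoint reproduces the uninterrupted run bit-compatibly.
#'
#' @param state A `fod_gan_state`.
#' @param dir Checkpoint directory (defaults to the one used in training).
#' @return `save_checkpoint` returns `dir` invisibly; `load_checkpoint`
#'   returns the state.
#' @export
save_checkpoint <- function(state, dir = state$checkpoint_dir) {
  if (is.null(dir)) stop("no checkpoint directory given")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  state$rng <- get(".Random.seed", envir = globalenv())
  saveRDS(state, file.path(dir, "state.rds"))
  sidecar <- list(
    epoch = state$epoch, seed = state$config$seed,
    steps = as.list(state$steps),
    latent_dim = state$config$scale$latent_dim,
    dims = state$config$scale$dims,
    n_coeff = state$config$n_coeff,
    lambda_l1 = state$config$lambda_l1,
    lambda_effective = state$config$lambda_eff,
    kappa_gp = state$config$kappa_gp,
    normalization_scales = state$constants)
  jsonlite::write_json(sidecar, file.path(dir, "checkpoint.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(dir) {
  path <- file.path(dir, "state.rds")
  if (!file.exists(path)) stop("no checkpoint found in ", dir)
  readRDS(path)
}
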