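# Scalar critics used to verify each loss term against hand arithmetic.
id_critic <- list(f = function(x) sum(x), grad = function(x) rep(1, length(x)))

test_that("the generator/encoder loss matches hand computation", {
  b <- list(x_real = matrix(0.5, 1, 1), x_dec = matrix(0.3, 1, 1),
            x_syn = matrix(-0.2, 1, 1), z_e = matrix(0.1, 1, 1))
  # -0.3 - (-0.2) - 0.1 + 10 * 0.2
  expect_equal(loss_ge(b, id_critic, id_critic, 10), 1.8)
  # perfect reconstruction with null critics scores zero
  b2 <- list(x_real = matrix(0.5, 1, 1), x_dec = matrix(0.5, 1, 1),
             x_syn = matrix(-0.2, 1, 1), z_e = matrix(0.1, 1, 1))
  zero_critic <- list(f = function(x) 0, grad = function(x) 0 * x)
  expect_equal(loss_ge(b2, zero_critic, zero_critic, 10), 0)
  # with lambda = 0, the reconstruction error no longer enters
  b3 <- b
  b3$x_dec <- matrix(0.9, 1, 1)
  expect_equal(loss_ge(b3, id_critic, id_critic, 0),
               -0.9 - (-0.2) - 0.1)
  # batch mean over several samples
  b4 <- list(x_real = matrix(c(1, 0), 1), x_dec = matrix(c(0, 0), 1),
             x_syn = matrix(c(0, 0), 1), z_e = matrix(c(0, 0), 1))
  expect_equal(loss_ge(b4, zero_critic, zero_critic, 2), 2 * 0.5)
})

test_that("the critic losses match hand computation", {
  b <- list(x_train = matrix(0.5, 1, 1), x_dec = matrix(0.3, 1, 1),
            x_syn = matrix(-0.2, 1, 1))
  expect_equal(loss_d(b, id_critic, kappa = 0), 0.3 - 0.2 - 1.0)
  # constant critic: adversarial part cancels identically
  const_critic <- list(f = function(x) 7, grad = function(x) 0 * x)
  expect_equal(loss_d(b, const_critic, kappa = 0), 0)
  # x_real is accepted as an alias of x_train
  b_alias <- list(x_real = b$x_train, x_dec = b$x_dec, x_syn = b$x_syn)
  expect_equal(loss_d(b_alias, id_critic, kappa = 0), -0.9)
  bc <- list(z_e = matrix(0.1, 1, 1), z_r = matrix(0.4, 1, 1))
  expect_equal(loss_cd(bc, id_critic, kappa = 0), -0.3)
})

test_that("the gradient penalty matches analytic critics", {
  set.seed(1)
  a <- matrix(rnorm(9), 3, 3)
  b <- matrix(rnorm(9), 3, 3)
  w <- c(0.6, 0.8, 0)
  unit_critic <- list(f = function(x) sum(w * x), grad = function(x) w)
  expect_equal(gradient_penalty(unit_critic, a, b), 0)
  twice_critic <- list(f = function(x) 2 * x[1],
                       grad = function(x) c(2, rep(0, length(x) - 1)))
  expect_equal(gradient_penalty_d(twice_critic, a, b, a), 2)
  const_critic <- list(f = function(x) 5, grad = function(x) 0 * x)
  expect_equal(gradient_penalty_d(const_critic, a, b, a), 2)
  # permutation of the batch (with its mixing weights) leaves the value fixed
  mix <- c(0.2, 0.5, 0.9)
  crit <- list(f = function(x) sum(x^2) / 2, grad = function(x) x)
  v1 <- gradient_penalty(crit, a, b, mix)
  perm <- c(3, 1, 2)
  v2 <- gradient_penalty(crit, a[, perm], b[, perm], mix[perm])
  expect_equal(v1, v2)
  # finite-difference fallback for plain function critics
  expect_equal(gradient_penalty(function(x) sum(w * x), a, b), 0,
               tolerance = 1e-6)
})

test_that("intensity normalization is an invertible affine map into [-1, 1]", {
  set.seed(2)
  cohort <- make_cohort(3, tiny_phantom_spec(seed = 4))
  constants <- fit_normalization(cohort)
  expect_true(all(constants > 0))
  img <- cohort[[1]]
  norm <- normalize_intensity(img, constants)
  expect_true(all(abs(norm$coefficients) <= 1))
  back <- denormalize_intensity(norm, constants)
  expect_lt(max(abs(back$coefficients - img$coefficients)), 1e-7)
  zero <- sh_image(array(0, dim(img)), img$voxel_size)
  expect_identical(normalize_intensity(zero, constants)$coefficients,
                   zero$coefficients)
  # out-of-range values are clipped and the count is reported
  hot <- sh_image(img$coefficients * 3, img$voxel_size)
  expect_message(clipped <- normalize_intensity(hot, constants), "clipped")
  expect_true(all(abs(clipped$coefficients) <= 1))
})

test_that("the epoch schedule performs exactly 1 E, 2 G, 4 D, 1 CD steps", {
  cohort <- make_cohort(4, phantom_spec(grid_dims = c(32, 32, 16),
                                        voxel_size = c(5, 5, 10), seed = 11))
  cfg <- train_config(epochs = 2, batch_size = 2, seed = 4, eval_every = 0)
  st <- train(cfg, cohort)
  expect_identical(st$steps, c(E = 2L, G = 4L, D = 8L, CD = 2L))
  expect_identical(st$epoch, 2L)
  log <- training_log(st)
  expect_identical(nrow(log), 2L)
  expect_true(all(is.finite(log$loss_ge)))
  # epochs = 0 leaves the freshly built networks untouched
  cfg0 <- train_config(epochs = 0, batch_size = 2, seed = 4, eval_every = 0)
  st0 <- train(cfg0, cohort)
  ref <- build_network(st0$G$spec, cfg0$seed + 1L, cfg0$precision)
  expect_identical(st0$G$layers, ref$layers)
  expect_identical(st0$steps, c(E = 0L, G = 0L, D = 0L, CD = 0L))
})

test_that("training is deterministic and resumable bit-compatibly", {
  cohort <- make_cohort(4, phantom_spec(grid_dims = c(32, 32, 16),
                                        voxel_size = c(5, 5, 10), seed = 11))
  cfg <- train_config(epochs = 2, batch_size = 2, seed = 9, eval_every = 0)
  st1 <- train(cfg, cohort)
  st2 <- train(cfg, cohort)
  expect_identical(training_log(st1), training_log(st2))
  expect_identical(st1$G$layers, st2$G$layers)
  # interrupt after epoch 1, resume to epoch 2, compare to the straight run
  dir <- withr::local_tempdir()
  cfg1 <- cfg; cfg1$epochs <- 1L
  train(cfg1, cohort, checkpoint_dir = dir)
  st3 <- train(cfg, cohort, resume_from = dir)
  expect_equal(training_log(st3), training_log(st1))
  expect_equal(st3$G$layers, st1$G$layers, tolerance = 1e-15)
  sidecar <- jsonlite::read_json(file.path(dir, "checkpoint.json"))
  expect_identical(sidecar$epoch, 1L)
})

test_that("a high reconstruction weight drives decoded output toward the data", {
  # VAE-limit sanity check: two phantoms, a few epochs, L1 must drop
  cohort <- make_cohort(2, phantom_spec(grid_dims = c(32, 32, 16),
                                        voxel_size = c(5, 5, 10), seed = 21))
  cfg <- train_config(epochs = 12, batch_size = 2, seed = 6, eval_every = 1)
  st <- train(cfg, cohort, val_cohort = cohort)
  log <- training_log(st)
  expect_lt(log$val_l1[nrow(log)], log$val_l1[1])
})
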