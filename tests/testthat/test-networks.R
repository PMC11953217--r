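test_that("full-scale network specs trace to their declared layer-table shapes", {
  G <- fullscale_generator_spec()
  trG <- trace_shapes(G)
  expect_identical(trG[[1]], c(3200L, 4L, 4L, 4L))
  expect_identical(trG[[6]], c(28L, 128L, 128L, 64L))
  expect_identical(G$layers[[1]]$kind, "tconv3d")
  expect_identical(G$layers[[6]]$activation, "tanh")

  D <- fullscale_discriminator_spec()
  trD <- trace_shapes(D)
  spatial <- t(vapply(trD, function(s) s[2:4], integer(3)))
  expect_identical(spatial,
                   rbind(c(64L, 64L, 32L), c(32L, 32L, 16L), c(16L, 16L, 8L),
                         c(8L, 8L, 4L), c(4L, 4L, 4L), c(1L, 1L, 1L)))
  expect_identical(trD[[6]], c(1L, 1L, 1L, 1L))
  expect_false(D$layers[[1]]$batch_norm)
  expect_true(all(vapply(D$layers[2:5], `[[`, TRUE, "batch_norm")))
  expect_false(D$layers[[6]]$batch_norm)

  E <- fullscale_encoder_spec()
  expect_identical(tail(trace_shapes(E), 1)[[1]], c(5000L, 1L, 1L, 1L))

  CD <- fullscale_code_discriminator_spec()
  expect_length(CD$layers, 3)
  expect_identical(tail(trace_shapes(CD), 1)[[1]], c(1L, 1L, 1L, 1L))
})

test_that("encoder and discriminator differ only in their final layer", {
  D <- fullscale_discriminator_spec()
  E <- fullscale_encoder_spec()
  for (i in 1:5) expect_identical(D$layers[[i]], E$layers[[i]])
  expect_identical(D$layers[[6]]$out_channels, 1L)
  expect_identical(E$layers[[6]]$out_channels, 5000L)
  d6 <- D$layers[[6]]; e6 <- E$layers[[6]]
  d6$out_channels <- e6$out_channels
  expect_identical(d6, e6)
})

test_that("scale_spec shrinks channels, swaps the latent, and keeps topology", {
  sc <- model_scale(c(32, 32, 16), 1 / 50, 64)
  g <- scale_spec(fullscale_generator_spec(), sc)
  expect_identical(tail(trace_shapes(g), 1)[[1]], c(28L, 32L, 32L, 16L))
  expect_identical(g$latent_dim, 64L)
  expect_identical(vapply(g$layers, `[[`, 1L, "out_channels"),
                   c(64L, 32L, 16L, 8L, 4L, 28L))
  # identity scaling reproduces the full-scale spec
  id <- scale_spec(fullscale_generator_spec(),
                   model_scale(c(128, 128, 64), 1, 5000))
  expect_identical(id$layers, fullscale_generator_spec()$layers)
  expect_error(model_scale(c(30, 32, 16)), "divisible")
  d <- scale_spec(fullscale_discriminator_spec(), sc)
  expect_identical(tail(trace_shapes(d), 1)[[1]], c(1L, 1L, 1L, 1L))
  cd <- scale_spec(fullscale_code_discriminator_spec(), sc)
  expect_identical(cd$layers[[1]]$in_channels, 64L)
})

test_that("built networks are reproducible and honour the forward contract", {
  sc <- model_scale(c(32, 32, 16), 1 / 50, 64)
  spec <- scale_spec(fullscale_generator_spec(), sc)
  n1 <- build_network(spec, seed = 5)
  n2 <- build_network(spec, seed = 5)
  expect_identical(n1$layers, n2$layers)
  n3 <- build_network(spec, seed = 6)
  expect_false(identical(n1$layers[[1]]$W, n3$layers[[1]]$W))
  z <- matrix(rnorm(64 * 3), 64, 3)
  y <- net_forward(n1, z, train = TRUE)$y
  expect_identical(dim(y), c(28L, 32L, 32L, 16L, 3L))
  expect_true(all(y >= -1 & y <= 1))
  d <- build_network(scale_spec(fullscale_discriminator_spec(), sc), seed = 2)
  fw <- net_forward(d, y, train = TRUE, keep_cache = TRUE)
  expect_length(fw$y, 3)
  bw <- net_backward(fw$net, fw$cache, rep(1, 3), want_params = FALSE,
                     want_input = TRUE)
  expect_true(all(is.finite(bw$dx)))
  expect_gt(sum(abs(bw$dx)), 0)
})

test_that("backpropagation matches numeric differentiation for every layer kind", {
  ls1 <- fodgan:::layer_spec("tconv3d", 5, 4, kernel = c(2, 2, 1), stride = 1,
                             padding = 0, batch_norm = TRUE,
                             activation = "leaky_relu", slope = 0.1)
  ls2 <- fodgan:::layer_spec("conv3d", 4, 3, kernel = 3, stride = 1,
                             padding = 1, batch_norm = TRUE,
                             activation = "relu", upsample = c(2, 2, 2))
  ls3 <- fodgan:::layer_spec("conv3d", 3, 2, kernel = c(2, 2, 2), stride = 2,
                             padding = 0, activation = "tanh")
  spec <- fodgan:::net_spec("generator", list(ls1, ls2, ls3), latent_dim = 5,
                            input_kind = "latent", input_shape = 5,
                            output_shape = c(2, 2, 2, 1))
  net <- build_network(spec, seed = 3)
  set.seed(42)
  x <- matrix(rnorm(5 * 3), 5, 3)
  loss_of <- function(net, x) sum(sin(net_forward(net, x, train = TRUE)$y))
  fw <- net_forward(net, x, train = TRUE, keep_cache = TRUE)
  bw <- net_backward(fw$net, fw$cache, cos(fw$y), want_params = TRUE,
                     want_input = TRUE)
  h <- 1e-6
  for (i in seq_along(net$layers)) {
    for (nm in intersect(c("W", "b", "gamma", "beta"),
                         names(net$layers[[i]]))) {
      p <- net$layers[[i]][[nm]]
      for (j in sample(length(p), min(4, length(p)))) {
        np <- net; np$layers[[i]][[nm]][j] <- p[j] + h
        nm_ <- net; nm_$layers[[i]][[nm]][j] <- p[j] - h
        num <- (loss_of(np, x) - loss_of(nm_, x)) / (2 * h)
        expect_equal(bw$grads[[i]][[nm]][j], num, tolerance = 1e-5,
                     ignore_attr = TRUE)
      }
    }
  }
  for (j in sample(length(x), 5)) {
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    num <- (loss_of(net, xp) - loss_of(net, xm)) / (2 * h)
    expect_equal(bw$dx[j], num, tolerance = 1e-5, ignore_attr = TRUE)
  }
})

test_that("single-precision forward agrees with double precision", {
  sc <- model_scale(c(32, 32, 16), 1 / 50, 64)
  spec <- scale_spec(fullscale_generator_spec(), sc)
  nd <- build_network(spec, seed = 5, precision = "double")
  ns <- build_network(spec, seed = 5, precision = "single")
  z <- matrix(rnorm(64 * 2), 64, 2)
  yd <- net_forward(nd, z, train = TRUE)$y
  ys <- net_forward(ns, z, train = TRUE)$y
  expect_lt(max(abs(yd - ys)), 1e-4)
})

test_that("parameter counts follow the layer tables", {
  CD <- fullscale_code_discriminator_spec()
  expect_identical(n_params(CD),
                   5000 * 4096 + 4096 + 2 * 4096 +
                     4096 * 4096 + 4096 + 2 * 4096 +
                     4096 * 1 + 1)
  tiny <- scale_spec(CD, model_scale(latent_dim = 10))
  net <- build_network(tiny, seed = 1)
  got <- sum(vapply(net$layers, function(p)
    sum(vapply(p[intersect(c("W", "b", "gamma", "beta"), names(p))],
               length, 1L)), numeric(1)))
  expect_identical(got, n_params(tiny))
})
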