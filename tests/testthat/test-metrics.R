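test_that("dice follows the overlap formula and its edge cases", {
  A <- array(FALSE, c(4, 4, 2)); B <- A
  A[1:2, 1, 1] <- TRUE
  expect_equal(dice(A, A), 1)
  B[3:4, 2, 2] <- TRUE
  expect_equal(dice(A, B), 0)
  expect_equal(dice(B, A), dice(A, B))
  C <- array(FALSE, c(4, 4, 2)); C[1, 1, 1] <- TRUE
  D <- array(FALSE, c(4, 4, 2)); D[1:3, 1, 1] <- TRUE
  expect_equal(dice(C, D), 0.5)   # 2 * 1 / (1 + 3)
  expect_error(dice(A, array(FALSE, c(3, 3, 3))), "dimensions")
  expect_error(dice(A & FALSE, B & FALSE), "empty")
})

test_that("pairwise squared differences enumerate unordered pairs", {
  one_voxel <- function(v) sh_image(array(v, c(1, 1, 1, 1)), c(1, 1, 1))
  expect_equal(pairwise_ssd(list(one_voxel(2), one_voxel(2)))$values, 0)
  expect_equal(pairwise_ssd(list(one_voxel(1), one_voxel(3)))$values, 4)
  cohort <- make_cohort(5, tiny_phantom_spec(seed = 2))
  res <- pairwise_ssd(cohort)
  expect_length(res$values, choose(5, 2))
  expect_equal(res$mean, mean(res$values))
  expect_error(pairwise_ssd(list(cohort[[1]], one_voxel(1))), "grids")
})

test_that("channel histograms conserve voxel counts", {
  cohort <- make_cohort(2, tiny_phantom_spec(seed = 3))
  breaks <- seq(-4, 4, by = 0.25)
  h <- channel_histograms(cohort, breaks)
  expect_identical(dim(h), c(6L, length(breaks) - 1L))
  expect_true(all(rowSums(h) == 2 * prod(dim(cohort[[1]])[2:4])))
  const <- sh_image(array(1.3, c(6, 3, 3, 3)), c(1, 1, 1))
  hc <- channel_histograms(list(const), breaks)
  expect_true(all(rowSums(hc > 0) == 1))
  # isotropic channel of a clean phantom is non-negative
  expect_equal(sum(h[1, breaks[-1] <= 0]), 0)
})

test_that("connectome normalization scales the total weight to two", {
  C <- make_toy_connectome(20, seed = 5)
  n1 <- normalize_connectome(C)
  expect_equal(sum(n1$weights), 2, tolerance = 1e-12)
  expect_identical(n1$weights, t(n1$weights))
  n2 <- normalize_connectome(n1)
  expect_equal(n2$weights, n1$weights, tolerance = 1e-12)
  two <- connectome(matrix(c(0, 7, 7, 0), 2))
  expect_equal(normalize_connectome(two)$weights,
               matrix(c(0, 1, 1, 0), 2), ignore_attr = TRUE)
  expect_error(normalize_connectome(connectome(matrix(0, 3, 3))), "weight")
  # normalization preserves efficiency ratios of commonly scaled networks
  Cb <- connectome(C$weights * 3.7)
  expect_equal(global_efficiency(normalize_connectome(C)),
               global_efficiency(normalize_connectome(Cb)),
               tolerance = 1e-12)
})

test_that("weighted global efficiency matches a Floyd-Warshall oracle", {
  W <- matrix(0.7, 3, 3); diag(W) <- 0
  expect_equal(global_efficiency(connectome(W)), 0.7)
  expect_equal(global_efficiency(connectome(matrix(0, 4, 4))), 0)
  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(3:15, 1)
    C <- random_connectome(n, seed)
    expect_equal(global_efficiency(C), fw_global_efficiency(C$weights),
                 tolerance = 1e-12)
  }
})

test_that("the Mantel statistic behaves like a correlation and respects labels", {
  C1 <- make_toy_connectome(15, seed = 2)
  expect_equal(mantel(C1, C1, 99, seed = 1)$r, 1)
  affine <- connectome(C1$weights * 2.5 + (C1$weights > 0) * 0)
  expect_equal(mantel(C1, affine, 99, seed = 1)$r, 1)
  C2 <- make_toy_connectome(15, seed = 8)
  m <- mantel(C1, C2, 499, seed = 3)
  expect_true(m$p >= 1 / 500 && m$p <= 1)
  # identical node permutation of both matrices leaves r unchanged
  perm <- sample(15)
  m2 <- mantel(connectome(C1$weights[perm, perm]),
               connectome(C2$weights[perm, perm]), 499, seed = 3)
  expect_equal(m2$r, m$r, tolerance = 1e-12)
  ms <- mantel(C1, C2, 99, seed = 1, method = "spearman")
  expect_true(abs(ms$r) <= 1)
  expect_error(mantel(connectome(matrix(0, 3, 3)),
                      connectome(matrix(0, 3, 3)), 9), "variance")
  # cross-check the observed statistic against vegan's Mantel r
  v <- vegan::mantel(as.dist(max(C1$weights) - C1$weights),
                     as.dist(max(C2$weights) - C2$weights),
                     permutations = 0)
  expect_equal(mantel(connectome(max(C1$weights) - C1$weights -
                                   diag(max(C1$weights), 15)),
                      connectome(max(C2$weights) - C2$weights -
                                   diag(max(C2$weights), 15)), 9,
                      seed = 1)$r,
               unname(v$statistic), tolerance = 1e-10)
})

test_that("streamline resampling yields equidistant points with fixed ends", {
  straight <- cbind(seq(0, 99, by = 9), 0, 0)
  rs <- resample_streamline(straight, 100)
  expect_identical(nrow(rs), 100L)
  spacing <- sqrt(rowSums(diff(rs)^2))
  expect_equal(spacing, rep(1, 99), tolerance = 1e-10)
  expect_identical(rs[1, ], straight[1, ])
  expect_identical(rs[100, ], straight[nrow(straight), ])
  # an already equidistant 100-point line is a fixed point
  t <- seq(0, 1, length.out = 100)
  curve <- cbind(t * 30, 0, 0)
  expect_lt(max(abs(resample_streamline(curve, 100) - curve)), 1e-10)
  expect_error(resample_streamline(rbind(c(0, 0, 0), c(0, 0, 0))), "length")
})

test_that("apparent fibre density is the spherical FOD integral", {
  iso <- sh_image(array(c(1 / sqrt(4 * pi), rep(0, 27)), c(28, 1, 1, 1)),
                  c(1, 1, 1))
  expect_equal(afd_map(iso)$values[1, 1, 1], 1)
  zero <- sh_image(array(0, c(28, 2, 2, 2)), c(1, 1, 1))
  expect_true(all(afd_map(zero)$values == 0))
  # rotation invariance: AFD depends only on the l = 0 channel
  set.seed(4)
  coeffs <- rnorm(28)
  R <- random_triple_rotation(30)
  expect_equal(rotate_sh(coeffs, R)[1] * sqrt(4 * pi),
               coeffs[1] * sqrt(4 * pi), tolerance = 1e-8)
  # quadrature oracle: integral over the sphere equals sqrt(4 pi) c0
  q <- sphere_quadrature()
  expect_equal(sum(q$weights * evaluate_sh(coeffs, q$dirs)),
               coeffs[1] * sqrt(4 * pi), tolerance = 1e-8)
})

test_that("along-tract profiles sample the map without leakage", {
  const <- scalar_map(array(2.5, c(10, 10, 10)), c(1, 1, 1))
  tract <- streamline_set(list(cbind(seq(1, 9, length.out = 20), 5, 5),
                               cbind(seq(1, 9, length.out = 13), 4.5, 5)))
  pr <- along_tract_profile(const, tract)
  expect_length(pr$mean, 100)
  expect_equal(pr$mean, rep(2.5, 100))
  expect_equal(pr$sd, rep(0, 100))
  single <- along_tract_profile(const, streamline_set(tract$streamlines[1]))
  expect_equal(single$sd, rep(0, 100))
  # linear-gradient map along a straight line gives a linear profile
  grad <- scalar_map(array(rep(1:10, 100), c(10, 10, 10)), c(1, 1, 1))
  line <- streamline_set(list(cbind(seq(0.5, 9.5, length.out = 40), 5, 5)))
  prg <- along_tract_profile(grad, line)
  expected <- seq(1, 10, length.out = 100)
  expect_lt(max(abs(prg$mean - expected)), 1e-8)
})

test_that("rasterization marks every voxel a segment traverses", {
  seg <- streamline_set(list(cbind(c(0.5, 5.5), c(0.5, 0.5), c(0.5, 0.5))))
  m <- streamlines_to_mask(seg, 1, c(8, 2, 2))
  expect_true(sum(m$mask) %in% c(5, 6))
  # supersampling oracle: densely sampled points land only in marked voxels
  set.seed(6)
  pts <- rbind(c(0.3, 0.4, 0.2), c(4.7, 1.6, 1.1), c(2.2, 0.2, 1.9))
  tr <- streamline_set(list(pts))
  m2 <- streamlines_to_mask(tr, 1, c(6, 2, 2))
  for (i in seq_len(nrow(pts) - 1)) {
    tt <- seq(0, 1, length.out = 500)
    dense <- outer(1 - tt, pts[i, ]) + outer(tt, pts[i + 1, ])
    cells <- unique(floor(dense), MARGIN = 1)
    for (r in seq_len(nrow(cells)))
      expect_true(m2$mask[cells[r, 1] + 1, cells[r, 2] + 1, cells[r, 3] + 1])
  }
  # adding streamlines never removes voxels
  tr3 <- streamline_set(c(tr$streamlines, seg$streamlines))
  m3 <- streamlines_to_mask(tr3, 1, c(8, 2, 2))
  expect_gte(sum(m3$mask), sum(m2$mask))
  outside <- streamline_set(list(cbind(c(0, 12), c(0, 0), c(0, 0))))
  expect_error(streamlines_to_mask(outside, 1, c(8, 2, 2)), "extent")
})

test_that("relative differences are symmetric and bounded", {
  expect_equal(relative_diff(1, 1, 2, 2), list(delta_mean = 0, delta_sd = 0))
  expect_equal(relative_diff(3, 1, 1, 1)$delta_mean, 0.5)
  expect_equal(relative_diff(1, 3, 1, 1)$delta_mean, 0.5)
  expect_error(relative_diff(0, 0, 1, 1), "positive")
})

test_that("cohort comparison enumerates pair groups and ranks subjects", {
  g1 <- as.list(1:5)
  g2 <- as.list(6:9)
  cc <- cohort_compare(g1, g2, function(a, b) abs(a - b), "pairwise")
  expect_length(cc$syn_syn, 10)
  expect_length(cc$val_val, 6)
  expect_length(cc$syn_val, 20)
  # identical groups: within- and between-group dice distributions coincide
  masks <- lapply(1:4, function(i) {
    set.seed(i)
    array(runif(64) < 0.5, c(4, 4, 4))
  })
  cd <- cohort_compare(masks, masks, dice, "pairwise")
  expect_true(all(sort(unique(cd$syn_val)) %in%
                    sort(unique(c(cd$syn_syn, 1)))))
  # per-subject mode returns a two-sided rank-sum p
  set.seed(2)
  cs <- cohort_compare(as.list(rnorm(10)), as.list(rnorm(10) + 3),
                       function(a) a, "per_subject")
  expect_lt(cs$p_value, 0.01)
  # null calibration at small scale: same-distribution groups rarely reject
  set.seed(11)
  rej <- mean(replicate(100, {
    cohort_compare(as.list(rnorm(8)), as.list(rnorm(8)),
                   function(a) a, "per_subject")$p_value <= 0.05
  }))
  expect_lte(rej, 0.10)
})
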