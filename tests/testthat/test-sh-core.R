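test_that("basis size follows the even-order closed form and rejects bad input", {
  for (lmax in seq(0, 12, by = 2))
    expect_identical(sh_basis_size(lmax), as.integer((lmax + 1) * (lmax + 2) / 2))
  expect_identical(sh_basis_size(6), 28L)
  expect_error(sh_basis_size(5), "even")
  expect_error(sh_basis_size(-2), "non-negative")
  b <- sh_basis(6)
  expect_equal(nrow(b$ordering), 28)
  expect_true(all(b$ordering[, "l"] %% 2 == 0))
})

test_that("evaluate_sh matches the isotropic closed form and an independent oracle", {
  dirs <- sphere_directions(100)
  iso <- c(1, rep(0, 27))
  expect_equal(evaluate_sh(iso, dirs), rep(1 / sqrt(4 * pi), 100),
               tolerance = 1e-12)
  expect_equal(evaluate_sh(rep(0, 28), dirs), rep(0, 100))
  set.seed(7)
  coeffs <- rnorm(28)
  expect_equal(evaluate_sh(coeffs, dirs),
               oracle_sh_eval(coeffs, dirs, 6), tolerance = 1e-10)
  expect_error(evaluate_sh(coeffs, matrix(c(1, 1, 0), 1)), "unit")
})

test_that("the basis is orthonormal under exact band-limited quadrature", {
  q <- sphere_quadrature()
  B <- sh_design_matrix(q$dirs, sh_basis(6))
  gram <- t(B) %*% (q$weights * B)
  expect_equal(gram, diag(28), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("fit_sh inverts evaluate_sh and respects band limits", {
  basis <- sh_basis(6)
  dirs <- sphere_directions(256)
  set.seed(11)
  coeffs <- rnorm(28)
  fitted <- fit_sh(evaluate_sh(coeffs, dirs), dirs, basis)
  expect_lt(max(abs(fitted - coeffs)), 1e-8)
  # constant amplitudes load only the isotropic channel
  const <- fit_sh(rep(2.5, 256), dirs, basis)
  expect_equal(const[1], 2.5 * sqrt(4 * pi), tolerance = 1e-8)
  expect_lt(max(abs(const[-1])), 1e-8)
  # an order-4 band-limited function has no order-6 content
  c4 <- c(rnorm(sh_basis_size(4)), rep(0, 28 - sh_basis_size(4)))
  refit <- fit_sh(evaluate_sh(c4, dirs), dirs, basis)
  l6 <- basis$ordering[, "l"] == 6
  expect_lt(max(abs(refit[l6])), 1e-8)
  # quadrature cross-check: projection of the order-4 function on order 6 is 0
  q <- sphere_quadrature()
  amps <- evaluate_sh(c4, q$dirs)
  proj <- t(sh_design_matrix(q$dirs, basis)) %*% (q$weights * amps)
  expect_lt(max(abs(proj[l6])), 1e-10)
  expect_error(fit_sh(rep(1, 30), matrix(rep(c(0, 0, 1), 30), ncol = 3,
                                         byrow = TRUE), basis),
               "rank")
})

test_that("SH rotation preserves the isotropic part, band norms, and composes", {
  basis <- sh_basis(6)
  set.seed(5)
  coeffs <- rnorm(28)
  expect_equal(rotate_sh(coeffs, diag(3)), coeffs, tolerance = 1e-8)
  R1 <- rotation_about_axis("z", 37) %*% rotation_about_axis("x", -21)
  R2 <- rotation_about_axis("y", 63)
  rot <- rotate_sh(coeffs, R1)
  expect_equal(rot[1], coeffs[1], tolerance = 1e-8)
  for (l in c(0, 2, 4, 6)) {
    idx <- basis$ordering[, "l"] == l
    expect_equal(sqrt(sum(rot[idx]^2)), sqrt(sum(coeffs[idx]^2)),
                 tolerance = 1e-6)
  }
  # quadrature oracle: the function norm is rotation-invariant
  q <- sphere_quadrature()
  expect_equal(sum(q$weights * evaluate_sh(rot, q$dirs)^2),
               sum(q$weights * evaluate_sh(coeffs, q$dirs)^2),
               tolerance = 1e-8)
  expect_equal(rotate_sh(rot, R2), rotate_sh(coeffs, R2 %*% R1),
               tolerance = 1e-6)
  expect_error(check_rotation(matrix(rnorm(9), 3)), "orthonormal")
})

test_that("crop_volume implements 0-based inclusive slice ranges", {
  img <- sh_image(array(rnorm(145 * 174 * 145), c(1, 145, 174, 145)),
                  c(1.25, 1.25, 1.25))
  cropped <- crop_volume(img, c(10, 137), c(7, 171), c(2, 129))
  expect_identical(dim(cropped)[2:4], c(128L, 165L, 128L))
  expect_identical(cropped$coefficients[1, 1, 1, 1],
                   img$coefficients[1, 11, 8, 3])
  expect_identical(cropped$voxel_size, img$voxel_size)
  full <- crop_volume(img, c(0, 144), c(0, 173), c(0, 144))
  expect_identical(full$coefficients, img$coefficients)
  single <- crop_volume(img, c(3, 3), c(4, 4), c(5, 5))
  expect_identical(dim(single)[2:4], c(1L, 1L, 1L))
  expect_error(crop_volume(img, c(0, 145), c(0, 173), c(0, 144)), "bounds")
})

test_that("regrid preserves physical extent and constant images", {
  img <- sh_image(array(rnorm(145 * 174 * 145), c(1, 145, 174, 145)),
                  c(1.25, 1.25, 1.25))
  cropped <- crop_volume(img, c(10, 137), c(7, 171), c(2, 129))
  out <- regrid(cropped, c(128, 128, 64))
  expect_identical(dim(out)[2:4], c(128L, 128L, 64L))
  expect_equal(out$voxel_size[1], 1.25)
  expect_equal(round(out$voxel_size[2], 2), 1.61)
  expect_equal(out$voxel_size[3], 2.5)
  same <- regrid(cropped, dim(cropped)[2:4])
  expect_equal(same$coefficients, cropped$coefficients, tolerance = 1e-12)
  const <- sh_image(array(3.3, c(6, 5, 6, 7)), c(1, 1, 1))
  expect_lt(max(abs(regrid(const, c(9, 4, 11))$coefficients - 3.3)), 1e-10)
})

test_that("NIfTI round trip is exact and malformed files are diagnosed", {
  set.seed(3)
  img <- sh_image(array(rnorm(28 * 8 * 8 * 4), c(28, 8, 8, 4)),
                  c(1.25, 1.61, 2.5))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_fod(img, path)
  back <- read_fod(path)
  expect_identical(back$coefficients, img$coefficients)
  expect_equal(back$voxel_size, img$voxel_size, tolerance = 1e-6)
  expect_identical(back$basis$lmax, 6L)
  # a 3D file is rejected with a message about the expected layout
  p3 <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(4, 4, 4))), p3)
  expect_error(read_fod(p3), "4D")
  # an invalid channel count names the neighbouring valid basis sizes
  p27 <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(4, 4, 4, 27))), p27)
  expect_error(read_fod(p27), "15.*28")
})
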