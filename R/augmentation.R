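#' Rotation matrix about a principal axis
#'
#' @param axis One of `"x"`, `"y"`, `"z"`.
#' @param angle_deg Rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  a <- angle_deg * pi / 180
  c_ <- cos(a); s_ <- sin(a)
  switch(match.arg(axis, c("x", "y", "z")),
         x = rbind(c(1, 0, 0), c(0, c_, -s_), c(0, s_, c_)),
         y = rbind(c(c_, 0, s_), c(0, 1, 0), c(-s_, 0, c_)),
         z = rbind(c(c_, -s_, 0), c(s_, c_, 0), c(0, 0, 1)))
}

#' Random small rotation about one principal axis
#'
#' Draws an angle from `N(0, sd_deg^2)` (degrees) using the current RNG
#' stream; `sd_deg = 0` returns the identity.
#'
#' @param axis One of `"x"`, `"y"`, `"z"`.
#' @param sd_deg Angle standard deviation in degrees.
#' @return 3x3 rotation matrix.
#' @export
random_axis_rotation <- function(axis, sd_deg) {
  if (sd_deg < 0) stop("sd_deg must be >= 0")
  axis <- match.arg(axis, c("x", "y", "z"))
  if (sd_deg == 0) return(diag(3))
  rotation_about_axis(axis, rnorm(1, 0, sd_deg))
}

#' Random triple rotation
#'
#' Product `Rz %*% Ry %*% Rx` of three independent single-axis rotations with
#' `N(0, sd_deg^2)` angles.
#'
#' @inheritParams random_axis_rotation
#' @return 3x3 rotation matrix.
#' @export
random_triple_rotation <- function(sd_deg) {
  if (sd_deg < 0) stop("sd_deg must be >= 0")
  if (sd_deg == 0) return(diag(3))
  Rx <- random_axis_rotation("x", sd_deg)
  Ry <- random_axis_rotation("y", sd_deg)
  Rz <- random_axis_rotation("z", sd_deg)
  Rz %*% Ry %*% Rx
}

#' Training-pool augmentation policy
#'
#' The default expands each dataset to five instances: the original plus one
#' small random rotation about each principal axis and one triply-rotated
#' variant, with angles drawn from `N(0, 1 degree^2)`.
#'
#' @param sd_deg Angle standard deviation in degrees.
#' @param variants Number of rotated copies per subject (default 4).
#' @param include_triple Whether the last variant is a triple rotation.
#' @param reorient Whether SH coefficients are reoriented (true FOD
#'   rotation) in addition to spatial grid resampling.
#' @param seed Integer seed; cohort augmentation derives child seeds
#'   `seed + subject_index` so results are order-independent per subject.
#' @return An object of class `augmentation_policy`.
#' @export
augmentation_policy <- function(sd_deg = 1, variants = 4,
                                include_triple = TRUE, reorient = TRUE,
                                seed = 1) {
  if (sd_deg < 0) stop("sd_deg must be >= 0")
  if (variants < 0) stop("variants must be >= 0")
  structure(list(sd_deg = sd_deg, variants = as.integer(variants),
                 include_triple = include_triple, reorient = reorient,
                 seed = as.integer(seed)),
            class = "augmentation_policy")
}

#' Rotate an FOD image about its grid centre
#'
#' The spatial grid is resampled trilinearly at rotated coordinates
#' (zero-padded outside the volume) and, when `reorient = TRUE`, the SH
#' coefficients of every voxel are rotated by the same matrix so the encoded
#' fibre orientations follow the anatomy.  The identity rotation returns the
#' image unchanged.
#'
#' @param img An [sh_image()].
#' @param R 3x3 rotation matrix.
#' @param reorient Reorient SH coefficients (default `TRUE`).
#' @return The rotated [sh_image()].
#' @export
rotate_image <- function(img, R, reorient = TRUE) {
  stopifnot(inherits(img, "sh_image"))
  check_rotation(R)
  if (all(R == diag(3))) return(img)
  dims <- grid_dims(img)
  # voxel-index coordinates of the rotation centre (grid centre in mm)
  ctr <- (dims - 1) / 2
  ax <- lapply(1:3, function(a) seq_len(dims[a]) - 1)
  tgt <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  # pull back target voxel centres through the rotation (in mm, then back)
  mm <- sweep(tgt, 2, ctr) %*% diag(img$voxel_size)
  src <- (mm %*% R) %*% diag(1 / img$voxel_size)  # R^T applied to row vectors
  src <- sweep(src, 2, ctr, "+")
  vals <- cpp_trilinear_sample(img$coefficients, dim(img$coefficients), src, 1L)
  if (reorient) vals <- sh_rotation_matrix(img$basis, R) %*% vals
  sh_image(array(vals, dim = dim(img$coefficients)), img$voxel_size,
           img$basis)
}

# the sequence of rotations for one subject under a policy (RNG already set)
policy_rotations <- function(policy) {
  kinds <- character(0)
  if (policy$variants > 0) {
    axes <- c("x", "y", "z")
    n_single <- if (policy$include_triple) policy$variants - 1 else policy$variants
    n_single <- max(0, n_single)
    kinds <- c(rep(axes, length.out = n_single),
               if (policy$include_triple && policy$variants > 0) "triple")
  }
  lapply(kinds, function(k)
    if (k == "triple") random_triple_rotation(policy$sd_deg)
    else random_axis_rotation(k, policy$sd_deg))
}

#' Augment one FOD image
#'
#' Returns the original image followed by `policy$variants` rotated copies
#' (default: one per principal axis plus one triple rotation, i.e. 5 images
#' in total).
#'
#' @param img An [sh_image()].
#' @param policy An [augmentation_policy()].
#' @param seed Seed for this subject's rotation draws (defaults to
#'   `policy$seed`).
#' @return List of [sh_image()] of length `1 + policy$variants`.
#' @export
augment_dataset <- function(img, policy = augmentation_policy(),
                            seed = policy$seed) {
  stopifnot(inherits(img, "sh_image"))
  set.seed(as.integer(seed))
  rots <- policy_rotations(policy)
  c(list(img), lapply(rots, function(R)
    rotate_image(img, R, reorient = policy$reorient)))
}

#' Augment a cohort of FOD images
#'
#' Each subject is augmented with its own child seed (`policy$seed +
#' subject_index`), so the output is `length(cohort) * (1 + variants)` images
#' and per-subject results do not depend on cohort order.
#'
#' @param cohort Non-empty list of [sh_image()].
#' @param policy An [augmentation_policy()].
#' @return Flat list of augmented images, originals first within each
#'   subject.
#' @export
augment_cohort <- function(cohort, policy = augmentation_policy()) {
  if (length(cohort) == 0) stop("cohort must be non-empty")
  out <- lapply(seq_along(cohort), function(i)
    augment_dataset(cohort[[i]], policy, seed = policy$seed + i))
  do.call(c, out)
}
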