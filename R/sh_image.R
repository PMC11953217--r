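#' FOD coefficient volume
#'
#' A 4D array of real even-order spherical-harmonic coefficients on a voxel
#' grid.  Coefficients are stored channel-first, `dim = c(n_coeff, nx, ny,
#' nz)`, with physical voxel sizes in mm.  World coordinates place the corner
#' of voxel `(1,1,1)` at the origin, so the centre of 0-based voxel `i` lies
#' at `(i + 0.5) * voxel_size` mm.
#'
#' @param coefficients 4D numeric array `[n_coeff, nx, ny, nz]` of finite
#'   values.
#' @param voxel_size Length-3 positive numeric, voxel edge lengths in mm.
#' @param basis An [sh_basis()]; defaults to the basis implied by the channel
#'   count.
#' @return An object of class `sh_image`.
#' @export
sh_image <- function(coefficients, voxel_size,
                     basis = basis_for_size(dim(coefficients)[1])) {
  if (!is.array(coefficients) || length(dim(coefficients)) != 4)
    stop("coefficients must be a 4D array [n_coeff, nx, ny, nz]")
  if (dim(coefficients)[1] != basis$size)
    stop("channel count ", dim(coefficients)[1],
         " does not match basis size ", basis$size)
  if (!all(is.finite(coefficients)))
    stop("coefficients contain non-finite values")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3 || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("voxel_size must be 3 strictly positive values (mm)")
  structure(list(coefficients = coefficients, voxel_size = voxel_size,
                 basis = basis),
            class = "sh_image")
}

#' @export
print.sh_image <- function(x, ...) {
  d <- dim(x$coefficients)
  cat(sprintf("FOD image: %d SH coefficients (lmax %d) on %d x %d x %d grid, voxel %s mm\n",
              d[1], x$basis$lmax, d[2], d[3], d[4],
              paste(signif(x$voxel_size, 4), collapse = " x ")))
  invisible(x)
}

#' @export
dim.sh_image <- function(x) dim(x$coefficients)

grid_dims <- function(img) dim(img$coefficients)[2:4]

#' Crop an FOD image by inclusive 0-based slice ranges
#'
#' Slice ranges follow the 0-based inclusive numbering used when trimming
#' empty slices from co-registered cohorts: keeping slices `lo` to `hi`
#' retains `hi - lo + 1` slices.  The default ranges reproduce the standard
#' whole-brain trim of a 145 x 145 x 174 grid (sagittal 10-137, frontal
#' 7-171, axial 2-129), yielding 128 x 165 x 128.
#'
#' @param img An [sh_image()].
#' @param x_range,y_range,z_range Length-2 integer vectors `c(lo, hi)`,
#'   0-based inclusive.
#' @return The cropped [sh_image()]; values are copied unchanged and the
#'   voxel size is preserved.
#' @export
crop_volume <- function(img, x_range, y_range, z_range) {
  stopifnot(inherits(img, "sh_image"))
  dims <- grid_dims(img)
  rng <- list(x_range, y_range, z_range)
  for (a in 1:3) {
    r <- rng[[a]]
    if (length(r) != 2 || any(r != round(r)) || r[1] > r[2])
      stop("range for axis ", a, " must be c(lo, hi) with lo <= hi")
    if (r[1] < 0 || r[2] > dims[a] - 1)
      stop("range ", r[1], "-", r[2], " out of bounds for axis ", a,
           " (0-", dims[a] - 1, ")")
  }
  out <- img$coefficients[, (x_range[1]:x_range[2]) + 1,
                          (y_range[1]:y_range[2]) + 1,
                          (z_range[1]:z_range[2]) + 1, drop = FALSE]
  sh_image(out, img$voxel_size, img$basis)
}

#' Regrid an FOD image to new grid dimensions
#'
#' The physical extent is preserved: the new voxel size along each axis is
#' `old_size * old_dims / target_dims`.  Each coefficient channel is
#' interpolated trilinearly at the new voxel centres (edge-clamped), so
#' constant images stay constant.
#'
#' @param img An [sh_image()].
#' @param target_dims Length-3 positive integers.
#' @return The regridded [sh_image()].
#' @export
regrid <- function(img, target_dims) {
  stopifnot(inherits(img, "sh_image"))
  target_dims <- as.integer(target_dims)
  if (length(target_dims) != 3 || any(target_dims < 1))
    stop("target_dims must be 3 positive integers")
  dims <- grid_dims(img)
  new_vs <- img$voxel_size * dims / target_dims
  if (all(target_dims == dims)) return(sh_image(img$coefficients, new_vs, img$basis))
  # target voxel centre i maps to source coordinate (i + .5) * old/new - .5
  ax <- lapply(1:3, function(a)
    (seq_len(target_dims[a]) - 0.5) * dims[a] / target_dims[a] - 0.5)
  coords <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  vals <- cpp_trilinear_sample(img$coefficients, dim(img$coefficients),
                               coords, 0L)
  out <- array(vals, dim = c(dim(img$coefficients)[1], target_dims))
  sh_image(out, new_vs, img$basis)
}

#' Read / write FOD images as 4D NIfTI
#'
#' Files store the spatial grid in dimensions 1-3 and the coefficient
#' channels in dimension 4; voxel sizes come from the header `pixdim`.  A
#' write-then-read round trip reproduces coefficients bit-exactly.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `read_fod` returns an [sh_image()]; `write_fod` returns `path`
#'   invisibly.
#' @export
read_fod <- function(path) {
  nii <- RNifti::readNifti(path)
  arr <- as.array(nii)
  if (length(dim(arr)) != 4)
    stop("expected a 4D NIfTI (x, y, z, coefficient), got ",
         length(dim(arr)), "D; coefficient channels belong in dimension 4")
  basis <- basis_for_size(dim(arr)[4])
  vs <- RNifti::pixdim(nii)[1:3]
  sh_image(aperm(arr, c(4, 1, 2, 3)), vs, basis)
}

#' @rdname read_fod
#' @param img An [sh_image()] to write.
#' @export
write_fod <- function(img, path) {
  stopifnot(inherits(img, "sh_image"))
  arr <- aperm(img$coefficients, c(2, 3, 4, 1))
  attr(arr, "pixdim") <- c(img$voxel_size, 1)
  nii <- RNifti::asNifti(arr, datatype = "double")
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Scalar 3D map on a voxel grid
#'
#' Container for scalar per-voxel maps (apparent fibre density, masks turned
#' numeric, ...) sharing the world-coordinate convention of [sh_image()].
#'
#' @param values 3D numeric array.
#' @param voxel_size Length-3 positive numeric (mm).
#' @return An object of class `scalar_map`.
#' @export
scalar_map <- function(values, voxel_size) {
  if (!is.array(values) || length(dim(values)) != 3)
    stop("values must be a 3D array")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3 || any(voxel_size <= 0))
    stop("voxel_size must be 3 strictly positive values (mm)")
  structure(list(values = values, voxel_size = voxel_size),
            class = "scalar_map")
}
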