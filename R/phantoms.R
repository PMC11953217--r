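#' Streamline set
#'
#' Ordered 3D point sequences in mm with optional non-negative per-streamline
#' weights, the container for tractography output consumed by the validation
#' metrics (and produced synthetically by [make_phantom()]).
#'
#' @param streamlines List of `n_i x 3` numeric matrices (mm), each with at
#'   least 2 points and no repeated consecutive point.
#' @param weights Optional numeric vector, one non-negative weight per
#'   streamline.
#' @return An object of class `streamline_set`.
#' @export
streamline_set <- function(streamlines, weights = NULL) {
  if (!is.list(streamlines) || length(streamlines) == 0)
    stop("streamlines must be a non-empty list of point matrices")
  for (i in seq_along(streamlines)) {
    s <- streamlines[[i]]
    if (!is.matrix(s) || ncol(s) != 3 || nrow(s) < 2)
      stop("streamline ", i, " must be an n x 3 matrix with n >= 2")
    if (any(rowSums(abs(diff(s))) == 0))
      stop("streamline ", i, " has repeated consecutive points")
  }
  if (!is.null(weights)) {
    if (length(weights) != length(streamlines) || any(weights < 0))
      stop("weights must be one non-negative value per streamline")
  }
  structure(list(streamlines = streamlines, weights = weights),
            class = "streamline_set")
}

#' @export
length.streamline_set <- function(x) length(x$streamlines)

#' Weighted structural connectome
#'
#' Symmetric non-negative node-by-node weight matrix with zero diagonal, as
#' produced by streamline-count mapping onto an atlas parcellation (116
#' regions in the default whole-brain setting).
#'
#' @param weights Square symmetric numeric matrix, non-negative, zero
#'   diagonal.
#' @param labels Optional character node labels.
#' @return An object of class `connectome`.
#' @export
connectome <- function(weights, labels = NULL) {
  if (!is.matrix(weights) || nrow(weights) != ncol(weights))
    stop("weights must be a square matrix")
  if (any(weights != t(weights)))
    stop("weights must be exactly symmetric")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (any(diag(weights) != 0)) stop("diagonal must be zero")
  if (is.null(labels)) labels <- paste0("node", seq_len(nrow(weights)))
  if (length(labels) != nrow(weights))
    stop("need one label per node")
  dimnames(weights) <- list(labels, labels)
  structure(list(weights = weights, labels = labels), class = "connectome")
}

#' Read / write connectomes as CSV
#'
#' Square numeric CSV with a header row of node labels.
#'
#' @param path File path.
#' @return `read_connectome` returns a [connectome()].
#' @export
read_connectome <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  connectome(as.matrix(df), labels = colnames(df))
}

#' @rdname read_connectome
#' @param C A [connectome()].
#' @export
write_connectome <- function(C, path) {
  write.csv(as.data.frame(C$weights, check.names = FALSE), path,
            row.names = FALSE)
  invisible(path)
}

# quadratic Bezier through 3 control points (rows of P, mm); returns points
# and unit tangents at parameters t
bezier_curve <- function(P, t) {
  b <- cbind((1 - t)^2, 2 * t * (1 - t), t^2)
  db <- cbind(-2 * (1 - t), 2 - 4 * t, 2 * t)
  pts <- b %*% P
  tan <- db %*% P
  tan <- tan / sqrt(rowSums(tan^2))
  list(points = pts, tangents = tan)
}

# default bundle archetypes in normalized [0,1]^3 coordinates
default_bundles <- function(n_bundles, radius_mm, amplitude) {
  arch <- list(
    rbind(c(0.18, 0.50, 0.55), c(0.50, 0.50, 0.80), c(0.82, 0.50, 0.55)),
    rbind(c(0.50, 0.18, 0.58), c(0.50, 0.50, 0.72), c(0.50, 0.82, 0.58)),
    rbind(c(0.35, 0.45, 0.18), c(0.38, 0.50, 0.50), c(0.42, 0.55, 0.82)),
    rbind(c(0.65, 0.45, 0.18), c(0.62, 0.50, 0.50), c(0.58, 0.55, 0.82)))
  if (n_bundles > length(arch))
    stop("at most ", length(arch), " default bundles available")
  lapply(seq_len(n_bundles), function(i)
    list(control_points = arch[[i]], radius_mm = radius_mm,
         amplitude = amplitude))
}

#' Synthetic FOD phantom specification
#'
#' Defines a brain-shaped phantom: an ellipsoidal support, a small number of
#' smooth fibre bundles (quadratic Bezier centrelines carrying an axially
#' symmetric single-fibre SH lobe along the local tangent, summed in crossing
#' voxels), an isotropic "ventricle" compartment holding only an `l = 0`
#' component, optional coefficient noise, and inter-subject geometric jitter.
#'
#' @param grid_dims Length-3 integer grid size (each `>= 4`).
#' @param voxel_size Length-3 voxel size in mm.
#' @param lmax Even SH order of the phantom (2 or 6 are the intended desk
#'   scales).
#' @param n_bundles Number of fibre bundles (0-4 with the built-in
#'   archetypes); ignored if `bundles` is given.
#' @param bundles Optional list of bundles, each
#'   `list(control_points = 3 x 3 matrix in normalized [0,1] coordinates,
#'   radius_mm, amplitude)`.
#' @param bundle_radius_mm,bundle_amplitude Radius and peak FOD amplitude of
#'   the default bundles; the radius defaults to 18% of the smallest grid
#'   extent so the archetype geometries fit any grid size.
#' @param ventricle `list(center, radii, amplitude)`, centre and semi-axes in
#'   normalized coordinates, isotropic amplitude per steradian; `NULL`
#'   disables it.
#' @param noise_sd Gaussian sd added to every coefficient inside the brain
#'   mask (0 = clean geometry).
#' @param jitter_sd Inter-subject geometric jitter sd in mm, applied by
#'   [make_cohort()] to bundle control points and the ventricle centre.
#' @param seed Integer seed; all phantom randomness derives from it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_dims = c(16, 16, 8), voxel_size = c(2, 2, 2),
                         lmax = 6, n_bundles = 2, bundles = NULL,
                         bundle_radius_mm = NULL, bundle_amplitude = 1,
                         ventricle = list(center = c(0.5, 0.5, 0.42),
                                          radii = c(0.14, 0.2, 0.16),
                                          amplitude = 0.8),
                         noise_sd = 0, jitter_sd = 0.5, seed = 1) {
  grid_dims <- as.integer(grid_dims)
  if (length(grid_dims) != 3 || any(grid_dims < 4))
    stop("grid_dims must be 3 integers >= 4")
  if (any(voxel_size <= 0)) stop("voxel_size must be positive")
  if (noise_sd < 0 || jitter_sd < 0) stop("noise/jitter sd must be >= 0")
  if (is.null(bundle_radius_mm))
    bundle_radius_mm <- 0.18 * min(grid_dims * voxel_size)
  if (is.null(bundles))
    bundles <- default_bundles(n_bundles, bundle_radius_mm, bundle_amplitude)
  for (b in bundles)
    if (b$radius_mm <= 0) stop("bundle radius must be positive")
  structure(list(grid_dims = grid_dims, voxel_size = as.numeric(voxel_size),
                 lmax = lmax, bundles = bundles, ventricle = ventricle,
                 noise_sd = noise_sd, jitter_sd = jitter_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# voxel centres in mm for a grid
voxel_centers <- function(grid_dims, voxel_size) {
  ax <- lapply(1:3, function(a) ((seq_len(grid_dims[a]) - 1) + 0.5) * voxel_size[a])
  as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
}

#' Generate one synthetic FOD phantom
#'
#' Deterministic given the spec (and its seed).  Background voxels are
#' exactly zero; bundle voxels carry a single-fibre lobe `(d . t)^lmax`
#' aligned with the local tangent `t` (exactly band-limited, hence
#' non-negative up to fit round-off); ventricle voxels carry only the
#' isotropic coefficient.  Ground-truth bundle masks and per-bundle
#' streamline sets are geometrically consistent with the encoded
#' orientations.
#'
#' @param spec A [phantom_spec()].
#' @param streamlines_per_bundle Number of streamlines generated along each
#'   bundle (centreline plus parallel offsets).
#' @return A list with elements `image` ([sh_image()]), `brain_mask`
#'   (3D logical), `bundle_masks` (list of 3D logical), `streamlines` (list
#'   of [streamline_set()]), `ventricle_mask`, and `spec`.
#' @export
make_phantom <- function(spec, streamlines_per_bundle = 5) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  basis <- sh_basis(spec$lmax)
  dims <- spec$grid_dims
  extent <- dims * spec$voxel_size
  centers <- voxel_centers(dims, spec$voxel_size)
  n_vox <- nrow(centers)

  ell <- sweep(sweep(centers, 2, extent / 2), 2, 0.48 * extent, "/")
  brain <- rowSums(ell^2) <= 1

  op <- sh_fit_operator(basis)
  coeffs <- matrix(0, basis$size, n_vox)
  bundle_masks <- vector("list", length(spec$bundles))
  streams <- vector("list", length(spec$bundles))
  for (bi in seq_along(spec$bundles)) {
    b <- spec$bundles[[bi]]
    P <- b$control_points %*% diag(extent)
    tt <- seq(0, 1, length.out = 4 * max(dims))
    curve <- bezier_curve(P, tt)
    if (any(curve$points < b$radius_mm) ||
        any(sweep(curve$points, 2, extent - b$radius_mm) > 0))
      stop("bundle ", bi, " does not fit inside the grid at radius ",
           b$radius_mm, " mm")
    # nearest curve sample per voxel
    d2 <- vapply(seq_len(nrow(curve$points)), function(k)
      (centers[, 1] - curve$points[k, 1])^2 +
      (centers[, 2] - curve$points[k, 2])^2 +
      (centers[, 3] - curve$points[k, 3])^2, numeric(n_vox))
    nearest <- max.col(-d2, ties.method = "first")
    inside <- d2[cbind(seq_len(n_vox), nearest)] <= b$radius_mm^2
    bundle_masks[[bi]] <- array(inside, dim = dims)
    brain <- brain | inside
    for (v in which(inside)) {
      tang <- curve$tangents[nearest[v], ]
      amp <- drop(op$dirs %*% tang)^spec$lmax   # exactly band-limited lobe
      coeffs[, v] <- coeffs[, v] + b$amplitude * drop(op$pinv %*% amp)
    }
    streams[[bi]] <- bundle_streamlines(curve, b$radius_mm,
                                        streamlines_per_bundle)
  }

  if (spec$noise_sd > 0) {
    nb <- sum(brain)
    coeffs[, brain] <- coeffs[, brain] +
      matrix(rnorm(basis$size * nb, sd = spec$noise_sd), basis$size, nb)
  }

  vent_mask <- array(FALSE, dim = dims)
  if (!is.null(spec$ventricle)) {
    v <- spec$ventricle
    q <- sweep(sweep(centers, 2, v$center * extent), 2, v$radii * extent, "/")
    vent <- rowSums(q^2) <= 1
    vent_mask <- array(vent, dim = dims)
    coeffs[, vent] <- 0
    coeffs[1, vent] <- v$amplitude * sqrt(4 * pi)  # amplitude per steradian
    brain <- brain | vent
  }
  coeffs[, !brain] <- 0

  img <- sh_image(array(coeffs, dim = c(basis$size, dims)), spec$voxel_size,
                  basis)
  list(image = img, brain_mask = array(brain, dim = dims),
       bundle_masks = bundle_masks, streamlines = streams,
       ventricle_mask = vent_mask, spec = spec)
}

# centreline plus parallel offset polylines within the bundle radius
bundle_streamlines <- function(curve, radius_mm, n_streamlines) {
  n_pts <- nrow(curve$points)
  keep <- unique(round(seq(1, n_pts, length.out = max(16, n_pts %/% 4))))
  out <- list(curve$points[keep, , drop = FALSE])
  if (n_streamlines > 1) {
    t0 <- curve$tangents[1, ]
    ref <- if (abs(t0[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    n1 <- ref - sum(ref * t0) * t0
    n1 <- n1 / sqrt(sum(n1^2))
    n2 <- c(t0[2] * n1[3] - t0[3] * n1[2],
            t0[3] * n1[1] - t0[1] * n1[3],
            t0[1] * n1[2] - t0[2] * n1[1])
    ang <- 2 * pi * seq_len(n_streamlines - 1) / (n_streamlines - 1)
    for (a in ang) {
      off <- 0.5 * radius_mm * (cos(a) * n1 + sin(a) * n2)
      out[[length(out) + 1]] <- sweep(curve$points[keep, , drop = FALSE],
                                      2, off, "+")
    }
  }
  streamline_set(out)
}

#' Generate a cohort of jittered phantoms
#'
#' Each subject `i` uses the child seed `seed + i`, perturbing bundle control
#' points and the ventricle centre by `N(0, jitter_sd^2)` mm (clamped so
#' bundles stay inside the grid) before generating the phantom, so subjects
#' are reproducible individually and the cohort carries genuine geometric
#' variability.
#'
#' @param n Number of subjects.
#' @param spec A [phantom_spec()].
#' @param seed Root seed (defaults to `spec$seed`).
#' @return List of `n` [sh_image()] objects.
#' @export
make_cohort <- function(n, spec, seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"), n >= 1)
  lapply(seq_len(n), function(i) {
    make_phantom(jitter_spec(spec, seed + i))$image
  })
}

# child-seeded geometric perturbation of a phantom spec
jitter_spec <- function(spec, child_seed) {
  s <- spec
  s$seed <- as.integer(child_seed)
  if (spec$jitter_sd > 0) {
    set.seed(as.integer(child_seed))
    extent <- spec$grid_dims * spec$voxel_size
    for (bi in seq_along(s$bundles)) {
      b <- s$bundles[[bi]]
      cp_mm <- b$control_points %*% diag(extent) +
        matrix(rnorm(9, sd = spec$jitter_sd), 3, 3)
      margin <- (b$radius_mm + 1e-6) / extent
      cp <- cp_mm %*% diag(1 / extent)
      cp <- pmin(pmax(cp, rep(margin, each = 3)),
                 rep(1 - margin, each = 3))
      s$bundles[[bi]]$control_points <- cp
    }
    if (!is.null(s$ventricle))
      s$ventricle$center <- s$ventricle$center +
        rnorm(3, sd = spec$jitter_sd) / extent
  }
  s
}

#' Block-structured toy connectome
#'
#' Emulates the visual structure of whole-brain structural connectomes:
#' dense diagonal blocks separated by sparser off-block connections.  Nodes
#' are split into `n_blocks` contiguous communities; an edge between two
#' nodes exists with probability `1.5 * density` within a block (capped at 1)
#' and `0.5 * density` across blocks, with uniform weights of mean 1.0
#' (in-block) and 0.4 (off-block).
#'
#' @param n_nodes Number of nodes (`>= 2`).
#' @param n_blocks Number of communities.
#' @param density Baseline edge density in `[0, 1]`; 0 gives the zero matrix.
#' @param seed Integer seed.
#' @return A [connectome()].
#' @export
make_toy_connectome <- function(n_nodes, n_blocks = 4, density = 0.3,
                                seed = 1) {
  if (n_nodes < 2) stop("n_nodes must be >= 2")
  set.seed(as.integer(seed))
  block <- cut(seq_len(n_nodes), n_blocks, labels = FALSE)
  W <- matrix(0, n_nodes, n_nodes)
  ut <- which(upper.tri(W), arr.ind = TRUE)
  same <- block[ut[, 1]] == block[ut[, 2]]
  p <- ifelse(same, pmin(1, 1.5 * density), 0.5 * density)
  present <- runif(nrow(ut)) < p
  w <- ifelse(same, runif(nrow(ut), 0.5, 1.5), runif(nrow(ut), 0.1, 0.7))
  vals <- ifelse(present, w, 0)
  W[ut] <- vals
  W <- W + t(W)
  connectome(W, labels = paste0("R", seq_len(n_nodes)))
}
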