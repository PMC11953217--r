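# Quantitative validation suite: tract-overlap dice, pairwise squared
# differences, channel histograms, connectome normalization, weighted global
# efficiency, Mantel permutation tests, streamline resampling/rasterization,
# apparent fibre density and along-tract profiling.

#' Sorensen-Dice overlap of two binary masks
#'
#' `S(A, B) = 2 sum(A * B) / (sum(A) + sum(B))` over all voxels.
#'
#' @param A,B 3D logical (or 0/1) arrays of identical dimensions.
#' @return Dice score in `[0, 1]`.
#' @export
dice <- function(A, B) {
  if (!all(dim(A) == dim(B)))
    stop("mask dimensions disagree: ", paste(dim(A), collapse = "x"),
         " vs ", paste(dim(B), collapse = "x"))
  a <- as.logical(A); b <- as.logical(B)
  denom <- sum(a) + sum(b)
  if (denom == 0) stop("both masks are empty; dice is undefined")
  2 * sum(a & b) / denom
}

#' Pairwise sums of voxelwise squared differences across a cohort
#'
#' For every unordered pair of images, the sum over all voxels and channels
#' of the squared coefficient difference; the distribution of these values
#' quantifies cohort variation.
#'
#' @param cohort List of [sh_image()] on identical grids.
#' @return List with `values` (length `choose(n, 2)`), `pairs` (2-column
#'   index matrix), `mean` and `sd`.
#' @export
pairwise_ssd <- function(cohort) {
  n <- length(cohort)
  if (n < 2) stop("need at least two images")
  d1 <- dim(cohort[[1]]$coefficients)
  for (img in cohort)
    if (!all(dim(img$coefficients) == d1)) stop("image grids disagree")
  pairs <- t(utils::combn(n, 2))
  values <- apply(pairs, 1, function(p)
    sum((cohort[[p[1]]]$coefficients - cohort[[p[2]]]$coefficients)^2))
  list(values = values, pairs = pairs, mean = mean(values),
       sd = if (length(values) > 1) sd(values) else 0)
}

#' Per-channel histograms of FOD coefficient values across a cohort
#'
#' Values outside the bin range are counted in the outermost bins, so the
#' per-channel counts always sum to the total voxel number.
#'
#' @param cohort List of [sh_image()] sharing one basis.
#' @param breaks Increasing vector of bin edges.
#' @return Matrix `[n_channels, n_bins]` of counts.
#' @export
channel_histograms <- function(cohort, breaks) {
  if (length(breaks) < 2 || is.unsorted(breaks, strictly = TRUE))
    stop("breaks must be strictly increasing with at least two edges")
  n_ch <- dim(cohort[[1]]$coefficients)[1]
  n_bins <- length(breaks) - 1
  counts <- matrix(0, n_ch, n_bins)
  for (img in cohort) {
    if (dim(img$coefficients)[1] != n_ch) stop("channel counts disagree")
    m <- matrix(img$coefficients, n_ch)
    for (ch in seq_len(n_ch)) {
      v <- pmin(pmax(m[ch, ], breaks[1]), breaks[length(breaks)])
      idx <- findInterval(v, breaks, rightmost.closed = TRUE,
                          all.inside = TRUE)
      counts[ch, ] <- counts[ch, ] + tabulate(idx, nbins = n_bins)
    }
  }
  counts
}

#' Normalize a connectome to total weight two
#'
#' Scales the matrix so that the sum of all entries is exactly two — i.e.
#' the sum of unique connections is one, each connection appearing twice in
#' the symmetric matrix.  This removes global streamline-weighting bias
#' before network measures are compared.
#'
#' @param C A [connectome()].
#' @return The normalized [connectome()].
#' @export
normalize_connectome <- function(C) {
  stopifnot(inherits(C, "connectome"))
  total <- sum(C$weights)
  if (total <= 0) stop("connectome has no weight; cannot normalize")
  connectome(C$weights * (2 / total), C$labels)
}

#' Weighted global efficiency
#'
#' Edges carry connection lengths `1 / weight` (zero weight = no edge);
#' efficiency is the mean over ordered node pairs `i != j` of the inverse
#' weighted shortest-path length, with disconnected pairs contributing 0.
#' Shortest paths are computed with Dijkstra's algorithm (via igraph).
#'
#' @param C A [connectome()].
#' @return Non-negative scalar.
#' @export
global_efficiency <- function(C) {
  stopifnot(inherits(C, "connectome"))
  W <- C$weights
  n <- nrow(W)
  if (n < 2) stop("need at least two nodes")
  L <- W
  L[W > 0] <- 1 / W[W > 0]
  L[W == 0] <- 0   # igraph treats 0 as no edge
  g <- igraph::graph_from_adjacency_matrix(L, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  d <- igraph::distances(g, algorithm = "dijkstra")
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Mantel permutation test between two connectomes
#'
#' Correlates the upper-triangle off-diagonal entries of the two matrices
#' and assesses significance by permuting the node labels of the second
#' matrix; the one-sided p-value uses the add-one estimator
#' `(count(r_perm >= r_obs) + 1) / (n_permutations + 1)`.
#'
#' @param C1,C2 [connectome()] objects of equal size (`>= 3` nodes).
#' @param n_permutations Number of label permutations.
#' @param seed Integer seed for the permutation draws.
#' @param method Correlation type, `"pearson"` (default) or `"spearman"`.
#' @return List with `r` (observed correlation) and `p`.
#' @export
mantel <- function(C1, C2, n_permutations = 9999, seed = 1,
                   method = c("pearson", "spearman")) {
  stopifnot(inherits(C1, "connectome"), inherits(C2, "connectome"))
  method <- match.arg(method)
  n <- nrow(C1$weights)
  if (n != nrow(C2$weights)) stop("connectome sizes disagree")
  if (n < 3) stop("need at least 3 nodes")
  ut <- upper.tri(C1$weights)
  v1 <- C1$weights[ut]
  if (sd(v1) == 0 || sd(C2$weights[ut]) == 0)
    stop("zero variance in upper triangle; correlation undefined")
  r_obs <- cor(v1, C2$weights[ut], method = method)
  set.seed(as.integer(seed))
  count <- 0L
  for (k in seq_len(n_permutations)) {
    p <- sample.int(n)
    r_perm <- cor(v1, C2$weights[p, p][ut], method = method)
    if (r_perm >= r_obs) count <- count + 1L
  }
  list(r = r_obs, p = (count + 1) / (n_permutations + 1))
}

#' Resample a streamline to equidistant points
#'
#' Re-parameterizes the polyline by arc length into `n_points` points with
#' equal spacing; the endpoints are preserved exactly.
#'
#' @param polyline `n x 3` matrix of points in mm (`n >= 2`, positive
#'   length).
#' @param n_points Number of output points (default 100).
#' @return `n_points x 3` matrix.
#' @export
resample_streamline <- function(polyline, n_points = 100) {
  if (!is.matrix(polyline) || ncol(polyline) != 3 || nrow(polyline) < 2)
    stop("polyline must be an n x 3 matrix with n >= 2")
  seg <- sqrt(rowSums(diff(polyline)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) stop("polyline has zero length")
  target <- seq(0, total, length.out = n_points)
  out <- matrix(0, n_points, 3)
  out[1, ] <- polyline[1, ]
  out[n_points, ] <- polyline[nrow(polyline), ]
  for (i in seq(2, n_points - 1)) {
    j <- findInterval(target[i], s, all.inside = TRUE)
    w <- (target[i] - s[j]) / (s[j + 1] - s[j])
    out[i, ] <- (1 - w) * polyline[j, ] + w * polyline[j + 1, ]
  }
  out
}

#' Apparent fibre density map
#'
#' The integral of the FOD over the sphere, which in an orthonormal SH basis
#' is `sqrt(4 pi)` times the isotropic (`l = 0`) coefficient.  This is the
#' simplified whole-FOD form: fixel-wise AFD would require FOD lobe
#' segmentation, and the along-tract machinery accepts any externally
#' supplied scalar map in its place.
#'
#' @param img An [sh_image()].
#' @return A [scalar_map()].
#' @export
afd_map <- function(img) {
  stopifnot(inherits(img, "sh_image"))
  vals <- img$coefficients[1, , , ] * sqrt(4 * pi)
  dim(vals) <- dim(img$coefficients)[2:4]
  scalar_map(vals, img$voxel_size)
}

#' Along-tract profile of a scalar map
#'
#' Every streamline is resampled to `n_points` equidistant points; the map
#' is sampled by trilinear interpolation at each point, and the profile
#' reports the mean and standard deviation across streamlines at each
#' increment.
#'
#' @param map A [scalar_map()].
#' @param tract A [streamline_set()] lying within the map extent.
#' @param n_points Number of arc-length increments (default 100).
#' @return List of class `tract_profile` with `mean` and `sd` vectors of
#'   length `n_points`.
#' @export
along_tract_profile <- function(map, tract, n_points = 100) {
  stopifnot(inherits(map, "scalar_map"), inherits(tract, "streamline_set"))
  if (length(tract) == 0) stop("empty tract")
  vol <- array(map$values, dim = c(1, dim(map$values)))
  samples <- vapply(tract$streamlines, function(s) {
    pts <- resample_streamline(s, n_points)
    coords <- sweep(pts %*% diag(1 / map$voxel_size), 2, 0.5)
    as.numeric(cpp_trilinear_sample(vol, dim(vol), coords, 0L))
  }, numeric(n_points))
  samples <- matrix(samples, n_points, length(tract))
  structure(list(mean = rowMeans(samples),
                 sd = apply(samples, 1, function(v)
                   if (length(v) > 1) sd(v) else 0)),
            class = "tract_profile")
}

#' Relative differences of fibre-density summaries
#'
#' `delta = |a_syn - a_val| / (a_syn + a_val)` for the mean and the standard
#' deviation of regional fibre densities; symmetric in its arguments and in
#' `[0, 1)` for positive inputs.
#'
#' @param mean_syn,mean_val,sd_syn,sd_val Positive-denominator summaries of
#'   the synthetic and validation groups.
#' @return List with `delta_mean` and `delta_sd`.
#' @export
relative_diff <- function(mean_syn, mean_val, sd_syn, sd_val) {
  if (any(mean_syn + mean_val <= 0) || any(sd_syn + sd_val <= 0))
    stop("denominators must be positive")
  list(delta_mean = abs(mean_syn - mean_val) / (mean_syn + mean_val),
       delta_sd = abs(sd_syn - sd_val) / (sd_syn + sd_val))
}

#' Rasterize streamlines into a binary mask
#'
#' A voxel is marked if any streamline segment intersects it, using exact
#' 3D voxel traversal (DDA) rather than vertex binning, so masks stay
#' continuous however coarse the streamline step size.
#'
#' @param tract A [streamline_set()].
#' @param voxel_size Isotropic voxel size in mm (default 1).
#' @param dims Optional grid dimensions; inferred from the streamline
#'   bounding box when missing.  Points outside the grid are an error.
#' @return List of class `binary_mask` with `mask` (3D logical) and
#'   `voxel_size`.
#' @export
streamlines_to_mask <- function(tract, voxel_size = 1, dims = NULL) {
  stopifnot(inherits(tract, "streamline_set"))
  all_pts <- do.call(rbind, tract$streamlines)
  if (is.null(dims)) dims <- pmax(1, ceiling(apply(all_pts, 2, max) / voxel_size))
  dims <- as.integer(dims)
  bad <- which(all_pts[, 1] < 0 | all_pts[, 2] < 0 | all_pts[, 3] < 0 |
               all_pts[, 1] > dims[1] * voxel_size |
               all_pts[, 2] > dims[2] * voxel_size |
               all_pts[, 3] > dims[3] * voxel_size)
  if (length(bad))
    stop("streamline points outside the grid extent, e.g. (",
         paste(signif(all_pts[bad[1], ], 4), collapse = ", "), ") mm")
  mask <- array(FALSE, dim = dims)
  for (s in tract$streamlines) {
    v <- s / voxel_size   # continuous voxel coordinates, corner origin
    for (i in seq_len(nrow(v) - 1))
      mask <- dda_mark(mask, v[i, ], v[i + 1, ], dims)
  }
  structure(list(mask = mask, voxel_size = rep(voxel_size, 3)),
            class = "binary_mask")
}

# mark all voxels crossed by the segment a -> b (continuous voxel coords)
dda_mark <- function(mask, a, b, dims) {
  cell <- pmin(pmax(floor(a), 0), dims - 1)
  end_cell <- pmin(pmax(floor(b), 0), dims - 1)
  mask[cell[1] + 1, cell[2] + 1, cell[3] + 1] <- TRUE
  d <- b - a
  step <- sign(d)
  t_max <- rep(Inf, 3)
  t_delta <- rep(Inf, 3)
  for (ax in 1:3) {
    if (d[ax] != 0) {
      nxt <- if (step[ax] > 0) cell[ax] + 1 else cell[ax]
      t_max[ax] <- (nxt - a[ax]) / d[ax]
      t_delta[ax] <- abs(1 / d[ax])
    }
  }
  guard <- sum(abs(end_cell - cell)) + 3
  while (any(cell != end_cell) && guard > 0) {
    ax <- which.min(t_max)
    cell[ax] <- cell[ax] + step[ax]
    if (cell[ax] < 0 || cell[ax] >= dims[ax]) break
    t_max[ax] <- t_max[ax] + t_delta[ax]
    mask[cell[1] + 1, cell[2] + 1, cell[3] + 1] <- TRUE
    guard <- guard - 1
  }
  mask
}

#' Compare a statistic between synthetic and validation cohorts
#'
#' For pairwise statistics (dice, Mantel r, squared differences) the three
#' distributions are all within-synthetic pairs, all within-validation
#' pairs, and all cross pairs.  For per-subject statistics (global
#' efficiency, tract volume) the two per-group distributions are compared
#' with a two-sided Wilcoxon-Mann-Whitney rank-sum test.
#'
#' @param group_syn,group_val Non-empty lists of subjects.
#' @param statistic For `mode = "pairwise"`, `function(a, b)`; for
#'   `mode = "per_subject"`, `function(a)`.
#' @param mode `"pairwise"` or `"per_subject"`.
#' @return List of class `cohort_comparison` with `syn_syn`, `val_val`,
#'   `syn_val` value vectors and, for per-subject statistics, the rank-sum
#'   `p_value`.
#' @export
cohort_compare <- function(group_syn, group_val, statistic,
                           mode = c("pairwise", "per_subject")) {
  mode <- match.arg(mode)
  if (length(group_syn) == 0 || length(group_val) == 0)
    stop("both groups must be non-empty")
  if (mode == "pairwise") {
    within <- function(g) {
      if (length(g) < 2) return(numeric(0))
      apply(t(utils::combn(length(g), 2)), 1, function(p)
        statistic(g[[p[1]]], g[[p[2]]]))
    }
    cross <- as.vector(outer(seq_along(group_syn), seq_along(group_val),
                             Vectorize(function(i, j)
                               statistic(group_syn[[i]], group_val[[j]]))))
    out <- list(syn_syn = within(group_syn), val_val = within(group_val),
                syn_val = cross, p_value = NA_real_, mode = mode)
  } else {
    syn <- vapply(group_syn, statistic, numeric(1))
    val <- vapply(group_val, statistic, numeric(1))
    p <- wilcox.test(syn, val, exact = FALSE)$p.value
    out <- list(syn_syn = syn, val_val = val, syn_val = numeric(0),
                p_value = p, mode = mode)
  }
  structure(out, class = "cohort_comparison")
}
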