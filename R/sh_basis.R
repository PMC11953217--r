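#' @useDynLib fodgan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd cor wilcox.test quantile
#' @importFrom utils head read.csv write.csv
NULL

# cache for per-lmax fit operators on the default sphere sampling
.fodgan_cache <- new.env(parent = emptyenv())

#' Number of coefficients in a real even-order spherical-harmonic basis
#'
#' Fibre orientation distributions are antipodally symmetric, so only even
#' harmonic orders `l = 0, 2, ..., lmax` are retained.  The basis then has
#' `(lmax + 1)(lmax + 2) / 2` real coefficients; `lmax = 6` gives the 28
#' coefficient volumes used throughout the package defaults.
#'
#' @param lmax Maximum (even, non-negative) harmonic order.
#' @return Integer basis size.
#' @export
#' @examples
#' sh_basis_size(6)  # 28
sh_basis_size <- function(lmax) {
  if (length(lmax) != 1L || !is.finite(lmax) || lmax != round(lmax))
    stop("lmax must be a single integer")
  if (lmax < 0) stop("lmax must be non-negative, got ", lmax)
  if (lmax %% 2 != 0)
    stop("lmax must be even (antipodally symmetric basis), got ", lmax)
  as.integer((lmax + 1) * (lmax + 2) / 2)
}

#' Real even-order spherical-harmonic basis
#'
#' Defines the channel ordering of all FOD volumes in this package: pairs
#' `(l, m)` with even `l` ascending and, within each order, `m` from `-l` to
#' `l`.  The basis functions are the real orthonormal spherical harmonics
#' (`sqrt(2)`-scaled sine/cosine combinations for `m != 0`), so channel 1 is
#' the isotropic `Y_0^0 = 1 / sqrt(4 pi)`.
#'
#' @param lmax Maximum even harmonic order.
#' @return An object of class `sh_basis` with elements `lmax`, `size` and an
#'   `ordering` matrix with columns `l` and `m`.
#' @export
sh_basis <- function(lmax) {
  n <- sh_basis_size(lmax)
  ord <- do.call(rbind, lapply(seq(0L, lmax, by = 2L), function(l)
    cbind(l = l, m = seq(-l, l))))
  structure(list(lmax = as.integer(lmax), size = n, ordering = ord),
            class = "sh_basis")
}

#' @export
print.sh_basis <- function(x, ...) {
  cat("Real even-order SH basis: lmax =", x$lmax, "->", x$size,
      "coefficients\n")
  invisible(x)
}

# Associated Legendre P_l^m(x) for m >= 0, without the Condon-Shortley phase,
# via the standard diagonal/upward recurrences. Vectorized over x.
assoc_legendre <- function(l, m, x) {
  stopifnot(m >= 0, l >= m)
  pmm <- rep(1, length(x))
  if (m > 0) {
    somx2 <- sqrt(pmax(0, 1 - x^2))
    fact <- 1
    for (i in seq_len(m)) {
      pmm <- pmm * fact * somx2
      fact <- fact + 2
    }
  }
  if (l == m) return(pmm)
  pmmp1 <- x * (2 * m + 1) * pmm
  if (l == m + 1) return(pmmp1)
  for (ll in seq(m + 2, l)) {
    pll <- (x * (2 * ll - 1) * pmmp1 - (ll + m - 1) * pmm) / (ll - m)
    pmm <- pmmp1
    pmmp1 <- pll
  }
  pmmp1
}

# log factorial ratio (l - m)! / (l + m)! kept exact at these tiny orders
.sh_norm <- function(l, m) {
  sqrt((2 * l + 1) / (4 * pi) * exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
}

check_unit_directions <- function(directions, tol = 1e-8) {
  if (is.null(dim(directions))) directions <- matrix(directions, nrow = 1)
  if (ncol(directions) != 3) stop("directions must be an n x 3 matrix")
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > tol))
    stop("directions must be unit vectors (max |norm - 1| = ",
         format(max(abs(nrm - 1))), ")")
  directions
}

#' Design matrix of the real even-order SH basis
#'
#' @param directions `n x 3` matrix of unit vectors.
#' @param basis An [sh_basis()].
#' @return `n x basis$size` matrix with column `j` holding basis function `j`
#'   evaluated at each direction.
#' @export
sh_design_matrix <- function(directions, basis) {
  directions <- check_unit_directions(directions)
  ct <- pmin(1, pmax(-1, directions[, 3]))           # cos(theta)
  phi <- atan2(directions[, 2], directions[, 1])
  B <- matrix(0, nrow(directions), basis$size)
  for (j in seq_len(basis$size)) {
    l <- basis$ordering[j, "l"]
    m <- basis$ordering[j, "m"]
    am <- abs(m)
    p <- assoc_legendre(l, am, ct) * .sh_norm(l, am)
    B[, j] <- if (m == 0) p
      else if (m > 0) sqrt(2) * p * cos(m * phi)
      else sqrt(2) * p * sin(am * phi)
  }
  B
}

#' Evaluate an SH coefficient vector at directions on the sphere
#'
#' @param coeffs Coefficient vector of length `basis$size`.
#' @param directions `n x 3` matrix of unit vectors.
#' @param basis An [sh_basis()]; defaults to the basis implied by
#'   `length(coeffs)`.
#' @return Numeric vector of amplitudes, one per direction.
#' @export
evaluate_sh <- function(coeffs, directions, basis = basis_for_size(length(coeffs))) {
  if (length(coeffs) != basis$size)
    stop("coeffs length ", length(coeffs), " does not match basis size ",
         basis$size)
  drop(sh_design_matrix(directions, basis) %*% coeffs)
}

#' Least-squares SH fit of sampled spherical amplitudes
#'
#' @param amplitudes Amplitude per direction.
#' @param directions `n x 3` matrix of unit vectors, `n >= basis$size`,
#'   spread so the design matrix has full column rank.
#' @param basis An [sh_basis()].
#' @return Coefficient vector of length `basis$size`.
#' @export
fit_sh <- function(amplitudes, directions, basis) {
  B <- sh_design_matrix(directions, basis)
  if (nrow(B) < ncol(B))
    stop("need at least ", ncol(B), " directions, got ", nrow(B))
  qrB <- qr(B)
  if (qrB$rank < ncol(B))
    stop("direction set is rank-deficient for lmax = ", basis$lmax,
         " (rank ", qrB$rank, " < ", ncol(B), ")")
  drop(qr.coef(qrB, amplitudes))
}

# basis matching a coefficient count, with a helpful error otherwise
basis_for_size <- function(n) {
  for (lmax in seq(0L, 40L, by = 2L)) {
    sz <- sh_basis_size(lmax)
    if (sz == n) return(sh_basis(lmax))
    if (sz > n) {
      lo <- if (lmax >= 2) sh_basis_size(lmax - 2L) else NA
      stop("channel count ", n, " is not a valid even-order SH basis size; ",
           "nearest valid sizes are ", lo, " (lmax ", lmax - 2L, ") and ",
           sz, " (lmax ", lmax, ")")
    }
  }
  stop("channel count ", n, " exceeds supported lmax")
}

#' Quasi-uniform unit directions (Fibonacci spiral)
#'
#' Deterministic, well-spread sphere sampling used for SH rotation by
#' sample-and-refit and for peak finding.
#'
#' @param n Number of directions.
#' @return `n x 3` matrix of unit vectors.
#' @export
sphere_directions <- function(n = 512) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (1 + sqrt(5)) * i
  cbind(r * cos(phi), r * sin(phi), z)
}

# cached (pseudo-inverse, directions) pair for a given lmax
sh_fit_operator <- function(basis, n_dirs = max(512L, 4L * basis$size)) {
  key <- paste0("fit_", basis$lmax, "_", n_dirs)
  hit <- .fodgan_cache[[key]]
  if (!is.null(hit)) return(hit)
  dirs <- sphere_directions(n_dirs)
  B <- sh_design_matrix(dirs, basis)
  P <- qr.solve(qr(B), diag(nrow(B)))   # (B'B)^-1 B'
  out <- list(dirs = dirs, pinv = P)
  assign(key, out, envir = .fodgan_cache)
  out
}

#' Validate a 3D rotation matrix
#'
#' @param R A 3x3 matrix.
#' @param tol Orthonormality/determinant tolerance.
#' @return `R`, invisibly, after validation.
#' @export
check_rotation <- function(R, tol = 1e-10) {
  if (!is.matrix(R) || any(dim(R) != c(3, 3)))
    stop("rotation must be a 3x3 matrix")
  if (max(abs(crossprod(R) - diag(3))) > tol)
    stop("rotation matrix is not orthonormal within ", tol)
  if (abs(det(R) - 1) > tol)
    stop("rotation matrix determinant is ", det(R), ", not +1")
  invisible(R)
}

#' Linear operator rotating SH coefficients
#'
#' Rotation is performed by sample-and-refit: the function is evaluated on a
#' dense quasi-uniform direction set pulled back through the rotation, then
#' re-fitted in the same basis.  Each even order transforms unitarily, so
#' per-order coefficient norms are preserved.
#'
#' @param basis An [sh_basis()].
#' @param R 3x3 rotation matrix (applied to the function's frame).
#' @return `basis$size` square matrix `M` with `rotated_coeffs = M %*% coeffs`.
#' @export
sh_rotation_matrix <- function(basis, R) {
  check_rotation(R)
  op <- sh_fit_operator(basis)
  # rotated f'(d) = f(R^T d); rows of dirs are d^T, so R^T d per row = dirs %*% R
  op$pinv %*% sh_design_matrix(op$dirs %*% R, basis)
}

#' Rotate an SH coefficient vector
#'
#' @inheritParams sh_rotation_matrix
#' @param coeffs Coefficient vector.
#' @return Rotated coefficient vector.
#' @export
rotate_sh <- function(coeffs, R, basis = basis_for_size(length(coeffs))) {
  drop(sh_rotation_matrix(basis, R) %*% coeffs)
}
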