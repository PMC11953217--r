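# Independent oracles used across the suite.

# Brute-force real SH evaluation from pracma's associated Legendre routine
# (MATLAB convention, Condon-Shortley phase included; removed here to match
# the package's documented phase-free convention).
oracle_sh_eval <- function(coeffs, directions, lmax) {
  ct <- directions[, 3]
  phi <- atan2(directions[, 2], directions[, 1])
  vals <- numeric(nrow(directions))
  j <- 0
  for (l in seq(0, lmax, by = 2)) {
    P <- pracma::legendre(l, ct)   # (l+1) x n, rows m = 0..l, with CS phase
    if (is.null(dim(P))) P <- matrix(P, nrow = l + 1)
    for (m in -l:l) {
      j <- j + 1
      am <- abs(m)
      nrm <- sqrt((2 * l + 1) / (4 * pi) *
                    exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      p <- (-1)^am * P[am + 1, ]   # strip the Condon-Shortley phase
      y <- if (m == 0) nrm * p
        else if (m > 0) sqrt(2) * nrm * p * cos(m * phi)
        else sqrt(2) * nrm * p * sin(am * phi)
      vals <- vals + coeffs[j] * y
    }
  }
  vals
}

# Gauss-Legendre (polar) x trapezoid (azimuth) sphere quadrature: exact for
# band-limited spherical polynomials.
sphere_quadrature <- function(n_theta = 24, n_phi = 48) {
  gl <- pracma::gaussLegendre(n_theta, -1, 1)
  phi <- 2 * pi * (seq_len(n_phi) - 1) / n_phi
  grid <- expand.grid(i = seq_len(n_theta), j = seq_len(n_phi))
  ct <- gl$x[grid$i]
  st <- sqrt(pmax(0, 1 - ct^2))
  dirs <- cbind(st * cos(phi[grid$j]), st * sin(phi[grid$j]), ct)
  list(dirs = dirs, weights = gl$w[grid$i] * (2 * pi / n_phi))
}

# Floyd-Warshall weighted global efficiency (edge length 1/weight)
fw_global_efficiency <- function(W) {
  n <- nrow(W)
  L <- ifelse(W > 0, 1 / W, Inf)
  diag(L) <- 0
  for (k in seq_len(n)) L <- pmin(L, outer(L[, k], L[k, ], "+"))
  inv <- 1 / L
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

# small clean phantom used by several files
tiny_phantom_spec <- function(lmax = 2, seed = 1) {
  phantom_spec(grid_dims = c(8, 8, 4), voxel_size = c(2, 2, 2), lmax = lmax,
               seed = seed)
}

random_connectome <- function(n, seed, density = 0.6) {
  set.seed(seed)
  W <- matrix(0, n, n)
  ut <- upper.tri(W)
  W[ut] <- ifelse(runif(sum(ut)) < density, runif(sum(ut), 0.05, 3), 0)
  connectome(W + t(W))
}
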