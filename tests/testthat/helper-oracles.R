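# Independent oracles used across the suite.

# Excess kurtosis of the projection at angle theta for 2-channel data,
# computed directly from the definition (not via the package's kernel).
alpha_at_angle <- function(theta, x_white) {
  y <- cos(theta) * x_white[1L, ] + sin(theta) * x_white[2L, ]
  sum(y^4) / length(y) - 3
}

# Brute-force maximum of the objective over a dense angle grid (N = 2).
grid_phi_max <- function(x_white, n_grid = 3600L) {
  thetas <- seq(0, pi, length.out = n_grid + 1L)[-(n_grid + 1L)]
  alphas <- vapply(thetas, alpha_at_angle, numeric(1), x_white = x_white)
  ok <- alphas > -2
  max(upsilon(alphas[ok]))
}

# Whitening oracle via explicit covariance eigendecomposition (checked
# against the package's SVD route).
whiten_eigen_oracle <- function(x) {
  xc <- x - rowMeans(x)
  cov <- tcrossprod(xc) / ncol(x)
  eg <- eigen(cov, symmetric = TRUE)
  tr <- eg$vectors %*% diag(1 / sqrt(eg$values), nrow(x)) %*% t(eg$vectors)
  tr %*% xc
}

# A small well-conditioned mixture used by several tests.
toy_mixture <- function(seed = 42, m = 4000) {
  synthesize_mixture(c("laplace", "uniform", "gaussian"), m, seed = seed)
}
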