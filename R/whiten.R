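#' Centre and whiten a multichannel signal matrix
#'
#' Removes the per-channel mean and applies a linear transform so the
#' result has identity sample covariance with the moment convention
#' \eqn{\Sigma = X X^\top / M} (denominator M, not M-1).  Whitening is the
#' standard ICA preconditioning: after it, separating directions can be
#' constrained to an orthonormal set.
#'
#' The transform is computed from the singular value decomposition of the
#' centred data rather than an explicit covariance eigendecomposition,
#' which is better conditioned for nearly rank-deficient inputs.
#'
#' @param x numeric N x M matrix, channels in rows.
#' @param rank_tolerance relative tolerance below which a covariance
#'   eigenvalue is treated as zero (default `1e-10` times the largest).
#'   The component count is fixed at N, so a rank-deficient input is an
#'   error rather than a silent dimension reduction.
#' @return object of class `"whitening"`: a list with
#'   \item{x}{the whitened N x M matrix;}
#'   \item{model}{a `"whitening_model"` with fields `mean` (length-N
#'     centring vector), `transform` and `inverse_transform` (N x N
#'     matrices with `transform %*% inverse_transform = I`).}
#' @examples
#' xs <- synthesize_mixture(c("laplace", "uniform"), 1000, seed = 1)
#' w <- whiten(xs$x)
#' tcrossprod(w$x) / ncol(w$x)  # identity
#' @export
whiten <- function(x, rank_tolerance = 1e-10) {
  x <- as_signal_matrix(x)
  n <- nrow(x)
  m <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  sv <- svd(xc, nu = n, nv = 0)
  # covariance eigenvalues are d^2 / M
  d <- sv$d
  deficient <- d * d < rank_tolerance * d[1L]^2
  if (any(deficient))
    oi_stop("orderica_rank_error",
            "covariance is rank deficient: %d of %d dimensions carry no variance (e.g. a duplicated or constant channel)",
            sum(deficient), n)
  scale <- sqrt(m) / d
  transform <- sv$u %*% (scale * t(sv$u))          # U diag(sqrt(M)/d) U'
  inverse_transform <- sv$u %*% ((1 / scale) * t(sv$u))
  structure(
    list(
      x = transform %*% xc,
      model = structure(
        list(mean = mu, transform = transform,
             inverse_transform = inverse_transform),
        class = "whitening_model")
    ),
    class = "whitening")
}

#' Undo a whitening transform
#'
#' Maps whitened signals back to the original coordinates:
#' `inverse_transform %*% y + mean`.
#'
#' @param model a `"whitening_model"` from [whiten()].
#' @param y whitened N x M matrix.
#' @return matrix in the original signal space.
#' @export
dewhiten <- function(model, y) {
  stopifnot(inherits(model, "whitening_model"))
  model$inverse_transform %*% y + model$mean
}

#' @export
print.whitening_model <- function(x, ...) {
  cat(sprintf("Whitening model: %d channels\n", length(x$mean)))
  invisible(x)
}
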