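#' Sample excess kurtosis
#'
#' \eqn{\alpha = \sum_m y_m^4 / M - 3}, the estimated excess kurtosis of a
#' projection that is already unit-variance (which the orthonormality
#' constraint of the deflation guarantees for whitened data).  Zero for a
#' Gaussian, positive for super-Gaussian (heavy-tailed) sources, negative
#' for sub-Gaussian ones; bounded below by -2, attained only by a
#' symmetric two-point variable.
#'
#' @param y numeric vector of length M.
#' @return the excess kurtosis estimate.
#' @examples
#' estimate_kurtosis(c(1, -1, 1, -1))   # -2, the two-point minimum
#' @export
estimate_kurtosis <- function(y) {
  if (length(y) == 0L)
    oi_stop("orderica_data_error", "cannot estimate kurtosis of an empty vector")
  if (!is.numeric(y) || !all(is.finite(y)))
    oi_stop("orderica_data_error", "`y` must be finite numeric")
  sum(y^4) / length(y) - 3
}

#' Projector onto the span of previously extracted rows
#'
#' During deflation every new direction is kept orthogonal to the rows
#' already accepted into the separating matrix W.  For orthonormal rows
#' the projector is simply `t(W) %*% W`; with no rows it is the zero
#' matrix.
#'
#' @param w_matrix matrix whose rows are the accepted directions (may have
#'   zero rows), or `NULL`.
#' @param n dimension, required when `w_matrix` is `NULL`/empty.
#' @return symmetric idempotent N x N matrix.
#' @export
deflation_projector <- function(w_matrix, n = ncol(w_matrix)) {
  if (is.null(w_matrix) || nrow(w_matrix) == 0L)
    return(matrix(0, n, n))
  crossprod(w_matrix)
}

#' One FastICA restart under deflation
#'
#' Runs the kurtosis fixed-point iteration from a given start `w0`,
#' constrained orthogonal to the subspace spanned by previously extracted
#' components.  Each full cycle performs, in order:
#' \enumerate{
#'   \item \eqn{y \gets w^\top \tilde X}
#'   \item \eqn{w \gets \tilde X (y \circ y \circ y)^\top / M - 3 w}
#'   \item \eqn{w \gets w - E w} (deflation)
#'   \item \eqn{w \gets w / \lVert w \rVert}
#' }
#' The cubic update flips the sign of `w` freely, so convergence is
#' declared when the direction is fixed up to sign:
#' `min(||w - w_prev||, ||w + w_prev||) <= eps`.
#'
#' @param w0 start vector of length N (any nonzero vector not inside the
#'   deflation subspace).
#' @param x_white whitened N x M signal matrix.
#' @param e deflation projector (N x N), e.g. from [deflation_projector()];
#'   `NULL` means no deflation.
#' @param k_max maximum number of iterations (default 30).
#' @param eps convergence threshold on the direction change (default 1e-6).
#' @param degenerate_tolerance if `w0` after deflation has norm below this,
#'   the start is degenerate (it lies in the already-extracted subspace)
#'   and a classed error of class `"orderica_degenerate_start"` is raised
#'   so the caller can resample; this is distinct from non-convergence.
#' @param trace if `TRUE`, record the unit vector after every iteration in
#'   the `trace` field (used to verify the deflation constraint holds at
#'   every step, not only at exit).
#' @return list of class `"fastica_candidate"` with fields `w` (unit
#'   vector), `y` (recovered row `w' x_white`), `alpha` (excess kurtosis of
#'   `y`), `converged`, `iterations`, and optionally `trace`.
#' @export
fastica_candidate <- function(w0, x_white, e = NULL, k_max = 30L,
                              eps = 1e-6, degenerate_tolerance = 1e-12,
                              trace = FALSE) {
  n <- nrow(x_white)
  m <- ncol(x_white)
  stopifnot(length(w0) == n, k_max >= 1L, eps > 0)
  if (is.null(e)) e <- matrix(0, n, n)
  w <- as.numeric(w0)
  w <- w - drop(e %*% w)
  nw <- sqrt(sum(w * w))
  if (nw <= degenerate_tolerance)
    oi_stop("orderica_degenerate_start",
            "start vector lies in the deflation subspace (post-projection norm %.3g)", nw)
  w <- w / nw
  iters <- 0L
  converged <- FALSE
  tr <- if (trace) vector("list", k_max) else NULL
  repeat {
    w_prev <- w
    y <- drop(crossprod(w, x_white))       # w' X~
    w <- drop(x_white %*% (y * y * y)) / m - 3 * w
    w <- w - drop(e %*% w)
    nw <- sqrt(sum(w * w))
    if (nw <= degenerate_tolerance)
      oi_stop("orderica_degenerate_start",
              "iterate collapsed into the deflation subspace (norm %.3g)", nw)
    w <- w / nw
    iters <- iters + 1L
    if (trace) tr[[iters]] <- w
    dmin <- min(sqrt(sum((w - w_prev)^2)), sqrt(sum((w + w_prev)^2)))
    if (dmin <= eps) { converged <- TRUE; break }
    if (iters >= k_max) break
  }
  y <- drop(crossprod(w, x_white))
  out <- list(w = w, y = y, alpha = estimate_kurtosis(y),
              converged = converged, iterations = iters)
  if (trace) out$trace <- tr[seq_len(iters)]
  class(out) <- "fastica_candidate"
  out
}
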