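#' Validate a channels-by-samples signal matrix
#'
#' Signals are stored channels-in-rows throughout: an N x M numeric matrix
#' holds N channels observed at M time points.  The linear model is
#' X = A S with A an invertible N x N mixing matrix, so at least two
#' channels and more samples than channels are required.
#'
#' @param x numeric matrix (or object coercible to one), channels in rows.
#' @param arg name used in error messages.
#' @return the validated matrix (invisibly usable as a plain matrix).
#' @export
as_signal_matrix <- function(x, arg = "x") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    oi_stop("orderica_data_error", "`%s` must be a numeric matrix", arg)
  if (nrow(x) < 2L)
    oi_stop("orderica_data_error",
            "`%s` must have at least 2 channels (rows), got %d", arg, nrow(x))
  if (ncol(x) <= nrow(x))
    oi_stop("orderica_data_error",
            "`%s` must have more samples (columns) than channels: N=%d, M=%d",
            arg, nrow(x), ncol(x))
  if (!all(is.finite(x)))
    oi_stop("orderica_data_error", "`%s` contains non-finite values", arg)
  x
}

# Row-wise second moment with the M (not M-1) denominator used throughout:
# the whitening constraint is sum_m y_im y_jm / M = delta_ij.
row_moment2 <- function(x) rowMeans(x * x)
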