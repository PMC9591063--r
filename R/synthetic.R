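# Analytic excess kurtosis of the supported source families.
#
#   laplace                 3
#   uniform                -1.2
#   gaussian                0
#   generalized_gaussian    G(5/b)G(1/b)/G(3/b)^2 - 3       (shape b > 0)
#   bimodal_mixture         -2 d^4 / (1 + d^2)^2            (mode sep. d)
#   student_t               6/(df - 4)                      (df > 4)
#   bernoulli               -2  (excluded boundary; opt-in only)
gg_kurtosis <- function(shape) {
  gamma(5 / shape) * gamma(1 / shape) / gamma(3 / shape)^2 - 3
}
bimodal_kurtosis <- function(sep) -2 * sep^4 / (1 + sep^2)^2

# Parse "family", "family(param)" or list(name=, param=) into a sampler
# spec with its analytic kurtosis.
parse_family <- function(fam, allow_excluded = FALSE) {
  if (is.list(fam)) {
    name <- fam$name; param <- fam$param
  } else {
    m <- regmatches(fam, regexec("^([a-z_]+)(\\(([-0-9.eE+]+)\\))?$", fam))[[1L]]
    if (length(m) == 0L)
      oi_stop("orderica_data_error", "cannot parse source family '%s'", fam)
    name <- m[2L]
    param <- if (nzchar(m[4L])) as.numeric(m[4L]) else NULL
  }
  spec <- switch(name,
    laplace = list(kurtosis = 3, sample = function(n)
      (rexp(n) - rexp(n)) / sqrt(2)),
    uniform = list(kurtosis = -1.2, sample = function(n)
      runif(n, -sqrt(3), sqrt(3))),
    gaussian = list(kurtosis = 0, sample = function(n) rnorm(n)),
    generalized_gaussian = {
      shape <- if (is.null(param)) 0.7 else param
      if (shape <= 0)
        oi_stop("orderica_domain_error", "generalized_gaussian shape must be > 0")
      a <- sqrt(gamma(1 / shape) / gamma(3 / shape))
      list(kurtosis = gg_kurtosis(shape), sample = function(n)
        sample(c(-1, 1), n, replace = TRUE) *
          a * rgamma(n, shape = 1 / shape)^(1 / shape))
    },
    bimodal_mixture = {
      sep <- if (is.null(param)) 2 else param
      sc <- sqrt(1 + sep^2)
      list(kurtosis = bimodal_kurtosis(sep), sample = function(n)
        (sample(c(-sep, sep), n, replace = TRUE) + rnorm(n)) / sc)
    },
    student_t = {
      df <- if (is.null(param)) 5 else param
      if (df <= 4)
        oi_stop("orderica_domain_error",
                "student_t requires df > 4 for finite kurtosis; got %g", df)
      list(kurtosis = 6 / (df - 4), sample = function(n)
        rt(n, df = df) / sqrt(df / (df - 2)))
    },
    bernoulli = {
      if (!allow_excluded)
        oi_stop("orderica_domain_error",
          paste("the symmetric Bernoulli source (excess kurtosis -2) is excluded",
                "from the uniqueness guarantee; pass allow_excluded = TRUE to",
                "generate it for negative tests"))
      list(kurtosis = -2, sample = function(n)
        sample(c(-1, 1), n, replace = TRUE))
    },
    oi_stop("orderica_data_error", "unknown source family '%s'", name)
  )
  spec$label <- if (is.null(param)) name else sprintf("%s(%g)", name, param)
  spec
}

#' Generate normalised independent non-Gaussian sources
#'
#' Draws one i.i.d. sample row per requested family and standardises each
#' row to exactly zero mean and unit variance (moment convention:
#' denominator M).  The analytic excess kurtosis of every family is
#' recorded as the ground truth, which is what the extraction order of
#' [ordering_ica()] is compared against.
#'
#' Supported families (parameter in parentheses where applicable):
#' `"laplace"`, `"uniform"`, `"gaussian"`,
#' `"generalized_gaussian(shape)"`, `"bimodal_mixture(separation)"`,
#' `"student_t(df)"` with df > 4.  The symmetric two-point source
#' `"bernoulli"` sits exactly on the excluded kurtosis boundary -2 and is
#' only available with `allow_excluded = TRUE`, for negative tests.
#'
#' @param families character vector (or list of `list(name=, param=)`).
#' @param n_samples samples per row, M >= 100.
#' @param seed integer seed; the generator is seed-deterministic.
#' @param allow_excluded permit the `"bernoulli"` family.
#' @return list of class `"ica_sources"` with fields `sources` (N x M),
#'   `families` (labels), `true_kurtosis`, `true_upsilon` (`NA` for the
#'   excluded boundary family), `n_samples`, `seed`.
#' @export
generate_sources <- function(families, n_samples, seed = 1L,
                             allow_excluded = FALSE) {
  if (length(families) < 1L)
    oi_stop("orderica_data_error", "need at least one source family")
  if (n_samples < 100)
    oi_stop("orderica_data_error", "n_samples must be >= 100, got %d", n_samples)
  specs <- lapply(families, parse_family, allow_excluded = allow_excluded)
  set.seed(seed)
  s <- t(vapply(specs, function(sp) {
    row <- sp$sample(n_samples)
    row <- row - mean(row)
    row / sqrt(mean(row * row))
  }, numeric(n_samples)))
  kappa <- vapply(specs, `[[`, numeric(1), "kurtosis")
  structure(
    list(sources = s,
         families = vapply(specs, `[[`, character(1), "label"),
         true_kurtosis = kappa,
         true_upsilon = ifelse(kappa > -2, kappa - 2 * log(kappa / 2 + 1),
                               NA_real_),
         n_samples = as.integer(n_samples), seed = as.integer(seed)),
    class = "ica_sources")
}

#' Generate a random invertible mixing matrix
#'
#' Entries are standard Gaussian; draws are rejected until the condition
#' number is at most `cond_cap`, so the mixture is guaranteed to be
#' comfortably invertible.
#'
#' @param n dimension (>= 2).
#' @param seed integer seed.
#' @param cond_cap maximum accepted 2-norm condition number (> 1,
#'   default 100).
#' @param identity return the identity matrix instead (unmixed "mixture").
#' @return invertible n x n matrix.
#' @export
generate_mixing <- function(n, seed = 1L, cond_cap = 100, identity = FALSE) {
  if (n < 2) oi_stop("orderica_data_error", "`n` must be >= 2")
  if (identity) return(diag(n))
  if (cond_cap <= 1)
    oi_stop("orderica_domain_error", "`cond_cap` must be > 1")
  set.seed(seed)
  repeat {
    a <- matrix(rnorm(n * n), n, n)
    d <- svd(a, nu = 0, nv = 0)$d
    if (d[n] > 0 && d[1L] / d[n] <= cond_cap) return(a)
  }
}

#' Generate a ground-truthed linear mixture X = A S
#'
#' Convenience wrapper combining [generate_sources()] and
#' [generate_mixing()]: the observed signals, true sources, mixing matrix
#' and analytic kurtoses are returned together so separation quality and
#' extraction order can be scored against the truth.
#'
#' @inheritParams generate_sources
#' @param mixing `"random"` (condition-capped Gaussian matrix) or
#'   `"identity"`.
#' @param cond_cap condition-number cap for the random mixing matrix.
#' @return list of class `"ica_ground_truth"` with fields `x` (N x M
#'   observed), `sources`, `mixing`, `families`, `true_kurtosis`,
#'   `true_upsilon`, `seed`.
#' @export
synthesize_mixture <- function(families, n_samples, seed = 1L,
                               mixing = c("random", "identity"),
                               cond_cap = 100, allow_excluded = FALSE) {
  mixing <- match.arg(mixing)
  if (length(families) < 2L)
    oi_stop("orderica_data_error", "a mixture needs at least 2 source families")
  src <- generate_sources(families, n_samples, seed = seed,
                          allow_excluded = allow_excluded)
  n <- nrow(src$sources)
  # separate seed stream for the mixing matrix
  a <- generate_mixing(n, seed = (as.numeric(seed) + 1000003) %% 2147483647,
                       cond_cap = cond_cap,
                       identity = identical(mixing, "identity"))
  structure(
    list(x = a %*% src$sources, sources = src$sources, mixing = a,
         families = src$families, true_kurtosis = src$true_kurtosis,
         true_upsilon = src$true_upsilon, seed = src$seed),
    class = "ica_ground_truth")
}

#' Score a separation against known ground truth
#'
#' Expresses the true unmixing directions in the whitened space used by
#' the fit (rows of `solve(transform %*% A)`), then greedily matches each
#' estimated row, in extraction order, to its best remaining true source
#' by absolute cosine.  A score of 1 means the direction was recovered
#' exactly (up to sign).  The order-agreement flag is `TRUE` iff the
#' matched sequence of true \eqn{\Upsilon(\kappa)} values is
#' non-increasing, i.e. the components came out in the order the
#' uniqueness theory predicts.
#'
#' @param result an [ordering_ica()] fit (run with `whiten = TRUE`, or on
#'   data whitened externally — then pass `whitening_model`).
#' @param truth an `"ica_ground_truth"` from [synthesize_mixture()].
#' @param whitening_model optional [whiten()] model if the fit does not
#'   carry one.
#' @return list with `scores` (per estimated component, extraction order),
#'   `matched_source` (index into the truth's rows), `matched_upsilon`,
#'   and `order_agreement`.
#' @export
recovery_score <- function(result, truth, whitening_model = NULL) {
  stopifnot(inherits(result, "ordering_ica"),
            inherits(truth, "ica_ground_truth"))
  model <- if (!is.null(result$whitening)) result$whitening else whitening_model
  n <- nrow(result$w_matrix)
  if (n != nrow(truth$mixing))
    oi_stop("orderica_data_error",
            "fit has %d components but truth has %d sources",
            n, nrow(truth$mixing))
  b <- if (is.null(model)) truth$mixing else model$transform %*% truth$mixing
  true_rows <- solve(b)          # row j recovers source j in the fit's frame
  scores <- numeric(n)
  matched <- integer(n)
  remaining <- seq_len(n)
  for (i in seq_len(n)) {
    w <- result$w_matrix[i, ]
    cosines <- vapply(remaining, function(j) {
      tr <- true_rows[j, ]
      abs(sum(w * tr)) / sqrt(sum(w * w) * sum(tr * tr))
    }, numeric(1))
    pick <- which.max(cosines)
    scores[i] <- cosines[pick]
    matched[i] <- remaining[pick]
    remaining <- remaining[-pick]
  }
  m_ups <- truth$true_upsilon[matched]
  list(scores = scores, matched_source = matched, matched_upsilon = m_ups,
       order_agreement = !is.unsorted(rev(m_ups), strictly = FALSE))
}
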