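#' Convex non-Gaussianity score of a kurtosis value
#'
#' \deqn{\Upsilon(\alpha) = \alpha - 2\log(\alpha/2 + 1)}
#' Non-negative, zero only at \eqn{\alpha = 0} (Gaussian), strictly convex
#' and increasing in \eqn{|\alpha|} on each side of zero, so it scores
#' super- and sub-Gaussian sources on one common scale.  Undefined at
#' \eqn{\alpha \le -2}: the boundary \eqn{\alpha = -2} corresponds to the
#' symmetric two-point (Bernoulli) variable excluded from the uniqueness
#' guarantee.
#'
#' @param alpha excess kurtosis value(s), each `> -2`.
#' @return \eqn{\Upsilon(\alpha)}, vectorised.
#' @examples
#' upsilon(3)      # Laplace source: 3 - 2*log(2.5)
#' upsilon(-1.2)   # uniform source
#' @export
upsilon <- function(alpha) {
  if (!is.numeric(alpha) || any(!is.finite(alpha)))
    oi_stop("orderica_domain_error", "`alpha` must be finite numeric")
  if (any(alpha <= -2))
    oi_stop("orderica_domain_error",
            "upsilon is undefined for alpha <= -2 (symmetric Bernoulli boundary); got %g",
            min(alpha))
  alpha - 2 * log(alpha / 2 + 1)
}

#' Default number of restart candidates
#'
#' The restart count L is tied to the hardware: `L = n_cores * R` rounded,
#' with a floor of 1, where R is an "overhead rate" trading extra
#' robustness (more candidates) against wall-clock overhead.  The default
#' R = 1 launches one candidate per core.
#'
#' @param n_cores number of available cores (default: detected).
#' @param overhead_rate positive multiplier R (default 1).
#' @return integer L >= 1.
#' @export
default_candidate_count <- function(n_cores = parallel::detectCores(),
                                    overhead_rate = 1) {
  if (!is.numeric(n_cores) || length(n_cores) != 1L || is.na(n_cores) ||
      n_cores < 1)
    oi_stop("orderica_domain_error", "`n_cores` must be a positive number")
  if (!is.numeric(overhead_rate) || length(overhead_rate) != 1L ||
      is.na(overhead_rate) || overhead_rate <= 0)
    oi_stop("orderica_domain_error", "`overhead_rate` must be positive")
  max(1L, as.integer(round(n_cores * overhead_rate)))
}

# One independent seed per (component, batch, candidate) triple, derived
# from the master seed.  Candidates therefore see identical random starts
# whether they are executed serially or across any number of workers.
candidate_seeds <- function(seed, n_components, l_candidates, n_batches = 2L) {
  set.seed(seed)
  array(sample.int(2147483646L, n_components * n_batches * l_candidates,
                   replace = TRUE),
        dim = c(l_candidates, n_batches, n_components))
}

# Draw a random start for one candidate under its own seed; resample if it
# falls (numerically) inside the deflation subspace.
run_one_candidate <- function(sub_seed, n, x_white, e, k_max, eps,
                              degenerate_tolerance) {
  set.seed(sub_seed)
  for (try in 1:100) {
    w0 <- rnorm(n)
    res <- tryCatch(
      fastica_candidate(w0, x_white, e, k_max = k_max, eps = eps,
                        degenerate_tolerance = degenerate_tolerance),
      orderica_degenerate_start = function(cnd) NULL)
    if (!is.null(res)) return(res)
  }
  oi_stop("orderica_convergence_error",
          "could not draw a start outside the deflation subspace after 100 tries")
}

#' Ordering ICA: globally restarted kurtosis deflation
#'
#' Estimates the separating matrix W one row at a time.  For component i,
#' `l_candidates` FastICA restarts are launched from independent random
#' starts, each constrained orthogonal to the rows already extracted; the
#' converged candidate with the highest score
#' \eqn{\Upsilon(\alpha)} is kept (ties broken by lowest candidate index).
#' Because \eqn{\Upsilon} is convex in the kurtosis, its global maximum
#' over the constraint set lies at a local extremum of the kurtosis, which
#' is exactly what each FastICA run finds — so with enough restarts the
#' per-step global optimum is reached and components emerge in descending
#' order of \eqn{\Upsilon}, making the solution unique up to sign.
#'
#' Non-converged restarts are excluded from the selection (their kurtosis
#' may be meaningless).  If every restart of a step fails to converge, one
#' fresh batch of `l_candidates` restarts is drawn; a second total failure
#' is an error naming the component.
#'
#' Randomness is fully reproducible: the master `seed` spawns one
#' sub-stream per (component, candidate) pair, so equal `(seed,
#' l_candidates)` give bit-identical results for any `workers` setting.
#'
#' @param x numeric N x M signal matrix, channels in rows.
#' @param l_candidates number of restarts L per component (default
#'   [default_candidate_count()]).
#' @param k_max maximum FastICA iterations K per restart (default 30).
#' @param eps convergence threshold (default 1e-6).
#' @param seed master seed (integer).
#' @param whiten whiten `x` internally (default `TRUE`).  With
#'   `whiten = FALSE` the input must already be zero-mean with identity
#'   covariance (denominator M).
#' @param workers number of parallel workers for the restarts (forked via
#'   \pkg{parallel}; values > 1 are ignored on Windows).  Affects speed
#'   only, never the result.
#' @param keep_candidates retain every restart's direction, kurtosis and
#'   convergence flag per component (needed for [success_rate()]).
#' @param degenerate_tolerance see [fastica_candidate()].
#' @return object of class `"ordering_ica"`:
#'   \item{w_matrix}{N x N separating matrix in the whitened space, rows in
#'     extraction order, orthonormal;}
#'   \item{alphas, upsilons}{per-component excess kurtosis and score;}
#'   \item{sources}{N x M recovered source estimates `w_matrix %*% x_white`;}
#'   \item{mixing_estimate}{estimated mixing matrix in the original signal
#'     space (`inverse_transform %*% t(w_matrix)` when whitening was
#'     applied);}
#'   \item{unmixing}{separating matrix mapped to the original space;}
#'   \item{whitening}{the [whiten()] model used, or `NULL`;}
#'   \item{run_meta}{seed, L, K, eps, per-component convergence counts;}
#'   \item{candidates}{per-component list of restarts when
#'     `keep_candidates = TRUE`.}
#' @examples
#' gt <- synthesize_mixture(c("laplace", "uniform", "gaussian"), 5000, seed = 7)
#' fit <- ordering_ica(gt$x, l_candidates = 16, seed = 7)
#' fit$upsilons  # descending: Laplace, uniform, Gaussian
#' @export
ordering_ica <- function(x, l_candidates = default_candidate_count(),
                         k_max = 30L, eps = 1e-6, seed = 1L,
                         whiten = TRUE, workers = 1L,
                         keep_candidates = FALSE,
                         degenerate_tolerance = 1e-12) {
  x <- as_signal_matrix(x)
  if (!is.numeric(l_candidates) || l_candidates < 1)
    oi_stop("orderica_domain_error", "`l_candidates` must be >= 1")
  l_candidates <- as.integer(l_candidates)
  n <- nrow(x)
  model <- NULL
  if (isTRUE(whiten)) {
    wh <- whiten(x)
    x_white <- wh$x
    model <- wh$model
  } else {
    x_white <- x
  }
  seeds <- candidate_seeds(seed, n, l_candidates)
  apply_fun <- if (workers > 1L && .Platform$OS.type == "unix") {
    function(xs, f) parallel::mclapply(xs, f, mc.cores = workers)
  } else {
    function(xs, f) lapply(xs, f)
  }

  w_matrix <- matrix(numeric(0), 0L, n)
  alphas <- numeric(n)
  conv_counts <- integer(n)
  all_candidates <- if (keep_candidates) vector("list", n) else NULL

  for (i in seq_len(n)) {
    e <- deflation_projector(w_matrix, n)
    cands <- NULL
    for (batch in 1:2) {
      cands <- apply_fun(seeds[, batch, i], function(s)
        run_one_candidate(s, n, x_white, e, k_max, eps,
                          degenerate_tolerance))
      if (any(vapply(cands, `[[`, logical(1), "converged"))) break
      if (batch == 2L)
        oi_stop("orderica_convergence_error",
                "all %d candidates failed to converge twice for component %d",
                l_candidates, i)
    }
    conv <- vapply(cands, `[[`, logical(1), "converged")
    alpha_l <- vapply(cands, `[[`, numeric(1), "alpha")
    score <- rep(-Inf, l_candidates)
    ok <- conv & is.finite(alpha_l) & alpha_l > -2
    score[ok] <- upsilon(alpha_l[ok])
    best <- which.max(score)   # ties: lowest index
    w_matrix <- rbind(w_matrix, cands[[best]]$w)
    alphas[i] <- alpha_l[best]
    conv_counts[i] <- sum(conv)
    if (keep_candidates) all_candidates[[i]] <- cands
  }
  rownames(w_matrix) <- NULL
  ups <- upsilon(alphas)
  unmixing <- if (is.null(model)) w_matrix else w_matrix %*% model$transform
  mixing_estimate <- if (is.null(model)) t(w_matrix) else
    model$inverse_transform %*% t(w_matrix)
  structure(
    list(w_matrix = w_matrix, alphas = alphas, upsilons = ups,
         sources = w_matrix %*% x_white,
         mixing_estimate = mixing_estimate, unmixing = unmixing,
         whitening = model,
         run_meta = list(seed = as.integer(seed), L = l_candidates,
                         K = as.integer(k_max), eps = eps,
                         convergence_counts = conv_counts),
         candidates = all_candidates),
    class = "ordering_ica")
}

#' @export
print.ordering_ica <- function(x, ...) {
  n <- nrow(x$w_matrix)
  cat(sprintf("Ordering ICA fit: %d components (L = %d, K = %d, eps = %g, seed = %d)\n",
              n, x$run_meta$L, x$run_meta$K, x$run_meta$eps, x$run_meta$seed))
  tab <- data.frame(component = seq_len(n),
                    kurtosis = signif(x$alphas, 5),
                    upsilon = signif(x$upsilons, 5),
                    converged = x$run_meta$convergence_counts)
  print(tab, row.names = FALSE)
  invisible(x)
}
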