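#' Divergence between two separating directions
#'
#' \deqn{\delta = 1 - |\cos(w_a, w_b)|}
#' The sign of an ICA direction is arbitrary, so the absolute cosine is
#' used: 0 iff the directions coincide up to sign, 1 iff orthogonal.  A
#' missing operand (a component absent from one run because its extraction
#' failed to converge) scores the maximum, 1.
#'
#' @param w_a,w_b numeric vectors of equal length; either may be `NULL` or
#'   all-`NA` to denote a missing component.
#' @return divergence in `[0, 1]`.
#' @examples
#' divergence(c(1, 0), c(1, 1))  # 1 - 1/sqrt(2)
#' @export
divergence <- function(w_a, w_b) {
  missing_a <- is.null(w_a) || all(is.na(w_a))
  missing_b <- is.null(w_b) || all(is.na(w_b))
  if (missing_a || missing_b) return(1)
  na <- sqrt(sum(w_a * w_a))
  nb <- sqrt(sum(w_b * w_b))
  if (na == 0 || nb == 0)
    oi_stop("orderica_domain_error", "divergence of a zero-norm vector is undefined")
  if (length(w_a) != length(w_b))
    oi_stop("orderica_data_error", "vectors must have equal length")
  # clamp: rounding can push |cos| epsilon above 1
  1 - min(1, abs(sum(w_a * w_b)) / (na * nb))
}

#' Align separating matrices from repeated runs
#'
#' Sorts the rows of every run by \eqn{\Upsilon(\alpha)} descending, so
#' that the i-th row of each aligned matrix refers to the i-th most
#' non-Gaussian component.  This removes the permutation ambiguity before
#' run-to-run comparison.  Runs that extracted fewer than the maximum
#' number of components are padded with `NA` rows; every comparison
#' against a padded row scores divergence 1.
#'
#' @param runs list of [ordering_ica()] fits, or of lists with fields
#'   `w_matrix` and `alphas` (or `upsilons`).
#' @return list of aligned matrices, all with the same number of rows.
#' @export
align_runs <- function(runs) {
  stopifnot(is.list(runs), length(runs) >= 1L)
  mats <- lapply(runs, function(r) {
    ups <- if (!is.null(r$upsilons)) r$upsilons else upsilon(r$alphas)
    w <- r$w_matrix
    stopifnot(length(ups) == nrow(w))
    w[order(ups, decreasing = TRUE), , drop = FALSE]
  })
  n_max <- max(vapply(mats, nrow, integer(1)))
  lapply(mats, function(w) {
    if (nrow(w) < n_max)
      w <- rbind(w, matrix(NA_real_, n_max - nrow(w), ncol(w)))
    w
  })
}

#' Mean fluctuation of one component across runs
#'
#' Average divergence over all `T*(T-1)/2` unordered pairs of runs for the
#' i-th (non-Gaussianity-ranked) component:
#' \deqn{\bar\delta(i) = \frac{\sum_{p=1}^{T}\sum_{q>p}^{T} \delta(i,p,q)}{T(T-1)/2}}
#' Zero means the component is reproduced identically (up to sign) in
#' every run — the unique-solution regime.
#'
#' @param aligned list of T aligned matrices from [align_runs()].
#' @param component row index i.
#' @return mean divergence in `[0, 1]`.
#' @export
mean_fluctuation <- function(aligned, component) {
  t_runs <- length(aligned)
  if (t_runs < 2L)
    oi_stop("orderica_data_error", "need at least 2 runs, got %d", t_runs)
  total <- 0
  for (p in seq_len(t_runs - 1L))
    for (q in (p + 1L):t_runs)
      total <- total + divergence(aligned[[p]][component, ],
                                  aligned[[q]][component, ])
  total / (t_runs * (t_runs - 1L) / 2)
}

#' Fluctuation profile across all components
#'
#' Convenience wrapper: aligns the runs and computes [mean_fluctuation()]
#' for every component rank.
#'
#' @param runs list of [ordering_ica()] fits (T >= 2).
#' @return numeric vector \eqn{\bar\delta(i)}, one entry per component rank.
#' @export
fluctuation_profile <- function(runs) {
  aligned <- align_runs(runs)
  vapply(seq_len(nrow(aligned[[1L]])), function(i)
    mean_fluctuation(aligned, i), numeric(1))
}

#' Empirical success rate of one component's restarts
#'
#' With all `L_max` restarts of one component retained, the best candidate
#' (highest \eqn{\Upsilon}) is taken as the unique global solution and the
#' success rate is the fraction of restarts that landed within `eps`
#' divergence of it:
#' \deqn{\bar\mu_i = \#\{k : \delta(i, k, \hat k) < \epsilon\} / L_{max}}
#' This estimates the probability that a single random restart finds the
#' global optimum.  Diverged restarts (non-converged or non-finite
#' kurtosis) cannot enter the set, so the minimum is `1/L_max` (the best
#' candidate always matches itself).
#'
#' @param candidates list of `L_max` restarts for one component, each with
#'   fields `w`, `alpha`, `converged` (as stored by
#'   `ordering_ica(keep_candidates = TRUE)`).
#' @param best_index index \eqn{\hat k} of the selected candidate; by
#'   default the converged candidate with the highest \eqn{\Upsilon}.
#' @param eps divergence threshold (default 0.001).
#' @return success rate in `[1/L_max, 1]`, or `NA` if every candidate
#'   diverged (such components are dropped from downstream analysis).
#' @export
success_rate <- function(candidates, best_index = NULL, eps = 0.001) {
  l_max <- length(candidates)
  if (l_max == 0L)
    oi_stop("orderica_data_error", "empty candidate set")
  conv <- vapply(candidates, function(c) isTRUE(c$converged) &&
                   is.finite(c$alpha) && c$alpha > -2, logical(1))
  if (!any(conv)) return(NA_real_)
  if (is.null(best_index)) {
    score <- rep(-Inf, l_max)
    score[conv] <- upsilon(vapply(candidates[conv], `[[`, numeric(1), "alpha"))
    best_index <- which.max(score)
  }
  w_best <- candidates[[best_index]]$w
  hits <- vapply(seq_len(l_max), function(k) {
    conv[k] && divergence(candidates[[k]]$w, w_best) < eps
  }, logical(1))
  sum(hits) / l_max
}

#' Failure rates implied by per-restart success rates
#'
#' If one restart finds the i-th component's global optimum with
#' probability \eqn{\mu_i}, then with L independent restarts the component
#' fails with \deqn{\nu_i^{each} = (1 - \mu_i)^L} (assuming all preceding
#' components were found), and the probability that the pipeline has
#' failed by component i follows the recurrence
#' \deqn{\nu_i^{total} = \nu_{i-1}^{total} + (1 - \nu_{i-1}^{total})\,\nu_i^{each}}
#' with \eqn{\nu_0^{total} = 0}, i.e. the complement of the product of
#' per-component successes.
#'
#' @param mu vector of success rates \eqn{\mu_i}, each in `(0, 1]`.
#' @param l_candidates number of restarts L deployed per component.
#' @return list with vectors `each` and `total`.
#' @export
failure_rates <- function(mu, l_candidates) {
  if (!is.numeric(mu) || any(!is.finite(mu)) || any(mu <= 0) || any(mu > 1))
    oi_stop("orderica_domain_error", "`mu` values must lie in (0, 1]")
  if (l_candidates < 1)
    oi_stop("orderica_domain_error", "`l_candidates` must be >= 1")
  each <- (1 - mu)^l_candidates
  total <- numeric(length(mu))
  prev <- 0
  for (i in seq_along(mu)) {
    prev <- prev + (1 - prev) * each[i]
    total[i] <- prev
  }
  list(each = each, total = total)
}

#' Log-log regression of success rate on non-Gaussianity
#'
#' Fits \deqn{\log_{10}\mu_i = \hat\beta_1 + \hat\beta_2 \log_{10}\Upsilon(\alpha_i)}
#' by ordinary least squares.  The observed relation between
#' non-Gaussianity and the restart success rate is approximately linear on
#' this scale, which lets the failure rate of strongly non-Gaussian
#' components be predicted from their score alone.
#'
#' @param upsilons per-component scores, all `> 0`.
#' @param mus per-component success rates, all `> 0` (components whose
#'   restarts all diverged must be excluded beforehand).
#' @return named vector `c(beta1, beta2)` (intercept, slope).
#' @export
fit_success_model <- function(upsilons, mus) {
  keep <- is.finite(upsilons) & is.finite(mus)
  upsilons <- upsilons[keep]; mus <- mus[keep]
  if (length(upsilons) < 2L)
    oi_stop("orderica_data_error", "need at least 2 points to fit")
  if (any(upsilons <= 0) || any(mus <= 0))
    oi_stop("orderica_domain_error", "all upsilon and mu values must be positive")
  fit <- lm(log10(mus) ~ log10(upsilons))
  b <- unname(coef(fit))
  c(beta1 = b[1L], beta2 = b[2L])
}

#' Analytic failure bound for strongly non-Gaussian components
#'
#' Empirically, components with \eqn{\Upsilon(\alpha) > 10} have restart
#' success rate \eqn{\mu > 10^{-1.5}} in almost all cases, so their
#' per-component failure rate with L restarts is bounded by
#' \deqn{(1 - 10^{-1.5})^L \simeq 10^{-0.0139 L}.}
#'
#' @param l_candidates number of restarts L (>= 0).
#' @return the bound; 1 when `l_candidates = 0`.
#' @examples
#' analytic_failure_bound(128)  # < 0.0164
#' analytic_failure_bound(256)  # < 3e-4
#' @export
analytic_failure_bound <- function(l_candidates) {
  if (!is.numeric(l_candidates) || any(l_candidates < 0))
    oi_stop("orderica_domain_error", "`l_candidates` must be >= 0")
  (1 - 10^-1.5)^l_candidates
}

#' Stability report for a batch of repeated runs
#'
#' Bundles the run-to-run fluctuation profile and, when one of the runs
#' retained its restart candidates, the per-component success rates,
#' failure-rate estimates and the log-log regression of success rate on
#' non-Gaussianity.
#'
#' @param runs list of [ordering_ica()] fits (`T >= 2`) or `NULL`.
#' @param candidate_run one `ordering_ica(keep_candidates = TRUE)` fit with
#'   `L_max` restarts retained, or `NULL`.
#' @param eps divergence threshold for [success_rate()].
#' @param l_deploy restart count L used for the failure-rate projection
#'   (defaults to the candidate run's own L).
#' @return object of class `"stability_report"` with fields
#'   `per_component_fluctuation`, `n_runs`, `success_rates`,
#'   `failure_each`, `failure_total`, `regression`.
#' @export
stability_report <- function(runs = NULL, candidate_run = NULL,
                             eps = 0.001, l_deploy = NULL) {
  out <- list(per_component_fluctuation = NULL, n_runs = 0L,
              success_rates = NULL, failure_each = NULL,
              failure_total = NULL, regression = NULL)
  if (!is.null(runs)) {
    out$per_component_fluctuation <- fluctuation_profile(runs)
    out$n_runs <- length(runs)
  }
  if (!is.null(candidate_run)) {
    stopifnot(!is.null(candidate_run$candidates))
    mu <- vapply(candidate_run$candidates, success_rate, numeric(1),
                 eps = eps)
    out$success_rates <- mu
    if (is.null(l_deploy)) l_deploy <- candidate_run$run_meta$L
    keep <- !is.na(mu)
    fr <- failure_rates(mu[keep], l_deploy)
    out$failure_each <- replace(rep(NA_real_, length(mu)), keep, fr$each)
    # total failure over the components that could be analysed
    out$failure_total <- replace(rep(NA_real_, length(mu)), keep, fr$total)
    ups <- candidate_run$upsilons
    fit_keep <- keep & is.finite(ups) & ups > 0 & mu > 0
    if (sum(fit_keep) >= 2L)
      out$regression <- fit_success_model(ups[fit_keep], mu[fit_keep])
  }
  structure(out, class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Stability report\n")
  if (!is.null(x$per_component_fluctuation)) {
    cat(sprintf("  fluctuation over %d runs: ", x$n_runs))
    cat(signif(x$per_component_fluctuation, 3), "\n")
  }
  if (!is.null(x$success_rates)) {
    cat("  success rates: ", signif(x$success_rates, 3), "\n")
    if (!is.null(x$regression))
      cat(sprintf("  log10(mu) = %.3f + %.3f log10(upsilon)\n",
                  x$regression["beta1"], x$regression["beta2"]))
  }
  invisible(x)
}
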