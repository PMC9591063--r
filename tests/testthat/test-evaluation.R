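test_that("divergence reproduces its defining cases", {
  w <- c(0.3, -0.8, 0.5)
  expect_equal(divergence(w, w), 0)
  expect_equal(divergence(w, -w), 0)
  expect_equal(divergence(c(1, 0), c(0, 1)), 1)
  expect_equal(divergence(c(1, 0), c(1, 1)), 1 - 1 / sqrt(2))
  expect_equal(divergence(NULL, w), 1)          # missing component
  expect_equal(divergence(w, rep(NA_real_, 3)), 1)
  expect_error(divergence(c(0, 0), w), class = "orderica_domain_error")
})

test_that("divergence is symmetric, bounded, and scale/sign invariant", {
  set.seed(44)
  for (rep in 1:25) {
    n <- sample(2:10, 1)
    a <- rnorm(n); b <- rnorm(n)
    d <- divergence(a, b)
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(d, divergence(b, a))
    expect_equal(d, divergence(3.7 * a, b))
    expect_equal(d, divergence(-a, 0.01 * b))
  }
})

test_that("mean fluctuation averages pairwise divergences", {
  w <- list(w_matrix = rbind(c(1, 0), c(0, 1)), alphas = c(3, -1.2))
  aligned <- align_runs(list(w, w, w))
  expect_equal(mean_fluctuation(aligned, 1), 0)
  expect_equal(mean_fluctuation(aligned, 2), 0)

  # T = 2: the single pair
  a2 <- align_runs(list(
    list(w_matrix = matrix(c(1, 0), 1), alphas = 3),
    list(w_matrix = matrix(c(1, 1), 1), alphas = 3)))
  expect_equal(mean_fluctuation(a2, 1), 1 - 1 / sqrt(2))

  # T = 3 with pairwise deltas 0, 0.3, 0.3 -> mean 0.2
  th <- acos(0.7)   # delta(u0, u_th) = 0.3
  u <- function(t) matrix(c(cos(t), sin(t)), 1)
  a3 <- align_runs(list(list(w_matrix = u(0), alphas = 3),
                        list(w_matrix = u(0), alphas = 3),
                        list(w_matrix = u(th), alphas = 3)))
  expect_equal(mean_fluctuation(a3, 1), 0.2)
  expect_error(mean_fluctuation(a3[1], 1), class = "orderica_data_error")
})

test_that("alignment removes permutations and pads missing components", {
  r1 <- list(w_matrix = rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
             alphas = c(5, 2, 1))
  r2 <- list(w_matrix = rbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, 1)),
             alphas = c(2, 5, 1))    # same directions, swapped order
  prof <- fluctuation_profile(list(r1, r2))
  expect_equal(prof, c(0, 0, 0))

  r3 <- list(w_matrix = rbind(c(1, 0, 0), c(0, 1, 0)), alphas = c(5, 2))
  prof2 <- fluctuation_profile(list(r1, r3))
  expect_equal(prof2, c(0, 0, 1))   # absent third component scores 1
})

test_that("success rate counts candidates near the selected optimum", {
  cand <- function(w, alpha = 3, converged = TRUE)
    list(w = w, alpha = alpha, converged = converged)
  base <- c(1, 0)
  all_same <- replicate(10, cand(base), simplify = FALSE)
  expect_equal(success_rate(all_same), 1)

  # only the best is near itself
  spread <- c(list(cand(base, alpha = 5)),
              replicate(9, cand(c(0, 1)), simplify = FALSE))
  expect_equal(success_rate(spread), 1 / 10)

  # 3 of 10 within eps (sign flips count as the same direction)
  three <- c(list(cand(base, alpha = 5), cand(-base, alpha = 5),
                  cand(base * 2, alpha = 5)),
             replicate(7, cand(c(0, 1)), simplify = FALSE))
  expect_equal(success_rate(three), 0.3)

  # diverged candidates cannot enter the set even if their w matches
  with_div <- c(list(cand(base, alpha = 5)),
                replicate(4, cand(base, converged = FALSE), simplify = FALSE))
  expect_equal(success_rate(with_div), 1 / 5)
  expect_true(is.na(success_rate(replicate(4, cand(base, converged = FALSE),
                                           simplify = FALSE))))
  expect_error(success_rate(list()), class = "orderica_data_error")
})

test_that("failure rates follow (1-mu)^L and its recurrence", {
  expect_equal(failure_rates(1, 64)$each, 0)
  fr <- failure_rates(10^-1.5, 128)
  expect_lt(fr$each, 0.0164)
  expect_equal(fr$each, (1 - 10^-1.5)^128)

  # constant per-component rate c gives total 1 - (1-c)^i
  mu <- rep(0.3, 6)
  fr2 <- failure_rates(mu, 2)
  c0 <- (1 - 0.3)^2
  expect_equal(fr2$total, 1 - (1 - c0)^(1:6))
  # total is non-decreasing and equals the product form for random mu
  set.seed(5)
  mu3 <- runif(8, 0.05, 1)
  fr3 <- failure_rates(mu3, 16)
  expect_true(all(diff(fr3$total) >= 0))
  expect_equal(fr3$total, 1 - cumprod(1 - fr3$each))
  expect_error(failure_rates(c(0.5, 0), 4), class = "orderica_domain_error")
})

test_that("the log-log success model is recovered by least squares", {
  ups <- c(0.5, 1, 2, 5, 10, 20)
  mus <- 10^(-0.9) * ups^0.12          # exact power law
  b <- fit_success_model(ups, mus)
  expect_equal(unname(b), c(-0.9, 0.12), tolerance = 1e-10)

  b2 <- fit_success_model(c(1, 10), c(0.1, 0.5))   # exact interpolation
  expect_equal(10^(b2[["beta1"]] + b2[["beta2"]] * log10(10)), 0.5,
               tolerance = 1e-10)

  # power law + log-space noise: recovery within 3 standard errors
  set.seed(77)
  ups3 <- 10^runif(200, -1, 1.5)
  mus3 <- 10^(-0.7 + 0.2 * log10(ups3) + rnorm(200, sd = 0.1))
  fit <- lm(log10(mus3) ~ log10(ups3))
  se <- sqrt(diag(vcov(fit)))
  b3 <- fit_success_model(ups3, mus3)
  expect_lt(abs(b3[["beta1"]] + 0.7), 3 * se[1])
  expect_lt(abs(b3[["beta2"]] - 0.2), 3 * se[2])
  expect_error(fit_success_model(1, 0.1), class = "orderica_data_error")
})

test_that("analytic failure bound and its decay coefficient", {
  expect_lte(analytic_failure_bound(128), 0.0164)
  expect_lte(analytic_failure_bound(256), 3e-4)
  expect_equal(analytic_failure_bound(0), 1)
  expect_gte(-log10(1 - 10^-1.5), 0.0139)
  # monotone decreasing in L
  expect_true(all(diff(analytic_failure_bound(c(1, 8, 64, 512))) < 0))
})

test_that("stability report bundles fluctuation, success and regression", {
  gt <- toy_mixture(seed = 55, m = 6000)
  runs <- lapply(1:3, function(s)
    ordering_ica(gt$x, l_candidates = 16, seed = s))
  cand_run <- ordering_ica(gt$x, l_candidates = 40, seed = 9,
                           keep_candidates = TRUE)
  rep <- stability_report(runs = runs, candidate_run = cand_run,
                          l_deploy = 16)
  expect_length(rep$per_component_fluctuation, 3)
  expect_true(all(rep$per_component_fluctuation >= 0 &
                    rep$per_component_fluctuation <= 1))
  mu <- rep$success_rates
  expect_true(all(is.na(mu) | (mu >= 1 / 40 & mu <= 1)))
  ok <- !is.na(mu)
  expect_equal(rep$failure_each[ok], (1 - mu[ok])^16)
})
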