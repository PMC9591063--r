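test_that("upsilon matches hand-evaluated values and guards its domain", {
  expect_equal(upsilon(0), 0)
  expect_equal(upsilon(3), 1.16741854, tolerance = 1e-4 / 1.17)
  expect_equal(upsilon(-1.2), 0.63258146, tolerance = 1e-4 / 0.63)
  # non-negative, zero only at 0
  a <- seq(-1.9, 25, by = 0.1)
  u <- upsilon(a)
  expect_true(all(u >= 0))
  expect_true(all(u[abs(a) > 1e-9] > 0))
  expect_error(upsilon(-2), class = "orderica_domain_error")
  expect_error(upsilon(-2.5), class = "orderica_domain_error")
})

test_that("default candidate count follows L = cores * R with a floor of 1", {
  expect_identical(default_candidate_count(32, 1), 32L)
  expect_identical(default_candidate_count(32, 4), 128L)
  expect_identical(default_candidate_count(1, 0.25), 1L)
  expect_error(default_candidate_count(0, 1), class = "orderica_domain_error")
  expect_error(default_candidate_count(4, 0), class = "orderica_domain_error")
})

test_that("sources mixed by the identity are recovered as a signed permutation", {
  gt <- synthesize_mixture(c("laplace", "uniform", "gaussian"), 20000,
                           seed = 19, mixing = "identity")
  fit <- ordering_ica(gt$x, l_candidates = 32, seed = 19)
  # rows of the unmixing matrix (original space) against coordinate axes
  for (i in 1:3) {
    w <- fit$unmixing[i, ]
    expect_gte(max(abs(w) / sqrt(sum(w * w))), 0.99)
  }
  rs <- recovery_score(fit, gt)
  expect_true(all(rs$scores >= 0.99))
  expect_true(rs$order_agreement)
})

test_that("extraction order follows descending upsilon on a known mixture", {
  gt <- synthesize_mixture(c("uniform", "gaussian", "laplace"), 50000,
                           seed = 23)
  fit <- ordering_ica(gt$x, l_candidates = 64, seed = 23)
  rs <- recovery_score(fit, gt)
  # Laplace (ups 1.167) first, uniform (0.633) second, Gaussian last
  expect_identical(rs$matched_source, c(3L, 1L, 2L))
  expect_true(rs$order_agreement)
  expect_true(all(diff(fit$upsilons) <= 1e-12))
})

test_that("results are bit-reproducible for equal (seed, L) and any worker count", {
  gt <- toy_mixture(seed = 29)
  f1 <- ordering_ica(gt$x, l_candidates = 8, seed = 101)
  f2 <- ordering_ica(gt$x, l_candidates = 8, seed = 101)
  expect_identical(f1$w_matrix, f2$w_matrix)
  expect_identical(f1$alphas, f2$alphas)
  f3 <- ordering_ica(gt$x, l_candidates = 8, seed = 101, workers = 2)
  expect_identical(f1$w_matrix, f3$w_matrix)
  f4 <- ordering_ica(gt$x, l_candidates = 8, seed = 102)
  expect_false(identical(f1$w_matrix, f4$w_matrix))
})

test_that("the final component is forced by orthogonality whatever L is", {
  gt <- synthesize_mixture(c("laplace", "uniform"), 8000, seed = 31)
  f_small <- ordering_ica(gt$x, l_candidates = 1, seed = 1)
  f_large <- ordering_ica(gt$x, l_candidates = 16, seed = 999)
  # first rows agree up to sign (same global optimum), so the residual
  # 1-D subspace and hence the last row is determined up to sign
  expect_gte(abs(sum(f_small$w_matrix[2, ] * f_large$w_matrix[2, ])), 1 - 1e-6)
})

test_that("rows of the separating matrix are orthonormal in the whitened space", {
  gt <- synthesize_mixture(c("laplace", "uniform", "gaussian", "bimodal_mixture(2)"),
                           10000, seed = 37)
  fit <- ordering_ica(gt$x, l_candidates = 16, seed = 37)
  g <- tcrossprod(fit$w_matrix)
  expect_lt(max(abs(g - diag(4))), 1e-6)
  expect_true(all(is.finite(fit$upsilons)) && all(fit$upsilons >= 0))
  # mixing estimate maps back through the whitening model
  expect_lt(max(abs(fit$mixing_estimate %*% fit$unmixing %*%
                      (gt$x - rowMeans(gt$x)) -
                      (gt$x - rowMeans(gt$x)))), 1e-6)
})

test_that("monotone ordering holds across seeded repetitions", {
  ok <- 0L
  for (s in 1:20) {
    gt <- synthesize_mixture(c("laplace", "uniform", "gaussian"), 5000,
                             seed = 700 + s)
    fit <- ordering_ica(gt$x, l_candidates = 64, seed = s)
    if (all(diff(fit$upsilons) <= 0.05)) ok <- ok + 1L
  }
  expect_gte(ok, 19L)
})

test_that("the first component's objective never degrades with more candidates", {
  ls <- c(1L, 4L, 16L, 64L)
  mean_ups <- vapply(ls, function(l) {
    vals <- vapply(1:50, function(s) {
      gt <- synthesize_mixture(c("laplace", "uniform"), 2000, seed = 4000 + s)
      ordering_ica(gt$x, l_candidates = l, seed = s)$upsilons[1L]
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  # non-decreasing in L up to sampling noise
  expect_true(all(diff(mean_ups) >= -0.02))
})

test_that("first extracted direction attains the grid-search optimum (N = 2)", {
  for (s in 1:10) {
    gt <- synthesize_mixture(c("laplace", "uniform"), 20000, seed = 60 + s)
    xw <- whiten(gt$x)
    fit <- ordering_ica(xw$x, l_candidates = 64, seed = s, whiten = FALSE)
    expect_lte(grid_phi_max(xw$x) - fit$upsilons[1L], 1e-4)
  }
})
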