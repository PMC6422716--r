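test_that("glasso solves the independence and full-sparsity cases exactly", {
  S <- diag(4)
  for (lam in c(0, 0.3, 1)) {
    fit <- glasso_solve(S, lam)
    expect_equal(fit$theta, diag(4), tolerance = 1e-10)
  }
  # any penalty at or above max |S_ij| empties the network, and the
  # diagonal of the working covariance stays at diag(S)
  S2 <- matrix(c(1, 0.5, 0.2,
                 0.5, 1, -0.4,
                 0.2, -0.4, 1), 3, 3)
  fit2 <- glasso_solve(S2, 0.5 + 1e-12)
  expect_true(all(fit2$theta[upper.tri(fit2$theta)] == 0))
  expect_equal(diag(fit2$w), diag(S2))
})

test_that("the unpenalized solution matches the matrix inverse", {
  X <- withr::with_seed(10, matrix(rnorm(500 * 6), 500, 6))
  X[, 2] <- X[, 2] + 0.5 * X[, 1]
  X[, 5] <- X[, 5] - 0.7 * X[, 4]
  S <- stats::cor(X)
  fit <- glasso_solve(S, 0)
  expect_lt(max(abs(fit$theta - solve(S))), 1e-4)
})

test_that("precision-to-partial follows the standard formula", {
  expect_equal(precision_to_partial(diag(3)), matrix(0, 3, 3))
  Theta <- matrix(c(2, -1, -1, 2), 2, 2)
  expect_equal(precision_to_partial(Theta)[1, 2], 0.5)
  expect_error(precision_to_partial(matrix(c(-1, 0, 0, 1), 2, 2)),
               "positive")

  # residual-correlation oracle on a random PD precision: the partials of
  # Theta equal the regression-residual partials of a large sample from
  # the implied Gaussian
  Theta4 <- withr::with_seed(2, {
    A <- matrix(rnorm(16), 4, 4)
    crossprod(A) + diag(4)
  })
  W <- precision_to_partial(Theta4)
  X <- withr::with_seed(3, MASS::mvrnorm(40000, rep(0, 4), solve(Theta4)))
  P <- oracle_partial_correlations(X)
  expect_lt(max(abs(W - P)), 0.03)
})

test_that("BIC combines the Gaussian log-likelihood and the edge penalty", {
  # identity model, p = 2, n = 100: loglik = (n/2)(0 - 2) = -100, E = 0
  expect_equal(bic_score(diag(2), diag(2), 100), 200)
  # independent recomputation on a random PD pair
  Theta <- matrix(c(1.5, -0.4, 0, -0.4, 1.2, 0.1, 0, 0.1, 0.9), 3, 3)
  S <- stats::cov2cor(solve(Theta))
  n <- 250
  ll <- (n / 2) * (log(det(Theta)) - sum(diag(S %*% Theta)))
  expect_equal(bic_score(Theta, S, n), -2 * ll + 2 * log(n))
  # one additional edge with (numerically) no likelihood change costs
  # exactly log(n)
  Theta2 <- Theta
  Theta2[1, 3] <- Theta2[3, 1] <- 1e-12
  expect_equal(bic_score(Theta2, S, n) - bic_score(Theta, S, n), log(n),
               tolerance = 1e-6)
  expect_error(bic_score(diag(3), diag(3), 2), "exceed")
})

test_that("lambda grid spans [ratio * max|S|, max|S|] in descending order", {
  S <- matrix(c(1, 0.8, 0.1, 0.8, 1, -0.3, 0.1, -0.3, 1), 3, 3)
  g <- lambda_grid(S, n_lambda = 50, ratio = 0.01)
  expect_equal(g[1], 0.8)
  expect_equal(g[50], 0.008)
  expect_true(all(diff(g) < 0))
  expect_equal(lambda_grid(S, n_lambda = 2, ratio = 0.01), c(0.8, 0.008))
  expect_warning(g0 <- lambda_grid(diag(3)), "zero")
  expect_equal(g0, 0)
})

test_that("BIC selection recovers the planted structure at large n", {
  m <- two_block_model(0.3)
  coh <- sample_cohort(cohort_spec(list(g = m), c(g = 5000), seed = 21))
  fit <- suppressWarnings(estimate_network(as_score_matrix(coh[, m$labels], "g")))
  expect_identical(unname(fit$W != 0), unname(m$partial != 0))
  # estimated weights close to the planted partial correlations
  on_edges <- m$partial != 0
  expect_lt(max(abs(fit$W[on_edges] - m$partial[on_edges])), 0.05)
  expect_true(fit$path$selected[which.min(fit$path$bic)])
})

test_that("independent variables yield an empty selected network", {
  X <- withr::with_seed(30, matrix(rnorm(10000 * 9), 10000, 9))
  fit <- suppressWarnings(estimate_network(as_score_matrix(X, "null")))
  expect_equal(sum(fit$W != 0), 0)
})

test_that("the selected network is invariant to rescaling of the scores", {
  m <- two_block_model(0.3)
  coh <- sample_cohort(cohort_spec(list(g = m), c(g = 800), seed = 22))
  X <- as.matrix(coh[, m$labels])
  X2 <- sweep(X, 2, c(100, 0.01, 3, 7, 1, 42, 5, 0.5, 9), `*`)
  f1 <- suppressWarnings(estimate_network(as_score_matrix(X, "g")))
  f2 <- suppressWarnings(estimate_network(as_score_matrix(X2, "g")))
  expect_equal(f1$W, f2$W, tolerance = 1e-10)
})

test_that("BIC prefers the true sparse chain over the full model", {
  # 3-variable chain x1 - x2 - x3: true support has 2 edges
  Theta <- matrix(c(1, -0.3, 0, -0.3, 1, -0.3, 0, -0.3, 1), 3, 3)
  wins_true <- wins_full <- 0
  for (r in 1:50) {
    X <- withr::with_seed(600 + r, MASS::mvrnorm(1000, rep(0, 3), solve(Theta)))
    fit <- suppressWarnings(estimate_network(as_score_matrix(X, "chain")))
    ne <- sum(fit$W[upper.tri(fit$W)] != 0)
    pattern_true <- fit$W[1, 2] != 0 && fit$W[2, 3] != 0 && fit$W[1, 3] == 0
    if (pattern_true) wins_true <- wins_true + 1
    if (ne == 3) wins_full <- wins_full + 1
  }
  expect_gt(wins_true, wins_full)
  expect_gt(wins_true, 40) # true 2-edge model dominates at n = 1000
})

test_that("fixture frontal network is led by the memory edge", {
  mods <- study_models()
  coh <- make_study_fixture(seed = 12, n = c(control = 100, nonfrontal = 100,
                                             frontal = 6000))
  sm <- split_complete_cases(coh)
  fit <- suppressWarnings(estimate_network(sm$frontal))
  w <- fit$W["15T", "15R"]
  expect_gt(w, 0)
  expect_equal(max(abs(fit$W)), w) # largest-magnitude edge
})

test_that("tidy and glance expose the fitted network the broom way", {
  m <- two_block_model(0.4)
  coh <- sample_cohort(cohort_spec(list(g = m), c(g = 600), seed = 31))
  fit <- suppressWarnings(estimate_network(as_score_matrix(coh[, m$labels], "g")))
  td <- tidy(fit)
  expect_true(all(c("from", "to", "weight", "group") %in% names(td)))
  expect_true(all(td$weight != 0))
  expect_equal(nrow(tidy(fit, all = TRUE)), 36)
  gl <- glance(fit)
  expect_equal(gl$edges, nrow(td))
  expect_equal(gl$n, 600)
})
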