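test_that("ramp loss clamps, is nondecreasing and 1-Lipschitz", {
  expect_equal(ramp_loss(c(-0.5, 0.5, 2)), c(0, 0.5, 1))
  x <- sort(runif(100, -3, 3))
  expect_true(all(diff(ramp_loss(x)) >= 0))
  expect_true(all(abs(diff(ramp_loss(x))) <= diff(x) + 1e-12))
})

test_that("multistage surrogate is the min of per-stage ramps", {
  expect_equal(multistage_surrogate(c(0.5, 2)), 0.5)
  expect_equal(multistage_surrogate(c(-1, 0.9)), 0)
  expect_equal(multistage_surrogate(c(1, 1, 1)), 1)
})

test_that("surrogate equals the product indicator for saturated margins", {
  set.seed(1)
  for (r in 1:50) {
    u <- sample(c(-1, 1), 3, TRUE) * runif(3, 1, 5)
    expect_equal(multistage_surrogate(u), prod(u > 0))
  }
})

test_that("alternative sequences enumerate exactly 2^T - 1 deviations", {
  d <- tiny_trajectory()
  terms <- surrogate_terms(d)
  # every subject has |Y| > 0: positives contribute 1 term, negatives 3
  n_pos <- sum(d$Y > 0)
  n_neg <- sum(d$Y < 0)
  expect_identical(length(terms$w), n_pos + 3L * n_neg)
  expect_true(all(terms$w >= 0))
})

test_that("hand-enumerated single-subject surrogate values are reproduced", {
  # positive part: Y = 2, both propensities 0.5, margins (1, 1)
  d <- trajectory_data(
    stages = list(list(H = cbind(Z = 0), A = 1, p = 0.5),
                  list(H = cbind(Z = 0), A = 1, p = 0.5)),
    Y = 2)
  theta <- dtr_coefficients(list(list(gamma = 1, beta = c(Z = 0)),
                                 list(gamma = 1, beta = c(Z = 0))))
  # w+ = 2 / 0.25 = 8, surrogate min(psi(1), psi(1)) = 1 -> sum-scale 8
  expect_equal(empirical_value_surrogate(theta, 1, d, "sum"), 8)
  expect_equal(empirical_value_surrogate(theta, 1, d, "mean"), 8)

  # negative part: Y = -1, margins +1 under exactly one alternative sequence
  d2 <- trajectory_data(
    stages = list(list(H = cbind(Z = 0), A = 1, p = 0.5),
                  list(H = cbind(Z = 0), A = 1, p = 0.5)),
    Y = -1)
  # g = (-1, -1): observed sequence (+1,+1) has margins (-1,-1); alternative
  # (-1,-1) has margins (1,1) -> surrogate 1; the two mixed alternatives have
  # one margin -1 -> 0.  w- = 1/0.25 = 4 -> sum-scale 4.
  theta2 <- dtr_coefficients(list(list(gamma = -1, beta = c(Z = 0)),
                                  list(gamma = -1, beta = c(Z = 0))))
  expect_equal(empirical_value_surrogate(theta2, 1, d2, "sum"), 4)
})

test_that("zero coefficients annihilate the objective", {
  theta0 <- dtr_coefficients(list(list(gamma = 0, beta = c(Z1 = 0, Z2 = 0)),
                                  list(gamma = 0, beta = c(Z1 = 0, Z2 = 0))))
  for (seed in 1:3) {
    d <- make_toy(15, seed = seed)
    expect_equal(empirical_value_surrogate(theta0, 10^-seed, d, "sum"), 0)
  }
})

test_that("vectorized surrogate agrees with term-by-term enumeration", {
  for (seed in 1:5) {
    d <- make_toy(3, seed = seed)
    theta <- dtr_coefficients(list(
      list(gamma = rnorm(1), beta = c(Z1 = rnorm(1), Z2 = rnorm(1))),
      list(gamma = rnorm(1), beta = c(Z1 = rnorm(1), Z2 = rnorm(1)))))
    for (eta in c(1, 0.37, 1e-3)) {
      expect_equal(empirical_value_surrogate(theta, eta, d, "mean"),
                   enumerate_surrogate(theta, eta, d, "mean"),
                   tolerance = 1e-12)
      expect_equal(empirical_value_surrogate(theta, eta, d, "sum"),
                   enumerate_surrogate(theta, eta, d, "sum"),
                   tolerance = 1e-12)
    }
  }
})

test_that("jointly rescaling coefficients and eta leaves the value unchanged", {
  d <- make_toy(10, seed = 9)
  theta <- dtr_coefficients(list(
    list(gamma = 0.3, beta = c(Z1 = -0.5, Z2 = 0.2)),
    list(gamma = -0.1, beta = c(Z1 = 0.4, Z2 = 0.7))))
  base <- empirical_value_surrogate(theta, 0.5, d, "mean")
  for (c_scale in c(0.2, 3, 40)) {
    scaled <- dtr_coefficients(lapply(theta$stages, function(s) {
      list(gamma = c_scale * s$gamma, alpha = c_scale * s$alpha,
           beta = c_scale * s$beta)
    }))
    expect_equal(empirical_value_surrogate(scaled, 0.5 * c_scale, d, "mean"),
                 base, tolerance = 1e-12)
  }
})

test_that("residualization removes an intercept and explainable variance", {
  # constant outcome, linear estimator: the intercept absorbs everything
  n <- 30
  set.seed(4)
  d <- trajectory_data(
    stages = list(list(H = cbind(Z1 = rnorm(n)), A = sample(c(-1, 1), n, TRUE),
                       p = rep(0.5, n))),
    Y = rep(3.7, n))
  res <- residualize_outcome(d, "linear")
  expect_lt(max(abs(res$Y)), 1e-10)

  # outcome driven by Z1: lasso residuals have much smaller variance
  set.seed(5)
  n <- 400
  Z1 <- rnorm(n)
  d2 <- trajectory_data(
    stages = list(list(H = cbind(Z1 = Z1, Z2 = rnorm(n)),
                       A = sample(c(-1, 1), n, TRUE), p = rep(0.5, n))),
    Y = 2 * Z1 + rnorm(n, sd = 0.5))
  res2 <- residualize_outcome(d2, "lasso")
  expect_lt(var(res2$Y), 0.5 * var(d2$Y))
  expect_equal(attr(res2, "conditional_mean")$kind, "lasso")
})

test_that("an intercept-only conditional mean centers the outcome", {
  # pure-noise outcome: the cross-validated lasso selects no features, so
  # residuals are exactly Y - mean(Y)
  set.seed(9)
  n <- 60
  d <- trajectory_data(
    stages = list(list(H = matrix(rnorm(n * 3), n,
                                  dimnames = list(NULL, c("a", "b", "c"))),
                       A = sample(c(-1, 1), n, TRUE), p = rep(0.5, n))),
    Y = rnorm(n))
  res <- residualize_outcome(d, "lasso")
  cv <- attr(res, "conditional_mean")$cv
  cf <- as.matrix(coef(cv, s = "lambda.min"))
  expect_true(all(abs(cf[-1, 1]) < 1e-12))
  expect_equal(res$Y, d$Y - mean(d$Y), tolerance = 1e-10)
})
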