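test_that("coordinate_minimize solves canonical one-dimensional problems", {
  expect_equal(coordinate_minimize(numeric(0), 0, l1_weight = 1), 0)
  expect_equal(coordinate_minimize(2, c(-1, 1), l1_weight = 0), 2)
  # 3*max(0, 1-x) + |x|: slopes -3 then 0; adding |x| gives -2 then +1 at 1
  expect_equal(coordinate_minimize(1, c(-3, 0), l1_weight = 1), 1)
  expect_error(coordinate_minimize(c(0, 1), c(1, 0.5, 2), 0), "non-convex")
})

test_that("coordinate_minimize matches dense grid search on random problems", {
  set.seed(31)
  box <- 3
  xs <- seq(-box, box, by = 1e-3)
  for (r in 1:200) {
    m <- sample(0:6, 1)
    breaks <- sort(runif(m, -2, 2))
    slopes <- runif(1, -6, 2) + c(0, cumsum(runif(m, 0, 3)))
    l1 <- sample(c(0, runif(1, 0, 2)), 1)
    xstar <- coordinate_minimize(breaks, slopes, l1, box = box)
    expect_true(abs(xstar) <= box)
    fx <- pwl_eval(xs, breaks, slopes, l1)
    expect_lte(pwl_eval(xstar, breaks, slopes, l1), min(fx) + 1e-9)
  }
})

test_that("an overwhelming penalty zeroes every candidate coefficient", {
  d <- make_toy(12, seed = 41)
  init <- dtr_coefficients(list(
    list(gamma = 1, beta = c(Z1 = 0.5, Z2 = -0.5)),
    list(gamma = -1, beta = c(Z1 = 0.5, Z2 = 0.5))))
  fit <- suppressWarnings(
    dc_fit(d, fit_config(1e-3, penalty_spec(1e8), init = init)))
  for (s in fit$theta$stages) expect_identical(unname(s$beta), c(0, 0))
})

test_that("the DC fit reaches the exhaustive grid optimum on a tiny instance", {
  set.seed(3)
  n <- 4
  d <- trajectory_data(
    stages = list(
      list(H = cbind(Z = rnorm(n)), A = c(1, -1, 1, -1), p = rep(0.5, n)),
      list(H = cbind(Z = rnorm(n)), A = c(1, 1, -1, -1), p = rep(0.5, n))),
    Y = c(2, -1, 1.5, -0.5))
  eta <- 1
  lam <- 0.05
  spec <- penalty_spec(lam, weights = c(Z = 1))

  # exhaustive oracle over [-2,2]^4, step 0.05 (intercept and slope per stage)
  terms <- surrogate_terms(d)
  gvals <- seq(-2, 2, by = 0.05)
  combo <- as.matrix(expand.grid(gamma = gvals, beta = gvals))
  ramp_grid <- function(t) {
    Hc <- d$stages[[t]]$H[terms$subject, 1]
    a <- terms$a[, t]
    u <- (outer(a, combo[, 1]) + outer(a * Hc, combo[, 2])) / eta
    matrix(pmax(pmin(u, 1), 0), nrow = length(a))
  }
  pen_grid <- lam * abs(combo[, 2])
  oracle <- l1mrl:::grid_objective_min_cpp(ramp_grid(1), ramp_grid(2),
                                           terms$w, pen_grid, pen_grid, n)

  # a handful of canonical starts (the pipeline always starts from a pilot)
  starts <- list(c(1, 0, 1, 0), c(-1, 0, -1, 0), c(0.5, 1, 0.5, 1),
                 c(0.5, -1, 0.5, -1), c(1, 1, -1, 1))
  best <- Inf
  for (s in starts) {
    init <- dtr_coefficients(list(list(gamma = s[1], beta = c(Z = s[2])),
                                  list(gamma = s[3], beta = c(Z = s[4]))))
    f <- suppressWarnings(dc_fit(d, fit_config(eta, spec, init = init,
                                               box = 2)))
    expect_true(f$state$monotone)
    best <- min(best, utils::tail(f$state$objective, 1))
  }
  expect_lte(best, oracle + 1e-6)
})

test_that("a stationary starting point is returned unchanged", {
  d <- make_toy(10, seed = 55)
  init <- dtr_coefficients(list(
    list(gamma = 0.8, beta = c(Z1 = 0.3, Z2 = -0.2)),
    list(gamma = -0.4, beta = c(Z1 = 0.1, Z2 = 0.6))))
  fit1 <- suppressWarnings(
    dc_fit(d, fit_config(0.5, penalty_spec(0.1), init = init)))
  obj1 <- utils::tail(fit1$state$objective, 1)
  fit2 <- suppressWarnings(
    dc_fit(d, fit_config(0.5, penalty_spec(0.1), init = fit1$theta)))
  expect_lte(utils::tail(fit2$state$objective, 1), obj1 + 1e-9)
  expect_lte(fit2$state$iterations, 2L)
  expect_equal(unlist(lapply(fit2$theta$stages, `[[`, "beta")),
               unlist(lapply(fit1$theta$stages, `[[`, "beta")),
               tolerance = 1e-8)
})

test_that("the objective decreases monotonically on random instances", {
  set.seed(61)
  for (r in 1:20) {
    d <- make_toy(8)
    init <- dtr_coefficients(list(
      list(gamma = rnorm(1), beta = c(Z1 = rnorm(1), Z2 = rnorm(1))),
      list(gamma = rnorm(1), beta = c(Z1 = rnorm(1), Z2 = rnorm(1)))))
    eta <- sample(c(1, 0.1, 1e-3), 1)
    lam <- sample(c(0, 0.05, 1), 1)
    fit <- suppressWarnings(
      dc_fit(d, fit_config(eta, penalty_spec(lam), init = init)))
    expect_true(fit$state$monotone)
    expect_true(all(diff(fit$state$objective) <= 1e-9))
  }
})

test_that("dc_linearize equals the numeric gradient away from kinks", {
  set.seed(71)
  d <- make_toy(6, seed = 71)
  # small coefficients with eta = 1 keep all margins strictly inside (0, 1)
  # or (-1, 0): perturb until no margin is near 0
  repeat {
    theta <- dtr_coefficients(list(
      list(gamma = runif(1, 0.2, 0.4), beta = c(Z1 = runif(1, 0.01, 0.05),
                                                Z2 = runif(1, 0.01, 0.05))),
      list(gamma = runif(1, 0.2, 0.4), beta = c(Z1 = runif(1, 0.01, 0.05),
                                                Z2 = runif(1, 0.01, 0.05)))))
    g <- decision_values(theta, d)
    terms <- surrogate_terms(d)
    u <- terms$a * g[terms$subject, ]
    if (min(abs(u)) > 1e-3 && max(abs(u)) < 0.99) break
  }
  H_fun <- function(th) {
    g <- decision_values(th, d)
    u <- terms$a * g[terms$subject, ]
    sum(terms$w * rowSums(pmax(u, 0))) / d$n
  }
  sub <- dc_linearize(theta, d, eta = 1, terms = terms)
  eps <- 1e-7
  bump <- function(th, t, j, delta) {
    # coordinate layout matches dc_linearize: intercept first, then beta
    if (j == 1) th$stages[[t]]$gamma <- th$stages[[t]]$gamma + delta
    else th$stages[[t]]$beta[j - 1] <- th$stages[[t]]$beta[j - 1] + delta
    th
  }
  for (t in 1:2) {
    for (j in seq_along(sub[[t]])) {
      num <- (H_fun(bump(theta, t, j, eps)) -
                H_fun(bump(theta, t, j, -eps))) / (2 * eps)
      expect_equal(unname(sub[[t]][j]), num, tolerance = 1e-5)
    }
  }
})

test_that("dc_linearize at zero coefficients is the zero subgradient", {
  d <- make_toy(6, seed = 81)
  theta0 <- dtr_coefficients(list(
    list(gamma = 0, beta = c(Z1 = 0, Z2 = 0)),
    list(gamma = 0, beta = c(Z1 = 0, Z2 = 0))))
  sub <- dc_linearize(theta0, d, eta = 1)
  expect_true(all(vapply(sub, function(s) all(s == 0), logical(1))))
})

test_that("reward rescaling scales the objective and preserves decisions", {
  d <- make_toy(14, seed = 91)
  init <- dtr_coefficients(list(
    list(gamma = 0.5, beta = c(Z1 = 0.2, Z2 = -0.1)),
    list(gamma = -0.3, beta = c(Z1 = 0.4, Z2 = 0.2))))
  cfg <- fit_config(0.1, penalty_spec(0), init = init)
  fit1 <- suppressWarnings(dc_fit(d, cfg))
  d5 <- d
  d5$Y <- 5 * d$Y
  fit5 <- suppressWarnings(dc_fit(d5, cfg))
  expect_equal(fit5$state$objective, 5 * fit1$state$objective,
               tolerance = 1e-9)
  # decisions agree wherever the decision value is not on the boundary
  # (floating-point ties can resolve differently between the two runs)
  g1 <- decision_values(fit1$theta, d)
  g5 <- decision_values(fit5$theta, d)
  firm <- pmin(abs(g1), abs(g5)) > 1e-8
  expect_identical(sign(g1)[firm], sign(g5)[firm])
  expect_gt(mean(firm), 0.9)
})

test_that("hitting the coefficient box raises a warning", {
  d <- trajectory_data(
    stages = list(list(H = cbind(Z = 0), A = 1, p = 0.5)),
    Y = 1)
  init <- dtr_coefficients(list(list(gamma = 0.0005, beta = c(Z = 0))))
  expect_warning(
    dc_fit(d, fit_config(0.01, penalty_spec(0), init = init, box = 0.001)),
    "box bound")
})
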