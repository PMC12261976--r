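test_that("the hinge LP matches an independent LP solver on fixed instances", {
  skip_if_not_installed("pracma")
  # seeds chosen where pracma's dense solver is numerically stable
  for (seed in c(42, 101)) {
    set.seed(seed)
    n <- 25; p <- 3
    X <- matrix(rnorm(n * p), n)
    L <- sample(c(-1, 1), n, TRUE)
    v <- abs(rnorm(n)) * 3
    lam <- 0.5
    fit <- solve_hinge_l1(X, L, v, lam)
    cc <- c(v, rep(lam, p + 1), rep(lam, p + 1))
    A <- cbind(-diag(n), -L * cbind(1, X), L * cbind(1, X))
    ref <- pracma::linprog(cc, A = A, b = rep(-1, n), maxiter = 1e5)
    expect_equal(fit$objective, ref$fval, tolerance = 1e-7)
  }
})

test_that("the hinge LP objective equals its primal recomputation", {
  # equality certifies that every hinge slack is tight at the solution
  set.seed(7)
  n <- 40
  X <- matrix(rnorm(n * 4), n, dimnames = list(NULL, paste0("x", 1:4)))
  L <- sample(c(-1, 1), n, TRUE)
  v <- abs(rnorm(n)) * 2
  for (lam in c(0.01, 1)) {
    fit <- solve_hinge_l1(X, L, v, lam)
    g <- fit$theta0 + drop(X %*% fit$theta)
    primal <- sum(v * pmax(0, 1 - L * g)) +
      lam * (abs(fit$theta0) + sum(abs(fit$theta)))
    expect_equal(fit$objective, primal, tolerance = 1e-6)
  }
})

test_that("the hinge LP matches dense grid search on a 2-D toy", {
  set.seed(13)
  n <- 10
  X <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "z"))
  L <- sample(c(-1, 1), n, TRUE)
  v <- abs(rnorm(n))
  lam <- 0.3
  fit <- solve_hinge_l1(X, L, v, lam)
  grid <- seq(-3, 3, by = 0.01)
  combos <- expand.grid(t0 = grid, t1 = grid)
  gvals <- outer(L, combos$t0) + outer(L * X[, 1], combos$t1)
  objs <- colSums(v * pmax(1 - gvals, 0)) +
    lam * (abs(combos$t0) + abs(combos$t1))
  expect_lte(fit$objective, min(objs) + 1e-9)
  expect_lte(min(objs) - fit$objective, 0.05)
})

test_that("degenerate hinge problems resolve as specified", {
  # all weights zero: the penalty decides, coefficients are zero
  fit0 <- solve_hinge_l1(cbind(z = rnorm(5)), rep(1, 5), rep(0, 5), 1)
  expect_equal(fit0$theta0, 0)
  expect_equal(unname(fit0$theta), 0)
  # a single separable subject at lambda = 0 attains zero hinge loss
  fit1 <- solve_hinge_l1(cbind(z = 1), L = 1, v = 1, lambda = 0)
  g <- fit1$theta0 + fit1$theta * 1
  expect_lte(max(0, 1 - g), 1e-9)
})

test_that("lasso Q-learning recovers a noiseless single-variable rule", {
  set.seed(23)
  n <- 300
  Z1 <- rnorm(n); Z2 <- rnorm(n)
  A1 <- sample(c(-1, 1), n, TRUE)
  A2 <- sample(c(-1, 1), n, TRUE)
  d <- trajectory_data(
    stages = list(list(H = cbind(Z1 = Z1, Z2 = Z2), A = A1),
                  list(H = cbind(Z1 = Z1, Z2 = Z2), A = A2)),
    Y = A2 * Z1)
  fit <- fit_l1_qlearning(d)
  th2 <- fit$stages[[2]]$theta
  expect_gt(th2[["Z1"]], 0.5)
  expect_lt(abs(th2[["Z2"]]), 0.05)
  dec <- predict(fit, d)
  expect_identical(unname(dec[, 2]), ifelse(Z1 >= 0, 1, -1))
})

test_that("Q-learning stage fits never read earlier-stage data", {
  set.seed(29)
  d <- make_toy(60, seed = 29)
  fit <- fit_l1_qlearning(d)
  d_perturbed <- d
  d_perturbed$stages[[1]]$H <- d$stages[[1]]$H + 100
  fit2 <- fit_l1_qlearning(d_perturbed)
  expect_equal(fit2$stages[[2]]$theta, fit$stages[[2]]$theta)
})

test_that("O-learning with zero outcomes returns zero rules", {
  d <- make_toy(20, seed = 37)
  d$Y <- rep(0, 20)
  fit <- fit_l1_olearning(d, outcome = "raw")
  for (s in fit$stages) {
    expect_equal(unname(s$theta), c(0, 0))
    expect_equal(s$theta0, 0)
  }
})

test_that("negating outcomes and flipping labels leaves raw O-learning rules intact", {
  # the weight/label reduction makes the flipped problem identical wherever
  # no later-stage concordance indicator intervenes: a single-stage fit is
  # exactly invariant, as is the terminal stage of a multistage fit
  set.seed(43)
  n <- 40
  d1 <- trajectory_data(
    stages = list(list(H = cbind(Z1 = rnorm(n), Z2 = rnorm(n)),
                       A = sample(c(-1, 1), n, TRUE),
                       p = runif(n, 0.3, 0.7))),
    Y = rnorm(n, sd = 2))
  fit <- fit_l1_olearning(d1, outcome = "raw")
  flipped <- d1
  flipped$Y <- -d1$Y
  flipped$stages[[1]]$A <- -d1$stages[[1]]$A
  fit_f <- fit_l1_olearning(flipped, outcome = "raw")
  expect_equal(fit_f$stages[[1]]$theta, fit$stages[[1]]$theta,
               tolerance = 1e-8)
  expect_equal(fit_f$stages[[1]]$theta0, fit$stages[[1]]$theta0,
               tolerance = 1e-8)

  d2 <- make_toy(40, seed = 44)
  fit2 <- fit_l1_olearning(d2, outcome = "raw")
  flipped2 <- d2
  flipped2$Y <- -d2$Y
  for (t in 1:2) flipped2$stages[[t]]$A <- -d2$stages[[t]]$A
  fit2_f <- fit_l1_olearning(flipped2, outcome = "raw")
  expect_equal(fit2_f$stages[[2]]$theta, fit2$stages[[2]]$theta,
               tolerance = 1e-8)
})

test_that("AOWL is O-learning on residualized outcomes", {
  d <- make_toy(50, seed = 47)
  set.seed(1)
  a <- fit_aowl(d)
  set.seed(1)
  b <- fit_l1_olearning(d, outcome = "residualized")
  for (t in 1:2) {
    expect_equal(a$stages[[t]]$theta, b$stages[[t]]$theta, tolerance = 1e-9)
  }
  expect_identical(a$method, "aowl")
})

test_that("the AOWL pilot ranks truly important covariates above noise", {
  imp <- c("Z1", "Z2", "Z7", "Z8", "X1")
  set.seed(53)
  seeds <- sample.int(1e6, 5)
  ratio <- vapply(seeds, function(seed) {
    set.seed(seed)
    cohort <- generate_cohort(simulation_config(1, 400))
    std <- standardize_trajectories(cohort)
    train <- attach_propensities(std$data)
    pilot <- fit_aowl(train)
    B <- abs(l1mrl:::pilot_matrix(pilot))
    mean(B[imp, ]) / max(mean(B[setdiff(rownames(B), imp), ]), 1e-12)
  }, numeric(1))
  expect_gt(mean(ratio > 1), 0.5)
})
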