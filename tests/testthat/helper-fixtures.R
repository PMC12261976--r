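# Small deterministic datasets used across test files, plus a cache for the
# replication studies shared by several acceptance checks.

# fixed 4-subject, 2-stage dataset with known propensities
tiny_trajectory <- function() {
  trajectory_data(
    stages = list(
      list(H = cbind(Z = c(0.5, -1.2, 0.3, 2.0)),
           A = c(1, -1, 1, -1), p = rep(0.5, 4)),
      list(H = cbind(Z = c(-0.4, 0.8, 1.5, -0.9)),
           A = c(1, 1, -1, -1), p = rep(0.5, 4))),
    Y = c(2, -1, 1.5, -0.5))
}

# random 2-stage toy with propensities, seeded by the caller
make_toy <- function(n, P = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  H1 <- matrix(rnorm(n * P), n, dimnames = list(NULL, paste0("Z", seq_len(P))))
  H2 <- matrix(rnorm(n * P), n, dimnames = list(NULL, paste0("Z", seq_len(P))))
  trajectory_data(
    stages = list(
      list(H = H1, A = sample(c(-1, 1), n, TRUE), p = runif(n, 0.3, 0.7)),
      list(H = H2, A = sample(c(-1, 1), n, TRUE), p = runif(n, 0.3, 0.7))),
    Y = rnorm(n, sd = 2))
}

# term-by-term enumeration of the empirical surrogate, independent of the
# package's vectorized path (the oracle for small instances)
enumerate_surrogate <- function(theta, eta, data, scale = "mean") {
  T <- data$n_stages
  total <- 0
  seqs <- as.matrix(expand.grid(rep(list(c(-1, 1)), T)))
  for (i in seq_len(data$n)) {
    ipw <- 1
    g <- numeric(T)
    a_obs <- numeric(T)
    for (t in seq_len(T)) {
      st <- data$stages[[t]]$H[i, , drop = FALSE]
      s <- theta$stages[[t]]
      g[t] <- s$gamma +
        sum(st[, names(s$beta)] * s$beta) +
        (if (length(s$alpha)) sum(st[, names(s$alpha)] * s$alpha) else 0)
      a_obs[t] <- data$stages[[t]]$A[i]
      ipw <- ipw * data$stages[[t]]$p[i]
    }
    ypos <- max(data$Y[i], 0)
    yneg <- max(-data$Y[i], 0)
    if (ypos > 0) {
      total <- total + ypos / ipw *
        min(pmax(pmin(a_obs * g / eta, 1), 0))
    }
    if (yneg > 0) {
      for (r in seq_len(nrow(seqs))) {
        if (all(seqs[r, ] == a_obs)) next
        total <- total + yneg / ipw *
          min(pmax(pmin(seqs[r, ] * g / eta, 1), 0))
      }
    }
  }
  if (scale == "mean") total / data$n else total
}

# replication studies reused by several acceptance checks; computed once per
# test run
replication_cache <- new.env(parent = emptyenv())
cached_replications <- function(method, setting, n, reps = 25L, seed = 20260923L) {
  key <- paste(method, setting, n, reps, seed, sep = "_")
  if (is.null(replication_cache[[key]])) {
    replication_cache[[key]] <-
      run_replications(method, simulation_config(setting, n, seed = seed,
                                                 reps = reps))
  }
  replication_cache[[key]]
}

# exact evaluation of a convex piecewise-linear function given by sorted
# breakpoints and nondecreasing segment slopes (anchored at F(0-ish) = 0):
# F(x) = s0 * x + sum_j jump_j * (x - b_j)_+ + l1 * |x|
pwl_eval <- function(x, breaks, slopes, l1) {
  out <- slopes[1L] * x + l1 * abs(x)
  for (j in seq_along(breaks)) {
    out <- out + (slopes[j + 1L] - slopes[j]) * pmax(0, x - breaks[j])
  }
  out
}

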