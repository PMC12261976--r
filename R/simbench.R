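#' Simulation study configuration
#'
#' Two-stage SMART-style benchmark scenarios: Setting 1 has a reward linear
#' in the tailoring variables (regimen models nearly correctly specified for
#' regression learners); Setting 2 multiplies each treatment by a quadratic
#' contrast (regimen models misspecified for linear rules).
#'
#' @param setting 1 or 2.
#' @param n Training cohort size (at least 20).
#' @param seed Base seed for the replication harness.
#' @param n_test Monte-Carlo evaluation cohort size (default 5000).
#' @param reps Number of replications.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(setting, n, seed = 1L, n_test = 5000L,
                              reps = 1L) {
  stopifnot(setting %in% c(1L, 2L), n >= 20L, n_test >= 1L, reps >= 1L)
  structure(list(setting = as.integer(setting), n = as.integer(n),
                 seed = as.integer(seed), n_test = as.integer(n_test),
                 reps = as.integer(reps)),
            class = "simulation_config")
}

# covariance of the 12 baseline covariates: unit variances, 0.2 among Z1..Z6
zeta_covariance <- function() {
  S <- diag(12)
  S[1:6, 1:6] <- 0.2
  diag(S) <- 1
  S
}

# latent draws shared by the cohort generator and the counterfactual
# evaluator: baseline covariates, per-subject loadings and stage-1 noise
draw_latents <- function(n) {
  Z <- MASS::mvrnorm(n, mu = rep(0, 12), Sigma = zeta_covariance())
  colnames(Z) <- paste0("Z", 1:12)
  list(Z = Z,
       omega = matrix(stats::runif(n * 3), n, 3),
       alpha = matrix(stats::rnorm(n * 3), n, 3),
       eps1 = matrix(stats::rnorm(n * 3), n, 3))
}

stage1_covariates <- function(lat) {
  X1 <- lat$Z[, 1] * lat$omega + lat$alpha + lat$eps1
  colnames(X1) <- paste0("X", 1:3)
  X1
}

# X_i2 = Z1 w_i + alpha_i (1 + A1/2) + eps_i2 : structural in the stage-1
# treatment, so counterfactual evaluation regenerates it under the rule
stage2_covariates <- function(lat, A1, eps2) {
  X2 <- lat$Z[, 1] * lat$omega + lat$alpha * (1 + A1 / 2) + eps2
  colnames(X2) <- paste0("X", 1:3)
  X2
}

# per-stage treatment effect contrast multiplying A_t in the reward
reward_contrast <- function(setting, Z, X1t) {
  if (setting == 1L) {
    3 * Z[, "Z1"] + 3 * Z[, "Z2"] - 2 * Z[, "Z7"] - 2 * Z[, "Z8"] - 2 * X1t
  } else {
    (Z[, "Z1"] + 3)^2 + (Z[, "Z2"] + 3)^2 + (Z[, "Z7"] - 3)^2 +
      (Z[, "Z8"] - 3)^2 + (2 / 3) * (X1t - 5)^2 - 60
  }
}

reward_baseline <- function(setting, Z) {
  if (setting == 1L) {
    1 + Z[, "Z1"] + Z[, "Z3"]
  } else {
    1 + Z[, "Z1"] + Z[, "Z2"] + 0.5 * (Z[, "Z3"]^2 + Z[, "Z4"]^2)
  }
}

#' Generate a two-stage SMART-style cohort
#'
#' Draws 12 baseline covariates (unit variance, covariance 0.2 among the
#' first six), three time-dependent covariates per stage built from
#' per-subject uniform loadings and normal random intercepts, assigns
#' treatments from logistic models (stage 1: logit = X1/3; stage 2:
#' logit = X1/3 + A1/2 on the stage-2 measurement), and computes the terminal
#' reward for the requested setting with standard normal noise.  Stage
#' histories are H1 = (Z1..Z12, X1, X2, X3) and H2 = (Z1..Z12, X1, X2, X3,
#' A1); the 15 covariates are selection candidates at both stages, A1 is
#' carried unpenalized.
#'
#' @param config A [simulation_config()] (or setting number, with `n` given).
#' @param n Cohort size when `config` is a setting number.
#' @param attach_propensity Store the true assignment probabilities of the
#'   observed arms in the dataset (default `FALSE`: downstream code treats
#'   them as unknown and estimates them).
#' @return A [trajectory_data()]; the data-generating truth (latent draws,
#'   true observed-arm probabilities, important-variable names) is attached
#'   as attribute `"truth"`.
#' @export
generate_cohort <- function(config, n = NULL, attach_propensity = FALSE) {
  if (!inherits(config, "simulation_config")) {
    config <- simulation_config(setting = config, n = n)
  }
  n <- config$n
  setting <- config$setting
  lat <- draw_latents(n)
  X1 <- stage1_covariates(lat)

  p1 <- stats::plogis(X1[, 1] / 3)
  A1 <- ifelse(stats::runif(n) < p1, 1, -1)
  eps2 <- matrix(stats::rnorm(n * 3), n, 3)
  X2 <- stage2_covariates(lat, A1, eps2)
  p2 <- stats::plogis(X2[, 1] / 3 + A1 / 2)
  A2 <- ifelse(stats::runif(n) < p2, 1, -1)

  Y <- reward_baseline(setting, lat$Z) +
    A1 * reward_contrast(setting, lat$Z, X1[, 1]) +
    A2 * reward_contrast(setting, lat$Z, X2[, 1]) +
    stats::rnorm(n)

  p1_obs <- ifelse(A1 == 1, p1, 1 - p1)
  p2_obs <- ifelse(A2 == 1, p2, 1 - p2)
  H1 <- cbind(lat$Z, X1)
  H2 <- cbind(lat$Z, X2, A1 = A1)
  candidates <- c(colnames(lat$Z), paste0("X", 1:3))
  design <- stage_design(penalized = list(candidates, candidates),
                         unpenalized = list(character(0), "A1"))
  out <- trajectory_data(
    stages = list(
      list(H = H1, A = A1, p = if (attach_propensity) p1_obs else NULL),
      list(H = H2, A = A2, p = if (attach_propensity) p2_obs else NULL)),
    Y = Y, design = design)
  attr(out, "truth") <- list(setting = setting, latent = lat,
                             p_obs = cbind(p1_obs, p2_obs),
                             important = c("Z1", "Z2", "Z7", "Z8", "X1"))
  out
}

#' Monte-Carlo value of a regimen under the true generative models
#'
#' Simulates `n_test` fresh subjects, applies the stage-1 rule, regenerates
#' the stage-2 covariates under the assigned stage-1 treatment (the
#' covariate model is structural in A1) with fresh measurement noise, applies
#' the stage-2 rule, and averages the resulting rewards.  With the same seed
#' the latent draws are identical across rules, so values are directly
#' comparable.
#'
#' @param rule A fitted object accepted by [as_rule()], or a
#'   `function(stage, H)` returning treatments in \{-1,+1\} from a raw-scale
#'   feature matrix.
#' @param setting Scenario number (1 or 2), or a [simulation_config()].
#' @param n_test Evaluation cohort size.
#' @param seed Seed for the evaluation draws.
#' @return The mean simulated reward under the regimen.
#' @export
true_value <- function(rule, setting, n_test = 5000L, seed = NULL) {
  if (inherits(setting, "simulation_config")) {
    n_test <- setting$n_test
    setting <- setting$setting
  }
  rule <- as_rule(rule)
  if (!is.null(seed)) set.seed(seed)
  lat <- draw_latents(n_test)
  X1 <- stage1_covariates(lat)
  H1 <- cbind(lat$Z, X1)
  a1 <- rule(1L, H1)
  eps2 <- matrix(stats::rnorm(n_test * 3), n_test, 3)
  X2 <- stage2_covariates(lat, a1, eps2)
  H2 <- cbind(lat$Z, X2, A1 = a1)
  a2 <- rule(2L, H2)
  Y <- reward_baseline(setting, lat$Z) +
    a1 * reward_contrast(setting, lat$Z, X1[, 1]) +
    a2 * reward_contrast(setting, lat$Z, X2[, 1]) +
    stats::rnorm(n_test)
  mean(Y)
}

#' The oracle regimen of a simulation setting
#'
#' Chooses each stage's treatment by the sign of the true per-stage contrast
#' multiplying A_t in the reward model.
#'
#' @param setting 1 or 2.
#' @return A `function(stage, H)` rule.
#' @export
oracle_rule <- function(setting) {
  force(setting)
  function(stage, H) {
    sign_pos(reward_contrast(setting, H, H[, "X1"]))
  }
}

#' Selected candidate features of a fitted regimen
#'
#' @param fit A fitted `l1mrl_fit`, `backward_fit`, or [dtr_coefficients()].
#' @param threshold Magnitude above which a coefficient counts as selected.
#' @return A list (per stage) of selected candidate-feature names.
#' @export
selected_features <- function(fit, threshold = 1e-6) {
  UseMethod("selected_features")
}

#' @export
selected_features.dtr_coefficients <- function(fit, threshold = 1e-6) {
  lapply(fit$stages, function(s) names(s$beta)[abs(s$beta) > threshold])
}

#' @export
selected_features.l1mrl_fit <- function(fit, threshold = 1e-6) {
  selected_features(fit$theta, threshold)
}

#' @export
selected_features.backward_fit <- function(fit, threshold = 1e-6) {
  lapply(seq_len(fit$n_stages), function(t) {
    b <- fit$stages[[t]]$theta[fit$penalized[[t]]]
    names(b)[abs(b) > threshold]
  })
}

#' Variable-selection error metrics
#'
#' Per stage: FN is the number of truly important candidates the fit missed,
#' FP the number of selected candidates outside the important set, and
#' FDR = (FN + FP) / P the overall false-discovery proportion among the P
#' candidates.
#'
#' @param fit A fitted object (see [selected_features()]), or a list of
#'   selected-name character vectors per stage.
#' @param truth Character vector of truly important candidate names.
#' @param P Number of candidate features per stage (default: taken from the
#'   fit).
#' @param threshold Selection threshold passed to [selected_features()].
#' @return A data.frame with one row per stage and columns `stage`, `FN`,
#'   `FP`, `FDR`.
#' @export
selection_metrics <- function(fit, truth = c("Z1", "Z2", "Z7", "Z8", "X1"),
                              P = NULL, threshold = 1e-6) {
  sel <- if (is.list(fit) && !is.object(fit)) fit
         else selected_features(fit, threshold)
  if (is.null(P)) {
    P <- if (inherits(fit, "backward_fit")) length(fit$penalized[[1L]])
         else if (inherits(fit, "l1mrl_fit")) length(fit$theta$stages[[1L]]$beta)
         else if (inherits(fit, "dtr_coefficients")) length(fit$stages[[1L]]$beta)
         else stop("P must be supplied for plain selection lists")
  }
  out <- lapply(seq_along(sel), function(t) {
    fn <- length(setdiff(truth, sel[[t]]))
    fp <- length(setdiff(sel[[t]], truth))
    data.frame(stage = t, FN = fn, FP = fp, FDR = (fn + fp) / P)
  })
  do.call(rbind, out)
}

#' Average pairwise Jaccard index of selected-variable sets
#'
#' J(S1, S2) = |intersection| / |union|, with J = 1 by convention when both
#' sets are empty; averaged over all unordered pairs of replications.
#'
#' @param selected_sets List (length >= 2) of character vectors.
#' @return The mean pairwise Jaccard index in \[0, 1\].
#' @export
jaccard_summary <- function(selected_sets) {
  m <- length(selected_sets)
  if (m < 2L) stop("need at least two selected sets")
  tot <- 0
  for (i in seq_len(m - 1L)) {
    for (j in seq(i + 1L, m)) {
      s1 <- selected_sets[[i]]
      s2 <- selected_sets[[j]]
      u <- length(union(s1, s2))
      tot <- tot + if (u == 0L) 1 else length(intersect(s1, s2)) / u
    }
  }
  tot / (m * (m - 1L) / 2)
}

#' Stabilized inverse-probability-weighted value estimator
#'
#' V^(f) = sum_i Y_i w_i / sum_i w_i with
#' w_i = prod_t 1\{A_it concordant with f_t(H_it)\} / prod_t p(A_it|H_it):
#' the ratio form cancels the scale of the weights, stabilizing the estimate
#' on observational data.
#'
#' @param rule A fitted object or `function(stage, H)` (see [as_rule()]).
#' @param data A [trajectory_data()] with propensities present (known or
#'   estimated).
#' @return The estimated value of the regimen.
#' @export
sipwe <- function(rule, data) {
  rule <- as_rule(rule)
  w <- rep(1, data$n)
  for (t in seq_len(data$n_stages)) {
    st <- data$stages[[t]]
    if (is.null(st$p)) stop("propensities are required for the SIPWE")
    d <- rule(t, st$H)
    w <- w * (st$A == d) / st$p
  }
  if (sum(w) <= 0) {
    stop("undefined value: no subject is concordant with the rule at all stages")
  }
  sum(data$Y * w) / sum(w)
}

#' Run the replication benchmark for one learner
#'
#' Per replication (seeded reproducibly from the base seed): generate a
#' training cohort, standardize, estimate the nuisance models, fit the
#' requested learner, evaluate the Monte-Carlo testing reward under the true
#' generative models, and record per-stage selection metrics.  Failed
#' replications are recorded, excluded from the aggregates and reported.
#'
#' @param method One of `"l1mrl"`, `"l1_qlearning"`, `"l1_olearning"`,
#'   `"aowl"`.
#' @param config A [simulation_config()].
#' @param ... Extra arguments passed to the learner (e.g. `grid` for
#'   `"l1mrl"`).
#' @param verbose Print one line per replication.
#' @return A list with `per_rep` (one row per successful replication),
#'   `summary` (means, SDs and per-stage Jaccard indices), `selected`
#'   (per-stage selected sets), and `failures`.
#' @export
run_replications <- function(method = c("l1mrl", "l1_qlearning",
                                        "l1_olearning", "aowl"),
                             config, ..., verbose = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2L * config$reps),
                  ncol = 2L)
  rows <- vector("list", config$reps)
  sel1 <- list()
  sel2 <- list()
  failures <- list()
  for (r in seq_len(config$reps)) {
    res <- tryCatch(
      run_one_replication(method, config, seeds[r, 1L], seeds[r, 2L], ...),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        data.frame(rep = r, message = conditionMessage(res))
      if (verbose) message(sprintf("rep %d FAILED: %s", r,
                                   conditionMessage(res)))
      next
    }
    rows[[r]] <- data.frame(rep = r, reward = res$reward,
                            FN1 = res$metrics$FN[1L], FP1 = res$metrics$FP[1L],
                            FDR1 = res$metrics$FDR[1L],
                            FN2 = res$metrics$FN[2L], FP2 = res$metrics$FP[2L],
                            FDR2 = res$metrics$FDR[2L])
    sel1[[length(sel1) + 1L]] <- res$selected[[1L]]
    sel2[[length(sel2) + 1L]] <- res$selected[[2L]]
    if (verbose) {
      message(sprintf("rep %d: reward %.3f, FDR (%.2f, %.2f)", r, res$reward,
                      res$metrics$FDR[1L], res$metrics$FDR[2L]))
    }
  }
  per_rep <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(per_rep) || nrow(per_rep) == 0L) {
    stop("every replication failed; first error: ", failures[[1L]]$message)
  }
  summary <- data.frame(
    method = method, setting = config$setting, n = config$n,
    reps = nrow(per_rep),
    reward_mean = mean(per_rep$reward), reward_sd = stats::sd(per_rep$reward),
    FN1 = mean(per_rep$FN1), FP1 = mean(per_rep$FP1),
    FDR1 = mean(per_rep$FDR1),
    JI1 = if (nrow(per_rep) >= 2L) jaccard_summary(sel1) else NA_real_,
    FN2 = mean(per_rep$FN2), FP2 = mean(per_rep$FP2),
    FDR2 = mean(per_rep$FDR2),
    JI2 = if (nrow(per_rep) >= 2L) jaccard_summary(sel2) else NA_real_)
  list(per_rep = per_rep, summary = summary,
       selected = list(stage1 = sel1, stage2 = sel2),
       failures = if (length(failures)) do.call(rbind, failures) else NULL)
}

run_one_replication <- function(method, config, train_seed, test_seed, ...) {
  set.seed(train_seed)
  cohort <- generate_cohort(config)
  if (method == "l1mrl") {
    fit <- fit_l1mrl(cohort, ...)
    rule <- as_rule(fit)
    sel <- selected_features(fit)
    metrics <- selection_metrics(fit)
  } else {
    std <- standardize_trajectories(cohort)
    train <- std$data
    if (method != "l1_qlearning") {
      train <- attach_propensities(train)
    }
    fit <- switch(method,
                  l1_qlearning = fit_l1_qlearning(train, ...),
                  l1_olearning = fit_l1_olearning(train, ...),
                  aowl = fit_aowl(train, ...))
    rule <- as_rule(fit, state = std$state)
    sel <- selected_features(fit)
    metrics <- selection_metrics(fit)
  }
  reward <- true_value(rule, config$setting, n_test = config$n_test,
                       seed = test_seed)
  list(reward = reward, metrics = metrics, selected = sel)
}
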