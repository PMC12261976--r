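#' Sequential comparison learners
#'
#' The package ships the three sequential learners used as references for the
#' simultaneous fit: lasso-penalized Q-learning, L1-penalized
#' outcome-weighted learning (O-learning) solved stage by stage as exact
#' linear programs, and augmented outcome-weighted learning (AOWL), which is
#' O-learning on residualized outcomes.  All fit backward (stage T first);
#' the stage-t fit only ever reads the later-stage rules.
#'
#' @name baselines
NULL

new_backward_fit <- function(method, stages, data) {
  structure(list(method = method, stages = stages,
                 penalized = data$design$penalized,
                 n_stages = data$n_stages),
            class = "backward_fit")
}

#' @exportS3Method base::print
print.backward_fit <- function(x, ...) {
  cat("Backward-fitted regimen (", x$method, ")\n", sep = "")
  for (t in seq_len(x$n_stages)) {
    s <- x$stages[[t]]
    cat(sprintf("  stage %d: %d/%d penalized features selected (lambda = %s)\n",
                t, sum(abs(s$theta[x$penalized[[t]]]) > 1e-6),
                length(x$penalized[[t]]),
                format(s$lambda, digits = 3)))
  }
  invisible(x)
}

# decision values g_t(H) = theta0 + H' theta for a backward fit
backward_decision_values <- function(fit, data) {
  g <- matrix(0, data$n, data$n_stages)
  for (t in seq_len(data$n_stages)) {
    s <- fit$stages[[t]]
    H <- data$stages[[t]]$H
    g[, t] <- s$theta0 + drop(H[, names(s$theta), drop = FALSE] %*% s$theta)
  }
  g
}

#' @export
#' @rdname baselines
#' @param object A fitted `backward_fit`.
#' @param newdata A [trajectory_data()] on the scale the rules were fitted on.
#' @param ... Unused.
predict.backward_fit <- function(object, newdata, ...) {
  sign_pos(backward_decision_values(object, newdata))
}

#' Lasso-penalized Q-learning
#'
#' Backward induction with linear Q-function models
#' Q_t(H_t, A_t) = H_t' omega_t + A_t * (gamma_t + H_t' theta_t), each fitted
#' by cross-validated lasso regression of the stage pseudo-outcome on
#' (H_t, A_t, A_t * H_t).  The stage-(t-1) pseudo-outcome is the fitted
#' maximum of Q_t over the two arms (ties toward +1); the stage-t rule is
#' sign(gamma_t + H_t' theta_t).
#'
#' @param data A standardized [trajectory_data()].
#' @param nfolds Folds for the internal `cv.glmnet` calls.
#' @param foldid Optional fold assignment (default: deterministic
#'   round-robin).
#' @return A `backward_fit`; each stage holds the interaction coefficients
#'   `theta` (the decision-function slope), the treatment main effect
#'   `theta0`, the baseline coefficients `omega`, and the chosen lasso level.
#' @export
fit_l1_qlearning <- function(data, nfolds = 5L, foldid = NULL) {
  T <- data$n_stages
  if (is.null(foldid)) foldid <- rep_len(seq_len(nfolds), data$n)
  pseudo <- data$Y
  stages <- vector("list", T)
  for (t in rev(seq_len(T))) {
    H <- data$stages[[t]]$H
    A <- data$stages[[t]]$A
    X <- cbind(H, A = A, A * H)
    colnames(X) <- c(colnames(H), "A", paste0("A:", colnames(H)))
    if (stats::sd(pseudo) < 1e-10) {
      # degenerate pseudo-outcome (e.g. an earlier null fit): flat Q-function
      cf <- stats::setNames(c(mean(pseudo), rep(0, ncol(X))),
                            c("(Intercept)", colnames(X)))
      lam_t <- Inf
    } else {
      cv <- glmnet::cv.glmnet(X, pseudo, family = "gaussian", foldid = foldid)
      cf <- drop(as.matrix(stats::coef(cv, s = "lambda.min")))
      lam_t <- cv$lambda.min
    }
    omega <- cf[colnames(H)]
    theta0 <- cf[["A"]]
    theta <- stats::setNames(cf[paste0("A:", colnames(H))], colnames(H))
    stages[[t]] <- list(theta = theta, theta0 = theta0, omega = omega,
                        intercept = cf[["(Intercept)"]],
                        lambda = lam_t)
    # pseudo-outcome for the previous stage: fitted max over the two arms
    base <- cf[["(Intercept)"]] + drop(H %*% omega)
    contrast <- theta0 + drop(H %*% theta)
    pseudo <- base + abs(contrast)
  }
  new_backward_fit("l1_qlearning", stages, data)
}

#' Solve one weighted-hinge + L1 problem as a linear program
#'
#' min_theta sum_i v_i * max(0, 1 - L_i (theta0 + x_i' theta))
#'           + lambda * ||(theta0, theta)||_1
#' with v_i >= 0, solved exactly by the simplex method on the standard LP
#' reformulation (hinge slacks; positive/negative coefficient split).
#'
#' @param X Feature matrix (no intercept column; one is added).
#' @param L Labels in \{-1, +1\}.
#' @param v Nonnegative case weights; zero-weight rows are dropped.
#' @param lambda Nonnegative L1 penalty applied to every coefficient
#'   (including the intercept, which also removes a zero-cost ray from the
#'   LP).
#' @return List with `theta0`, `theta` (named), `objective`, `iterations`.
#' @export
solve_hinge_l1 <- function(X, L, v, lambda) {
  stopifnot(all(v >= 0), lambda >= 0)
  keep <- v > 0
  d <- ncol(X) + 1L
  if (!any(keep)) {
    return(list(theta0 = 0,
                theta = stats::setNames(rep(0, ncol(X)), colnames(X)),
                objective = 0, iterations = 0L))
  }
  Z <- L[keep] * cbind(1, X[keep, , drop = FALSE])
  res <- hinge_l1_lp_cpp(Z, v[keep], rep(lambda, d))
  if (res$status == 1L) {
    stop("solver error: LP reported unbounded (objective is bounded by 0; ",
         "this indicates corrupted inputs)")
  }
  if (res$status == 2L) {
    warning("hinge LP hit its iteration limit; solution may be inexact")
  }
  list(theta0 = res$theta[1L],
       theta = stats::setNames(res$theta[-1L], colnames(X)),
       objective = res$objective, iterations = res$iterations)
}

#' L1-penalized O-learning via backward linear programs
#'
#' For t = T, ..., 1 solves
#' min_theta sum_i w_it * hinge(A_it (theta0 + H_it' theta)) + lambda ||theta||_1
#' with w_it = \[prod_(s>t) 1\{A_is concordant with the fitted later rule\}\] *
#' Y_i / prod_(s=t..T) p(A_is|H_is).  A subject whose working weight is
#' negative (possible whenever Y takes negative values) enters with weight
#' |w| and flipped label -A, the standard exact reduction for signed-outcome
#' weighted classification.  The stage penalty is chosen from `lambda_grid`
#' by twofold cross-validation on the held-out inverse-probability-weighted
#' value of the candidate rule; ties resolve toward the larger penalty.
#'
#' @param data A standardized [trajectory_data()] with propensities.
#' @param lambda_grid Candidate penalty levels (default decades 1e-5..1e5).
#' @param outcome `"shifted"` (default) replaces Y by Y - min(Y), the
#'   classical device making every hinge weight nonnegative; `"raw"` uses Y
#'   as observed, absorbing any negative weight by the label flip;
#'   `"residualized"` first replaces Y by the residual from
#'   [residualize_outcome()] (label flips again cover the signs).
#' @param cv_foldid Optional length-n fold assignment in \{1, 2\} for the
#'   penalty cross-validation (default: deterministic round-robin).
#' @return A `backward_fit`.
#' @export
fit_l1_olearning <- function(data, lambda_grid = 10^(-5:5),
                             outcome = c("shifted", "raw", "residualized"),
                             cv_foldid = NULL) {
  outcome <- match.arg(outcome)
  score_Y <- data$Y
  if (outcome == "residualized") {
    data <- residualize_outcome(data, "lasso")
    score_Y <- data$Y
  }
  fit_Y <- if (outcome == "shifted") data$Y - min(data$Y) else data$Y
  fit_olearning_backward(data, fit_Y, score_Y, lambda_grid, cv_foldid,
                         method = paste0("l1_olearning_", outcome))
}

# backward weighted-hinge fits: hinge weights built from fit_Y (negatives
# enter as |w| with flipped label), the lambda cross-validation scored by the
# held-out inverse-probability-weighted value on the score_Y scale
fit_olearning_backward <- function(data, fit_Y, score_Y, lambda_grid,
                                   cv_foldid, method) {
  T <- data$n_stages
  n <- data$n
  if (is.null(cv_foldid)) cv_foldid <- rep_len(1:2, n)
  lambda_grid <- sort(lambda_grid)
  pmat <- vapply(data$stages, function(s) {
    if (is.null(s$p)) stop("propensities are required for O-learning")
    s$p
  }, numeric(n))
  pmat <- matrix(pmat, nrow = n)
  Amat <- matrix(vapply(data$stages, `[[`, numeric(n), "A"), nrow = n)

  stages <- vector("list", T)
  concord_later <- rep(1, n)       # prod_{s > t} 1{A_s matches fitted rule}
  for (t in rev(seq_len(T))) {
    H <- data$stages[[t]]$H
    A <- Amat[, t]
    ipw <- 1 / apply(pmat[, t:T, drop = FALSE], 1L, prod)
    wgt <- concord_later * fit_Y * ipw
    score_wgt <- concord_later * score_Y * ipw
    v <- abs(wgt)
    L <- ifelse(wgt < 0, -A, A)

    best <- NULL
    for (lam in lambda_grid) {
      val <- 0
      for (f in 1:2) {
        tr <- cv_foldid != f
        fit <- solve_hinge_l1(H[tr, , drop = FALSE], L[tr], v[tr], lam)
        g <- fit$theta0 + drop(H[!tr, , drop = FALSE] %*% fit$theta)
        val <- val + sum(score_wgt[!tr] * (A[!tr] == sign_pos(g)))
      }
      if (is.null(best) || val >= best$val - 1e-12) {
        best <- list(val = val, lambda = lam)   # >= keeps the larger lambda
      }
    }
    fit <- solve_hinge_l1(H, L, v, best$lambda)
    stages[[t]] <- list(theta = fit$theta, theta0 = fit$theta0,
                        lambda = best$lambda, cv_value = best$val)
    g <- fit$theta0 + drop(H %*% fit$theta)
    concord_later <- concord_later * (A == sign_pos(g))
  }
  new_backward_fit(method, stages, data)
}

#' Augmented outcome-weighted learning (AOWL)
#'
#' O-learning applied to residualized outcomes Y - E^\[Y|H_1\]: residuals are
#' centered, so their sign carries the treatment-benefit information while
#' the weight magnitudes shrink, and negative residuals are absorbed exactly
#' by weight |w| with flipped label.  The AOWL solution doubles as the pilot
#' estimator for the adaptive penalty weights and as the initializer of the
#' DC iteration in the simultaneous fit.
#'
#' @inheritParams fit_l1_olearning
#' @param residualize_foldid Optional fold assignment for the conditional-mean
#'   lasso.
#' @return A `backward_fit` (method `"aowl"`) with the conditional-mean model
#'   attached as attribute `"conditional_mean"`.
#' @export
fit_aowl <- function(data, lambda_grid = 10^(-5:5), cv_foldid = NULL,
                     residualize_foldid = NULL) {
  res <- residualize_outcome(data, "lasso", foldid = residualize_foldid)
  fit <- fit_olearning_backward(res, res$Y, res$Y, lambda_grid, cv_foldid,
                                method = "aowl")
  attr(fit, "conditional_mean") <- attr(res, "conditional_mean")
  fit
}

# pilot coefficient matrix (P x T) over penalized candidates
pilot_matrix <- function(fit) {
  stopifnot(inherits(fit, "backward_fit"))
  nm <- fit$penalized[[1L]]
  B <- vapply(seq_len(fit$n_stages), function(t) {
    unname(fit$stages[[t]]$theta[fit$penalized[[t]]])
  }, numeric(length(nm)))
  matrix(B, nrow = length(nm), dimnames = list(nm, NULL))
}

# backward fit -> dtr_coefficients on the same design (DC initial point)
backward_to_theta <- function(fit, data) {
  dtr_coefficients(lapply(seq_len(data$n_stages), function(t) {
    s <- fit$stages[[t]]
    pen <- data$design$penalized[[t]]
    unpen <- data$design$unpenalized[[t]]
    list(gamma = s$theta0, alpha = s$theta[unpen], beta = s$theta[pen])
  }))
}
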