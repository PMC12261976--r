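#' Default tuning grid
#'
#' Penalty levels lambda in powers of two 2^0..2^10 and shifting parameters
#' eta in \{1e-3, 1e-4, 1e-5\}; both sets are configurable.
#'
#' @param lambda Candidate penalty levels.
#' @param eta Candidate shifting parameters in (0, 1].
#' @return A list with components `lambda` and `eta`.
#' @export
default_tuning_grid <- function(lambda = 2^(0:10), eta = 10^c(-3, -4, -5)) {
  stopifnot(all(lambda >= 0), all(eta > 0), all(eta <= 1))
  list(lambda = lambda, eta = eta)
}

#' AIC-type tuning criterion
#'
#' n* log( R^(theta_hat, eta) / R^(theta_ref, eta) ) - k(theta_hat), where
#' R^ is the sum-scale empirical surrogate value on the evaluation data, n*
#' the number of evaluation rows, theta_ref the unpenalized (lambda = 0) fit
#' under the same eta, and k the number of coefficients with magnitude above
#' `threshold`.  Larger is better: the log-ratio measures how much surrogate
#' value the penalized fit retains, and k charges for model size.  The
#' criterion is undefined when either surrogate value is nonpositive; such
#' pairs are marked invalid (-Inf).
#'
#' @param theta_hat Penalized fit, a [dtr_coefficients()].
#' @param theta_ref Unpenalized reference fit under the same eta.
#' @param eta Shifting parameter both fits were obtained under.
#' @param eval_data Evaluation [trajectory_data()] (held-out fold), with
#'   propensities and on the fitting scale.
#' @param terms Optionally, precomputed [surrogate_terms()] for `eval_data`.
#' @param threshold Magnitude above which a coefficient counts as nonzero.
#' @return The criterion value, or `-Inf` when undefined.
#' @export
aic_criterion <- function(theta_hat, theta_ref, eta, eval_data, terms = NULL,
                          threshold = 1e-6) {
  if (is.null(terms)) terms <- surrogate_terms(eval_data)
  r_hat <- empirical_value_surrogate(theta_hat, eta, eval_data, "sum",
                                     terms = terms)
  r_ref <- empirical_value_surrogate(theta_ref, eta, eval_data, "sum",
                                     terms = terms)
  if (!is.finite(r_hat) || !is.finite(r_ref) || r_hat <= 0 || r_ref <= 0) {
    return(-Inf)
  }
  eval_data$n * log(r_hat / r_ref) - count_nonzero(theta_hat, threshold)
}

#' Count nonzero coefficients of a regimen
#'
#' @param theta A [dtr_coefficients()].
#' @param threshold Magnitude threshold (default 1e-6, the same hard-zero
#'   cutoff used for selection reporting).
#' @return Integer count over all stages and all coefficient blocks.
#' @export
count_nonzero <- function(theta, threshold = 1e-6) {
  as.integer(sum(vapply(theta$stages, function(s) {
    sum(abs(c(s$gamma, s$alpha, s$beta)) > threshold)
  }, numeric(1))))
}

# deal rows into k folds, stratified by the given factor, using the current RNG
stratified_folds <- function(strata, k) {
  n <- length(strata)
  fold <- integer(n)
  for (lev in unique(strata)) {
    idx <- which(strata == lev)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Tune and fit the penalized multistage ramp objective by cross-validation
#'
#' For each fold and each eta: estimates the nuisance models on the training
#' half (assignment probabilities by lasso logistic regression, the
#' conditional mean E\[Y|H1\] by lasso when residualizing), fits the AOWL
#' pilot there, fits the unpenalized (lambda = 0) problem initialized at the
#' pilot, then each lambda > 0 warm-started from the lambda = 0 solution, and
#' scores every (lambda, eta) with [aic_criterion()] on the held-out half.
#' Criteria are averaged over folds; the winning pair (ties toward larger
#' lambda, then smaller eta) is refitted on the full data.
#'
#' @param data A standardized [trajectory_data()] (see
#'   [standardize_trajectories()]); propensities may be present, otherwise
#'   set `refit_nuisance = TRUE` (default) to estimate them.
#' @param grid A [default_tuning_grid()]-style list.
#' @param folds Number of cross-validation folds (default 2).
#' @param residualize Fit on residualized outcomes Y - E^\[Y|H1\] (default)
#'   or on raw Y.
#' @param refit_nuisance Estimate assignment probabilities per training set
#'   (default); when `FALSE` the probabilities already stored in `data` are
#'   used everywhere.
#' @param criterion_outcome Outcome scale for the held-out criterion:
#'   `"raw"` (default) evaluates the surrogate value R^ with the observed Y,
#'   matching the criterion's definition, while `"residualized"` scores on
#'   the same residualized outcome the fits use.
#' @param weight_cap Cap for the adaptive penalty weights.
#' @param box Coefficient box bound for the DC solver.
#' @param pilot Optional function(data) returning a `backward_fit` used as
#'   pilot/initializer instead of AOWL.
#' @param verbose Print per-fold progress.
#' @return An object of class `l1mrl_tuning`: the final `theta`, selected
#'   `lambda` and `eta`, the per-pair criterion table, the full-data pilot
#'   and DC state, and the fold assignment.
#' @export
cross_validate <- function(data, grid = default_tuning_grid(), folds = 2L,
                           residualize = TRUE, refit_nuisance = TRUE,
                           criterion_outcome = c("raw", "residualized"),
                           weight_cap = 1e6, box = 100, pilot = NULL,
                           verbose = FALSE) {
  criterion_outcome <- match.arg(criterion_outcome)
  stopifnot(folds >= 2L)
  if (length(grid$lambda) == 0L || length(grid$eta) == 0L) {
    stop("tuning grid must be nonempty")
  }
  if (anyDuplicated(grid$lambda) || anyDuplicated(grid$eta)) {
    message("duplicate grid entries removed")
    grid$lambda <- unique(grid$lambda)
    grid$eta <- unique(grid$eta)
  }
  lambdas <- sort(grid$lambda)
  etas <- sort(grid$eta, decreasing = TRUE)

  strata <- interaction(data$stages[[1L]]$A, data$Y >= 0, drop = TRUE)
  fold_id <- stratified_folds(strata, folds)

  crit <- array(NA_real_,
                dim = c(length(lambdas), length(etas), folds),
                dimnames = list(lambda = lambdas, eta = etas, fold = NULL))
  for (f in seq_len(folds)) {
    tr_rows <- fold_id != f
    prep <- prepare_training(subset_trajectories(data, tr_rows),
                             eval_data = subset_trajectories(data, !tr_rows),
                             residualize = residualize,
                             refit_nuisance = refit_nuisance,
                             criterion_outcome = criterion_outcome,
                             weight_cap = weight_cap, pilot = pilot)
    eval_terms <- surrogate_terms(prep$eval)
    for (e in seq_along(etas)) {
      path <- fit_lambda_path(prep, etas[e], lambdas, box)
      for (l in seq_along(lambdas)) {
        crit[l, e, f] <- aic_criterion(path$fits[[l]], path$ref, etas[e],
                                       prep$eval, terms = eval_terms)
      }
      if (verbose) {
        message(sprintf("fold %d, eta %.0e: best criterion %.2f", f, etas[e],
                        max(crit[, e, f], na.rm = TRUE)))
      }
    }
  }

  mean_crit <- apply(crit, c(1L, 2L), mean)
  tab <- data.frame(lambda = rep(lambdas, times = length(etas)),
                    eta = rep(etas, each = length(lambdas)),
                    criterion = as.vector(mean_crit))
  if (all(!is.finite(tab$criterion))) {
    stop("tuning failure: every (lambda, eta) pair was invalid ",
         "(nonpositive surrogate value on held-out data)")
  }
  # maximum criterion; ties toward larger lambda, then smaller eta
  ord <- order(-tab$criterion, -tab$lambda, tab$eta)
  sel <- tab[ord[1L], ]

  final_prep <- prepare_training(data, eval_data = NULL,
                                 residualize = residualize,
                                 refit_nuisance = refit_nuisance,
                                 criterion_outcome = criterion_outcome,
                                 weight_cap = weight_cap, pilot = pilot)
  final_path <- fit_lambda_path(final_prep, sel$eta, sel$lambda, box)
  structure(list(theta = final_path$fits[[1L]],
                 lambda = sel$lambda, eta = sel$eta,
                 criterion = sel$criterion, table = tab,
                 pilot = final_prep$pilot_fit,
                 penalty = final_prep$penalty_weights,
                 state = final_path$states[[1L]],
                 fold_id = fold_id,
                 conditional_mean = final_prep$conditional_mean,
                 propensity_models = final_prep$propensity_models),
            class = "l1mrl_tuning")
}

# nuisance fits + pilot on a training set; transforms eval_data consistently
prepare_training <- function(train, eval_data, residualize, refit_nuisance,
                             criterion_outcome, weight_cap, pilot) {
  prop_models <- NULL
  if (refit_nuisance) {
    prop_models <- lapply(seq_len(train$n_stages), function(t) {
      fit_propensity_model(train$stages[[t]]$H, train$stages[[t]]$A, stage = t)
    })
    for (t in seq_len(train$n_stages)) {
      train$stages[[t]]$p <- prop_models[[t]]$predict(train$stages[[t]]$H,
                                                      train$stages[[t]]$A)
      if (!is.null(eval_data)) {
        eval_data$stages[[t]]$p <-
          prop_models[[t]]$predict(eval_data$stages[[t]]$H,
                                   eval_data$stages[[t]]$A)
      }
    }
  } else {
    ok <- !vapply(train$stages, function(s) is.null(s$p), logical(1))
    if (!all(ok)) stop("refit_nuisance = FALSE needs propensities in the data")
  }
  cond <- NULL
  if (residualize) {
    train <- residualize_outcome(train, "lasso")
    cond <- attr(train, "conditional_mean")
    if (!is.null(eval_data) && criterion_outcome == "residualized") {
      eval_data$Y <- eval_data$Y - cond$predict(eval_data$stages[[1L]]$H)
    }
  }
  pilot_fit <- if (is.null(pilot)) fit_aowl(train) else pilot(train)
  omega <- adaptive_weights(pilot_normalize(pilot_matrix(pilot_fit)),
                            gamma = 1, cap = weight_cap)
  list(train = train, eval = eval_data, pilot_fit = pilot_fit,
       init = backward_to_theta(pilot_fit, train),
       penalty_weights = omega, conditional_mean = cond,
       propensity_models = prop_models)
}

# the linearized subproblem is routinely unbounded along saturated
# directions during tuning, so the (documented) box-bound warning would fire
# on nearly every grid fit; the state flag still records it
quiet_box <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("box bound", conditionMessage(w))) invokeRestart("muffleWarning")
  })
}

# lambda = 0 fit initialized at the pilot, then each lambda > 0 warm-started
# from the lambda = 0 solution
fit_lambda_path <- function(prep, eta, lambdas, box) {
  terms <- surrogate_terms(prep$train)
  ref_fit <- quiet_box(dc_fit(prep$train,
                    fit_config(eta, penalty_spec(0), init = prep$init,
                               box = box),
                    terms = terms))
  # theta = 0 is a stationary point of the surrogate (every margin sits at
  # the ramp kink), so an all-zero pilot would trap the DC iteration at zero
  # value; restart from the constant-sign intercept rules and keep the best
  if (utils::tail(ref_fit$state$objective, 1L) > -1e-10) {
    T <- prep$train$n_stages
    for (sgn in asplit(as.matrix(expand.grid(rep(list(c(1, -1)), T))), 1L)) {
      init <- dtr_coefficients(lapply(seq_len(T), function(t) {
        list(gamma = sgn[t],
             alpha = 0 * prep$init$stages[[t]]$alpha,
             beta = 0 * prep$init$stages[[t]]$beta)
      }))
      cand <- quiet_box(dc_fit(prep$train,
                     fit_config(eta, penalty_spec(0), init = init, box = box),
                     terms = terms))
      if (utils::tail(cand$state$objective, 1L) <
          utils::tail(ref_fit$state$objective, 1L)) {
        ref_fit <- cand
      }
    }
  }
  fits <- vector("list", length(lambdas))
  states <- vector("list", length(lambdas))
  for (l in seq_along(lambdas)) {
    if (lambdas[l] == 0) {
      fits[[l]] <- ref_fit$theta
      states[[l]] <- ref_fit$state
      next
    }
    f <- quiet_box(dc_fit(prep$train,
                fit_config(eta,
                           penalty_spec(lambdas[l],
                                        weights = prep$penalty_weights),
                           init = ref_fit$theta, box = box),
                terms = terms))
    fits[[l]] <- f$theta
    states[[l]] <- f$state
  }
  list(fits = fits, states = states, ref = ref_fit$theta,
       ref_state = ref_fit$state)
}

#' @exportS3Method base::print
print.l1mrl_tuning <- function(x, ...) {
  cat(sprintf("Tuned penalized multistage ramp fit: lambda = %g, eta = %g ",
              x$lambda, x$eta))
  cat(sprintf("(criterion %.3f)\n", x$criterion))
  print(x$theta)
  invisible(x)
}

#' Fit a sparse multistage regimen with tuned penalty
#'
#' The user-facing pipeline: standardizes the stage features (population-SD
#' convention), runs [cross_validate()] to pick (lambda, eta) and fit the
#' final coefficients, and packages the result with the standardization state
#' so that `predict()` can be applied to raw-scale data.
#'
#' @param data A [trajectory_data()] on the raw scale.
#' @param ... Passed to [cross_validate()] (`grid`, `folds`, `residualize`,
#'   `refit_nuisance`, `weight_cap`, `box`, ...).
#' @return An object of class `l1mrl_fit` with elements `theta`, `lambda`,
#'   `eta`, `tuning` (the full [cross_validate()] result) and
#'   `standardization`.
#' @export
fit_l1mrl <- function(data, ...) {
  std <- standardize_trajectories(data)
  tuned <- cross_validate(std$data, ...)
  structure(list(theta = tuned$theta, lambda = tuned$lambda, eta = tuned$eta,
                 tuning = tuned, standardization = std$state,
                 design = data$design),
            class = "l1mrl_fit")
}

#' @exportS3Method base::print
print.l1mrl_fit <- function(x, ...) {
  cat("Penalized multistage ramp regimen\n")
  cat(sprintf("  selected lambda = %g, eta = %g\n", x$lambda, x$eta))
  print(x$theta)
  invisible(x)
}

#' @export
coef.l1mrl_fit <- function(object, ...) object$theta

#' @export
#' @rdname fit_l1mrl
#' @param object A fitted `l1mrl_fit`.
#' @param newdata A raw-scale [trajectory_data()] with matching columns.
predict.l1mrl_fit <- function(object, newdata, ...) {
  dtr_decisions(object$theta,
                apply_standardization(object$standardization, newdata))
}

#' Turn a fitted object into a per-stage decision rule
#'
#' Returns `function(stage, H)` mapping a raw-scale feature matrix for one
#' stage to recommended treatments in \{-1,+1\}; used by the Monte-Carlo
#' value evaluator and the inverse-probability-weighted estimators.
#'
#' @param object A fitted `l1mrl_fit`, `backward_fit`, [dtr_coefficients()],
#'   or already a function(stage, H).
#' @param state Standardization to apply to `H` before evaluating linear
#'   rules (taken from the object when it carries one).
#' @return A `function(stage, H)`.
#' @export
as_rule <- function(object, state = NULL) UseMethod("as_rule")

#' @export
as_rule.function <- function(object, state = NULL) object

#' @export
as_rule.l1mrl_fit <- function(object, state = NULL) {
  as_rule(object$theta, state %||% object$standardization)
}

#' @export
as_rule.dtr_coefficients <- function(object, state = NULL) {
  function(stage, H) {
    H <- scale_features(H, state, stage)
    s <- object$stages[[stage]]
    g <- rep(s$gamma, nrow(H))
    if (length(s$beta)) g <- g + drop(H[, names(s$beta), drop = FALSE] %*% s$beta)
    if (length(s$alpha)) g <- g + drop(H[, names(s$alpha), drop = FALSE] %*% s$alpha)
    sign_pos(g)
  }
}

#' @export
as_rule.backward_fit <- function(object, state = NULL) {
  function(stage, H) {
    H <- scale_features(H, state, stage)
    s <- object$stages[[stage]]
    sign_pos(s$theta0 + drop(H[, names(s$theta), drop = FALSE] %*% s$theta))
  }
}

scale_features <- function(H, state, stage) {
  if (is.null(state)) return(H)
  st <- state[[stage]]
  cols <- names(st$center)
  H[, cols] <- sweep(sweep(H[, cols, drop = FALSE], 2L, st$center), 2L,
                     st$scale, "/")
  H
}
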