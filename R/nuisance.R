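#' Estimate treatment-assignment probabilities
#'
#' Fits a lasso-penalized logistic regression of the stage-t treatment on the
#' stage-t history and returns the predicted probability of the *observed*
#' arm for each subject.  The penalty level is chosen by cross-validated
#' deviance.  Intended for data where assignment probabilities are unknown
#' (observational data, or simulations that treat them as unknown).
#'
#' @param data A [trajectory_data()].
#' @param stage Stage index t.
#' @param clip Optional epsilon: predictions are clipped to
#'   \[clip, 1 - clip\].  Disabled (`NULL`) by default; under positivity the
#'   fitted probabilities stay inside (0, 1) on their own.
#' @param foldid Optional cross-validation fold assignment (supply for exact
#'   reproducibility).
#' @return Numeric vector of P(A_t = observed | H_t) in (0, 1), with the
#'   number of clipped subjects in attribute `"n_clipped"` when clipping is
#'   enabled.
#' @export
estimate_propensity <- function(data, stage, clip = NULL, foldid = NULL) {
  st <- data$stages[[stage]]
  model <- fit_propensity_model(st$H, st$A, foldid = foldid, stage = stage)
  p <- model$predict(st$H, st$A)
  if (!is.null(clip)) {
    n_clipped <- sum(p < clip | p > 1 - clip)
    p <- pmin(pmax(p, clip), 1 - clip)
    attr(p, "n_clipped") <- n_clipped
  }
  attr(p, "model") <- model
  p
}

# lasso logistic assignment model; returns a predictor reusable on new rows
fit_propensity_model <- function(H, A, foldid = NULL, stage = NULL) {
  y <- as.integer(A == 1)
  if (length(unique(y)) < 2L || min(table(y)) < 2L) {
    stop("degenerate stage ", stage, ": need at least 2 subjects per arm")
  }
  if (is.null(foldid)) foldid <- rep_len(seq_len(5L), length(y))
  cv <- glmnet::cv.glmnet(H, y, family = "binomial", foldid = foldid)
  list(cv = cv,
       predict = function(Hnew, Anew) {
         p1 <- drop(stats::predict(cv, newx = Hnew, s = "lambda.min",
                                   type = "response"))
         p <- ifelse(Anew == 1, p1, 1 - p1)
         pmin(pmax(p, 1e-12), 1 - 1e-12)  # guard exact 0/1 saturation
       })
}

#' Attach estimated propensities at every stage
#'
#' Convenience wrapper calling [estimate_propensity()] stage by stage and
#' storing the results in the dataset.  Stages that already carry
#' probabilities are left untouched unless `overwrite = TRUE`.
#'
#' @inheritParams estimate_propensity
#' @param overwrite Refit even when probabilities are already present.
#' @return The dataset with `p` filled in at every stage.
#' @export
attach_propensities <- function(data, clip = NULL, foldid = NULL,
                                overwrite = FALSE) {
  for (t in seq_len(data$n_stages)) {
    if (is.null(data$stages[[t]]$p) || overwrite) {
      data$stages[[t]]$p <- as.numeric(
        estimate_propensity(data, t, clip = clip, foldid = foldid))
    }
  }
  data
}

#' Subset a trajectory dataset by rows
#'
#' @param data A [trajectory_data()].
#' @param rows Integer or logical row index.
#' @return The subsetted [trajectory_data()].
#' @export
subset_trajectories <- function(data, rows) {
  if (is.logical(rows)) rows <- which(rows)
  stages <- lapply(data$stages, function(st) {
    list(H = st$H[rows, , drop = FALSE], A = st$A[rows],
         p = if (is.null(st$p)) NULL else st$p[rows])
  })
  trajectory_data(stages, data$Y[rows], data$design)
}

#' Drop subjects with extreme inverse-probability weights
#'
#' Optional preprocessing for observational data: removes subjects whose
#' absolute weighted reward |Y| / prod_t p(A_t|H_t) exceeds `cap` (default
#' 10), which otherwise dominate the weighted objective and destabilize
#' value estimates.
#'
#' @param data A [trajectory_data()] with propensities present.
#' @param cap Positive truncation level for |Y| / prod p.
#' @return The filtered dataset; the number of removed subjects is attached
#'   as attribute `"n_dropped"`.
#' @export
truncate_extreme_weights <- function(data, cap = 10) {
  stopifnot(cap > 0)
  pmat <- vapply(data$stages, function(s) {
    if (is.null(s$p)) stop("propensities required before truncation")
    s$p
  }, numeric(data$n))
  wr <- abs(data$Y) / apply(matrix(pmat, nrow = data$n), 1L, prod)
  keep <- wr <= cap
  out <- subset_trajectories(data, keep)
  attr(out, "n_dropped") <- sum(!keep)
  out
}
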