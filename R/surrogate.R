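#' Shifted ramp loss
#'
#' The clipped-linear function psi(x) = max(min(x, 1), 0): a bounded,
#' outlier-robust surrogate for the 0-1 loss.  Nondecreasing and 1-Lipschitz.
#'
#' @param x Numeric vector.
#' @return `pmax(pmin(x, 1), 0)`, elementwise in \[0, 1\].
#' @export
#' @examples
#' ramp_loss(c(-0.5, 0.5, 2))
ramp_loss <- function(x) pmax(pmin(x, 1), 0)

#' Multistage ramp surrogate
#'
#' The surrogate for the product of per-stage correct-decision indicators:
#' the minimum over stages of per-stage ramp losses.  Whenever every margin
#' has magnitude at least 1 it equals the product indicator exactly.
#'
#' @param margins Numeric vector of per-stage margins u_1, ..., u_T.
#' @return `min_t ramp_loss(u_t)`, a value in \[0, 1\].
#' @export
multistage_surrogate <- function(margins) min(ramp_loss(margins))

#' Expand a dataset into weighted surrogate terms
#'
#' The empirical multistage ramp objective is a weighted sum over terms, one
#' per subject with positive reward part (at the observed treatment sequence)
#' and one per subject-with-negative-part and alternative treatment sequence
#' (all 2^T - 1 sequences differing from the observed one).  Weights are
#' Y+ / prod_t p(A_t|H_t) and Y- / prod_t p(A_t|H_t); exactly one of the two
#' parts is active per subject.  Terms with zero weight are dropped.
#'
#' @param data A [trajectory_data()] with propensities present at each stage.
#' @return A list with `subject` (row index per term), `a` (term x T matrix of
#'   treatment signs), `w` (nonnegative weights) and `n` (the cohort size used
#'   for mean scaling).
#' @export
surrogate_terms <- function(data) {
  T <- data$n_stages
  pmat <- vapply(data$stages, function(s) {
    if (is.null(s$p)) stop("propensities are required; see estimate_propensity()")
    s$p
  }, numeric(data$n))
  pmat <- matrix(pmat, nrow = data$n)
  ipw <- 1 / apply(pmat, 1L, prod)
  Amat <- vapply(data$stages, `[[`, numeric(data$n), "A")
  Amat <- matrix(Amat, nrow = data$n)
  wpos <- pmax(data$Y, 0) * ipw
  wneg <- pmax(-data$Y, 0) * ipw

  subj <- integer(0)
  w <- numeric(0)
  a <- matrix(numeric(0), ncol = T)

  ip <- which(wpos > 0)
  if (length(ip)) {
    subj <- c(subj, ip)
    w <- c(w, wpos[ip])
    a <- rbind(a, Amat[ip, , drop = FALSE])
  }
  im <- which(wneg > 0)
  if (length(im)) {
    alts <- alternative_sequences(T)              # (2^T - 1) x T, in {0,1} flip mask
    for (r in seq_len(nrow(alts))) {
      seq_r <- Amat[im, , drop = FALSE]
      flip <- which(alts[r, ] == 1L)
      seq_r[, flip] <- -seq_r[, flip, drop = FALSE]
      subj <- c(subj, im)
      w <- c(w, wneg[im])
      a <- rbind(a, seq_r)
    }
  }
  list(subject = subj, a = a, w = w, n = data$n)
}

# all nonzero flip masks: which stages deviate from the observed sequence
alternative_sequences <- function(T) {
  grid <- as.matrix(expand.grid(rep(list(0:1), T)))
  grid <- grid[rowSums(grid) > 0L, , drop = FALSE]
  storage.mode(grid) <- "integer"
  unname(grid)
}

#' Empirical multistage ramp objective
#'
#' Evaluates the inverse-probability-weighted empirical surrogate
#' sum_i \[ w_i+ min_t psi(A_it g_t(H_it)/eta)
#'        + w_i- sum_(a != A_i) min_t psi(a_t g_t(H_it)/eta) \],
#' divided by n under `scale = "mean"` (the fitting objective) or left as a
#' sum under `scale = "sum"` (the form entering the AIC-type tuning
#' criterion).  Higher is better.
#'
#' @param theta A [dtr_coefficients()].
#' @param eta Shifting parameter in (0, 1]; margins are divided by `eta`
#'   inside the ramp, so smaller values sharpen the surrogate toward the 0-1
#'   loss.
#' @param data A [trajectory_data()] with propensities, on the scale `theta`
#'   was fitted on.
#' @param scale `"mean"` or `"sum"`.
#' @param terms Optionally, precomputed [surrogate_terms()] for `data`.
#' @return A single number.
#' @export
empirical_value_surrogate <- function(theta, eta, data,
                                      scale = c("mean", "sum"),
                                      terms = NULL) {
  scale <- match.arg(scale)
  if (!is.numeric(eta) || length(eta) != 1L || eta <= 0) {
    stop("eta must be a positive scalar (in (0, 1] for fitting)")
  }
  if (is.null(terms)) terms <- surrogate_terms(data)
  if (length(terms$w) == 0L) return(0)
  g <- decision_values(theta, data)
  val <- surrogate_terms_value(terms, g, eta)
  if (scale == "mean") val / terms$n else val
}

# sum over terms of w * min_t psi(a_t g_t / eta); shared by objective and tests
surrogate_terms_value <- function(terms, g, eta) {
  u <- terms$a * g[terms$subject, , drop = FALSE] / eta
  m <- apply(ramp_loss(u), 1L, min)
  sum(terms$w * m)
}

#' Residualize the terminal reward on stage-1 history
#'
#' Replaces Y by Y - E^[Y | H_1], the residual from a conditional-mean model
#' fitted on stage-1 features.  Subtracting any function of H_1 leaves the
#' optimal regimen unchanged but can reduce the variability of the weighted
#' objective, which improves finite-sample fits; it is the default
#' preprocessing for the penalized fits here.
#'
#' @param data A [trajectory_data()].
#' @param estimator `"lasso"` (cross-validated, the default) or `"linear"`
#'   (ordinary least squares; falls back to lasso if the design is singular).
#' @param fit_rows Rows used to fit the conditional mean (default: all);
#'   residuals are formed for every row with the fitted model.
#' @param foldid Optional fold assignment for the internal `cv.glmnet` call
#'   (supply for exact reproducibility).
#' @return The input dataset with `Y` replaced by residuals; the fitted model
#'   is attached as attribute `"conditional_mean"` (with `$predict`).
#' @export
residualize_outcome <- function(data, estimator = c("lasso", "linear"),
                                fit_rows = seq_len(data$n), foldid = NULL) {
  estimator <- match.arg(estimator)
  H1 <- data$stages[[1L]]$H
  Xf <- H1[fit_rows, , drop = FALSE]
  Yf <- data$Y[fit_rows]
  model <- NULL
  if (estimator == "linear") {
    fit <- tryCatch(stats::lm.fit(cbind(1, Xf), Yf), error = function(e) NULL)
    if (!is.null(fit) && !anyNA(fit$coefficients)) {
      cf <- fit$coefficients
      model <- list(kind = "linear",
                    predict = function(H) drop(cbind(1, H) %*% cf))
    } else {
      message("singular linear design; falling back to lasso")
      estimator <- "lasso"
    }
  }
  if (estimator == "lasso") {
    if (is.null(foldid)) {
      foldid <- rep_len(seq_len(5L), length(Yf))
    }
    cv <- glmnet::cv.glmnet(Xf, Yf, family = "gaussian", foldid = foldid)
    model <- list(kind = "lasso", cv = cv,
                  predict = function(H) {
                    drop(stats::predict(cv, newx = H, s = "lambda.min"))
                  })
  }
  data$Y <- data$Y - model$predict(H1)
  attr(data, "conditional_mean") <- model
  data
}
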