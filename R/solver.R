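#' Configuration for the DC fit
#'
#' @param eta Shifting parameter in (0, 1]; decision margins are divided by
#'   `eta` inside the ramp.
#' @param penalty A [penalty_spec()].
#' @param init Optional [dtr_coefficients()] used as the DC starting point
#'   (default: all zeros).
#' @param max_dc Maximum DC iterations.
#' @param max_sweep Maximum coordinate sweeps per DC step.
#' @param tol_obj Relative objective-decrease tolerance stopping the DC loop.
#' @param tol_coef Coordinate-change tolerance stopping the sweeps.
#' @param box Box bound B: every coefficient is confined to \[-B, B\] during
#'   the piecewise-linear line search (the subproblem can be flat along some
#'   directions, so an explicit bound is needed); a warning is raised if the
#'   bound is active at the solution.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(eta, penalty = penalty_spec(0), init = NULL,
                       max_dc = 50L, max_sweep = 100L,
                       tol_obj = 1e-6, tol_coef = 1e-8, box = 100) {
  stopifnot(is.numeric(eta), length(eta) == 1L, eta > 0, eta <= 1,
            inherits(penalty, "penalty_spec"),
            tol_obj > 0, tol_coef > 0, box > 0)
  structure(list(eta = eta, penalty = penalty, init = init,
                 max_dc = as.integer(max_dc), max_sweep = as.integer(max_sweep),
                 tol_obj = tol_obj, tol_coef = tol_coef, box = box),
            class = "fit_config")
}

#' Fit the penalized multistage ramp objective by the DC algorithm
#'
#' Minimizes the empirical objective (negative mean-scale surrogate value
#' plus the adaptive group-lasso penalty) by iterating between linearizing
#' the concave part at the current point and solving the resulting convex
#' piecewise-linear subproblem by cyclic coordinate descent with exact line
#' search (see [dc_linearize()] and [coordinate_minimize()] for the two
#' ingredients).  The objective decreases monotonically across DC steps; the
#' returned point admits no single-coordinate improvement of the linearized
#' subproblem beyond tolerance.
#'
#' @param data A standardized [trajectory_data()] with propensities present.
#' @param config A [fit_config()].
#' @param terms Optionally, precomputed [surrogate_terms()] for `data`.
#' @return A list with `theta` (a [dtr_coefficients()]) and `state`, a
#'   `dc_state` holding the monotone objective history, iteration count and
#'   convergence flag.
#' @export
dc_fit <- function(data, config, terms = NULL) {
  stopifnot(inherits(config, "fit_config"))
  if (is.null(terms)) terms <- surrogate_terms(data)
  if (any(!is.finite(terms$w))) {
    stop("numeric error: non-finite surrogate weights ",
         "(check rewards and propensities)")
  }
  layout <- design_layout(data)
  pen <- lapply(seq_len(data$n_stages), function(t) {
    lay <- layout[[t]]
    wts <- penalty_weights_for(config$penalty, lay$pen)
    c(0, rep(0, length(lay$unpen)), config$penalty$lambda * wts)
  })
  theta0 <- lapply(seq_len(data$n_stages), function(t) {
    lay <- layout[[t]]
    if (is.null(config$init)) {
      rep(0, 1L + length(lay$unpen) + length(lay$pen))
    } else {
      s <- config$init$stages[[t]]
      c(s$gamma, s$alpha[lay$unpen], s$beta[lay$pen])
    }
  })
  if (length(terms$w) == 0L) {
    # zero objective: nothing to fit, the penalty pins everything at zero
    theta <- layout_to_theta(lapply(theta0, function(x) 0 * x), layout)
    state <- structure(list(objective = 0, iterations = 0L, converged = TRUE,
                            monotone = TRUE, box_hit = FALSE),
                       class = "dc_state")
    return(list(theta = theta, state = state))
  }
  fit <- dc_fit_cpp(M = lapply(layout, `[[`, "M"),
                    subject = as.integer(terms$subject),
                    a = term_sign_matrix(terms),
                    w = terms$w, penw = pen, theta0 = theta0,
                    eta = config$eta, B = config$box,
                    max_dc = config$max_dc, max_sweep = config$max_sweep,
                    tol_obj = config$tol_obj, tol_coef = config$tol_coef)
  if (any(!is.finite(fit$objective))) {
    stop("numeric error: non-finite objective during the DC iteration")
  }
  if (fit$box_hit) {
    warning("a coefficient reached the box bound B = ", config$box,
            "; consider enlarging fit_config(box = )")
  }
  theta <- layout_to_theta(fit$theta, layout)
  state <- structure(list(objective = fit$objective,
                          iterations = fit$iterations,
                          converged = fit$converged,
                          monotone = fit$monotone,
                          box_hit = fit$box_hit),
                     class = "dc_state")
  list(theta = theta, state = state)
}

term_sign_matrix <- function(terms) {
  a <- terms$a
  storage.mode(a) <- "integer"
  a
}

# per-stage design layout: column order [intercept | unpenalized | penalized]
design_layout <- function(data) {
  lapply(seq_len(data$n_stages), function(t) {
    pen <- data$design$penalized[[t]]
    unpen <- data$design$unpenalized[[t]]
    H <- data$stages[[t]]$H
    M <- cbind(`(Intercept)` = 1,
               H[, unpen, drop = FALSE],
               H[, pen, drop = FALSE])
    list(M = M, pen = pen, unpen = unpen)
  })
}

layout_to_theta <- function(theta_flat, layout) {
  dtr_coefficients(lapply(seq_along(layout), function(t) {
    lay <- layout[[t]]
    v <- theta_flat[[t]]
    nu <- length(lay$unpen)
    list(gamma = v[1L],
         alpha = stats::setNames(v[seq_len(nu) + 1L], lay$unpen),
         beta = stats::setNames(v[seq_len(length(lay$pen)) + 1L + nu],
                                lay$pen))
  }))
}

# weights match candidates by name when the stage shares the weight names;
# otherwise by position (the p-th candidate corresponds across stages even
# when its per-stage measurement carries a different column name)
penalty_weights_for <- function(spec, pen_names) {
  if (length(pen_names) == 0L) return(numeric(0))
  if (is.null(spec$weights)) return(rep(1, length(pen_names)))
  if (all(pen_names %in% names(spec$weights))) {
    return(unname(spec$weights[pen_names]))
  }
  if (length(spec$weights) == length(pen_names)) {
    return(unname(spec$weights))
  }
  stop("adaptive weights match neither the names nor the number of the ",
       "stage's candidate features")
}

#' @exportS3Method base::print
print.dc_state <- function(x, ...) {
  cat(sprintf("DC fit: %d iteration(s), %s, objective %.6g -> %.6g\n",
              x$iterations, if (x$converged) "converged" else "iteration cap",
              x$objective[1L], x$objective[length(x$objective)]))
  invisible(x)
}

#' Subgradient of the concave part of the DC decomposition
#'
#' The minimization objective splits as G(theta) - H(theta) with both parts
#' convex piecewise-linear: writing psi = phi1 - phi2, phi1(u) = max(u, 0),
#' phi2(u) = max(u - 1, 0),
#' H(theta) = (1/n) sum_k w_k sum_s phi1(u_ks).  Each DC step minimizes
#' G(theta) - <grad H(theta_k), theta> + penalty.  At a kink (a margin
#' exactly 0) the slope-0 element of the subdifferential is taken, a fixed
#' convention that keeps runs reproducible; any valid subgradient preserves
#' the monotone decrease.
#'
#' @param theta A [dtr_coefficients()].
#' @param data A standardized [trajectory_data()] with propensities.
#' @param eta Shifting parameter.
#' @param terms Optionally, precomputed [surrogate_terms()].
#' @return A list (one element per stage) of named subgradient vectors in the
#'   layout `(Intercept)`, unpenalized, penalized.
#' @export
dc_linearize <- function(theta, data, eta, terms = NULL) {
  if (is.null(terms)) terms <- surrogate_terms(data)
  layout <- design_layout(data)
  g <- decision_values(theta, data)
  u <- terms$a * g[terms$subject, , drop = FALSE] / eta
  lapply(seq_len(data$n_stages), function(t) {
    r <- terms$w * (u[, t] > 0) * terms$a[, t] / (terms$n * eta)
    M <- layout[[t]]$M
    rows <- numeric(nrow(M))
    for (k in seq_along(r)) {
      rows[terms$subject[k]] <- rows[terms$subject[k]] + r[k]
    }
    drop(crossprod(M, rows))
  })
}

#' Exact minimizer of a convex piecewise-linear function plus an L1 term
#'
#' Given a continuous convex piecewise-linear f specified by its sorted
#' breakpoints and the slopes of its segments (length(slopes) =
#' length(breakpoints) + 1, nondecreasing), returns the global minimizer of
#' f(x) + l1_weight * |x| restricted to \[-box, box\].  The minimizer always
#' lies in \{breakpoints\} union \{0, -box, box\}; it is found by scanning the
#' combined slope-change events in order.  Ties over a flat segment resolve
#' to the segment's left endpoint.
#'
#' @param breakpoints Sorted numeric vector (may be empty).
#' @param slopes Numeric vector of segment slopes, nondecreasing.
#' @param l1_weight Nonnegative L1 weight.
#' @param box Box bound (default 100).
#' @return The scalar minimizer.
#' @export
#' @examples
#' coordinate_minimize(2, c(-1, 1), 0)         # f(x) = |x - 2|
#' coordinate_minimize(1, c(-3, 0), 1)         # 3*max(0, 1 - x) + |x|
coordinate_minimize <- function(breakpoints, slopes, l1_weight = 0,
                                box = 100) {
  stopifnot(l1_weight >= 0, box > 0)
  breakpoints <- as.numeric(breakpoints)
  slopes <- as.numeric(slopes)
  if (length(slopes) != length(breakpoints) + 1L) {
    stop("need length(slopes) == length(breakpoints) + 1")
  }
  if (is.unsorted(breakpoints)) stop("breakpoints must be sorted")
  jumps <- diff(slopes)
  if (any(jumps < -1e-12)) {
    stop("non-convex slope sequence (slopes must be nondecreasing)")
  }
  pos <- breakpoints
  if (l1_weight > 0) {
    pos <- c(pos, 0)
    jumps <- c(jumps, 2 * l1_weight)
    o <- order(pos)
    pos <- pos[o]
    jumps <- jumps[o]
  }
  s <- slopes[1L] - l1_weight
  inside <- pos > -box & pos < box
  s <- s + sum(jumps[pos <= -box])
  pos <- pos[inside]
  jumps <- jumps[inside]
  if (s >= 0) return(-box)
  for (i in seq_along(pos)) {
    s <- s + jumps[i]
    if (s >= 0) return(pos[i])
  }
  box
}
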