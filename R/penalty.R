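#' Adaptive group-lasso penalty specification
#'
#' The selection penalty is lambda * sum_p omega_p * sum_t |beta_tp|: an L1
#' penalty on each candidate feature's coefficients pooled across stages,
#' with per-feature adaptive weights omega_p derived from a pilot fit so that
#' features unimportant at every stage are penalized hardest.  Intercepts and
#' unpenalized features never enter the penalty.
#'
#' @param lambda Nonnegative penalty level.
#' @param weights Positive per-feature weights, length P (default: all 1).
#' @param gamma Exponent used when deriving weights from a pilot (recorded
#'   for provenance; the weights themselves are taken as given here).
#' @param weight_cap Finite upper bound applied to the weights (default 1e6);
#'   a pilot coefficient that is exactly zero at every stage would otherwise
#'   give an infinite weight.
#' @return An object of class `penalty_spec`.
#' @export
penalty_spec <- function(lambda, weights = NULL, gamma = 1, weight_cap = 1e6) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L, lambda >= 0,
            gamma > 0, weight_cap > 0, is.finite(weight_cap))
  if (!is.null(weights)) {
    weights <- as_named_numeric(weights)
    if (any(weights <= 0)) stop("adaptive weights must be strictly positive")
    weights <- pmin(weights, weight_cap)
  }
  structure(list(lambda = lambda, weights = weights, gamma = gamma,
                 weight_cap = weight_cap),
            class = "penalty_spec")
}

#' Normalize pilot coefficients stagewise
#'
#' Scales each stage's pilot coefficient vector over the P candidate features
#' to unit Euclidean norm, the normalization under which the adaptive weights
#' are defined.  An all-zero stage vector is left as zeros (the weight cap
#' absorbs the degenerate case downstream).
#'
#' @param beta_pilot A P x T matrix (or list of per-stage named vectors) of
#'   pilot coefficients for the candidate features.
#' @return A P x T matrix with unit-norm (or zero) columns.
#' @export
#' @examples
#' pilot_normalize(cbind(s1 = c(3, 4, 0)))
pilot_normalize <- function(beta_pilot) {
  B <- as_pilot_matrix(beta_pilot)
  nrm <- sqrt(colSums(B^2))
  nz <- nrm > 0
  B[, nz] <- sweep(B[, nz, drop = FALSE], 2L, nrm[nz], "/")
  B
}

as_pilot_matrix <- function(beta_pilot) {
  if (is.list(beta_pilot)) {
    nm <- names(beta_pilot[[1L]])
    B <- vapply(beta_pilot, function(b) as.numeric(b[nm]), numeric(length(nm)))
    B <- matrix(B, nrow = length(nm), dimnames = list(nm, NULL))
  } else {
    B <- as.matrix(beta_pilot)
  }
  B
}

#' Adaptive weights from a normalized pilot
#'
#' omega_p = (sum_t beta~_tp^2)^(-gamma/2), truncated at `cap`: features with
#' small pooled pilot magnitude receive large weights and are shrunk to exact
#' zero at any practical penalty level.
#'
#' @param beta_norm P x T matrix of stagewise-normalized pilot coefficients
#'   (see [pilot_normalize()]).
#' @param gamma Positive exponent; `gamma = 1` gives the penalty used by the
#'   main fitting routine.
#' @param cap Finite truncation bound for the weights.
#' @return A named vector of P positive weights.
#' @export
adaptive_weights <- function(beta_norm, gamma = 1, cap = 1e6) {
  stopifnot(gamma > 0, cap > 0)
  B <- as_pilot_matrix(beta_norm)
  g <- rowSums(B^2)
  w <- ifelse(g > 0, g^(-gamma / 2), Inf)
  stats::setNames(pmin(w, cap), rownames(B))
}

#' Penalty value at a coefficient vector
#'
#' lambda * sum_p omega_p * sum_t |beta_tp|.  Only penalized candidate
#' coefficients contribute; alpha and the intercepts are never penalized.
#'
#' @param theta A [dtr_coefficients()].
#' @param spec A [penalty_spec()]; if its weights are `NULL`, unit weights
#'   are used for every candidate present in `theta`.
#' @return A nonnegative number.
#' @export
penalty_value <- function(theta, spec) {
  stopifnot(inherits(theta, "dtr_coefficients"), inherits(spec, "penalty_spec"))
  if (spec$lambda == 0) return(0)
  total <- 0
  for (s in theta$stages) {
    b <- abs(s$beta)
    w <- if (is.null(spec$weights)) rep(1, length(b)) else {
      if (all(names(b) %in% names(spec$weights))) spec$weights[names(b)]
      else if (length(spec$weights) == length(b)) spec$weights  # positional
      else stop("adaptive weights match neither the names nor the number ",
                "of penalized coefficients")
    }
    total <- total + sum(w * b)
  }
  spec$lambda * total
}
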