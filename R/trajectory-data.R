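#' Multistage trajectory dataset
#'
#' Container for longitudinal SMART-style cohorts: `n` subjects observed over
#' `n_stages` decision stages.  Each stage carries a feature matrix `H` (no
#' intercept column; the intercept is handled by the models), a treatment
#' vector `A` coded in \{-1, +1\}, and optionally a vector `p` of
#' treatment-assignment probabilities P(A = observed | H).  A single terminal
#' cumulative reward `Y` is observed per subject (larger is better).
#'
#' @param stages List with one element per stage; each element is a list with
#'   components `H` (numeric matrix with column names), `A` (treatments in
#'   \{-1,+1\}) and optionally `p` (probabilities in (0,1)).
#' @param Y Numeric vector of terminal rewards, length `n`.
#' @param design A [stage_design()] describing which columns are candidates
#'   for selection.  If `NULL`, all columns at every stage are penalized.
#'
#' @return An object of class `trajectory_data` with fields `n`, `n_stages`,
#'   `stages`, `Y` and `design`.
#' @export
#' @examples
#' H1 <- cbind(Z1 = rnorm(4))
#' d <- trajectory_data(
#'   stages = list(list(H = H1, A = c(1, -1, 1, -1))),
#'   Y = rnorm(4)
#' )
#' d$n_stages
trajectory_data <- function(stages, Y, design = NULL) {
  stopifnot(is.list(stages), length(stages) >= 1L)
  Y <- as.numeric(Y)
  if (any(!is.finite(Y))) stop("terminal reward Y must be finite")
  n <- length(Y)
  stages <- lapply(seq_along(stages), function(t) {
    st <- stages[[t]]
    H <- as.matrix(st$H)
    if (is.null(colnames(H))) {
      colnames(H) <- paste0("V", seq_len(ncol(H)))
    }
    storage.mode(H) <- "double"
    if (nrow(H) != n) {
      stop("stage ", t, ": feature matrix has ", nrow(H),
           " rows but Y has length ", n)
    }
    A <- as.numeric(st$A)
    if (length(A) != n || !all(A %in% c(-1, 1))) {
      stop("stage ", t, ": treatments must be a length-", n,
           " vector with entries in {-1, +1}")
    }
    p <- st$p
    if (!is.null(p)) {
      p <- as.numeric(p)
      if (length(p) != n || any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
        stop("stage ", t, ": assignment probabilities must lie in (0, 1)")
      }
    }
    list(H = H, A = A, p = p)
  })
  if (is.null(design)) {
    design <- stage_design(
      penalized = lapply(stages, function(s) colnames(s$H))
    )
  }
  obj <- structure(
    list(n = n, n_stages = length(stages), stages = stages, Y = Y,
         design = design),
    class = "trajectory_data"
  )
  validate_trajectory_data(obj)
  obj
}

validate_trajectory_data <- function(x) {
  d <- x$design
  if (length(d$penalized) != x$n_stages) {
    stop("stage design covers ", length(d$penalized), " stages but data has ",
         x$n_stages)
  }
  P <- lengths(d$penalized)
  if (length(unique(P)) != 1L) {
    stop("the number P of penalized candidate features must be identical ",
         "across stages (got ", paste(P, collapse = ", "), ")")
  }
  for (t in seq_len(x$n_stages)) {
    cn <- colnames(x$stages[[t]]$H)
    pen <- d$penalized[[t]]
    unpen <- d$unpenalized[[t]]
    if (length(intersect(pen, unpen)) > 0L) {
      stop("stage ", t, ": penalized and unpenalized sets overlap")
    }
    miss <- setdiff(c(pen, unpen), cn)
    if (length(miss) > 0L) {
      stop("stage ", t, ": design names columns not in the data: ",
           paste(miss, collapse = ", "))
    }
  }
  invisible(x)
}

#' Stage design: penalized vs. unpenalized feature bookkeeping
#'
#' Splits each stage's history into `O_t` (a fixed number P of candidate
#' tailoring features, subject to selection) and `W_t` (already-known
#' important features such as earlier treatments, never penalized).  P must be
#' identical across stages so that coefficients of the same candidate can be
#' pooled across stages by the group penalty.
#'
#' @param penalized List (one character vector per stage) of candidate
#'   feature column names; all vectors must have equal length P.
#' @param unpenalized Optional list of unpenalized feature column names per
#'   stage (default: none).
#' @param no_scale Optional character vector of column names that must never
#'   be centered/scaled (e.g., \{-1,+1\}-coded earlier treatments carried as
#'   features).  Defaults to the unpenalized columns.
#'
#' @return An object of class `stage_design`.
#' @export
stage_design <- function(penalized, unpenalized = NULL, no_scale = NULL) {
  penalized <- lapply(penalized, as.character)
  n_stages <- length(penalized)
  if (is.null(unpenalized)) {
    unpenalized <- rep(list(character(0)), n_stages)
  }
  unpenalized <- lapply(unpenalized, as.character)
  if (length(unpenalized) != n_stages) {
    stop("penalized and unpenalized must describe the same number of stages")
  }
  if (length(unique(lengths(penalized))) != 1L) {
    stop("all stages must expose the same number P of penalized candidates")
  }
  if (is.null(no_scale)) no_scale <- unique(unlist(unpenalized))
  structure(
    list(penalized = penalized, unpenalized = unpenalized,
         P = length(penalized[[1L]]), no_scale = as.character(no_scale)),
    class = "stage_design"
  )
}

#' @exportS3Method base::print
print.trajectory_data <- function(x, ...) {
  cat("Multistage trajectory dataset\n")
  cat("  subjects:", x$n, "  stages:", x$n_stages, "\n")
  for (t in seq_len(x$n_stages)) {
    st <- x$stages[[t]]
    cat(sprintf("  stage %d: %d features (%d penalized), propensities %s\n",
                t, ncol(st$H), length(x$design$penalized[[t]]),
                if (is.null(st$p)) "absent" else "present"))
  }
  cat(sprintf("  reward Y: mean %.3f, range [%.3f, %.3f]\n",
              mean(x$Y), min(x$Y), max(x$Y)))
  invisible(x)
}

#' Read a delimited cohort table into a trajectory dataset
#'
#' Reads a comma- or tab-delimited table with a header row and assembles a
#' [trajectory_data()] according to a column map.  Treatment columns coded as
#' two arbitrary levels are recoded deterministically: the lexicographically
#' smaller level becomes -1.
#'
#' @param path Path to the delimited file (delimiter sniffed from the header
#'   line unless `sep` is given).
#' @param schema Column map: a list with one entry per stage, each a list with
#'   `features` (character vector), `treatment` (single column name) and
#'   optionally `propensity`; plus a top-level `reward` entry naming the
#'   reward column and optional `unpenalized` (list per stage).  See
#'   [read_schema()] for the key-value file form.
#' @param sep Field delimiter; `NULL` (default) sniffs "," vs tab.
#'
#' @return A [trajectory_data()].
#' @export
read_cohort <- function(path, schema, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  stage_specs <- schema$stages
  if (is.null(stage_specs)) stop("schema must contain a 'stages' list")
  if (is.null(schema$reward)) stop("schema must name the reward column")
  need <- c(schema$reward,
            unlist(lapply(stage_specs, function(s) c(s$features, s$treatment,
                                                     s$propensity))))
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) {
    stop("schema error: missing column(s): ", paste(miss, collapse = ", "))
  }
  Y <- tab[[schema$reward]]
  if (any(!is.finite(Y))) stop("validation error: non-finite reward values")
  stages <- lapply(seq_along(stage_specs), function(t) {
    sp <- stage_specs[[t]]
    H <- as.matrix(tab[, sp$features, drop = FALSE])
    A <- recode_treatment(tab[[sp$treatment]], sp$treatment)
    p <- if (!is.null(sp$propensity)) tab[[sp$propensity]] else NULL
    list(H = H, A = A, p = p)
  })
  unpen <- schema$unpenalized
  design <- stage_design(
    penalized = lapply(seq_along(stage_specs), function(t) {
      sp <- stage_specs[[t]]
      setdiff(sp$features,
              if (is.null(unpen)) character(0) else unpen[[t]])
    }),
    unpenalized = if (is.null(unpen)) NULL else lapply(unpen, as.character)
  )
  trajectory_data(stages, Y, design)
}

# Map a 2-level treatment coding onto {-1,+1}; lexicographically smaller
# level -> -1.  Already-signed numeric input passes through.
recode_treatment <- function(a, col) {
  lv <- sort(unique(as.character(a)))
  if (length(lv) != 2L) {
    stop("coding error: treatment column '", col, "' has ", length(lv),
         " levels; exactly 2 required")
  }
  if (setequal(lv, c("-1", "1"))) {
    return(as.numeric(as.character(a)))
  }
  ifelse(as.character(a) == lv[1L], -1, 1)
}

#' Write a trajectory dataset to a delimited table
#'
#' Inverse of [read_cohort()]: flattens the per-stage matrices into one table
#' with columns `<name>.s<t>` for features that recur across stages, `A<t>`,
#' optional `p<t>`, and `Y`.  Returns the schema needed to read it back.
#'
#' @param data A [trajectory_data()].
#' @param path Output file path; the delimiter is chosen from the extension
#'   (".tsv" gives tab, anything else comma).
#' @return Invisibly, the schema list that round-trips the file through
#'   [read_cohort()].
#' @export
write_cohort <- function(data, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  out <- data.frame(row.names = seq_len(data$n))
  stages <- vector("list", data$n_stages)
  for (t in seq_len(data$n_stages)) {
    st <- data$stages[[t]]
    feat <- paste0(colnames(st$H), ".s", t)
    H <- st$H
    colnames(H) <- feat
    out <- cbind(out, H)
    out[[paste0("A", t)]] <- st$A
    sp <- list(features = feat, treatment = paste0("A", t))
    if (!is.null(st$p)) {
      out[[paste0("p", t)]] <- st$p
      sp$propensity <- paste0("p", t)
    }
    stages[[t]] <- sp
  }
  out$Y <- data$Y
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  unpen <- lapply(seq_len(data$n_stages), function(t) {
    paste0(data$design$unpenalized[[t]],
           ifelse(data$design$unpenalized[[t]] %in%
                    colnames(data$stages[[t]]$H), paste0(".s", t), ""))
  })
  schema <- list(stages = stages, reward = "Y",
                 unpenalized = if (all(lengths(unpen) == 0L)) NULL else unpen)
  invisible(schema)
}

#' Center and scale stage features
#'
#' Standardizes every feature column (except columns listed in the design's
#' `no_scale`, e.g. treatment-coded ones) using means and population standard
#' deviations computed on `fit_rows`, so that held-out folds can reuse the
#' training statistics.  Constant columns are left unscaled (scale fixed at 1)
#' with a warning.
#'
#' @param data A [trajectory_data()].
#' @param fit_rows Row indices used to compute the statistics (default: all).
#' @return A list with `data` (the transformed dataset) and `state`, a
#'   `standardization_state` reusable via [apply_standardization()].
#' @export
standardize_trajectories <- function(data, fit_rows = seq_len(data$n)) {
  fit_rows <- as.integer(fit_rows)
  if (length(fit_rows) == 0L) stop("fit_rows must be nonempty")
  state <- vector("list", data$n_stages)
  for (t in seq_len(data$n_stages)) {
    H <- data$stages[[t]]$H[fit_rows, , drop = FALSE]
    m <- nrow(H)
    center <- colMeans(H)
    # population SD: divide by n, one fixed convention for penalized fits
    scale <- sqrt(colMeans(sweep(H, 2L, center)^2))
    skip <- colnames(H) %in% data$design$no_scale
    const <- !skip & scale <= .Machine$double.eps * 1e2
    if (any(const)) {
      warning("stage ", t, ": constant column(s) left unscaled: ",
              paste(colnames(H)[const], collapse = ", "))
    }
    center[skip | const] <- 0
    scale[skip | const] <- 1
    state[[t]] <- list(center = center, scale = scale)
  }
  state <- structure(state, class = "standardization_state")
  list(data = apply_standardization(state, data), state = state)
}

#' Apply a previously learned standardization
#'
#' @param state A `standardization_state` from [standardize_trajectories()].
#' @param data A [trajectory_data()] whose stage columns match the state.
#' @return The transformed [trajectory_data()].
#' @export
apply_standardization <- function(state, data) {
  stopifnot(inherits(state, "standardization_state"),
            length(state) == data$n_stages)
  for (t in seq_len(data$n_stages)) {
    st <- state[[t]]
    H <- data$stages[[t]]$H
    if (!identical(colnames(H), names(st$center))) {
      stop("stage ", t, ": columns do not match the standardization state")
    }
    data$stages[[t]]$H <- sweep(sweep(H, 2L, st$center), 2L, st$scale, "/")
  }
  data
}

#' Per-stage linear decision-rule coefficients
#'
#' A fitted regimen is one linear decision function per stage,
#' g_t(H_t) = O_t' beta_t + W_t' alpha_t + gamma_t, with the recommended
#' treatment sign(g_t) (sign(0) resolved to +1).  `beta` holds the penalized
#' candidate coefficients, `alpha` the unpenalized ones, `gamma` the
#' intercept.
#'
#' @param stages List with one element per stage, each a list with named
#'   numeric vectors `beta` and `alpha` and scalar `gamma`.
#' @return An object of class `dtr_coefficients`.
#' @export
dtr_coefficients <- function(stages) {
  stages <- lapply(stages, function(s) {
    list(beta = as_named_numeric(s$beta), alpha = as_named_numeric(s$alpha),
         gamma = as.numeric(s$gamma %||% 0))
  })
  structure(list(stages = stages, n_stages = length(stages)),
            class = "dtr_coefficients")
}

as_named_numeric <- function(x) {
  if (is.null(x)) return(stats::setNames(numeric(0), character(0)))
  y <- as.numeric(x)
  names(y) <- names(x)
  y
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @exportS3Method base::print
print.dtr_coefficients <- function(x, ...) {
  cat("Linear dynamic treatment regimen coefficients\n")
  for (t in seq_len(x$n_stages)) {
    s <- x$stages[[t]]
    nz <- sum(abs(s$beta) > 1e-6)
    cat(sprintf("  stage %d: %d/%d penalized features selected; intercept %.4g\n",
                t, nz, length(s$beta), s$gamma))
  }
  invisible(x)
}

#' Evaluate the linear decision functions
#'
#' @param theta A [dtr_coefficients()].
#' @param data A [trajectory_data()] on the same (standardized) scale the
#'   coefficients were fitted on.
#' @return An `n x n_stages` matrix of decision values g_t(H_it).
#' @export
decision_values <- function(theta, data) {
  stopifnot(inherits(theta, "dtr_coefficients"),
            theta$n_stages == data$n_stages)
  g <- matrix(0, data$n, data$n_stages)
  for (t in seq_len(data$n_stages)) {
    s <- theta$stages[[t]]
    H <- data$stages[[t]]$H
    v <- rep(s$gamma, data$n)
    if (length(s$beta)) v <- v + H[, names(s$beta), drop = FALSE] %*% s$beta
    if (length(s$alpha)) v <- v + H[, names(s$alpha), drop = FALSE] %*% s$alpha
    g[, t] <- v
  }
  g
}

#' Recommended treatments under a fitted regimen
#'
#' @inheritParams decision_values
#' @return An `n x n_stages` matrix with entries in \{-1,+1\};
#'   `sign(0)` resolves to +1.
#' @export
dtr_decisions <- function(theta, data) {
  sign_pos(decision_values(theta, data))
}

# fixed tie-break: sign(0) -> +1
sign_pos <- function(x) ifelse(x >= 0, 1, -1)
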