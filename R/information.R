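#' Fisher information of a subject observed at the first j occasions
#'
#' Returns \eqn{X_{[j]}^T V_{[j]}^{-1} X_{[j]}}, where the subscript
#' denotes the leading j rows of the design matrix and the leading j-by-j
#' block of the response covariance (the marginal covariance of a
#' truncated multivariate normal follow-up series).
#'
#' @param X q-by-p fixed-effects design matrix.
#' @param V q-by-q response covariance matrix.
#' @param j Number of observed occasions, `1 <= j <= q`.
#' @return A p-by-p matrix.
#' @export
pattern_information <- function(X, V, j) {
  stopifnot(is.matrix(X), is.matrix(V), nrow(X) == nrow(V),
            nrow(V) == ncol(V))
  j <- as.integer(j)
  if (j < 1L || j > nrow(X)) stop("'j' must be in 1..q", call. = FALSE)
  Xj <- X[seq_len(j), , drop = FALSE]
  Vj <- V[seq_len(j), seq_len(j), drop = FALSE]
  sol <- tryCatch(solve(Vj, Xj), error = function(e) {
    stop("leading ", j, "x", j, " covariance block is singular",
         call. = FALSE)
  })
  crossprod(Xj, sol)
}

#' Expected Fisher information of a design under dropout
#'
#' The information expected from an available-case analysis, summing each
#' group's per-pattern subject information weighted by the expected
#' pattern counts:
#' \deqn{\sum_{k=1}^{c} \sum_{j=1}^{q} m_{k,j}\,
#'   X_{k[j]}^T V_{k[j]}^{-1} X_{k[j]},}
#' with \eqn{m_{k,j} = N w_k \pi_{k,j}} from
#' [expected_pattern_counts()]. With no dropout this reduces to the
#' complete-data information \eqn{N \sum_k w_k X_k^T V_k^{-1} X_k}.
#'
#' @param design A [trial_design()].
#' @param model An [lmm_spec()].
#' @param dropout A [dropout_spec()] (shared by all groups) or a list of
#'   one per group.
#' @return An object of class `"fisher_info"`: list with the p-by-p
#'   `matrix` and `p`.
#' @export
expected_information <- function(design, model, dropout) {
  stopifnot(inherits(design, "trial_design"), inherits(model, "lmm_spec"))
  c_groups <- length(design$groups)
  if (model$fixed$model == "Mg" && c_groups != model$fixed$groups) {
    stop("design has ", c_groups, " groups but the model expects ",
         model$fixed$groups, call. = FALSE)
  }
  dropout <- per_group_dropout(dropout, c_groups)
  p <- model$fixed$p
  A <- matrix(0, p, p)
  for (k in seq_len(c_groups)) {
    g <- design$groups[[k]]
    X <- build_fixed_design(model$fixed, g$t, group = k, dose = g$dose)
    V <- model_covariance(model, g$t)
    m <- design$N * g$w *
      pattern_probabilities(dropout[[k]], g$t, g$dose)
    for (j in seq_along(g$t)) {
      if (m[j] > 0) A <- A + m[j] * pattern_information(X, V, j)
    }
  }
  A <- (A + t(A)) / 2
  structure(list(matrix = A, p = p), class = "fisher_info")
}

#' D-optimality criterion (log-determinant of the information)
#'
#' @param info A `"fisher_info"` object or a plain symmetric matrix.
#' @return The log-determinant, or `-Inf` when the matrix is not positive
#'   definite (so that an optimizer rejects the design).
#' @export
d_criterion <- function(info) {
  A <- if (inherits(info, "fisher_info")) info$matrix else info
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  ld <- determinant(A, logarithm = TRUE)
  if (ld$sign <= 0) return(-Inf)
  ## determinant() does not guarantee positive definiteness, only a
  ## positive determinant; check via Cholesky
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  as.numeric(ld$modulus)
}

#' Relative D-efficiency of one design against a reference
#'
#' \deqn{\mathrm{RED}(\xi, \xi^*) =
#'   \left(\frac{|\mathrm{cov}_{\xi^*}|}{|\mathrm{cov}_{\xi}|}\right)^{1/p},}
#' the per-parameter efficiency of design \eqn{\xi} (candidate) relative
#' to \eqn{\xi^*} (reference), both summarised by the covariance matrix of
#' the fixed-effect estimator. Values below one mean the candidate is less
#' efficient than the reference.
#'
#' @param cov_candidate p-by-p covariance matrix of the candidate design.
#' @param cov_reference p-by-p covariance matrix of the reference design.
#' @param p Number of fixed effects (defaults to `nrow(cov_candidate)`).
#' @return A positive scalar.
#' @export
relative_d_efficiency <- function(cov_candidate, cov_reference,
                                  p = nrow(cov_candidate)) {
  for (M in list(cov_candidate, cov_reference)) {
    stopifnot(is.matrix(M), nrow(M) == ncol(M), nrow(M) == p)
    if (is.null(tryCatch(chol(M), error = function(e) NULL))) {
      stop("covariance matrix is not positive definite", call. = FALSE)
    }
  }
  ldc <- as.numeric(determinant(cov_candidate, TRUE)$modulus)
  ldr <- as.numeric(determinant(cov_reference, TRUE)$modulus)
  exp((ldr - ldc) / p)
}

#' Approximate covariance of the fixed-effect estimator under a design
#'
#' The inverse of the expected Fisher information, used throughout as the
#' covariance approximation for design comparison.
#'
#' @inheritParams expected_information
#' @return A p-by-p matrix.
#' @export
design_covariance <- function(design, model, dropout) {
  info <- expected_information(design, model, dropout)
  solve(info$matrix)
}

#' @export
print.fisher_info <- function(x, ...) {
  cat("Expected Fisher information (p =", x$p, ")\n")
  print(x$matrix)
  cat("log det =", format(d_criterion(x)), "\n")
  invisible(x)
}
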