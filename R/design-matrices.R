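#' Fixed-effects design matrix of one group
#'
#' Builds the q-by-p design matrix whose row j is the gradient of the mean
#' response at time `t[j]` with respect to the fixed effects. For model
#' `"Mg"` in group k the row has a 1 in the intercept column and `t[j]` in
#' the slope column of group k (all other entries 0); for model `"Md"` the
#' row is `(1, t[j], dose)`.
#'
#' @param spec A [fixed_effects()] object.
#' @param t Strictly increasing vector of measurement times.
#' @param group Group index in `1:spec$groups` (model `"Mg"` only; also
#'   accepted and ignored for `"Md"`).
#' @param dose Dose level (required for model `"Md"`, forbidden for `"Mg"`).
#' @return A `length(t)` by `spec$p` numeric matrix.
#' @examples
#' build_fixed_design(fixed_effects("Md"), t = c(0, 42), dose = 100)
#' build_fixed_design(fixed_effects("Mg"), t = c(-1, 1), group = 2)
#' @export
build_fixed_design <- function(spec, t, group = 1L, dose = NULL) {
  stopifnot(inherits(spec, "fixed_effects"))
  check_times(t)
  q <- length(t)
  if (spec$model == "Md") {
    if (is.null(dose)) {
      stop("model 'Md' requires a dose level", call. = FALSE)
    }
    stopifnot(is.numeric(dose), length(dose) == 1L)
    return(cbind(1, t, dose, deparse.level = 0))
  }
  if (!is.null(dose)) {
    stop("model 'Mg' does not take a dose level", call. = FALSE)
  }
  group <- as.integer(group)
  if (group < 1L || group > spec$groups) {
    stop("'group' must be in 1..", spec$groups, call. = FALSE)
  }
  X <- matrix(0, q, spec$p)
  X[, 1L] <- 1
  X[, group + 1L] <- t
  X
}

#' Marginal covariance matrix of a subject's repeated measurements
#'
#' Computes \eqn{V = Z D Z^T + \sigma^2 \Psi} at the supplied time points,
#' where the random-effects design Z has a column of ones for a random
#' intercept and a column of times for a random slope (no Z for the
#' fixed-effects class), and \eqn{\Psi} follows the serial correlation
#' structure in `corr`.
#'
#' Because V depends on the times only through pairwise differences and
#' the per-time Z rows, the leading j-by-j block of V over a full schedule
#' equals V evaluated at the first j times: truncating a subject's
#' follow-up simply marginalises the multivariate normal.
#'
#' @param t Strictly increasing vector of measurement times.
#' @param random A [random_effects()] object.
#' @param sigma2 Error variance.
#' @param corr A [corr_spec()] object.
#' @return A symmetric positive-definite `length(t)` square matrix.
#' @examples
#' build_response_covariance(c(0, 1), random_effects("RI", 1), 1,
#'                           corr_spec("independent"))
#' @export
build_response_covariance <- function(t, random, sigma2, corr) {
  stopifnot(inherits(random, "random_effects"), inherits(corr, "corr_spec"),
            is.numeric(sigma2), length(sigma2) == 1L, sigma2 > 0)
  check_times(t)
  q <- length(t)
  Psi <- switch(corr$kind,
    independent = diag(q),
    compound_symmetry = {
      M <- matrix(corr$rho, q, q)
      diag(M) <- 1
      M
    },
    ar1 = {
      if (corr$rho == 0) diag(q) else corr$rho^abs(outer(t, t, "-"))
    }
  )
  V <- sigma2 * Psi
  if (random$class != "FE") {
    Z <- if (random$class == "RI") cbind(rep(1, q)) else cbind(1, t)
    D <- if (random$class == "RI") {
      matrix(random$d11, 1, 1)
    } else {
      matrix(c(random$d11, random$d12, random$d12, random$d22), 2, 2)
    }
    V <- V + Z %*% D %*% t(Z)
  }
  V <- (V + t(V)) / 2
  if (min(eigen(V, symmetric = TRUE, only.values = TRUE)$values) <= 1e-10) {
    stop("response covariance is not positive definite", call. = FALSE)
  }
  V
}

## V for one group of a model spec (internal)
model_covariance <- function(model, t) {
  build_response_covariance(t, model$random, model$sigma2, model$corr)
}
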