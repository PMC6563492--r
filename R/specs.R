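#' Serial correlation structure of the within-subject errors
#'
#' Describes the correlation matrix \eqn{\Psi} of the observational errors
#' at a subject's measurement times. Three structures are supported:
#' `"independent"` (identity), `"compound_symmetry"` (constant off-diagonal
#' correlation `rho`), and `"ar1"`, a continuous-time first-order
#' autoregressive process with entries \eqn{\rho^{|t_j - t_{j'}|}}.
#'
#' `rho` is interpreted per unit of whatever time scale the caller uses for
#' the design (e.g. per day when time points are in days); no internal
#' rescaling is performed. At `rho = 0` the AR(1) structure is defined as
#' the identity matrix (continuity convention, `0^0 = 1` on the diagonal).
#'
#' @param kind One of `"independent"`, `"compound_symmetry"`, `"ar1"`.
#' @param rho Correlation parameter in `[0, 1)`. Ignored for
#'   `kind = "independent"`.
#' @return An object of class `"corr_spec"`.
#' @examples
#' corr_spec("ar1", rho = 0.3326)
#' @export
corr_spec <- function(kind = c("independent", "compound_symmetry", "ar1"),
                      rho = 0) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(rho), length(rho) == 1L, is.finite(rho))
  if (kind != "independent" && (rho < 0 || rho >= 1)) {
    stop("'rho' must lie in [0, 1) for kind = '", kind, "'", call. = FALSE)
  }
  if (kind == "independent") rho <- 0
  structure(list(kind = kind, rho = rho), class = "corr_spec")
}

#' Random-effects structure of a linear mixed model
#'
#' The subject-level random coefficients are at most a random intercept
#' \eqn{b_0} and a random time slope \eqn{b_1} with covariance matrix
#' \deqn{D = \begin{pmatrix} d_{11} & d_{12} \\ d_{12} & d_{22} \end{pmatrix}.}
#' The four recognised classes are the fixed-effects model (`"FE"`, D = 0),
#' the random-intercept model (`"RI"`), uncorrelated random intercept and
#' slope (`"RIRS"`), and correlated random intercept and slope (`"RIRSc"`).
#'
#' @param class One of `"FE"`, `"RI"`, `"RIRS"`, `"RIRSc"`.
#' @param d11 Variance of the random intercept.
#' @param d22 Variance of the random slope.
#' @param d12 Covariance between intercept and slope.
#' @return An object of class `"random_effects"`.
#' @examples
#' random_effects("RI", d11 = 2.661^2)
#' random_effects("RIRS", d11 = 1, d22 = 3)
#' @export
random_effects <- function(class = c("FE", "RI", "RIRS", "RIRSc"),
                           d11 = 0, d22 = 0, d12 = 0) {
  class <- match.arg(class)
  stopifnot(is.numeric(d11), is.numeric(d22), is.numeric(d12),
            length(d11) == 1L, length(d22) == 1L, length(d12) == 1L)
  ok <- switch(class,
    FE    = d11 == 0 && d22 == 0 && d12 == 0,
    RI    = d11 > 0 && d22 == 0 && d12 == 0,
    RIRS  = d11 > 0 && d22 > 0 && d12 == 0,
    RIRSc = d11 > 0 && d22 > 0 && d12 != 0 && d12^2 < d11 * d22
  )
  if (!ok) {
    stop("(d11, d22, d12) = (", d11, ", ", d22, ", ", d12,
         ") is not a valid covariance for random-effects class '",
         class, "'", call. = FALSE)
  }
  structure(list(class = class, d11 = d11, d22 = d22, d12 = d12),
            class = "random_effects")
}

#' Fixed-effects structure of the trial model
#'
#' Two mean structures are supported. Model `"Mg"` assumes comparable
#' baselines across the `groups` arms: a common intercept and one time
#' slope per group, selected by a group indicator, so the mean at time
#' \eqn{t} for a subject in group \eqn{k} is \eqn{\beta_0 + t \beta_k}
#' (p = groups + 1 fixed effects). Model `"Md"` treats the arm as a dose
#' level \eqn{\delta} of a continuous treatment variable, with mean
#' \eqn{\beta_0 + t \beta_1 + \delta \beta_2} (p = 3 fixed effects).
#'
#' @param model `"Mg"` or `"Md"`.
#' @param groups Number of arms (at least 2).
#' @param beta Optional vector of fixed-effect coefficients, used only by
#'   the trial simulator; design criteria do not depend on it.
#' @return An object of class `"fixed_effects"` with an element `p`, the
#'   number of fixed effects.
#' @examples
#' fixed_effects("Md", beta = c(8.939, -0.0866, 0.01458))
#' @export
fixed_effects <- function(model = c("Mg", "Md"), groups = 2L, beta = NULL) {
  model <- match.arg(model)
  groups <- as.integer(groups)
  stopifnot(groups >= 2L)
  p <- if (model == "Mg") groups + 1L else 3L
  if (!is.null(beta)) {
    stopifnot(is.numeric(beta))
    if (length(beta) != p) {
      stop("'beta' must have length ", p, " for model ", model, call. = FALSE)
    }
  }
  structure(list(model = model, groups = groups, p = p, beta = beta),
            class = "fixed_effects")
}

#' Linear mixed model specification
#'
#' Bundles the fixed-effect structure, random-effects covariance, error
#' variance and serial correlation into a single model object
#' \eqn{y_i = X_i \beta + Z_i b_i + \varepsilon_i} with
#' \eqn{b_i \sim N(0, D)} and
#' \eqn{\varepsilon_i \sim N(0, \sigma^2 \Psi)}.
#'
#' @param fixed A [fixed_effects()] object.
#' @param random A [random_effects()] object.
#' @param sigma2 Error variance \eqn{\sigma^2 > 0}.
#' @param corr A [corr_spec()] object.
#' @return An object of class `"lmm_spec"`.
#' @examples
#' lmm_spec(fixed_effects("Md"), random_effects("RI", d11 = 2.661^2),
#'          sigma2 = 2.613^2, corr = corr_spec("ar1", 0.3326))
#' @export
lmm_spec <- function(fixed, random, sigma2, corr = corr_spec("independent")) {
  stopifnot(inherits(fixed, "fixed_effects"),
            inherits(random, "random_effects"),
            inherits(corr, "corr_spec"),
            is.numeric(sigma2), length(sigma2) == 1L, sigma2 > 0)
  structure(list(fixed = fixed, random = random,
                 sigma2 = sigma2, corr = corr),
            class = "lmm_spec")
}

#' @export
print.lmm_spec <- function(x, ...) {
  cat("Linear mixed model (", x$fixed$model, "), ",
      x$fixed$groups, " groups, p = ", x$fixed$p, " fixed effects\n",
      "  random effects: ", x$random$class,
      " (d11 = ", format(x$random$d11), ", d22 = ", format(x$random$d22),
      ", d12 = ", format(x$random$d12), ")\n",
      "  sigma^2 = ", format(x$sigma2), ", errors: ", x$corr$kind,
      if (x$corr$kind != "independent") paste0(" (rho = ", x$corr$rho, ")"),
      "\n", sep = "")
  invisible(x)
}

## shared helper: strictly increasing time vector
check_times <- function(t) {
  if (!is.numeric(t) || length(t) < 1L || anyNA(t)) {
    stop("time points must be a numeric vector without NAs", call. = FALSE)
  }
  if (is.unsorted(t, strictly = TRUE)) {
    stop("time points must be strictly increasing", call. = FALSE)
  }
  invisible(t)
}
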