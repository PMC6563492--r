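#' Response-probability (retention) function of one group
#'
#' Describes the probability that a subject is still observed at time t,
#' possibly depending on the dose level. Supported families:
#' \describe{
#'   \item{`linear`}{`p = a + b t`, coefficients `c(a, b)`.}
#'   \item{`quadratic`}{`p = a + b t + c t^2`, coefficients `c(a, b, c)`.}
#'   \item{`logistic`}{`p = 1 / (1 + exp(g0 + g1 dose + g2 t))`,
#'     coefficients `c(g0, g1, g2)`; `g1 < 0`, `g2 > 0` gives retention
#'     increasing with dose and decreasing with time.}
#'   \item{`constant_one`}{no dropout, `p = 1` everywhere.}
#' }
#'
#' `baseline_certain` controls how dropout patterns are formed at the first
#' (baseline) occasion; see [pattern_probabilities()]. By default it is
#' `TRUE` for the logistic family, whose retention probability can never
#' equal one at baseline, and `FALSE` otherwise.
#'
#' @param family Response-probability family.
#' @param coef Numeric coefficient vector (see above; empty for
#'   `constant_one`).
#' @param baseline_certain Logical; is the baseline measurement always
#'   observed?
#' @return An object of class `"dropout_spec"`.
#' @examples
#' dropout_spec("linear", c(0.65, -0.35))
#' dropout_spec("logistic", c(-2.2332, -0.0131, 0.0100))
#' @export
dropout_spec <- function(family = c("linear", "quadratic", "logistic",
                                    "constant_one"),
                         coef = numeric(),
                         baseline_certain = NULL) {
  family <- match.arg(family)
  need <- c(linear = 2L, quadratic = 3L, logistic = 3L, constant_one = 0L)
  if (length(coef) != need[[family]]) {
    stop("family '", family, "' needs ", need[[family]], " coefficients",
         call. = FALSE)
  }
  stopifnot(is.numeric(coef))
  if (is.null(baseline_certain)) baseline_certain <- family == "logistic"
  stopifnot(is.logical(baseline_certain), length(baseline_certain) == 1L)
  structure(list(family = family, coef = unname(coef),
                 baseline_certain = baseline_certain),
            class = "dropout_spec")
}

#' Probability of still being observed at a time point
#'
#' @param spec A [dropout_spec()].
#' @param t Time point(s) within the declared design region.
#' @param dose Dose level; required for the logistic family, ignored
#'   otherwise.
#' @return Probability value(s) in `[0, 1]`.
#' @examples
#' response_prob(dropout_spec("linear", c(0.65, -0.35)), -1)
#' @export
response_prob <- function(spec, t, dose = NULL) {
  stopifnot(inherits(spec, "dropout_spec"), is.numeric(t))
  p <- switch(spec$family,
    constant_one = rep(1, length(t)),
    linear = spec$coef[1] + spec$coef[2] * t,
    quadratic = spec$coef[1] + spec$coef[2] * t + spec$coef[3] * t^2,
    logistic = {
      if (is.null(dose)) {
        stop("logistic response probability requires a dose", call. = FALSE)
      }
      1 / (1 + exp(spec$coef[1] + spec$coef[2] * dose + spec$coef[3] * t))
    }
  )
  if (any(p < -1e-12 | p > 1 + 1e-12)) {
    stop("response probability falls outside [0, 1] at the supplied times",
         call. = FALSE)
  }
  pmin(pmax(p, 0), 1)
}

#' Validate a dropout model over a design region
#'
#' Checks numerically, on a grid of 1000 points, that the response
#' probability lies in `[0, 1]` and is non-increasing in time over the
#' declared region (a monotone response-probability function is what makes
#' the dropout patterns a proper multinomial).
#'
#' @param spec A [dropout_spec()].
#' @param region Length-2 numeric vector, the time design region.
#' @param dose Dose level for the logistic family.
#' @return `TRUE` invisibly, or an error.
#' @export
validate_dropout <- function(spec, region, dose = NULL) {
  stopifnot(is.numeric(region), length(region) == 2L, region[1] < region[2])
  grid <- seq(region[1], region[2], length.out = 1000L)
  p <- response_prob(spec, grid, dose)
  if (any(diff(p) > 1e-12)) {
    stop("response probability is not non-increasing over the region",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Multinomial dropout-pattern probabilities of one group
#'
#' Under monotone dropout a subject is observed at the first j occasions
#' and missing thereafter; the pattern index j follows a multinomial
#' distribution across subjects. With `baseline_certain = TRUE` (subjects
#' are always observed at baseline) the probabilities are
#' \deqn{\pi_1 = 1 - p(t_2),\quad \pi_j = p(t_j) - p(t_{j+1})\ (2 \le j < q),
#'   \quad \pi_q = p(t_q).}
#' With `baseline_certain = FALSE` the first element is
#' \eqn{p(t_1) - p(t_2)}, which requires `p(t_1) = 1` (within `1e-9`) so
#' that the probabilities sum to one; the two forms then coincide.
#'
#' @param spec A [dropout_spec()].
#' @param t Strictly increasing time vector of length at least 2.
#' @param dose Dose level for the logistic family.
#' @return Numeric vector of length `length(t)`, non-negative, summing
#'   to 1.
#' @examples
#' pattern_probabilities(dropout_spec("logistic",
#'   c(-2.2332, -0.0131, 0.0100)), c(0, 42, 126, 210, 364), dose = 0)
#' @export
pattern_probabilities <- function(spec, t, dose = NULL) {
  stopifnot(inherits(spec, "dropout_spec"))
  check_times(t)
  q <- length(t)
  if (q < 2L) stop("need at least two time points", call. = FALSE)
  p <- response_prob(spec, t, dose)
  if (!spec$baseline_certain && abs(p[1] - 1) > 1e-9) {
    stop("response probability at baseline is ", format(p[1]),
         ", not 1; use baseline_certain = TRUE or fix the model",
         call. = FALSE)
  }
  pi <- c(1 - p[2],
          if (q > 2L) p[2:(q - 1L)] - p[3:q],
          p[q])
  if (any(pi < -1e-9)) {
    stop("negative pattern probability: response probability is not ",
         "monotone over the supplied time points", call. = FALSE)
  }
  pi <- pmax(pi, 0)
  pi / sum(pi)
}

## round half away from zero, for human-readable count tables
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Expected dropout-pattern counts of one group
#'
#' Multiplies the multinomial pattern probabilities by the group
#' allocation: `m[j]` is the expected number of subjects observed at
#' exactly j occasions.
#'
#' @param spec A [dropout_spec()].
#' @param t Strictly increasing time vector.
#' @param dose Dose level for the logistic family.
#' @param n_alloc Number of subjects allocated to the group (may be
#'   fractional for approximate designs).
#' @return An object of class `"pattern_counts"`: a list with elements
#'   `m` (expected counts), `m_rounded` (rounded half away from zero),
#'   `pattern_probs`, and `n_alloc`.
#' @examples
#' expected_pattern_counts(dropout_spec("logistic",
#'   c(-2.2332, -0.0131, 0.0100)), c(0, 42, 126, 210, 364),
#'   dose = 0, n_alloc = 72)
#' @export
expected_pattern_counts <- function(spec, t, dose = NULL, n_alloc) {
  stopifnot(is.numeric(n_alloc), length(n_alloc) == 1L, n_alloc >= 0)
  pi <- pattern_probabilities(spec, t, dose)
  m <- n_alloc * pi
  structure(list(m = m,
                 m_rounded = as.integer(round_half_away(m)),
                 pattern_probs = pi,
                 n_alloc = n_alloc),
            class = "pattern_counts")
}

#' @export
print.pattern_counts <- function(x, ...) {
  cat("Expected dropout-pattern counts (n =", format(x$n_alloc), ")\n")
  tab <- rbind(`P(j observed)` = round(x$pattern_probs, 4),
               `expected m_j` = round(x$m, 2),
               rounded = x$m_rounded)
  colnames(tab) <- paste0("j=", seq_along(x$m))
  print(tab)
  invisible(x)
}
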