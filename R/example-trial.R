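#' Bundled example: redesigning a one-year two-arm dementia trial
#'
#' A worked configuration for a one-year trial on Alzheimer's disease
#' comparing placebo (dose 0) with an active treatment (dose 100 on a
#' standardised scale), five measurement occasions, and N = 144 subjects.
#' The model is the dose-response linear mixed model (`"Md"`) with a
#' random intercept and AR(1) errors on the day scale; the dropout model
#' is logistic in dose and time. Parameter values are point estimates
#' elicited from historical data of such a trial and are the local values
#' at which the bundled design problems are optimal.
#'
#' `dementia_model()` uses the variance reading `d11 = 2.661^2`,
#' `sigma^2 = 2.613^2` by default; `reading = "literal"` keeps `2.6612`
#' and `2.6132` as-is. Because a random-intercept model's optimal time
#' points depend only on `d11 / sigma^2` and `rho`, the two readings give
#' nearly identical designs.
#'
#' @param reading `"squared"` (default) or `"literal"`.
#' @return `dementia_model()`: an [lmm_spec()]. `dementia_dropout()`: a
#'   [dropout_spec()]. `dementia_designs()`: a named list of
#'   [trial_design()] objects (`original`, `optimal5`, `optimal5_ri`,
#'   `optimal5_rirs`, `optimal5_rirsc`, `optimal4`).
#'   `dementia_problem()`: a [design_problem()].
#' @examples
#' expected_pattern_counts(dementia_dropout(),
#'   dementia_designs()$original$groups[[1]]$t, dose = 0, n_alloc = 72)
#' @name dementia_example
NULL

#' @rdname dementia_example
#' @export
dementia_model <- function(reading = c("squared", "literal")) {
  reading <- match.arg(reading)
  d11 <- if (reading == "squared") 2.661^2 else 2.6612
  s2 <- if (reading == "squared") 2.613^2 else 2.6132
  lmm_spec(fixed_effects("Md", beta = c(8.939, -0.0866, 0.01458)),
           random_effects("RI", d11 = d11),
           sigma2 = s2,
           corr = corr_spec("ar1", rho = 0.3326))
}

#' @rdname dementia_example
#' @export
dementia_dropout <- function() {
  dropout_spec("logistic", c(-2.2332, -0.0131, 0.0100))
}

#' @rdname dementia_example
#' @export
dementia_designs <- function() {
  mk <- function(t, w1, n1, N = 144L) {
    trial_design(list(group_design(t, w1, dose = 0),
                      group_design(t, 1 - w1, dose = 100)),
                 N = N, n = c(n1, N - n1))
  }
  list(
    original       = mk(c(0, 42, 126, 210, 364), 0.5, 72L),
    optimal5       = mk(c(0, 42, 285.2340, 355.6943, 364), 0.4221, 60L),
    optimal5_ri    = mk(c(0, 42, 292.2367, 349.1291, 364), 0.4189, 60L),
    optimal5_rirs  = mk(c(0, 42, 46.3915, 153.7180, 364), 0.4865, 70L),
    optimal5_rirsc = mk(c(0, 42, 46.3841, 153.8501, 364), 0.4865, 70L),
    optimal4       = mk(c(0, 42, 318.5670, 364), 0.4183, 72L, N = 172L)
  )
}

#' @rdname dementia_example
#' @param q Number of occasions (5 or 4).
#' @param N Total sample size.
#' @param model Optional replacement model (e.g. a sensitivity variant).
#' @export
dementia_problem <- function(q = 5L, N = 144L, model = dementia_model()) {
  times <- c(0, 42, rep(NA_real_, q - 3L), 364)
  design_problem(model, dementia_dropout(),
                 time_region = c(0, 364), times = times,
                 condition = "restricted",
                 doses = c(NA, 100), dose_region = c(0, 100),
                 N = N)
}
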