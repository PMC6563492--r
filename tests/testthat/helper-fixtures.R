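## shared fixtures: small model/dropout constructors used across tests

ri_day_model <- function() dementia_model()

logistic_drop <- function() dementia_dropout()

## two-group standardised-region study, polynomial retention
quad_drop <- function() dropout_spec("quadratic", c(0.5, -0.35, 0.15))
lin_drop <- function() dropout_spec("linear", c(0.65, -0.35))

mg_model <- function(class = "RIRS", d11 = 1, d22 = 3, d12 = 0,
                     rho = 0.5, sigma2 = 1) {
  lmm_spec(fixed_effects("Mg"),
           random_effects(class, d11 = d11, d22 = d22, d12 = d12),
           sigma2 = sigma2,
           corr = if (rho == 0) corr_spec("independent")
                  else corr_spec("ar1", rho))
}

mg_problem <- function(model, condition = "restricted", N = 100L,
                       weights = NULL) {
  design_problem(model, list(quad_drop(), lin_drop()),
                 time_region = c(-1, 1), times = c(-1, NA, NA, 1),
                 condition = condition, weights = weights, N = N)
}

## shared-schedule two-arm dose design
dose_design <- function(t, w1, n1 = NULL, N = 144L,
                        doses = c(0, 100)) {
  trial_design(list(group_design(t, w1, dose = doses[1]),
                    group_design(t, 1 - w1, dose = doses[2])),
               N = N, n = if (!is.null(n1)) c(n1, N - n1))
}
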