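test_that("simulated trials have monotone missingness and exact sizes", {
  des <- dose_design(c(0, 42, 126, 210, 364), 0.4221)
  dat <- simulate_trial(des, ri_day_model(), logistic_drop(), seed = 1)
  expect_s3_class(dat, "trial_data")
  expect_equal(length(unique(dat$subject)), 144L)
  expect_equal(as.vector(table(dat$group[!duplicated(dat$subject)])),
               des$n)
  ## monotone: observed flags are a leading run of ones; baseline observed
  for (s in split(dat, dat$subject)) {
    s <- s[order(s$time), ]
    expect_equal(s$observed[1], 1L)
    expect_true(all(diff(s$observed) <= 0))
    expect_true(all(is.na(s$y[s$observed == 0])))
    expect_true(all(!is.na(s$y[s$observed == 1])))
  }
})

test_that("no dropout yields complete data; seeds reproduce bit-identically", {
  des <- dose_design(c(0, 100, 364), 0.5, N = 20L)
  dat <- simulate_trial(des, ri_day_model(), dropout_spec("constant_one"),
                        seed = 2)
  expect_true(all(dat$observed == 1L))
  dat2 <- simulate_trial(des, ri_day_model(),
                         dropout_spec("constant_one"), seed = 2)
  expect_identical(dat, dat2)
  dat3 <- simulate_trial(des, ri_day_model(),
                         dropout_spec("constant_one"), seed = 3)
  expect_false(identical(dat$y, dat3$y))
})

test_that("simulated pattern frequencies match the multinomial model", {
  ## one large group so the empirical pattern distribution is tight
  des <- trial_design(list(group_design(c(0, 42, 210, 364), 1,
                                        dose = 0)), N = 20000L)
  dat <- simulate_trial(des, ri_day_model(), logistic_drop(), seed = 4)
  obs_j <- tapply(dat$observed, dat$subject, sum)
  freq <- tabulate(obs_j, nbins = 4) / 20000
  pi <- pattern_probabilities(logistic_drop(), c(0, 42, 210, 364), 0)
  se <- sqrt(pi * (1 - pi) / 20000)
  expect_true(all(abs(freq - pi) < 3 * se + 1e-12))
})

test_that("per-occasion response variance matches the error model", {
  ## pure measurement error: variance sigma^2 at every occasion
  model <- lmm_spec(fixed_effects("Md", beta = c(1, 0.5, 0)),
                    random_effects("FE"), sigma2 = 4,
                    corr = corr_spec("independent"))
  des <- trial_design(list(group_design(c(0, 1, 2), 1, dose = 0)),
                      N = 4000L)
  dat <- simulate_trial(des, model, dropout_spec("constant_one"),
                        seed = 5)
  v <- tapply(dat$y, dat$time, var)
  expect_true(all(abs(v - 4) < 4 * 4 * sqrt(2 / 4000)))
})

test_that("available-case GLS reduces to OLS for iid errors, complete data", {
  model <- lmm_spec(fixed_effects("Md", beta = c(2, -0.1, 0.01)),
                    random_effects("FE"), sigma2 = 1,
                    corr = corr_spec("independent"))
  des <- dose_design(c(0, 5, 10), 0.5, N = 30L)
  dat <- simulate_trial(des, model, dropout_spec("constant_one"),
                        seed = 6)
  bhat <- fit_available_case(dat, model)
  ols <- coef(lm(y ~ time + dose, data = dat))
  expect_equal(as.vector(bhat), unname(ols))
})

test_that("single-observation patterns are pooled exactly; rank is checked", {
  model <- lmm_spec(fixed_effects("Md", beta = c(0, 0, 0)),
                    random_effects("RI", 2), sigma2 = 3,
                    corr = corr_spec("independent"))
  ## three subjects, one observation each, jointly identifying beta:
  ## an exact-fit configuration must be recovered exactly by GLS
  beta_true <- c(1, 2, 0.1)
  dat <- data.frame(subject = 1:3, group = c(1L, 1L, 2L),
                    dose = c(0, 0, 10), time = c(0, 1, 0),
                    observed = 1L)
  dat$y <- c(1 + 0, 1 + 2, 1 + 1)  # X %*% beta_true rowwise
  bhat <- fit_available_case(dat, model)
  expect_equal(as.vector(bhat), beta_true)
  ## a single scalar observation cannot identify three fixed effects
  expect_error(fit_available_case(dat[1, ], model), "singular")
})

test_that("available-case GLS is unbiased under dropout", {
  model <- ri_day_model()
  des <- dose_design(c(0, 42, 285.2340, 355.6943, 364), 0.4221, n1 = 60L)
  out <- dropoutDesign:::replicate_estimates(
    des, model, list(logistic_drop(), logistic_drop()), reps = 400L)
  m <- colMeans(out$est)
  se <- apply(out$est, 2, sd) / sqrt(nrow(out$est))
  expect_true(all(abs(m - c(8.939, -0.0866, 0.01458)) < 3.5 * se))
})

test_that("fast replicate engine agrees with the per-subject pipeline", {
  model <- ri_day_model()
  des <- dose_design(c(0, 42, 210, 364), 0.5, N = 60L)
  ## distributional agreement: estimate means/covariances both ways
  set.seed(10)
  fast <- dropoutDesign:::replicate_estimates(
    des, model, list(logistic_drop(), logistic_drop()), reps = 300L)$est
  slow <- t(vapply(seq_len(300L), function(r) {
    dat <- simulate_trial(des, model, logistic_drop(), seed = 20000 + r)
    unname(fit_available_case(dat, model))
  }, numeric(3)))
  for (j in 1:3) {
    sd_pool <- sqrt(var(fast[, j]) / 300 + var(slow[, j]) / 300)
    expect_lt(abs(mean(fast[, j]) - mean(slow[, j])), 3.5 * sd_pool)
    expect_lt(abs(sd(fast[, j]) / sd(slow[, j]) - 1), 0.35)
  }
})

test_that("empirical covariance matches theory and seeds reproduce results", {
  ## no dropout, fixed-effects model: closed-form estimator covariance
  model <- lmm_spec(fixed_effects("Md", beta = c(1, -0.05, 0.01)),
                    random_effects("FE"), sigma2 = 2,
                    corr = corr_spec("ar1", 0.4))
  t <- c(0, 1, 3)
  des <- dose_design(t, 0.5, N = 40L)
  ev <- evaluate_designs(list(a = des), model,
                         dropout_spec("constant_one"),
                         reps = 4000L, seed = 12)
  V <- build_response_covariance(t, model$random, model$sigma2,
                                 model$corr)
  A <- matrix(0, 3, 3)
  for (k in 1:2) {
    X <- build_fixed_design(model$fixed, t, dose = des$groups[[k]]$dose)
    A <- A + des$n[k] * crossprod(X, solve(V, X))
  }
  closed <- solve(A)
  expect_true(all(abs(ev$results$a$cov - closed) <
                    0.15 * max(abs(closed))))
  ## identical seed: identical evaluation; a design against itself with
  ## different seeds has efficiency near one
  ev2 <- evaluate_designs(list(a = des), model,
                          dropout_spec("constant_one"),
                          reps = 4000L, seed = 12)
  expect_identical(ev$results$a$cov, ev2$results$a$cov)
  ev3 <- evaluate_designs(list(a = des, b = des), model,
                          dropout_spec("constant_one"),
                          reps = 4000L, seed = 13)
  expect_equal(ev3$red["a", "b"], 1, tolerance = 0.1)
  expect_gt(ev3$red_se["a", "b"], 0)
})
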