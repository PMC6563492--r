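test_that("pattern information truncates design and covariance together", {
  t <- c(0, 1, 3)
  X <- build_fixed_design(fixed_effects("Md"), t, dose = 2)
  V <- build_response_covariance(t, random_effects("RI", 1), 1,
                                 corr_spec("ar1", 0.5))
  ## j = q: full generalized least squares information
  expect_equal(pattern_information(X, V, 3),
               crossprod(X, solve(V, X)))
  ## j = 1: scalar case
  expect_equal(pattern_information(X, V, 1),
               tcrossprod(X[1, ]) / V[1, 1])
  ## j = 2: brute-force oracle by explicit 2x2 inversion
  V2 <- V[1:2, 1:2]
  V2inv <- matrix(c(V2[2, 2], -V2[1, 2], -V2[2, 1], V2[1, 1]), 2, 2) /
    (V2[1, 1] * V2[2, 2] - V2[1, 2] * V2[2, 1])
  expect_equal(pattern_information(X, V, 2),
               t(X[1:2, ]) %*% V2inv %*% X[1:2, ])
  expect_error(pattern_information(X, V, 4), "1..q")
})

test_that("expected information reduces to complete-data form without dropout", {
  model <- ri_day_model()
  t <- c(0, 42, 200, 364)
  des <- dose_design(t, 0.4)
  des_nodrop <- expected_information(des, model,
                                     dropout_spec("constant_one"))
  V <- build_response_covariance(t, model$random, model$sigma2, model$corr)
  direct <- matrix(0, 3, 3)
  for (k in 1:2) {
    X <- build_fixed_design(model$fixed, t,
                            dose = des$groups[[k]]$dose)
    direct <- direct + 144 * des$groups[[k]]$w * crossprod(X, solve(V, X))
  }
  expect_equal(des_nodrop$matrix, direct)
})

test_that("expected information matches the multinomial sampling oracle", {
  set.seed(7)
  model <- ri_day_model()
  t <- c(0, 42, 285.2340, 355.6943, 364)
  des <- dose_design(t, 0.4221)
  info <- expected_information(des, model, logistic_drop())
  ## realized information is linear in the pattern counts g, so the
  ## average over multinomial draws must converge to the expectation
  R <- 20000L
  sim <- matrix(0, 3, 3)
  entries <- matrix(0, R, 9)
  for (k in 1:2) {
    g <- des$groups[[k]]
    X <- build_fixed_design(model$fixed, g$t, dose = g$dose)
    V <- build_response_covariance(g$t, model$random, model$sigma2,
                                   model$corr)
    M <- vapply(1:5, function(j) c(pattern_information(X, V, j)),
                numeric(9))
    pi_k <- pattern_probabilities(logistic_drop(), g$t, g$dose)
    G <- rmultinom(R, size = round(144 * g$w), prob = pi_k)
    entries <- entries + t(M %*% G)
  }
  avg <- matrix(colMeans(entries), 3, 3)
  se <- matrix(apply(entries, 2, sd) / sqrt(R), 3, 3)
  ## allocation rounding (60.78 -> 61) introduces a small bias bound
  slack <- abs(info$matrix) * 0.015
  expect_true(all(abs(avg - info$matrix) < 3 * se + slack))
})

test_that("expected information is linear in N and Loewner-monotone", {
  model <- ri_day_model()
  t <- c(0, 42, 126, 210, 364)
  i144 <- expected_information(dose_design(t, 0.5), model,
                               logistic_drop())
  i288 <- expected_information(dose_design(t, 0.5, N = 288L), model,
                               logistic_drop())
  expect_equal(i288$matrix, 2 * i144$matrix)
  ## adding pattern mass cannot decrease information (Loewner order)
  X <- build_fixed_design(model$fixed, t, dose = 0)
  V <- build_response_covariance(t, model$random, model$sigma2,
                                 model$corr)
  m <- c(3, 1, 0, 2, 5)
  m2 <- m + c(0, 2, 1, 0, 0)
  inf_m <- Reduce(`+`, lapply(1:5, function(j)
    m[j] * pattern_information(X, V, j)))
  inf_m2 <- Reduce(`+`, lapply(1:5, function(j)
    m2[j] * pattern_information(X, V, j)))
  expect_gte(min(eigen(inf_m2 - inf_m, symmetric = TRUE)$values), -1e-10)
})

test_that("D-criterion is the log determinant with sentinel for non-PD", {
  expect_equal(d_criterion(diag(3)), 0)
  expect_equal(d_criterion(matrix(c(2, 1, 1, 2), 2, 2)), log(3))
  A <- crossprod(matrix(rnorm(9, 1), 3, 3)) + diag(3)
  expect_equal(d_criterion(5 * A), d_criterion(A) + 3 * log(5))
  expect_identical(d_criterion(matrix(c(1, 2, 2, 1), 2, 2)), -Inf)
  ## d_criterion on a fisher_info agrees with the raw matrix
  info <- expected_information(dose_design(c(0, 42, 364), 0.5),
                               ri_day_model(), logistic_drop())
  expect_equal(d_criterion(info), d_criterion(info$matrix))
})

test_that("relative D-efficiency has the defining properties", {
  A <- crossprod(matrix(c(1, .2, 0, .3, 2, .1, 0, 0, 1.5), 3, 3)) +
    diag(3)
  expect_equal(relative_d_efficiency(A, A), 1.0)
  B <- 2.7 * A
  ## scale-free: common rescaling of both covariances cancels
  expect_equal(relative_d_efficiency(3 * A, 3 * B),
               relative_d_efficiency(A, B))
  ## determinant ratio to the 1/p: dets 2.828 and 1.526 give 0.8142,
  ## dets 1.526 and 1.169 give 1.0929 (both printed as published
  ## efficiencies 0.8140 / 1.093 for the one-year trial comparison)
  expect_equal(relative_d_efficiency(diag(3) * 2.828^(1 / 3),
                                     diag(3) * 1.526^(1 / 3)),
               0.8142, tolerance = 5e-4)
  expect_equal(relative_d_efficiency(diag(3) * 1.169^(1 / 3),
                                     diag(3) * 1.526^(1 / 3)),
               1.0929, tolerance = 5e-4)
  expect_error(relative_d_efficiency(matrix(c(1, 2, 2, 1), 2, 2),
                                     diag(2)), "positive definite")
})

test_that("design covariance is the inverse expected information", {
  model <- ri_day_model()
  des <- dose_design(c(0, 42, 126, 210, 364), 0.5)
  info <- expected_information(des, model, logistic_drop())
  expect_equal(design_covariance(des, model, logistic_drop()),
               solve(info$matrix))
})
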