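test_that("single-free-point optimum matches a dense grid search", {
  ## four occasions, only the third time point free, weights fixed
  problem <- design_problem(ri_day_model(), logistic_drop(),
                            time_region = c(0, 364),
                            times = c(0, 42, NA, 364),
                            doses = c(0, 100), weights = c(0.5, 0.5),
                            N = 144L)
  sol <- optimize_design(problem, seed = 1, n_starts = 5)
  grid <- seq(42.01, 363.99, length.out = 2000L)
  crit <- vapply(grid, function(t13) {
    d_criterion(expected_information(
      dose_design(c(0, 42, t13, 364), 0.5), ri_day_model(),
      logistic_drop()))
  }, 1)
  expect_gte(sol$criterion, max(crit) - 1e-6 * abs(max(crit)))
})

test_that("two-free-variable optimum matches a coarse grid oracle", {
  ## free third time point and free weight
  problem <- design_problem(ri_day_model(), logistic_drop(),
                            time_region = c(0, 364),
                            times = c(0, 42, NA, 364),
                            doses = c(0, 100), N = 144L)
  sol <- optimize_design(problem, seed = 2, n_starts = 8)
  ts <- seq(50, 360, length.out = 60L)
  ws <- seq(0.05, 0.95, length.out = 60L)
  crit <- outer(ts, ws, Vectorize(function(t13, w) {
    d_criterion(expected_information(
      dose_design(c(0, 42, t13, 364), w), ri_day_model(),
      logistic_drop()))
  }))
  expect_gte(sol$criterion, max(crit) - 1e-8)
})

test_that("optimum dominates the equidistant equal-weight design", {
  for (cond in c("restricted", "flexible")) {
    problem <- mg_problem(mg_model(), condition = cond)
    sol <- optimize_design(problem, seed = 3, n_starts = 6)
    equi <- trial_design(list(
      group_design(seq(-1, 1, length.out = 4), 0.5),
      group_design(seq(-1, 1, length.out = 4), 0.5)), N = 100L)
    base <- d_criterion(expected_information(
      equi, mg_model(), list(quad_drop(), lin_drop())))
    expect_gte(sol$criterion, base)
  }
})

test_that("restricted optimum never beats the flexible optimum", {
  for (mod in list(mg_model("RI", d11 = 1, d22 = 0),
                   mg_model("RIRS"))) {
    r <- optimize_design(mg_problem(mod, "restricted"), seed = 4,
                         n_starts = 6)
    f <- optimize_design(mg_problem(mod, "flexible"), seed = 4,
                         n_starts = 6)
    expect_lte(r$criterion, f$criterion + 1e-7)
  }
})

test_that("the returned solution is a fixed point of the search", {
  problem <- dementia_problem()
  sol <- optimize_design(problem, seed = 5, n_starts = 6)
  again <- optimize_design(problem, seed = 6, n_starts = 1,
                           extra_starts = list(sol$par))
  expect_lte(again$criterion - sol$criterion,
             1e-8 * abs(sol$criterion) + 1e-8)
  ## reported criterion is reproducible from the returned design
  expect_equal(sol$criterion,
               d_criterion(expected_information(
                 sol$design, problem$model, problem$dropout)))
})

test_that("fixed-effects model with independent errors splits weights evenly", {
  ## equal response rates at the optimal end points drive w1 = w2 = 0.5
  problem <- mg_problem(mg_model("FE", d11 = 0, d22 = 0, rho = 0),
                        condition = "restricted")
  sol <- optimize_design(problem, seed = 7, n_starts = 10)
  expect_equal(sol$design$groups[[1]]$w, 0.5, tolerance = 1e-3)
})

test_that("design problems validate their inputs", {
  expect_error(design_problem(ri_day_model(), logistic_drop(),
                              time_region = c(0, 364),
                              times = c(0, 42, 364),
                              doses = c(0, 100), weights = c(.5, .5)),
               "no free variables")
  expect_error(design_problem(ri_day_model(), logistic_drop(),
                              time_region = c(0, 100),
                              times = c(0, 42, NA, 364),
                              doses = c(0, 100)),
               "outside the time region")
  expect_error(design_problem(ri_day_model(), logistic_drop(),
                              time_region = c(0, 364),
                              times = c(42, 0, NA, 364),
                              doses = c(0, 100)),
               "ordering")
  expect_error(design_problem(ri_day_model(), logistic_drop(),
                              time_region = c(0, 364),
                              times = c(0, NA, 364),
                              doses = c(NA, 100)),
               "dose_region")
})

test_that("a singleton rho grid agrees with a direct optimization", {
  problem <- mg_problem(mg_model(rho = 0.5))
  prof <- profile_over_rho(problem, 0.5, seed = 8, n_starts = 6)
  direct <- optimize_design(problem, seed = 8 + 1, n_starts = 6)
  expect_equal(prof$solutions[[1]]$criterion, direct$criterion,
               tolerance = 1e-7)
  expect_equal(prof$summary$rho, 0.5)
})
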