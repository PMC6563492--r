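#' Specify a D-optimal design problem
#'
#' Describes which elements of a trial design are free to be optimized:
#' middle follow-up time points (entries of `times` set to `NA`), dose
#' levels (entries of `doses` set to `NA`), and the group allocation
#' weights (when `weights` is `NULL`). Under the `"restricted"` condition
#' every group shares one measurement schedule (as in a blinded trial);
#' under `"flexible"` each group's schedule is optimized separately (an
#' open-label trial).
#'
#' @param model An [lmm_spec()].
#' @param dropout A [dropout_spec()] or list of one per group.
#' @param time_region Length-2 vector, the admissible time interval.
#' @param times Template schedule of length q with `NA` marking free
#'   entries; for the flexible condition, optionally a list of one
#'   template per group (a single vector is recycled).
#' @param condition `"restricted"` or `"flexible"`.
#' @param doses Numeric vector of length c with `NA` for free dose
#'   levels; `NULL` for model `"Mg"`.
#' @param dose_region Length-2 vector bounding free doses.
#' @param weights `NULL` to optimize the allocation weights over the
#'   simplex, or a fixed weight vector summing to 1.
#' @param N Total sample size (a positive scale factor of the criterion;
#'   it does not move the optimum).
#' @param groups Number of arms c (defaults to the model's group count
#'   for `"Mg"`, or `length(doses)`).
#' @return An object of class `"design_problem"`.
#' @examples
#' mod <- lmm_spec(fixed_effects("Md"), random_effects("RI", 2.661^2),
#'                 sigma2 = 2.613^2, corr = corr_spec("ar1", 0.3326))
#' drop <- dropout_spec("logistic", c(-2.2332, -0.0131, 0.0100))
#' design_problem(mod, drop, time_region = c(0, 364),
#'                times = c(0, 42, NA, NA, 364),
#'                doses = c(NA, 100), dose_region = c(0, 100), N = 144)
#' @export
design_problem <- function(model, dropout, time_region, times,
                           condition = c("restricted", "flexible"),
                           doses = NULL, dose_region = NULL,
                           weights = NULL, N = 100L, groups = NULL) {
  condition <- match.arg(condition)
  stopifnot(inherits(model, "lmm_spec"),
            is.numeric(time_region), length(time_region) == 2L,
            time_region[1] < time_region[2])
  c_groups <- if (!is.null(groups)) as.integer(groups)
              else if (model$fixed$model == "Mg") model$fixed$groups
              else if (!is.null(doses)) length(doses)
              else 2L
  if (model$fixed$model == "Md" && is.null(doses)) {
    stop("model 'Md' requires a 'doses' vector (NA entries are optimized)",
         call. = FALSE)
  }
  if (model$fixed$model == "Mg" && !is.null(doses)) {
    stop("model 'Mg' does not take doses", call. = FALSE)
  }
  if (!is.null(doses)) {
    stopifnot(length(doses) == c_groups)
    if (anyNA(doses) && is.null(dose_region)) {
      stop("free doses need a 'dose_region'", call. = FALSE)
    }
  }
  if (is.list(times)) {
    if (condition == "restricted" && length(times) > 1L) {
      stop("the restricted condition uses a single shared schedule",
           call. = FALSE)
    }
    stopifnot(length(times) %in% c(1L, c_groups))
    if (length(times) == 1L) times <- rep(times, c_groups)
  } else {
    times <- rep(list(times), if (condition == "flexible") c_groups else 1L)
  }
  if (condition == "restricted") times <- times[1L]
  q <- unique(vapply(times, length, 1L))
  if (length(q) != 1L || q < 2L) {
    stop("all schedule templates must share one length q >= 2",
         call. = FALSE)
  }
  for (tv in times) {
    fx <- tv[!is.na(tv)]
    if (any(fx < time_region[1] - 1e-9 | fx > time_region[2] + 1e-9)) {
      stop("fixed times fall outside the time region", call. = FALSE)
    }
    if (is.unsorted(fx, strictly = TRUE)) {
      stop("fixed times violate the strict ordering", call. = FALSE)
    }
  }
  if (!is.null(weights)) {
    stopifnot(length(weights) == c_groups, abs(sum(weights) - 1) < 1e-8,
              all(weights >= 0))
  }
  n_free <- sum(vapply(times, function(tv) sum(is.na(tv)), 1L)) +
    sum(is.na(doses)) + if (is.null(weights)) c_groups - 1L else 0L
  if (n_free < 1L) {
    stop("the problem has no free variables", call. = FALSE)
  }
  structure(list(model = model,
                 dropout = per_group_dropout(dropout, c_groups),
                 time_region = time_region, times = times,
                 condition = condition, doses = doses,
                 dose_region = dose_region, weights = weights,
                 N = N, c = c_groups, q = q),
            class = "design_problem")
}

## --- internal parameter-vector machinery -------------------------------

## layout: per schedule template, its free times; then free doses; then
## c - 1 free weights
problem_layout <- function(problem) {
  gap <- 1e-6 * diff(problem$time_region)
  lower <- upper <- numeric(0)
  kinds <- character(0)
  for (tv in problem$times) {
    free <- which(is.na(tv))
    if (!length(free)) next
    before <- tv[seq_len(min(free) - 1)]
    after <- tv[setdiff(seq_along(tv), seq_len(max(free)))]
    after <- after[!is.na(after)]
    lo <- max(problem$time_region[1], before[!is.na(before)]) + gap
    hi <- min(problem$time_region[2], after) - gap
    if (lo >= hi) stop("fixed times leave no room for the free times",
                       call. = FALSE)
    lower <- c(lower, rep(lo, length(free)))
    upper <- c(upper, rep(hi, length(free)))
    kinds <- c(kinds, rep("time", length(free)))
  }
  nd <- sum(is.na(problem$doses))
  if (nd > 0) {
    lower <- c(lower, rep(problem$dose_region[1], nd))
    upper <- c(upper, rep(problem$dose_region[2], nd))
    kinds <- c(kinds, rep("dose", nd))
  }
  if (is.null(problem$weights)) {
    nw <- problem$c - 1L
    lower <- c(lower, rep(1e-4, nw))
    upper <- c(upper, rep(1 - 1e-4, nw))
    kinds <- c(kinds, rep("weight", nw))
  }
  list(lower = lower, upper = upper, kinds = kinds,
       gap = gap, n_par = length(lower))
}

## par vector -> trial_design (or NULL when infeasible)
assemble_design <- function(problem, par, layout) {
  i <- 0L
  tlist <- vector("list", length(problem$times))
  for (s in seq_along(problem$times)) {
    tv <- problem$times[[s]]
    free <- which(is.na(tv))
    if (length(free)) {
      vals <- sort(par[i + seq_along(free)])
      i <- i + length(free)
      tv[free] <- vals
    }
    if (any(diff(tv) < layout$gap)) return(NULL)
    tlist[[s]] <- tv
  }
  if (length(tlist) == 1L) tlist <- rep(tlist, problem$c)
  doses <- problem$doses
  if (!is.null(doses) && anyNA(doses)) {
    nd <- sum(is.na(doses))
    doses[is.na(doses)] <- par[i + seq_len(nd)]
    i <- i + nd
  }
  if (is.null(problem$weights)) {
    wfree <- par[i + seq_len(problem$c - 1L)]
    wlast <- 1 - sum(wfree)
    if (wlast < 1e-4) return(NULL)
    w <- c(wfree, wlast)
  } else {
    w <- problem$weights
  }
  trial_design(lapply(seq_len(problem$c), function(k) {
    group_design(tlist[[k]], w[k],
                 dose = if (is.null(doses)) NULL else doses[k])
  }), N = problem$N)
}

problem_objective <- function(problem, layout) {
  function(par) {
    des <- assemble_design(problem, par, layout)
    if (is.null(des)) return(1e10)
    val <- tryCatch(
      d_criterion(expected_information(des, problem$model, problem$dropout)),
      error = function(e) -Inf)
    if (!is.finite(val)) return(1e10)
    -val
  }
}

## free times are re-sorted inside assemble_design, so independent
## uniform draws per coordinate give feasible starts
random_start <- function(problem, layout) {
  iw <- layout$kinds == "weight"
  par <- stats::runif(layout$n_par, layout$lower, layout$upper)
  if (any(iw)) {
    u <- stats::runif(sum(iw) + 1L, 0.05, 1)
    par[iw] <- u[seq_len(sum(iw))] / sum(u)
  }
  par
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Search for a locally D-optimal design
#'
#' Maximizes the log-determinant of the dropout-expected Fisher
#' information over the problem's free variables by multistart
#' box-constrained quasi-Newton optimization (`L-BFGS-B`). Free time
#' points are kept strictly increasing (minimum gap `1e-6` times the
#' region width); free weights live on the simplex via `c - 1`
#' coordinates. The best start is polished with a tight convergence
#' tolerance and the returned criterion is recomputed from the assembled
#' design.
#'
#' @param problem A [design_problem()].
#' @param seed Integer seed controlling the random starts.
#' @param n_starts Number of random multistarts.
#' @param extra_starts Optional list of parameter vectors used as
#'   additional starts (e.g. warm starts).
#' @return An object of class `"design_solution"`: list with elements
#'   `design` (a [trial_design()]), `criterion` (log-det), `par`,
#'   `converged`, `n_starts`, and `starts` (per-start diagnostics).
#' @export
optimize_design <- function(problem, seed = 1L, n_starts = 20L,
                            extra_starts = NULL) {
  stopifnot(inherits(problem, "design_problem"))
  layout <- problem_layout(problem)
  obj <- problem_objective(problem, layout)
  with_seed(seed, {
    starts <- c(lapply(seq_len(n_starts), function(s)
      random_start(problem, layout)), extra_starts)
    runs <- lapply(starts, function(x0) {
      tryCatch(
        stats::optim(x0, obj, method = "L-BFGS-B",
                     lower = layout$lower, upper = layout$upper,
                     control = list(maxit = 1000L, factr = 1e4)),
        error = function(e) list(par = x0, value = obj(x0),
                                 convergence = 99L))
    })
    vals <- vapply(runs, `[[`, 1, "value")
    best <- runs[[which.min(vals)]]
    polish <- tryCatch(
      stats::optim(best$par, obj, method = "L-BFGS-B",
                   lower = layout$lower, upper = layout$upper,
                   control = list(maxit = 2000L, factr = 1e1)),
      error = function(e) best)
    if (polish$value <= best$value) best <- polish
  })
  design <- assemble_design(problem, best$par, layout)
  criterion <- d_criterion(
    expected_information(design, problem$model, problem$dropout))
  structure(list(design = design, criterion = criterion, par = best$par,
                 converged = any(vapply(runs, `[[`, 1L,
                                        "convergence") == 0L),
                 n_starts = length(starts),
                 starts = data.frame(
                   start = seq_along(runs),
                   value = -vals,
                   convergence = vapply(runs, `[[`, 1L, "convergence")),
                 problem = problem, seed = seed),
            class = "design_solution")
}

#' @export
print.design_solution <- function(x, ...) {
  cat("D-optimal design search (", x$n_starts, " starts, ",
      if (x$converged) "converged" else "NOT converged", ")\n", sep = "")
  cat("log det information =", format(x$criterion), "\n")
  print(x$design)
  invisible(x)
}

#' Profile of optimal designs across the serial correlation parameter
#'
#' Re-solves a design problem for each value of `rho_grid`, warm-starting
#' each optimization from the previous grid point's solution in addition
#' to fresh random starts.
#'
#' @param problem A [design_problem()] (its model must use a correlated
#'   error structure, or `"independent"` is substituted at `rho = 0`).
#' @param rho_grid Vector of correlation values in `[0, 1)`.
#' @param seed Integer seed.
#' @param n_starts Random multistarts per grid point.
#' @return An object of class `"rho_profile"`: list of solutions plus a
#'   `summary` data frame with one row per grid point (criterion, weights
#'   and optimized times per group).
#' @export
profile_over_rho <- function(problem, rho_grid, seed = 1L, n_starts = 10L) {
  stopifnot(all(rho_grid >= 0 & rho_grid < 1))
  sols <- vector("list", length(rho_grid))
  warm <- NULL
  for (i in seq_along(rho_grid)) {
    m <- problem$model
    m$corr <- corr_spec(if (m$corr$kind == "independent") "ar1"
                        else m$corr$kind, rho = rho_grid[i])
    pr <- problem
    pr$model <- m
    sols[[i]] <- optimize_design(pr, seed = seed + i, n_starts = n_starts,
                                 extra_starts = warm)
    warm <- list(sols[[i]]$par)
  }
  rows <- lapply(seq_along(sols), function(i) {
    d <- sols[[i]]$design
    w <- vapply(d$groups, `[[`, 1, "w")
    tt <- unlist(lapply(seq_along(d$groups), function(k) {
      v <- d$groups[[k]]$t
      stats::setNames(v, paste0("t", k, seq_along(v)))
    }))
    c(rho = rho_grid[i], criterion = sols[[i]]$criterion,
      stats::setNames(w, paste0("w", seq_along(w))), tt)
  })
  summary <- as.data.frame(do.call(rbind, rows))
  structure(list(solutions = sols, summary = summary,
                 rho_grid = rho_grid), class = "rho_profile")
}

#' @export
print.rho_profile <- function(x, digits = 4, ...) {
  cat("Optimal-design profile over rho (", length(x$rho_grid),
      " grid points)\n", sep = "")
  print(round(x$summary, digits))
  invisible(x)
}
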