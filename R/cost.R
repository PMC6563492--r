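#' Trial cost model
#'
#' Per-subject cost of a trial with q measurement occasions is
#' `recruit_cost + (q - 1) * visit_cost`: recruitment covers the baseline
#' measurement, and every planned follow-up visit is charged whether or
#' not the subject has dropped out by then (planned-visit costing).
#'
#' @param recruit_cost Cost of recruiting one subject (including the
#'   baseline measurement).
#' @param visit_cost Cost of one follow-up measurement.
#' @param budget Total budget.
#' @return An object of class `"cost_model"`.
#' @examples
#' cost_model(recruit_cost = 2, visit_cost = 1, budget = 144 * 6)
#' @export
cost_model <- function(recruit_cost, visit_cost, budget) {
  stopifnot(is.numeric(recruit_cost), recruit_cost > 0,
            is.numeric(visit_cost), visit_cost > 0,
            is.numeric(budget), budget > 0)
  structure(list(recruit_cost = recruit_cost, visit_cost = visit_cost,
                 budget = budget), class = "cost_model")
}

#' Budget implied by a reference trial
#'
#' Convenience constructor: the budget that exactly pays for `N` subjects
#' measured at `q` occasions.
#'
#' @inheritParams cost_model
#' @param N Reference sample size.
#' @param q Reference number of occasions.
#' @return A [cost_model()].
#' @export
cost_model_from_reference <- function(recruit_cost, visit_cost, N, q) {
  cost_model(recruit_cost, visit_cost,
             budget = N * (recruit_cost + (q - 1) * visit_cost))
}

#' Affordable sample size for a given number of occasions
#'
#' @param cost A [cost_model()].
#' @param q Number of measurement occasions (at least 2).
#' @param round `"floor"` (default; partial subjects cannot be recruited)
#'   or `"round"` for exploratory use.
#' @return Integer sample size.
#' @examples
#' affordable_n(cost_model(2, 1, 144 * 6), q = 4)  # 172
#' @export
affordable_n <- function(cost, q, round = c("floor", "round")) {
  stopifnot(inherits(cost, "cost_model"), q >= 2)
  round <- match.arg(round)
  per <- cost$recruit_cost + (q - 1) * cost$visit_cost
  n <- cost$budget / per
  if (n < 1) stop("budget does not cover a single subject", call. = FALSE)
  as.integer(if (round == "floor") floor(n) else round(n))
}

## derive a q'-occasion schedule template from a base template: keep the
## leading and trailing fixed entries, adjust the number of free slots
retarget_times <- function(times, q_new) {
  head_fix <- 0L
  while (head_fix < length(times) && !is.na(times[head_fix + 1L])) {
    head_fix <- head_fix + 1L
  }
  tail_fix <- 0L
  while (tail_fix < length(times) - head_fix &&
         !is.na(times[length(times) - tail_fix])) {
    tail_fix <- tail_fix + 1L
  }
  n_free <- q_new - head_fix - tail_fix
  if (n_free < 0L) {
    stop("q = ", q_new, " is smaller than the number of fixed times",
         call. = FALSE)
  }
  c(times[seq_len(head_fix)], rep(NA_real_, n_free),
    if (tail_fix > 0L) times[length(times) - rev(seq_len(tail_fix)) + 1L])
}

#' Scan the occasions-versus-sample-size trade-off under a fixed budget
#'
#' For each candidate number of occasions q, computes the affordable
#' sample size, re-solves the D-optimal design problem with that many
#' occasions (keeping the problem's leading and trailing fixed times and
#' adjusting the number of free middle points), and reports the criterion
#' together with the efficiency relative to a reference design.
#'
#' @param problem A [design_problem()].
#' @param cost A [cost_model()].
#' @param q_values Candidate numbers of occasions.
#' @param reference Optional reference for the relative D-efficiency
#'   column: a [trial_design()] evaluated under the same model/dropout.
#'   Defaults to the solution at the first q in `q_values`.
#' @param seed,n_starts Passed to [optimize_design()].
#' @return An object of class `"cost_scan"`: list with `table` (one row
#'   per q: q, N, criterion, red) and `solutions`.
#' @export
cost_scan <- function(problem, cost, q_values, reference = NULL,
                      seed = 1L, n_starts = 20L) {
  stopifnot(inherits(problem, "design_problem"),
            inherits(cost, "cost_model"), all(q_values >= 2))
  sols <- vector("list", length(q_values))
  Ns <- integer(length(q_values))
  for (i in seq_along(q_values)) {
    qv <- as.integer(q_values[i])
    pr <- problem
    pr$times <- lapply(problem$times, retarget_times, q_new = qv)
    pr$q <- qv
    pr$N <- Ns[i] <- affordable_n(cost, qv)
    sols[[i]] <- optimize_design(pr, seed = seed + i, n_starts = n_starts)
  }
  cov_ref <- if (is.null(reference)) {
    design_covariance(sols[[1L]]$design, problem$model, problem$dropout)
  } else {
    design_covariance(reference, problem$model, problem$dropout)
  }
  red <- vapply(sols, function(s) {
    relative_d_efficiency(
      design_covariance(s$design, problem$model, problem$dropout), cov_ref)
  }, 1)
  structure(list(table = data.frame(q = as.integer(q_values), N = Ns,
                                    criterion = vapply(sols, `[[`, 1,
                                                       "criterion"),
                                    red = red),
                 solutions = sols, cost = cost),
            class = "cost_scan")
}

#' @export
print.cost_scan <- function(x, digits = 4, ...) {
  cat("Cost-constrained design scan (budget =", format(x$cost$budget),
      ", recruit:visit =", format(x$cost$recruit_cost / x$cost$visit_cost),
      ")\n")
  tab <- x$table
  tab$criterion <- round(tab$criterion, digits)
  tab$red <- round(tab$red, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}
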