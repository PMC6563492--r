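#' Measurement schedule of one trial arm
#'
#' @param t Strictly increasing vector of measurement times (all arms of a
#'   design must share the same number of occasions q).
#' @param w Allocation weight in `[0, 1]`.
#' @param dose Dose level (model `"Md"`), or `NULL`.
#' @param fixed_mask Logical vector marking time entries that a design
#'   search must not move (defaults to all `FALSE`).
#' @return An object of class `"group_design"`.
#' @export
group_design <- function(t, w, dose = NULL, fixed_mask = NULL) {
  check_times(t)
  stopifnot(is.numeric(w), length(w) == 1L, w >= 0, w <= 1)
  if (!is.null(dose)) stopifnot(is.numeric(dose), length(dose) == 1L)
  if (is.null(fixed_mask)) fixed_mask <- rep(FALSE, length(t))
  stopifnot(is.logical(fixed_mask), length(fixed_mask) == length(t))
  structure(list(t = t, w = w, dose = dose, fixed_mask = fixed_mask),
            class = "group_design")
}

#' Trial design: schedules, weights, doses and sample size
#'
#' An approximate design carries continuous weights `w_k` summing to one;
#' an exact design additionally fixes integer group sizes `n`. If `n` is
#' not supplied it is derived by largest-remainder rounding of `N * w_k`
#' (see [exact_allocation()]).
#'
#' @param groups List of [group_design()] objects, one per arm.
#' @param N Total sample size.
#' @param n Optional integer allocation vector summing to `N`; overrides
#'   the rounding of `N * w_k`.
#' @return An object of class `"trial_design"`.
#' @examples
#' trial_design(list(group_design(c(0, 42, 126, 210, 364), 0.5, dose = 0),
#'                   group_design(c(0, 42, 126, 210, 364), 0.5, dose = 100)),
#'              N = 144)
#' @export
trial_design <- function(groups, N, n = NULL) {
  stopifnot(is.list(groups), length(groups) >= 1L,
            all(vapply(groups, inherits, TRUE, "group_design")),
            is.numeric(N), length(N) == 1L, N > 0)
  q <- vapply(groups, function(g) length(g$t), 1L)
  if (length(unique(q)) != 1L) {
    stop("all groups must have the same number of occasions", call. = FALSE)
  }
  w <- vapply(groups, `[[`, 1, "w")
  if (abs(sum(w) - 1) > 1e-8) {
    stop("group weights must sum to 1 (got ", format(sum(w)), ")",
         call. = FALSE)
  }
  if (is.null(n)) {
    n <- exact_allocation(N, w)
  } else {
    stopifnot(length(n) == length(groups), all(n >= 0), sum(n) == N)
    n <- as.integer(n)
  }
  structure(list(groups = groups, N = N, n = n, q = q[[1L]]),
            class = "trial_design")
}

#' Integer group sizes from approximate-design weights
#'
#' @param N Total sample size.
#' @param w Weight vector summing to 1.
#' @param method `"largest_remainder"` (default) assigns `floor(N w_k)`
#'   everywhere and distributes the leftover units to the largest
#'   fractional parts; `"floor"` floors every group but the last, which
#'   absorbs the remainder (the convention behind allocations such as
#'   `floor(144 * 0.4221) = 60`, `144 - 60 = 84`).
#' @return Integer vector summing to `N`.
#' @export
exact_allocation <- function(N, w, method = c("largest_remainder", "floor")) {
  method <- match.arg(method)
  stopifnot(abs(sum(w) - 1) < 1e-8, all(w >= 0))
  x <- N * w
  if (method == "floor") {
    n <- floor(x)
    n[length(n)] <- N - sum(n[-length(n)])
    return(as.integer(n))
  }
  n <- floor(x)
  left <- round(N - sum(n))
  if (left > 0) {
    take <- order(x - n, decreasing = TRUE)[seq_len(left)]
    n[take] <- n[take] + 1
  }
  as.integer(n)
}

#' @export
print.trial_design <- function(x, digits = 4, ...) {
  cat("Trial design: N =", x$N, ", q =", x$q, "occasions,",
      length(x$groups), "groups\n")
  for (k in seq_along(x$groups)) {
    g <- x$groups[[k]]
    cat(sprintf("  group %d: w = %s, n = %d%s\n    t = %s\n", k,
                format(round(g$w, digits)), x$n[k],
                if (!is.null(g$dose)) paste0(", dose = ", g$dose) else "",
                paste(round(g$t, digits), collapse = ", ")))
  }
  invisible(x)
}

#' @export
as.data.frame.trial_design <- function(x, ...) {
  do.call(rbind, lapply(seq_along(x$groups), function(k) {
    g <- x$groups[[k]]
    data.frame(group = k, w = g$w, n = x$n[k],
               dose = if (is.null(g$dose)) NA_real_ else g$dose,
               occasion = seq_along(g$t), time = g$t)
  }))
}

## dropout argument normalisation: one spec or a per-group list (internal)
per_group_dropout <- function(dropout, c) {
  if (inherits(dropout, "dropout_spec")) {
    return(rep(list(dropout), c))
  }
  stopifnot(is.list(dropout), length(dropout) == c,
            all(vapply(dropout, inherits, TRUE, "dropout_spec")))
  dropout
}
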