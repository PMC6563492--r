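#' Simulate one trial under a design with monotone dropout
#'
#' Draws every subject's response series from the linear mixed model
#' (fixed mean, random effects with covariance D, errors with covariance
#' \eqn{\sigma^2 \Psi} over the subject's schedule), then draws the
#' subject's number of observed occasions j from the multinomial
#' dropout-pattern distribution and flags occasions after j as missing.
#' Group sizes are the design's exact allocation (`design$n`).
#'
#' Random numbers are consumed in a fixed order (per subject: random
#' effects, then errors, then the pattern draw), so a seed identifies the
#' data set exactly.
#'
#' @param design A [trial_design()].
#' @param model An [lmm_spec()] whose `fixed$beta` is set.
#' @param dropout A [dropout_spec()] or per-group list.
#' @param seed Integer seed.
#' @return A `"trial_data"` data frame in long format with columns
#'   `subject`, `group`, `dose`, `time`, `y`, `observed` (0/1 flag; `y`
#'   is `NA` where unobserved).
#' @export
simulate_trial <- function(design, model, dropout, seed = 1L) {
  stopifnot(inherits(design, "trial_design"), inherits(model, "lmm_spec"))
  beta <- model$fixed$beta
  if (is.null(beta)) {
    stop("the model's 'beta' must be set to simulate responses",
         call. = FALSE)
  }
  dropout <- per_group_dropout(dropout, length(design$groups))
  rec <- with_seed(seed, {
    out <- vector("list", length(design$groups))
    sid <- 0L
    for (k in seq_along(design$groups)) {
      g <- design$groups[[k]]
      q <- length(g$t)
      X <- build_fixed_design(model$fixed, g$t, group = k, dose = g$dose)
      mu <- drop(X %*% beta)
      re <- model$random
      cholE <- chol(build_response_covariance(
        g$t, random_effects("FE"), model$sigma2, model$corr))
      Dm <- matrix(c(re$d11, re$d12, re$d12, re$d22), 2, 2)
      cholD <- if (re$class == "FE") NULL else
        chol(Dm[seq_len(if (re$class == "RI") 1 else 2),
                seq_len(if (re$class == "RI") 1 else 2), drop = FALSE])
      Z <- if (re$class == "RI") cbind(rep(1, q)) else cbind(1, g$t)
      pi_k <- pattern_probabilities(dropout[[k]], g$t, g$dose)
      rows <- vector("list", design$n[k])
      for (i in seq_len(design$n[k])) {
        sid <- sid + 1L
        contrib <- if (is.null(cholD)) rep(0, q) else {
          b <- drop(crossprod(cholD, stats::rnorm(nrow(cholD))))
          drop(Z[, seq_along(b), drop = FALSE] %*% b)
        }
        eps <- drop(crossprod(cholE, stats::rnorm(q)))
        y <- mu + contrib + eps
        j <- sample.int(q, 1L, prob = pi_k)
        obs <- as.integer(seq_len(q) <= j)
        y[obs == 0L] <- NA_real_
        rows[[i]] <- data.frame(
          subject = sid, group = k,
          dose = if (is.null(g$dose)) NA_real_ else g$dose,
          time = g$t, y = y, observed = obs)
      }
      out[[k]] <- do.call(rbind, rows)
    }
    do.call(rbind, out)
  })
  rownames(rec) <- NULL
  class(rec) <- c("trial_data", "data.frame")
  rec
}

#' Available-case generalized least squares estimate of the fixed effects
#'
#' Estimates \eqn{\beta} from the observed rows of every subject using
#' the model's (known) variance components:
#' \deqn{\hat\beta = \Big(\sum_i X_i^T V_i^{-1} X_i\Big)^{-1}
#'   \sum_i X_i^T V_i^{-1} y_i,}
#' where \eqn{X_i} and \eqn{V_i} are restricted to subject i's observed
#' occasions (the leading block of the schedule covariance). Variance
#' components are held at the specification's values; they are not
#' re-estimated.
#'
#' @param data A `"trial_data"` data frame from [simulate_trial()] (or
#'   any long-format data frame with the same columns).
#' @param model An [lmm_spec()].
#' @return Named numeric vector \eqn{\hat\beta} of length p, with the
#'   pooled information matrix in attribute `"information"`.
#' @export
fit_available_case <- function(data, model) {
  stopifnot(inherits(model, "lmm_spec"),
            all(c("subject", "group", "time", "y", "observed") %in%
              names(data)))
  obs <- data[data$observed == 1L, , drop = FALSE]
  if (!nrow(obs)) stop("no observed rows", call. = FALSE)
  p <- model$fixed$p
  A <- matrix(0, p, p)
  u <- numeric(p)
  cache <- new.env(parent = emptyenv())
  for (sid in unique(obs$subject)) {
    d <- obs[obs$subject == sid, , drop = FALSE]
    d <- d[order(d$time), , drop = FALSE]
    dose <- if (model$fixed$model == "Md") d$dose[1L] else NULL
    key <- paste(d$group[1L], paste(signif(d$time, 12), collapse = ","),
                 sep = "|")
    pre <- cache[[key]]
    if (is.null(pre)) {
      X <- build_fixed_design(model$fixed, d$time, group = d$group[1L],
                              dose = dose)
      V <- model_covariance(model, d$time)
      pre <- list(B = t(solve(V, X)), M = crossprod(X, solve(V, X)))
      cache[[key]] <- pre
    }
    A <- A + pre$M
    u <- u + drop(pre$B %*% d$y)
  }
  beta <- tryCatch(solve(A, u), error = function(e) {
    stop("pooled observed-information matrix is singular", call. = FALSE)
  })
  names(beta) <- paste0("beta", seq_len(p) - 1L)
  attr(beta, "information") <- A
  beta
}

## fast replicate engine used by evaluate_designs: group-wise response
## matrices, multinomial pattern counts, and pattern-grouped sufficient
## statistics. RNG order per group: random effects, errors, pattern
## counts.
replicate_estimates <- function(design, model, dropout, reps) {
  beta <- model$fixed$beta
  p <- model$fixed$p
  pre <- lapply(seq_along(design$groups), function(k) {
    g <- design$groups[[k]]
    q <- length(g$t)
    X <- build_fixed_design(model$fixed, g$t, group = k, dose = g$dose)
    V <- model_covariance(model, g$t)
    re <- model$random
    Dm <- matrix(c(re$d11, re$d12, re$d12, re$d22), 2, 2)
    nb <- switch(re$class, FE = 0L, RI = 1L, 2L)
    list(
      q = q, n = design$n[k], mu = drop(X %*% beta),
      cholE = chol(build_response_covariance(
        g$t, random_effects("FE"), model$sigma2, model$corr)),
      cholD = if (nb) chol(Dm[seq_len(nb), seq_len(nb), drop = FALSE]),
      Z = (if (re$class == "RI") cbind(rep(1, q)) else
           cbind(1, g$t))[, seq_len(max(nb, 1L)), drop = FALSE],
      pi = pattern_probabilities(dropout[[k]], g$t, g$dose),
      B = lapply(seq_len(q), function(j) {
        Xj <- X[seq_len(j), , drop = FALSE]
        t(solve(V[seq_len(j), seq_len(j), drop = FALSE], Xj))
      }),
      M = lapply(seq_len(q), function(j) pattern_information(X, V, j)))
  })
  est <- matrix(NA_real_, reps, p)
  n_failed <- 0L
  for (r in seq_len(reps)) {
    A <- matrix(0, p, p)
    u <- numeric(p)
    for (gp in pre) {
      nk <- gp$n
      q <- gp$q
      re_draw <- if (is.null(gp$cholD)) 0 else {
        b <- matrix(stats::rnorm(nk * nrow(gp$cholD)), nk) %*% gp$cholD
        tcrossprod(b, gp$Z)
      }
      E <- matrix(stats::rnorm(nk * q), nk) %*% gp$cholE
      Y <- sweep(E + re_draw, 2L, gp$mu, "+")
      cnt <- drop(stats::rmultinom(1L, nk, gp$pi))
      idx <- rep.int(seq_len(q), cnt)
      for (j in seq_len(q)) {
        if (cnt[j] == 0L) next
        s <- colSums(Y[idx == j, seq_len(j), drop = FALSE])
        u <- u + drop(gp$B[[j]] %*% s)
        A <- A + cnt[j] * gp$M[[j]]
      }
    }
    bhat <- tryCatch(solve(A, u), error = function(e) NULL)
    if (is.null(bhat)) n_failed <- n_failed + 1L else est[r, ] <- bhat
  }
  list(est = est[stats::complete.cases(est), , drop = FALSE],
       n_failed = n_failed)
}

#' Compare designs by Monte Carlo simulation
#'
#' Repeatedly simulates each design's trial (responses from the linear
#' mixed model, monotone dropout from the multinomial pattern
#' distribution), estimates the fixed effects of every replicate by
#' available-case generalized least squares with known variance
#' components, and summarises each design by the empirical covariance of
#' the replicate estimates. Pairwise relative D-efficiencies are computed
#' from the empirical covariances, with a batching standard error.
#'
#' @param designs Named list of [trial_design()] objects.
#' @param model An [lmm_spec()] with `fixed$beta` set.
#' @param dropout A [dropout_spec()] or per-group list (shared across
#'   designs).
#' @param reps Number of simulated trials per design (at least 2).
#' @param seed Integer seed.
#' @param n_batches Number of batches for the RED standard error.
#' @return An object of class `"design_evaluation"`: per-design results
#'   (`estimates`, `cov`, `vars`, `det`, `n_failed`), the pairwise `red`
#'   matrix (`red[i, j]` = efficiency of design i relative to design j),
#'   and `red_se`.
#' @export
evaluate_designs <- function(designs, model, dropout, reps = 10000L,
                             seed = 1L, n_batches = 10L) {
  stopifnot(is.list(designs), length(designs) >= 1L,
            all(vapply(designs, inherits, TRUE, "trial_design")),
            reps >= 2L)
  if (is.null(names(designs))) {
    names(designs) <- paste0("design", seq_along(designs))
  }
  p <- model$fixed$p
  results <- with_seed(seed, {
    lapply(designs, function(d) {
      dr <- per_group_dropout(dropout, length(d$groups))
      out <- replicate_estimates(d, model, dr, reps)
      est <- out$est
      list(estimates = est, cov = stats::cov(est),
           vars = stats::setNames(apply(est, 2L, stats::var),
                                  paste0("var_beta", seq_len(p) - 1L)),
           det = det(stats::cov(est)), n_failed = out$n_failed,
           batch_covs = {
             bi <- cut(seq_len(nrow(est)), n_batches, labels = FALSE)
             lapply(seq_len(n_batches), function(b)
               stats::cov(est[bi == b, , drop = FALSE]))
           })
    })
  })
  nd <- length(designs)
  red <- matrix(1, nd, nd, dimnames = list(names(designs), names(designs)))
  red_se <- matrix(0, nd, nd, dimnames = dimnames(red))
  for (i in seq_len(nd)) {
    for (j in seq_len(nd)) {
      if (i == j) next
      red[i, j] <- relative_d_efficiency(results[[i]]$cov,
                                         results[[j]]$cov, p)
      per_batch <- vapply(seq_along(results[[i]]$batch_covs), function(b) {
        relative_d_efficiency(results[[i]]$batch_covs[[b]],
                              results[[j]]$batch_covs[[b]], p)
      }, 1)
      red_se[i, j] <- stats::sd(per_batch) / sqrt(length(per_batch))
    }
  }
  structure(list(results = results, red = red, red_se = red_se,
                 reps = reps, seed = seed), class = "design_evaluation")
}

#' @export
print.design_evaluation <- function(x, ...) {
  cat("Design comparison by simulation (", x$reps, " replicates)\n",
      sep = "")
  tab <- t(vapply(x$results, function(r) c(r$vars, det = r$det),
                  numeric(length(x$results[[1]]$vars) + 1L)))
  print(signif(tab, 4))
  cat("\nRelative D-efficiency (row vs column):\n")
  print(round(x$red, 4))
  invisible(x)
}
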