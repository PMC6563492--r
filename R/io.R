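## configuration parsing, design serialisation and report writing

config_keys <- list(
  top = c("seed", "model", "dropout", "problem", "cost", "simulation",
          "output"),
  model = c("model", "groups", "beta", "random_class", "d11", "d22",
            "d12", "sigma2", "corr_kind", "rho"),
  dropout = c("family", "coefficients", "baseline_certain"),
  problem = c("time_region", "times", "condition", "doses", "dose_region",
              "weights", "n_total"),
  cost = c("recruit_cost", "visit_cost", "budget", "q_values"),
  simulation = c("reps", "n_batches")
)

check_keys <- function(block, name) {
  unknown <- setdiff(names(block), config_keys[[name]])
  if (length(unknown)) {
    stop("unknown key(s) in '", name, "' block: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
}

need_key <- function(block, key, name) {
  if (is.null(block[[key]])) {
    stop("missing required key '", name, ".", key, "'", call. = FALSE)
  }
  block[[key]]
}

## yaml represents free entries as nulls inside sequences
na_from_null <- function(x) {
  if (is.null(x)) return(NULL)
  vapply(x, function(v) if (is.null(v)) NA_real_ else as.numeric(v), 1)
}

parse_model_block <- function(b) {
  check_keys(b, "model")
  lmm_spec(
    fixed_effects(need_key(b, "model", "model"),
                  groups = b$groups %||% 2L, beta = b$beta),
    random_effects(need_key(b, "random_class", "model"),
                   d11 = b$d11 %||% 0, d22 = b$d22 %||% 0,
                   d12 = b$d12 %||% 0),
    sigma2 = need_key(b, "sigma2", "model"),
    corr = corr_spec(b$corr_kind %||% "independent", rho = b$rho %||% 0))
}

parse_dropout_block <- function(b) {
  if (!is.null(b$family)) {
    check_keys(b, "dropout")
    return(dropout_spec(b$family, coef = unlist(b$coefficients),
                        baseline_certain = b$baseline_certain))
  }
  lapply(b, parse_dropout_block)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load and validate a run configuration
#'
#' Reads a YAML configuration describing a model, a dropout model, and
#' optionally a design problem, a cost model and simulation settings.
#' Unknown keys are rejected; validation errors name the offending key.
#'
#' @param path Path to a YAML file.
#' @return A list of class `"run_config"` with elements `seed`, `model`
#'   ([lmm_spec()]), `dropout`, and optionally `problem`
#'   ([design_problem()]), `cost` ([cost_model()] plus `q_values`), and
#'   `simulation`.
#' @examples
#' cfg <- load_config(system.file("extdata", "five_point_trial.yaml",
#'                                package = "dropoutDesign"))
#' cfg$problem$N
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw) || !length(raw)) {
    stop("empty configuration; required keys: model, dropout",
         call. = FALSE)
  }
  check_keys(raw, "top")
  model <- parse_model_block(need_key(raw, "model", "top"))
  dropout <- parse_dropout_block(need_key(raw, "dropout", "top"))
  cfg <- list(seed = as.integer(raw$seed %||% 1L),
              model = model, dropout = dropout)
  if (!is.null(raw$problem)) {
    b <- raw$problem
    check_keys(b, "problem")
    times <- b$times
    times <- if (is.list(times) && all(vapply(times, is.list, TRUE))) {
      lapply(times, na_from_null)
    } else {
      na_from_null(times)
    }
    cfg$problem <- design_problem(
      model, dropout,
      time_region = unlist(need_key(b, "time_region", "problem")),
      times = times,
      condition = b$condition %||% "restricted",
      doses = na_from_null(b$doses),
      dose_region = if (!is.null(b$dose_region)) unlist(b$dose_region),
      weights = if (!is.null(b$weights)) unlist(b$weights),
      N = b$n_total %||% 100L)
  }
  if (!is.null(raw$cost)) {
    b <- raw$cost
    check_keys(b, "cost")
    cfg$cost <- cost_model(need_key(b, "recruit_cost", "cost"),
                           need_key(b, "visit_cost", "cost"),
                           need_key(b, "budget", "cost"))
    cfg$q_values <- unlist(b$q_values)
  }
  if (!is.null(raw$simulation)) {
    check_keys(raw$simulation, "simulation")
    cfg$simulation <- list(reps = as.integer(raw$simulation$reps %||%
                                               10000L),
                           n_batches = as.integer(
                             raw$simulation$n_batches %||% 10L))
  }
  class(cfg) <- "run_config"
  cfg
}

#' Serialise a trial design to JSON
#'
#' @param design A [trial_design()].
#' @param path File path.
#' @return `path` invisibly.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "trial_design"))
  obj <- list(N = design$N, n = design$n,
              groups = lapply(design$groups, function(g) {
                list(t = g$t, w = g$w, dose = g$dose)
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a trial design from JSON written by [write_design()]
#'
#' @param path File path.
#' @return A [trial_design()].
#' @export
read_design <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  trial_design(lapply(seq_len(nrow(obj$groups)), function(k) {
    group_design(unlist(obj$groups$t[k]), obj$groups$w[k],
                 dose = if (!is.null(obj$groups$dose)) obj$groups$dose[k])
  }), N = obj$N, n = obj$n)
}

#' Expected-count table of a design (text report)
#'
#' Formats, for each group, the design's time points and the rounded
#' expected number of subjects with exactly j observed measurements.
#'
#' @param design A [trial_design()].
#' @param dropout A [dropout_spec()] or per-group list.
#' @param labels Optional group labels.
#' @return Character vector of report lines.
#' @export
count_table <- function(design, dropout,
                        labels = paste("Group", seq_along(design$groups))) {
  dropout <- per_group_dropout(dropout, length(design$groups))
  lines <- character(0)
  for (k in seq_along(design$groups)) {
    g <- design$groups[[k]]
    cnt <- expected_pattern_counts(dropout[[k]], g$t, g$dose,
                                   n_alloc = design$n[k])
    if (k == 1L) {
      lines <- c(lines, paste(c("Time points:",
                                format(round(g$t, 4), trim = TRUE)),
                              collapse = " "))
    }
    lines <- c(lines, paste(c(labels[k], cnt$m_rounded,
                              sum(cnt$m_rounded)), collapse = " "))
  }
  lines
}

#' Write a deterministic report of a solution or evaluation
#'
#' Supported inputs: a `"design_solution"` (json, csv or text), a
#' `"cost_scan"` (csv or json), a `"design_evaluation"` (json or csv) or
#' a [trial_design()] (json). Identical inputs produce byte-identical
#' files; the text format lists the optimized time points and the
#' per-group rounded expected dropout-pattern counts.
#'
#' @param x Object to report.
#' @param path Output file path.
#' @param format One of `"json"`, `"csv"`, `"text"`.
#' @return `path` invisibly.
#' @export
write_report <- function(x, path, format = c("json", "csv", "text")) {
  format <- match.arg(format)
  if (inherits(x, "trial_design")) {
    stopifnot(format == "json")
    return(write_design(x, path))
  }
  if (inherits(x, "design_solution")) {
    if (format == "json") {
      obj <- list(criterion = x$criterion, converged = x$converged,
                  n_starts = x$n_starts, seed = x$seed,
                  N = x$design$N, n = x$design$n,
                  groups = lapply(x$design$groups, function(g) {
                    list(t = g$t, w = g$w, dose = g$dose)
                  }))
      jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                           null = "null")
    } else if (format == "csv") {
      utils::write.csv(as.data.frame(x$design), path, row.names = FALSE)
    } else {
      writeLines(c(sprintf("log det information: %.6f", x$criterion),
                   count_table(x$design, x$problem$dropout)), path)
    }
    return(invisible(path))
  }
  if (inherits(x, "cost_scan")) {
    if (format == "csv") {
      utils::write.csv(x$table, path, row.names = FALSE)
    } else {
      jsonlite::write_json(x$table, path, dataframe = "rows", digits = NA)
    }
    return(invisible(path))
  }
  if (inherits(x, "design_evaluation")) {
    summ <- lapply(x$results, function(r) {
      list(vars = unname(r$vars), det = r$det, n_failed = r$n_failed)
    })
    obj <- list(reps = x$reps, seed = x$seed, designs = summ,
                red = as.data.frame(x$red), red_se = as.data.frame(x$red_se))
    if (format == "json") {
      jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    } else {
      tab <- data.frame(design = names(x$results),
                        t(vapply(x$results, function(r)
                          c(r$vars, det = r$det),
                          numeric(length(x$results[[1]]$vars) + 1L))))
      utils::write.csv(tab, path, row.names = FALSE)
    }
    return(invisible(path))
  }
  stop("no report writer for class ", paste(class(x), collapse = "/"),
       call. = FALSE)
}
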