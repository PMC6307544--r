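# Adaptation error functionals: per-network, per-task, per-niche and
# whole-holobiont aggregation.

#' Adaptation error of an output signal against a task
#'
#' The time-averaged squared deviation between the output signal `R(t)` and
#' the target `F(t)` over `t = 1..t_max`:
#' `xi = (1/t_max) * sum_t (R(t) - F(t))^2`. Zero iff the signal matches the
#' task exactly; a value of 1 corresponds to one signal node deviating one
#' unit at every time step (the default adaptation threshold).
#'
#' @param signal Integer vector `R(t)`, `t = 1..t_max`.
#' @param target A `target_function` or plain integer vector of the same
#'   length.
#' @return Non-negative scalar error.
#' @export
adaptation_error <- function(signal, target) {
  if (length(signal) != length(target)) {
    abort("`signal` and `target` must have the same length (t_max).")
  }
  mean((as.numeric(signal) - as.numeric(target))^2)
}

#' Aggregate host and microbial errors into the holobiont error
#'
#' Two aggregation modes are supported. `"eq4"` weighs every network
#' equally: `(xi_H + sum_j xi_M_j) / (1 + PM)`. `"eq5"` weighs the host and
#' the whole microbiota equally: `(xi_H + mean_j xi_M_j) / 2`, making the
#' microbiota's contribution independent of its size. With no microbes both
#' modes reduce to the host error; with a single microbe they coincide.
#'
#' @param host_error Host adaptation error `xi_H`.
#' @param microbial_errors Numeric vector of per-microbe errors (may be
#'   empty).
#' @param mode `"eq5"` (default, used for all headline results) or `"eq4"`.
#' @return Scalar holobiont error `xi_L`.
#' @export
holobiont_error <- function(host_error, microbial_errors = numeric(0),
                            mode = c("eq5", "eq4")) {
  mode <- match.arg(mode)
  pm <- length(microbial_errors)
  if (pm == 0L) {
    return(host_error)
  }
  if (mode == "eq4") {
    (host_error + sum(microbial_errors)) / (1 + pm)
  } else {
    (host_error + mean(microbial_errors)) / 2
  }
}

#' Niche error in the specialized interaction scheme
#'
#' For a niche with `p` microbes assisting `q` tasks, the niche error is
#' `(xi_H_niche + sum_i mean_j xi_M_{i,j}) / (1 + p)`, where `xi_H_niche` is
#' the host's mean error over the niche's tasks and `xi_M_{i,j}` the error
#' of niche microbe `i` evaluated under the initial condition of niche task
#' `j`. The specialized holobiont error is the mean of the niche errors.
#'
#' @param host_per_task Host per-task errors over the niche's `q` tasks.
#' @param microbial_per_task `p` x `q` matrix (or length-`q` vector for a
#'   single microbe) of per-microbe, per-task errors within the niche.
#' @return Scalar niche error.
#' @export
niche_error <- function(host_per_task, microbial_per_task) {
  if (length(host_per_task) == 0L) {
    abort("a niche must be assigned at least one task")
  }
  if (is.null(dim(microbial_per_task))) {
    microbial_per_task <- matrix(microbial_per_task, nrow = 1L)
  }
  if (nrow(microbial_per_task) == 0L) {
    abort("a niche must contain at least one microbe")
  }
  if (ncol(microbial_per_task) != length(host_per_task)) {
    abort("microbial errors must cover the same tasks as `host_per_task`")
  }
  p <- nrow(microbial_per_task)
  (mean(host_per_task) + sum(rowMeans(microbial_per_task))) / (1 + p)
}

#' Is an error below the adaptation threshold?
#'
#' The comparison is inclusive: a network whose error equals the threshold
#' counts as well adapted.
#'
#' @param error Adaptation error(s).
#' @param delta_a Adaptation threshold (default 1).
#' @return Logical.
#' @export
is_well_adapted <- function(error, delta_a = 1) {
  error <= delta_a
}

#' Evaluate every error of a holobiont on a task set
#'
#' Runs one deterministic trajectory of the full holobiont per host task
#' (the host starting from that task's initial condition, each microbe from
#' its own fixed one) and computes all per-task, per-network, per-niche and
#' aggregate errors.
#'
#' @param holobiont A `holobiont` (or `bn_network`).
#' @param task_set A `task_set` with one microbial task per microbe.
#' @param init_conditions Host initial-condition matrix (one row per task).
#' @param mode Holobiont-error aggregation, `"eq5"` or `"eq4"`; ignored in
#'   favor of niche averaging when the holobiont carries a niche partition.
#' @param scope `"host_plus_niche"` (default): while evaluating a task,
#'   microbes outside the task's niche have their cross-network influence
#'   silenced (inert for holobionts without a niche partition). `"full"`:
#'   all networks' dynamics feed into every task evaluation.
#' @return An `error_report`: list with `host_per_task`, `host_total`,
#'   `microbial_per_task` (PM x T matrix), `microbial_totals`,
#'   `niche_errors` (or NULL), `holobiont_error`, `mode`.
#' @export
evaluate_holobiont <- function(holobiont, task_set, init_conditions,
                               mode = c("eq5", "eq4"),
                               scope = c("host_plus_niche", "full")) {
  mode <- match.arg(mode)
  scope <- match.arg(scope)
  holobiont <- as_holobiont(holobiont)
  pm <- n_microbes(holobiont)
  n_tasks <- length(task_set$host)
  if (length(task_set$microbial) != pm) {
    abort("`task_set` must hold exactly one microbial task per microbe")
  }
  if (nrow(init_conditions) != n_tasks) {
    abort("`init_conditions` must have one row per host task")
  }
  t_max <- length(task_set$host[[1L]])
  res <- cpp_evaluate(
    unclass(holobiont),
    tasks_matrix(task_set$host, t_max),
    tasks_matrix(task_set$microbial, t_max),
    init_conditions,
    as.integer(t_max),
    if (mode == "eq4") 4L else 5L,
    if (scope == "host_plus_niche") 1L else 0L,
    task_niche_vector(holobiont$task_assignment, n_tasks),
    detached_mask(holobiont)
  )
  res$mode <- mode
  res$scope <- scope
  structure(res, class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat("<error_report>\n")
  cat("  host total error:      ", format(x$host_total, digits = 4), "\n")
  if (length(x$microbial_totals)) {
    cat(
      "  mean microbial error:  ",
      format(mean(x$microbial_totals), digits = 4), "\n"
    )
  }
  cat(
    "  holobiont error (", x$mode, "): ",
    format(x$holobiont_error, digits = 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy an error report into one row per entity and task
#'
#' @param x An `error_report`.
#' @param ... Unused.
#' @return Tibble with columns `entity` ("host", "microbe_j" or "niche_g"),
#'   `task` (NA for niche rows) and `error`.
#' @export
tidy.error_report <- function(x, ...) {
  n_tasks <- length(x$host_per_task)
  out <- tibble::tibble(
    entity = "host",
    task = seq_len(n_tasks),
    error = as.numeric(x$host_per_task)
  )
  pm <- length(x$microbial_totals)
  if (pm > 0L) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      entity = rep(paste0("microbe_", seq_len(pm)), each = n_tasks),
      task = rep(seq_len(n_tasks), pm),
      error = as.numeric(t(x$microbial_per_task))
    ))
  }
  if (!is.null(x$niche_errors)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      entity = paste0("niche_", seq_along(x$niche_errors)),
      task = NA_integer_,
      error = as.numeric(x$niche_errors)
    ))
  }
  out
}
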