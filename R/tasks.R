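# Tasks (target functions), initial conditions and niche partitions.

#' Generate a random target function (task)
#'
#' A task is an integer time series `F(t)` on `t = 1..t_max` with
#' `0 < F(t) < n_signal` strictly: the required output signal can always be
#' realized by the signal nodes but is never the trivial all-on/all-off
#' pattern. Values are drawn i.i.d. uniform from `{1, ..., n_signal - 1}`.
#'
#' @param n_signal Number of signal nodes `Ns` the task is evaluated on
#'   (must be at least 2 for an admissible value to exist).
#' @param t_max Number of evaluated time steps (default 15).
#' @return A `target_function`: integer vector of length `t_max` with
#'   attributes `n_signal` and `t_max`.
#' @export
generate_target_function <- function(n_signal, t_max = 15L) {
  if (n_signal < 2L) {
    abort("`n_signal` must be >= 2: no integer lies strictly between 0 and 1.")
  }
  values <- sample.int(n_signal - 1L, t_max, replace = TRUE)
  structure(as.integer(values),
    n_signal = as.integer(n_signal), t_max = as.integer(t_max),
    class = "target_function"
  )
}

#' @export
print.target_function <- function(x, ...) {
  cat("<target_function> F(t), t = 1..", attr(x, "t_max"),
    ", 0 < F < ", attr(x, "n_signal"), "\n",
    sep = ""
  )
  print(as.integer(x))
  invisible(x)
}

#' Generate a task set for a holobiont
#'
#' Draws `n_tasks` host tasks and one microbial task per microbe, all
#' pairwise distinct (tasks are redrawn on collision, which for realistic
#' `n_signal`/`t_max` is essentially a formality). Requesting more distinct
#' tasks than the task space holds (e.g. several tasks at `n_signal = 2`,
#' where only the constant task exists) is an error.
#'
#' @param n_tasks Number of host tasks `T`.
#' @param n_microbes Number of microbial networks `PM`.
#' @inheritParams generate_target_function
#' @return A `task_set`: list with elements `host` (list of `T`
#'   `target_function`s) and `microbial` (list of `PM`).
#' @export
generate_task_set <- function(n_tasks, n_microbes = 0L, n_signal,
                              t_max = 15L) {
  n_distinct <- (n_signal - 1)^t_max
  if (n_tasks + n_microbes > n_distinct) {
    abort(sprintf(
      "cannot draw %d distinct tasks: only %g exist for n_signal = %d, t_max = %d",
      n_tasks + n_microbes, n_distinct, n_signal, t_max
    ))
  }
  seen <- character(0)
  draw_distinct <- function() {
    for (attempt in 1:10000) {
      tf <- generate_target_function(n_signal, t_max)
      key <- paste(as.integer(tf), collapse = ",")
      if (!key %in% seen) {
        seen <<- c(seen, key)
        return(tf)
      }
    }
    abort("failed to draw a distinct task after 10000 attempts")
  }
  structure(
    list(
      host = replicate(n_tasks, draw_distinct(), simplify = FALSE),
      microbial = replicate(n_microbes, draw_distinct(), simplify = FALSE)
    ),
    class = "task_set"
  )
}

#' Generate per-task host initial conditions
#'
#' Each host task is evaluated from its own fixed initial condition, drawn
#' uniformly at random once at simulation start. Microbes keep their own
#' single initial condition for every task.
#'
#' @param n_tasks Number of host tasks.
#' @param n_nodes Host network size `N`.
#' @return A `n_tasks` x `n_nodes` 0/1 integer matrix (one row per task).
#' @export
generate_initial_conditions <- function(n_tasks, n_nodes) {
  matrix(sample(0:1, n_tasks * n_nodes, replace = TRUE),
    nrow = n_tasks, ncol = n_nodes
  )
}

#' Partition microbes into niches and assign tasks to niches
#'
#' For the specialized interaction scheme, the `PM` microbes are divided
#' into `n_niches` disjoint non-empty niches (dealt round-robin) and the
#' `n_tasks` host tasks are partitioned across niches as evenly as possible
#' (contiguous blocks). Each niche assists the host only with its own tasks,
#' and microbes may interact only within their niche (all microbes may
#' interact with the host).
#'
#' @param n_microbes Number of microbial networks `PM`.
#' @param n_tasks Number of host tasks `T`.
#' @param n_niches Number of niches `PG` (default `min(PM, T)`; must satisfy
#'   `PG <= T` and `PG <= PM`).
#' @return A `niche_partition`: list with `niche` (niche index per microbe),
#'   `task_assignment` (list of task-index vectors per niche), `n_niches`,
#'   `n_microbes`, `n_tasks`.
#' @export
make_niche_partition <- function(n_microbes, n_tasks,
                                 n_niches = min(n_microbes, n_tasks)) {
  if (n_niches < 1L || n_niches > n_tasks || n_niches > n_microbes) {
    abort("`n_niches` must satisfy 1 <= n_niches <= min(n_microbes, n_tasks)")
  }
  niche <- rep(seq_len(n_niches), length.out = n_microbes)
  sizes <- rep(n_tasks %/% n_niches, n_niches)
  extra <- n_tasks %% n_niches
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  task_assignment <- split(
    seq_len(n_tasks),
    rep(seq_len(n_niches), times = sizes)
  )
  names(task_assignment) <- NULL
  structure(
    list(
      niche = as.integer(niche),
      task_assignment = lapply(task_assignment, as.integer),
      n_niches = as.integer(n_niches),
      n_microbes = as.integer(n_microbes),
      n_tasks = as.integer(n_tasks)
    ),
    class = "niche_partition"
  )
}

# T x tm integer matrix of host tasks (rows = tasks)
tasks_matrix <- function(task_list, t_max) {
  if (length(task_list) == 0L) {
    return(matrix(integer(0), nrow = 0L, ncol = t_max))
  }
  do.call(rbind, lapply(task_list, as.integer))
}

# Per-task niche index (1-based), or integer(0) when not specialized.
task_niche_vector <- function(task_assignment, n_tasks) {
  if (is.null(task_assignment)) {
    return(integer(0))
  }
  out <- integer(n_tasks)
  for (g in seq_along(task_assignment)) out[task_assignment[[g]]] <- g
  out
}
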