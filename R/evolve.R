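# Population-level evolutionary engine.

#' Simulation configuration
#'
#' Bundles and validates every simulation parameter. Defaults are the
#' standard study conditions: populations of `P = 100` networks with
#' `N = 50` nodes, connectivity `K = 2` (the critical regime for random
#' Boolean networks), `Ns = 12` signal nodes, tasks evaluated over
#' `t_max = 15` steps, host mutation rate `mu_H = 0.001` per node per
#' generation, microbial rate `mu_M = gamma * mu_H` with `gamma = 10`,
#' adaptation threshold `delta_A = 1`, and elitist selection of the 10 best
#' individuals, each replicated with 9 copies.
#'
#' @param n_nodes Nodes per network `N`.
#' @param in_degree Initial regulators per node `K`.
#' @param n_signal Signal nodes `Ns`.
#' @param t_max Task length `t_m`.
#' @param pop_size Population size `P`.
#' @param n_microbes Microbial networks per holobiont `PM`.
#' @param n_tasks Host tasks `T`.
#' @param n_niches Niches `PG` (specialized scheme only; default
#'   `min(PM, T)`).
#' @param mu_host Host per-node mutation rate.
#' @param gamma Ratio `mu_M / mu_H`. `gamma = Inf` is the within-lifespan
#'   limit and is implemented as `mu_host = 0` with `mu_microbe` kept at
#'   `10 * 0.001`.
#' @param mu_microbe Microbial per-node mutation rate; overrides `gamma`
#'   when supplied.
#' @param delta_a Adaptation threshold.
#' @param n_survivors Individuals selected each generation.
#' @param copies_per_survivor Copies made of each survivor
#'   (`n_survivors * (1 + copies_per_survivor)` must equal `pop_size`).
#' @param aggregation Holobiont-error definition, `"eq5"` (default) or
#'   `"eq4"`.
#' @param scheme Interaction scheme: `"control"` (no microbes),
#'   `"nonspecialized"` or `"specialized"`. Default: control when
#'   `n_microbes == 0`, specialized when `n_niches` is given, otherwise
#'   non-specialized.
#' @param evaluation_scope `"host_plus_niche"` (default) or `"full"`. Only
#'   meaningful for the specialized scheme: under `"host_plus_niche"` the
#'   evaluation of a task silences the cross-network influence of microbes
#'   outside the task's niche, so each niche's assistance is specific to its
#'   own tasks; under `"full"` every network's dynamics feeds into every
#'   task evaluation (see [evaluate_holobiont()]).
#' @param max_generations Generations to simulate.
#' @param k_max In-degree cap.
#' @param table_policy_add How a node's truth table grows when it gains a
#'   regulator: `"random"` (default) fills the new half with fresh uniform
#'   bits, so a single added connection is a standalone evolutionary move
#'   that can change the phenotype; `"copy"` duplicates the existing table,
#'   making the addition phenotypically neutral until the table mutates.
#' @param table_policy_remove Which half survives when a regulator is
#'   removed: `"zero"` (default) keeps the removed-regulator = 0 half,
#'   `"random"` keeps the half for a uniformly drawn regulator value.
#' @param mutate_survivors Are the selected survivors themselves exposed to
#'   mutation again each generation (`TRUE`), or is mutation restricted to
#'   their replicated copies (`FALSE`)?
#' @param tie_break How selection resolves equal errors: `"random"`
#'   (default) picks uniformly among ties, which allows selectively neutral
#'   variants to replace incumbent copies and the population to drift along
#'   neutral networks; `"stable"` keeps the earliest individual in input
#'   order.
#' @param seed Optional RNG seed consumed by [evolve()].
#' @return An `evolution_config` (validated named list).
#' @export
evolution_config <- function(n_nodes = 50L, in_degree = 2L, n_signal = 12L,
                             t_max = 15L, pop_size = 100L, n_microbes = 0L,
                             n_tasks = 1L, n_niches = NULL, mu_host = 0.001,
                             gamma = 10, mu_microbe = NULL, delta_a = 1,
                             n_survivors = 10L, copies_per_survivor = 9L,
                             aggregation = c("eq5", "eq4"), scheme = NULL,
                             evaluation_scope = c(
                               "host_plus_niche",
                               "full"
                             ),
                             max_generations = 500L, k_max = 10L,
                             table_policy_add = c("random", "copy"),
                             table_policy_remove = c("zero", "random"),
                             mutate_survivors = TRUE,
                             tie_break = c("random", "stable"),
                             seed = NULL) {
  aggregation <- match.arg(aggregation)
  evaluation_scope <- match.arg(evaluation_scope)
  table_policy_add <- match.arg(table_policy_add)
  table_policy_remove <- match.arg(table_policy_remove)
  tie_break <- match.arg(tie_break)
  if (is.infinite(gamma)) {
    mu_host <- 0
    mu_microbe <- mu_microbe %||% (10 * 0.001)
  }
  mu_microbe <- mu_microbe %||% (gamma * mu_host)
  scheme <- scheme %||% if (n_microbes == 0L) {
    "control"
  } else if (!is.null(n_niches)) {
    "specialized"
  } else {
    "nonspecialized"
  }
  scheme <- match.arg(scheme, c("control", "nonspecialized", "specialized"))
  if (scheme == "specialized") {
    n_niches <- n_niches %||% min(n_microbes, n_tasks)
  }
  if (scheme == "control" && n_microbes > 0L) {
    abort("the control scheme has no microbial networks; set n_microbes = 0")
  }
  if (n_survivors * (1L + copies_per_survivor) != pop_size) {
    abort(sprintf(
      "n_survivors * (1 + copies_per_survivor) must equal pop_size (%d * %d != %d)",
      n_survivors, 1L + copies_per_survivor, pop_size
    ))
  }
  if (!is.null(n_niches) &&
    (n_niches > n_tasks || n_niches > max(n_microbes, 1L))) {
    abort("`n_niches` must not exceed `n_tasks` or `n_microbes`")
  }
  if (mu_host < 0 || mu_microbe < 0) {
    abort("mutation rates must be non-negative")
  }
  if (n_signal < 2L || n_signal > n_nodes) {
    abort("`n_signal` must be in [2, n_nodes]")
  }
  structure(
    list(
      n_nodes = as.integer(n_nodes), in_degree = as.integer(in_degree),
      n_signal = as.integer(n_signal), t_max = as.integer(t_max),
      pop_size = as.integer(pop_size), n_microbes = as.integer(n_microbes),
      n_tasks = as.integer(n_tasks),
      n_niches = if (is.null(n_niches)) NULL else as.integer(n_niches),
      mu_host = mu_host, gamma = gamma, mu_microbe = mu_microbe,
      delta_a = delta_a, n_survivors = as.integer(n_survivors),
      copies_per_survivor = as.integer(copies_per_survivor),
      aggregation = aggregation, scheme = scheme,
      evaluation_scope = evaluation_scope,
      max_generations = as.integer(max_generations),
      k_max = as.integer(k_max),
      table_policy_add = table_policy_add,
      table_policy_remove = table_policy_remove,
      mutate_survivors = isTRUE(mutate_survivors),
      tie_break = tie_break, seed = seed
    ),
    class = "evolution_config"
  )
}

#' @export
print.evolution_config <- function(x, ...) {
  cat("<evolution_config>\n")
  cat(sprintf(
    "  networks: N = %d, K = %d, Ns = %d, t_max = %d\n",
    x$n_nodes, x$in_degree, x$n_signal, x$t_max
  ))
  cat(sprintf(
    "  population: P = %d (%d survivors x %d copies), %d generation(s)\n",
    x$pop_size, x$n_survivors, 1L + x$copies_per_survivor,
    x$max_generations
  ))
  cat(sprintf(
    "  scheme: %s, PM = %d, T = %d%s, aggregation %s\n",
    x$scheme, x$n_microbes, x$n_tasks,
    if (!is.null(x$n_niches)) sprintf(", PG = %d", x$n_niches) else "",
    x$aggregation
  ))
  cat(sprintf(
    "  rates: mu_H = %g, mu_M = %g, delta_A = %g\n",
    x$mu_host, x$mu_microbe, x$delta_a
  ))
  invisible(x)
}

# Map a table-policy label onto the compiled core's code for it
# (add: 1 = "copy"; remove: 1 = "random").
policy_code <- function(value, one_label) {
  if (identical(value, one_label)) 1L else 0L
}

# Rebuild (and so re-validate) a config with some fields replaced.  Derived
# fields are re-derived: changing gamma re-derives mu_microbe.
update_config <- function(config, ...) {
  fields <- unclass(config)
  changes <- list(...)
  if ("gamma" %in% names(changes) && !("mu_microbe" %in% names(changes))) {
    fields$mu_microbe <- NULL
  }
  if ("n_microbes" %in% names(changes) && !("scheme" %in% names(changes))) {
    if (identical(changes$n_microbes, 0L) || changes$n_microbes == 0) {
      fields$scheme <- NULL
      fields$n_niches <- NULL
    }
  }
  fields[names(changes)] <- changes
  do.call(evolution_config, fields)
}

#' Pretrain a microbial network on its own task
#'
#' Evolves a standalone population (same mutate/select/replicate algorithm,
#' no partner networks) seeded with `pop_size` copies of one random network
#' until the best individual's error is strictly below the adaptation
#' threshold, and returns that individual with its mutation counter reset.
#' If a random starting network fails to adapt within `max_generations`,
#' a fresh one is drawn (up to `max_attempts` starts).
#'
#' @param task A `target_function`, the microbe's own task.
#' @param config An [evolution_config()]; supplies the network geometry,
#'   population sizes and threshold.
#' @param mu Mutation rate used during pretraining (default the config's
#'   microbial rate `mu_microbe`: microbial networks generate mutants at
#'   their own faster rate during their standalone adaptation too).
#' @param max_generations Generation cap per attempt.
#' @param max_attempts Fresh random starts before giving up.
#' @return A well-adapted `bn_network` with attributes
#'   `pretrain_generations` and `pretrain_error`.
#' @export
pretrain_microbial_network <- function(task, config,
                                       mu = NULL,
                                       max_generations = 4000L,
                                       max_attempts = 5L) {
  mu <- mu %||% max(config$mu_microbe, 0.001)
  for (attempt in seq_len(max_attempts)) {
    net <- build_random_network(config$n_nodes, config$in_degree,
      n_signal = attr(task, "n_signal")
    )
    res <- cpp_pretrain(
      unclass(net), as.integer(task), config$pop_size,
      config$n_survivors, config$copies_per_survivor, mu,
      config$delta_a, as.integer(max_generations), config$k_max,
      config$t_max, policy_code(config$table_policy_add, "copy"),
      policy_code(config$table_policy_remove, "random"),
      if (config$mutate_survivors) 1L else 0L,
      if (config$tie_break == "random") 1L else 0L
    )
    if (isTRUE(res$success)) {
      out <- res$network
      attr(out, "pretrain_generations") <- res$generations
      attr(out, "pretrain_error") <- res$best_error
      return(out)
    }
  }
  abort(sprintf(
    "pretraining failed to reach error < %g within %d generations (%d attempts)",
    config$delta_a, max_generations, max_attempts
  ))
}

#' Elitist selection and replication
#'
#' Keeps the `n_survivors` holobionts with the smallest errors (ties broken
#' by stable input order) and restores the population to its original size
#' by making `copies_per_survivor` copies of each survivor. Copies inherit
#' wiring and mutation counters.
#'
#' @param population List of holobionts.
#' @param errors Numeric vector of holobiont errors, parallel to
#'   `population`.
#' @param n_survivors,copies_per_survivor Selection sizes.
#' @return New population (list) of the same size.
#' @export
select_and_replicate <- function(population, errors, n_survivors = 10L,
                                 copies_per_survivor = 9L) {
  if (length(population) != length(errors)) {
    abort("`population` and `errors` must have the same length")
  }
  if (n_survivors * (1L + copies_per_survivor) != length(population)) {
    abort("selection sizes do not restore the population size")
  }
  keep <- order(errors)[seq_len(n_survivors)]
  population[rep(keep, each = 1L + copies_per_survivor)]
}

#' Per-generation population statistics
#'
#' @param host_errors Per-individual host errors.
#' @param holobiont_errors Per-individual holobiont errors.
#' @param mutation_counts Per-individual host accumulated-mutation counters.
#' @param microbial_errors Optional per-individual mean microbial errors.
#' @param delta_a Adaptation threshold for the adaptation probability
#'   `P_A` (fraction of individuals with host error at or below the
#'   threshold).
#' @param generation Generation index to record.
#' @return One-row tibble with `generation`, `xi_h`, `xi_m`, `xi_l`, `p_a`,
#'   `omega_h`, `best_xi_l`.
#' @export
compute_generation_record <- function(host_errors, holobiont_errors,
                                      mutation_counts,
                                      microbial_errors = NULL,
                                      delta_a = 1, generation = NA_integer_) {
  tibble::tibble(
    generation = as.integer(generation),
    xi_h = mean(host_errors),
    xi_m = if (is.null(microbial_errors)) {
      NA_real_
    } else {
      mean(microbial_errors)
    },
    xi_l = mean(holobiont_errors),
    p_a = mean(host_errors <= delta_a),
    omega_h = mean(mutation_counts),
    best_xi_l = min(holobiont_errors)
  )
}

#' Evolve a population of holobionts
#'
#' Runs the full evolutionary loop: the initial population consists of
#' `pop_size` identical copies of one randomly constructed host paired with
#' copies of the pretrained microbes; each generation all networks of every
#' holobiont are mutated, every holobiont is evaluated on every host task,
#' population statistics are recorded, and the best holobionts are selected
#' and replicated. Fully deterministic given the seed.
#'
#' @param config An [evolution_config()].
#' @param task_set Optional [generate_task_set()] result (drawn from the
#'   config when omitted).
#' @param init_conditions Optional host initial-condition matrix.
#' @param microbes Optional list of pretrained microbial networks (one per
#'   microbe; pretrained internally when omitted).
#' @param host Optional starting host network (random when omitted).
#' @param return_population Keep the final population on the result?
#' @param seed RNG seed (default `config$seed`); when non-NULL, `set.seed()`
#'   is called so the whole run is reproducible.
#' @return A `holo_evolution` object: list with `records` (tibble, one row
#'   per generation `0..max_generations`), `population`, `final_errors`,
#'   `task_set`, `init_conditions`, `niche_partition`, `config` and
#'   `pretrain_generations`.
#' @examples
#' cfg <- evolution_config(
#'   n_nodes = 16, n_signal = 4, pop_size = 20,
#'   n_survivors = 4, copies_per_survivor = 4,
#'   max_generations = 20, seed = 1
#' )
#' fit <- evolve(cfg)
#' glance(fit)
#' @export
evolve <- function(config, task_set = NULL, init_conditions = NULL,
                   microbes = NULL, host = NULL, return_population = TRUE,
                   seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  task_set <- task_set %||% generate_task_set(
    config$n_tasks, config$n_microbes, config$n_signal, config$t_max
  )
  init_conditions <- init_conditions %||%
    generate_initial_conditions(config$n_tasks, config$n_nodes)
  partition <- NULL
  if (config$scheme == "specialized") {
    partition <- make_niche_partition(
      config$n_microbes, config$n_tasks, config$n_niches
    )
  }
  pretrain_gen <- integer(0)
  if (config$n_microbes > 0L && is.null(microbes)) {
    microbes <- lapply(task_set$microbial, pretrain_microbial_network,
      config = config
    )
    pretrain_gen <- vapply(microbes, attr, integer(1),
      which = "pretrain_generations"
    )
  }
  microbes <- microbes %||% list()
  host <- host %||% build_random_network(
    config$n_nodes, config$in_degree, config$n_signal
  )
  h0 <- new_holobiont(host, microbes, partition)
  task_niche <- task_niche_vector(h0$task_assignment, config$n_tasks)
  res <- cpp_evolve(
    unclass(h0),
    tasks_matrix(task_set$host, config$t_max),
    tasks_matrix(task_set$microbial, config$t_max),
    init_conditions,
    task_niche,
    config$pop_size, config$n_survivors, config$copies_per_survivor,
    config$mu_host, config$mu_microbe, config$delta_a,
    if (config$aggregation == "eq4") 4L else 5L,
    if (config$evaluation_scope == "host_plus_niche") 1L else 0L,
    config$k_max, config$t_max, config$max_generations,
    isTRUE(return_population),
    policy_code(config$table_policy_add, "copy"),
    policy_code(config$table_policy_remove, "random"),
    if (config$mutate_survivors) 1L else 0L,
    if (config$tie_break == "random") 1L else 0L
  )
  records <- tibble::as_tibble(as.data.frame(res$records))
  records$generation <- as.integer(records$generation)
  population <- NULL
  if (isTRUE(return_population)) {
    population <- lapply(res$population, function(h) {
      h <- set_field(h, "task_assignment", h0$task_assignment)
      set_field(h, "detached", NULL)
    })
  }
  structure(
    list(
      records = records,
      population = population,
      final_errors = tibble::tibble(
        individual = seq_along(res$final_xi_l),
        xi_l = res$final_xi_l,
        xi_h = res$final_xi_h
      ),
      task_set = task_set,
      init_conditions = init_conditions,
      niche_partition = partition,
      config = config,
      pretrain_generations = pretrain_gen
    ),
    class = "holo_evolution"
  )
}

#' @export
print.holo_evolution <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<holo_evolution> %s scheme, PM = %d, T = %d, %d generations\n",
    x$config$scheme, x$config$n_microbes, x$config$n_tasks,
    x$config$max_generations
  ))
  cat(sprintf(
    "  final xi_h = %.3f, P_A = %.2f, first crossing of delta_A: %s\n",
    g$final_xi_h, g$final_p_a,
    if (is.na(g$first_crossing)) "never" else g$first_crossing
  ))
  invisible(x)
}

#' First generation at which a trajectory statistic crosses a threshold
#'
#' @param records A `holo_evolution` records tibble (or the object itself).
#' @param delta_a Threshold (inclusive comparison).
#' @param column Which statistic to test (default the population-mean host
#'   error `"xi_h"`).
#' @return Integer generation, or `NA` if the threshold is never reached.
#' @export
first_crossing <- function(records, delta_a = 1, column = "xi_h") {
  if (inherits(records, "holo_evolution")) records <- records$records
  hit <- which(records[[column]] <= delta_a)
  if (length(hit) == 0L) {
    return(NA_integer_)
  }
  as.integer(records$generation[hit[1L]])
}
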