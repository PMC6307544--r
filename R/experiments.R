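# Scenario runners: replicated experiments, sweeps, disconnection
# (dysbiosis) interventions and diversity-loss curves.

#' Describe a replicated (optionally swept) experiment
#'
#' @param config Base [evolution_config()].
#' @param n_replicates Replicates per condition.
#' @param seeds Optional integer vector of per-replicate seeds (distinct);
#'   derived reproducibly from `master_seed` when omitted.
#' @param master_seed Seed used to derive replicate seeds (default
#'   `config$seed`, falling back to 1).
#' @param sweep_param Optional config field to sweep (e.g. `"n_microbes"`,
#'   `"gamma"`, `"delta_a"`, `"in_degree"`).
#' @param sweep_values Values for `sweep_param`.
#' @param return_populations Keep final populations for every run?
#' @return An `experiment_spec`.
#' @export
experiment_spec <- function(config, n_replicates = 10L, seeds = NULL,
                            master_seed = NULL, sweep_param = NULL,
                            sweep_values = NULL,
                            return_populations = FALSE) {
  if (is.null(seeds)) {
    master_seed <- master_seed %||% config$seed %||% 1L
    seeds <- derive_seeds(master_seed, n_replicates)
  }
  if (anyDuplicated(seeds)) {
    abort("replicate seeds must be distinct")
  }
  if (!is.null(sweep_param)) {
    if (is.null(sweep_values) || length(sweep_values) == 0L) {
      abort("`sweep_values` must be supplied with `sweep_param`")
    }
    if (!sweep_param %in% names(unclass(config))) {
      abort(sprintf("unknown sweep parameter `%s`", sweep_param))
    }
  }
  structure(
    list(
      config = config, n_replicates = as.integer(n_replicates),
      seeds = as.integer(seeds), sweep_param = sweep_param,
      sweep_values = sweep_values,
      return_populations = isTRUE(return_populations)
    ),
    class = "experiment_spec"
  )
}

#' Derive distinct child seeds from a master seed
#'
#' One hierarchical seeding scheme feeds every source of randomness:
#' a master seed deterministically yields per-replicate seeds, so adding
#' conditions or reordering runs cannot silently shift random draws.
#'
#' @param master_seed Integer master seed.
#' @param n Number of child seeds.
#' @return Integer vector of `n` distinct seeds.
#' @export
derive_seeds <- function(master_seed, n) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit(
    if (!is.null(old)) assign(".Random.seed", old, globalenv()),
    add = TRUE
  )
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run a replicated experiment
#'
#' Executes one [evolve()] per replicate (and per sweep value), each with
#' its own seed, and collects per-generation records plus per-run
#' summaries.
#'
#' @param spec An [experiment_spec()].
#' @return An `experiment_result`: list with `records` (tibble keyed by
#'   `replicate`, `seed` and the sweep column when present), `summary`
#'   (one row per run, from [glance()]), `runs` (the `holo_evolution`
#'   objects, populations included only when requested) and `spec`.
#' @export
run_experiment <- function(spec) {
  stopifnot(inherits(spec, "experiment_spec"))
  values <- spec$sweep_values %||% list(NULL)
  grid <- tidyr::expand_grid(
    value_index = seq_along(values),
    replicate = seq_len(spec$n_replicates)
  )
  runs <- vector("list", nrow(grid))
  rec_list <- vector("list", nrow(grid))
  sum_list <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    vi <- grid$value_index[r]
    rep_i <- grid$replicate[r]
    cfg <- spec$config
    if (!is.null(spec$sweep_param)) {
      cfg <- do.call(
        update_config,
        c(list(cfg), stats::setNames(
          list(values[[vi]]), spec$sweep_param
        ))
      )
    }
    seed <- spec$seeds[rep_i]
    if (!is.null(spec$sweep_param)) {
      # independent seeds per condition, still derived from the replicate
      seed <- derive_seeds(spec$seeds[rep_i], length(values))[vi]
    }
    fit <- evolve(cfg,
      seed = seed,
      return_population = spec$return_populations
    )
    key <- tibble::tibble(replicate = rep_i, seed = as.integer(seed))
    if (!is.null(spec$sweep_param)) {
      key[[spec$sweep_param]] <- values[[vi]]
    }
    rec_list[[r]] <- dplyr::bind_cols(key, fit$records)
    sum_list[[r]] <- dplyr::bind_cols(key, glance(fit))
    runs[[r]] <- fit
  }
  structure(
    list(
      records = dplyr::bind_rows(rec_list),
      summary = dplyr::bind_rows(sum_list),
      runs = runs,
      spec = spec
    ),
    class = "experiment_result"
  )
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(
    "<experiment_result> ", length(x$runs), " run(s)",
    if (!is.null(x$spec$sweep_param)) {
      paste0(" sweeping `", x$spec$sweep_param, "`")
    } else {
      ""
    },
    "\n",
    sep = ""
  )
  print(x$summary)
  invisible(x)
}

#' Disconnect microbial networks from a holobiont
#'
#' Severs the regulatory interactions between the selected microbes and the
#' rest of the holobiont, emulating the loss of microbiota (antibiotic
#' removal, culturing symbionts without their host). The default
#' `freeze_zero` mode is an evaluation-time intervention: cross-boundary
#' regulator values are read as 0 while truth tables stay untouched, so the
#' operation is exactly reversible with [reconnect_networks()]. The
#' `excise` mode permanently removes every cross-boundary edge through the
#' input-removal table policy.
#'
#' @param holobiont A `holobiont`.
#' @param microbes Microbe indices (1 = first microbe) to disconnect
#'   (default: all).
#' @param mode `"freeze_zero"` (default) or `"excise"`.
#' @return The modified holobiont.
#' @export
disconnect_networks <- function(holobiont,
                                microbes = seq_len(n_microbes(holobiont)),
                                mode = c("freeze_zero", "excise")) {
  mode <- match.arg(mode)
  holobiont <- as_holobiont(holobiont)
  nn <- length(holobiont$networks)
  if (length(microbes) && (min(microbes) < 1L ||
    max(microbes) > nn - 1L)) {
    abort("`microbes` out of range")
  }
  mask <- holobiont$detached %||% logical(nn)
  mask[microbes + 1L] <- TRUE
  if (mode == "freeze_zero") {
    holobiont$detached <- mask
    return(holobiont)
  }
  out <- restore_fields(cpp_excise(unclass(holobiont), mask), holobiont)
  set_field(out, "detached", NULL)
}

#' Restore connections frozen by [disconnect_networks()]
#'
#' Only meaningful for `freeze_zero` disconnections (excision is
#' irreversible).
#'
#' @param holobiont A `holobiont`.
#' @return The holobiont with all networks re-attached.
#' @export
reconnect_networks <- function(holobiont) {
  set_field(holobiont, "detached", NULL)
}

#' Dysbiosis (disconnection) experiment
#'
#' Coevolves holobiont populations, then disconnects the whole microbiota
#' of each replicate's best individual and re-evaluates host and microbial
#' errors. After successful coevolution the host typically loses its
#' adapted phenotype without its partners, the model's analogue of
#' dysbiosis.
#'
#' @param config An [evolution_config()] with `n_microbes >= 1`.
#' @param n_replicates Number of independent coevolution runs.
#' @param seeds Optional per-replicate seeds (derived from `config$seed`
#'   otherwise).
#' @return Tibble with one row per replicate: errors of the best holobiont
#'   before (`xi_h_pre`, `xi_m_pre`) and after (`xi_h_post`, `xi_m_post`)
#'   disconnection.
#' @export
dysbiosis_experiment <- function(config, n_replicates = 10L, seeds = NULL) {
  if (config$n_microbes < 1L) {
    abort("a dysbiosis experiment needs at least one microbial network")
  }
  seeds <- seeds %||% derive_seeds(config$seed %||% 1L, n_replicates)
  purrr::map_dfr(seq_len(n_replicates), function(i) {
    fit <- evolve(config, seed = seeds[i], return_population = TRUE)
    best <- fit$population[[which.min(fit$final_errors$xi_l)]]
    pre <- evaluate_holobiont(best, fit$task_set, fit$init_conditions,
      mode = config$aggregation, scope = config$evaluation_scope
    )
    cut <- disconnect_networks(best)
    post <- evaluate_holobiont(cut, fit$task_set, fit$init_conditions,
      mode = config$aggregation, scope = config$evaluation_scope
    )
    tibble::tibble(
      replicate = i, seed = as.integer(seeds[i]),
      xi_h_pre = pre$host_total,
      xi_m_pre = mean(pre$microbial_totals),
      xi_h_post = post$host_total,
      xi_m_post = mean(post$microbial_totals)
    )
  })
}

#' Host error under progressive loss of microbial diversity
#'
#' For each `delta_n`, disconnects `reps` uniformly drawn subsets of
#' `delta_n` microbial networks from an adapted holobiont and averages the
#' resulting host error (over tasks and subsets).
#'
#' @param holobiont An adapted `holobiont`.
#' @param task_set,init_conditions The tasks and initial conditions it was
#'   evolved on.
#' @param delta_n Integer vector of subset sizes (default `0..PM`).
#' @param reps Random subsets per `delta_n` (a single evaluation is used
#'   for the deterministic endpoints `delta_n = 0` and `delta_n = PM`).
#' @param mode,scope Passed to [evaluate_holobiont()].
#' @return Tibble with `delta_n`, `xi_h` (mean host error), `sd_xi_h`, `n`.
#' @export
diversity_loss_sweep <- function(holobiont, task_set, init_conditions,
                                 delta_n = 0:n_microbes(holobiont),
                                 reps = 20L, mode = "eq5",
                                 scope = "host_plus_niche") {
  pm <- n_microbes(holobiont)
  if (any(delta_n < 0L) || any(delta_n > pm)) {
    abort("`delta_n` values must lie in [0, PM]")
  }
  purrr::map_dfr(delta_n, function(dn) {
    n_draws <- if (dn == 0L || dn == pm) 1L else reps
    errs <- vapply(seq_len(n_draws), function(i) {
      cut <- if (dn == 0L) {
        holobiont
      } else {
        disconnect_networks(holobiont, sample.int(pm, dn))
      }
      evaluate_holobiont(cut, task_set, init_conditions,
        mode = mode, scope = scope
      )$host_total
    }, numeric(1))
    tibble::tibble(
      delta_n = as.integer(dn), xi_h = mean(errs),
      sd_xi_h = if (n_draws > 1L) sd(errs) else NA_real_,
      n = n_draws
    )
  })
}

#' Adaptation probability versus microbiota size
#'
#' Evolves multitask holobionts for a range of microbiota sizes under the
#' non-specialized or specialized interaction scheme and reports the
#' fraction of adapted hosts at the final recorded generation.
#'
#' @param config Base [evolution_config()] (its `n_tasks`,
#'   `max_generations` and population settings are used).
#' @param pm_values Microbiota sizes to scan (`0` runs the control
#'   multitask baseline, identical in both schemes).
#' @param scheme `"nonspecialized"` or `"specialized"` (specialized uses
#'   `PG = min(PM, T)` niches with tasks split evenly).
#' @param n_replicates Replicates per size.
#' @param seeds Optional per-replicate seeds.
#' @return Tibble with one row per run: `pm`, `replicate`, `seed`, `p_a`
#'   (adaptation probability at the final generation), `first_crossing`,
#'   `final_xi_h`.
#' @export
multitask_adaptation_scan <- function(config, pm_values,
                                      scheme = c(
                                        "nonspecialized",
                                        "specialized"
                                      ),
                                      n_replicates = 5L, seeds = NULL) {
  scheme <- match.arg(scheme)
  seeds <- seeds %||% derive_seeds(config$seed %||% 1L, n_replicates)
  purrr::map_dfr(pm_values, function(pm) {
    cfg <- if (pm == 0L) {
      update_config(config,
        n_microbes = 0L, scheme = "control",
        n_niches = NULL
      )
    } else if (scheme == "specialized") {
      update_config(config,
        n_microbes = as.integer(pm), scheme = "specialized",
        n_niches = min(pm, config$n_tasks)
      )
    } else {
      update_config(config,
        n_microbes = as.integer(pm),
        scheme = "nonspecialized", n_niches = NULL
      )
    }
    purrr::map_dfr(seq_len(n_replicates), function(i) {
      seed <- derive_seeds(seeds[i], max(pm, 1L))[max(pm, 1L)]
      fit <- evolve(cfg, seed = seed, return_population = FALSE)
      tail_row <- fit$records[nrow(fit$records), ]
      tibble::tibble(
        pm = as.integer(pm), replicate = i, seed = as.integer(seed),
        p_a = tail_row$p_a,
        first_crossing = first_crossing(fit, cfg$delta_a),
        final_xi_h = tail_row$xi_h
      )
    })
  })
}
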