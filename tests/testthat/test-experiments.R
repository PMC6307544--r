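# Scenario runners: replicated experiments, disconnection, diversity loss.

test_that("run_experiment produces recomputable records and summaries", {
  spec <- experiment_spec(tiny_config(max_generations = 8L),
    n_replicates = 2L, seeds = c(5L, 6L)
  )
  res <- run_experiment(spec)
  expect_equal(nrow(res$records), 2L * 9L)
  expect_equal(nrow(res$summary), 2L)
  # summaries are recomputable from the stored per-generation tables
  for (i in 1:2) {
    rec_i <- res$records[res$records$replicate == i, ]
    expect_equal(
      res$summary$final_xi_h[i],
      rec_i$xi_h[nrow(rec_i)]
    )
    expect_equal(res$summary$max_p_a[i], max(rec_i$p_a))
  }
  # one replicate, one generation: exactly two record rows (g = 0, 1)
  r1 <- run_experiment(experiment_spec(
    tiny_config(max_generations = 1L),
    n_replicates = 1L, seeds = 9L
  ))
  expect_equal(nrow(r1$records), 2L)
  # same spec, same seeds: identical summaries
  res2 <- run_experiment(spec)
  expect_identical(res$summary, res2$summary)
})

test_that("sweeps rebuild the configuration per value", {
  spec <- experiment_spec(tiny_config(max_generations = 4L),
    n_replicates = 1L, seeds = 3L,
    sweep_param = "gamma", sweep_values = c(1, 10)
  )
  res <- run_experiment(spec)
  expect_setequal(unique(res$records$gamma), c(1, 10))
  cfgs <- lapply(res$runs, function(f) f$config)
  expect_equal(cfgs[[1L]]$mu_microbe, 1 * cfgs[[1L]]$mu_host)
  expect_equal(cfgs[[2L]]$mu_microbe, 10 * cfgs[[2L]]$mu_host)
  expect_error(
    experiment_spec(tiny_config(), sweep_param = "nope", sweep_values = 1),
    "unknown"
  )
})

test_that("disconnection is a null operation without cross edges", {
  set.seed(60)
  h <- new_holobiont(
    build_random_network(8, 2, 3),
    list(build_random_network(8, 2, 3))
  )
  ts <- generate_task_set(1, 1, 3, t_max = 10)
  ic <- generate_initial_conditions(1, 8)
  before <- evaluate_holobiont(h, ts, ic)
  after <- evaluate_holobiont(disconnect_networks(h), ts, ic)
  expect_equal(before$host_total, after$host_total)
  expect_equal(before$microbial_totals, after$microbial_totals)
})

test_that("freeze_zero disconnection is exactly reversible", {
  set.seed(61)
  h <- random_small_holobiont(n_networks = 3L, nodes_per_net = 5L,
    n_signal = 2L, cross_prob = 0.5)
  ts <- generate_task_set(2, 2, 3, t_max = 10)
  ic <- generate_initial_conditions(2, 5)
  before <- evaluate_holobiont(h, ts, ic)
  cut <- disconnect_networks(h, microbes = 1L)
  restored <- evaluate_holobiont(reconnect_networks(cut), ts, ic)
  expect_identical(before, restored)
})

test_that("freeze_zero and excise disconnection agree dynamically", {
  # build a holobiont where each node keeps at least one within-network
  # regulator: excising cross edges (keeping the regulator = 0 table half)
  # is then exactly the freeze_zero dynamics, since no node drops to the
  # regulator-free frozen case
  set.seed(62)
  host <- build_random_network(5, 2, 2)
  mics <- list(build_random_network(5, 2, 2), build_random_network(5, 2, 2))
  h <- new_holobiont(host, mics)
  for (i in 1:3) {
    for (n in 1:5) {
      if (runif(1) < 0.5) {
        h$networks[[i]]$nodes[[n]]$reg_net[1L] <- sample(1:3, 1L)
      }
    }
  }
  ts <- generate_task_set(1, 2, 3, t_max = 12)
  ic <- generate_initial_conditions(1, 5)
  froz <- evaluate_holobiont(disconnect_networks(h, 1:2), ts, ic)
  exc_h <- disconnect_networks(h, 1:2, mode = "excise")
  exc <- evaluate_holobiont(exc_h, ts, ic)
  expect_equal(froz$host_per_task, exc$host_per_task)
  expect_equal(froz$microbial_per_task, exc$microbial_per_task)
  # excision really removes the cross edges
  edges <- network_edges(exc_h)
  expect_equal(sum(edges$src_network != edges$dst_network), 0L)
})

test_that("disconnecting a never-connected microbe changes nothing", {
  set.seed(63)
  host <- build_random_network(8, 2, 3)
  m1 <- build_random_network(8, 2, 3)
  m2 <- build_random_network(8, 2, 3)
  h <- new_holobiont(host, list(m1, m2))
  # wire host <-> microbe 1 only, by hand
  h$networks[[1L]]$nodes[[1L]]$reg_net[1L] <- 2L
  h$networks[[1L]]$nodes[[1L]]$reg_node[1L] <- 4L
  ts <- generate_task_set(1, 2, 3, t_max = 10)
  ic <- generate_initial_conditions(1, 8)
  base <- evaluate_holobiont(h, ts, ic)
  cut2 <- evaluate_holobiont(disconnect_networks(h, microbes = 2L), ts, ic)
  expect_equal(base$host_total, cut2$host_total)
  expect_equal(base$microbial_per_task, cut2$microbial_per_task)
})

test_that("diversity loss sweep endpoints are consistent", {
  set.seed(64)
  h <- random_small_holobiont(n_networks = 4L, nodes_per_net = 4L,
    n_signal = 2L, cross_prob = 0.5)
  ts <- generate_task_set(2, 3, 3, t_max = 8)
  ic <- generate_initial_conditions(2, 4)
  sweep <- diversity_loss_sweep(h, ts, ic, delta_n = c(0L, 3L), reps = 3L)
  base <- evaluate_holobiont(h, ts, ic)$host_total
  full <- evaluate_holobiont(disconnect_networks(h), ts, ic)$host_total
  expect_equal(sweep$xi_h[sweep$delta_n == 0L], base)
  expect_equal(sweep$xi_h[sweep$delta_n == 3L], full)
  expect_error(diversity_loss_sweep(h, ts, ic, delta_n = 5L), "delta_n")
})

test_that("one-niche specialization equals non-specialized wiring", {
  # with a single niche holding every microbe and task, the specialized
  # wiring constraint collapses onto the non-specialized rule: identical
  # trajectories under a shared seed
  host <- withr::with_seed(65, build_random_network(10, 2, 3))
  mics <- withr::with_seed(66, lapply(1:2, function(i) {
    build_random_network(10, 2, 3)
  }))
  ts <- withr::with_seed(67, generate_task_set(2, 2, 3))
  ic <- withr::with_seed(68, generate_initial_conditions(2, 10))
  cfg_spec <- evolution_config(
    n_nodes = 10, n_signal = 3, pop_size = 10, n_survivors = 2,
    copies_per_survivor = 4, n_microbes = 2, n_tasks = 2,
    scheme = "specialized", n_niches = 1, aggregation = "eq4",
    max_generations = 10
  )
  cfg_flat <- update_config(cfg_spec,
    scheme = "nonspecialized",
    n_niches = NULL
  )
  fit_spec <- evolve(cfg_spec,
    task_set = ts, init_conditions = ic,
    microbes = mics, host = host, seed = 69
  )
  fit_flat <- evolve(cfg_flat,
    task_set = ts, init_conditions = ic,
    microbes = mics, host = host, seed = 69
  )
  expect_equal(fit_spec$records$xi_h, fit_flat$records$xi_h)
  expect_equal(fit_spec$records$xi_l, fit_flat$records$xi_l)
})

test_that("multitask scan covers the control baseline at PM = 0", {
  cfg <- tiny_config(n_tasks = 2L, max_generations = 5L)
  scan <- multitask_adaptation_scan(cfg,
    pm_values = c(0L, 1L),
    scheme = "specialized", n_replicates = 1L, seeds = 70L
  )
  expect_equal(nrow(scan), 2L)
  expect_true(all(scan$p_a >= 0 & scan$p_a <= 1))
})
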