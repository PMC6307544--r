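# Target functions, initial conditions, niches and every error functional.

test_that("target functions respect the strict bounds", {
  set.seed(1)
  tf <- generate_target_function(12, 15)
  expect_length(tf, 15L)
  expect_true(all(tf >= 1L & tf <= 11L))
  # Ns = 2 leaves a single admissible value
  expect_equal(as.integer(generate_target_function(2, 10)), rep(1L, 10L))
  expect_error(generate_target_function(1, 10), "n_signal")
})

test_that("task sets are pairwise distinct", {
  set.seed(2)
  ts <- generate_task_set(n_tasks = 5, n_microbes = 5, n_signal = 4,
    t_max = 8)
  keys <- vapply(c(ts$host, ts$microbial), function(tf) {
    paste(as.integer(tf), collapse = ",")
  }, character(1))
  expect_false(anyDuplicated(keys) > 0L)
  # independent draws at realistic sizes essentially never collide
  set.seed(3)
  pairs <- replicate(2000, {
    a <- paste(as.integer(generate_target_function(12, 15)), collapse = ",")
    b <- paste(as.integer(generate_target_function(12, 15)), collapse = ",")
    a == b
  })
  expect_false(any(pairs))
})

test_that("adaptation error is the time-averaged squared deviation", {
  tf <- generate_target_function(12, 15)
  expect_equal(adaptation_error(as.integer(tf), tf), 0)
  # one-unit deviation at every step sits exactly at the threshold
  expect_equal(adaptation_error(as.integer(tf) + 1L, tf), 1)
  expect_true(is_well_adapted(adaptation_error(as.integer(tf) + 1L, tf)))
  # a single deviation of 2 contributes 4/tm
  r <- as.integer(tf)
  r[7L] <- r[7L] + 2L
  expect_equal(adaptation_error(r, tf), 4 / 15)
  expect_error(adaptation_error(1:10, tf), "length")
})

test_that("holobiont error arithmetic matches both aggregation modes", {
  expect_equal(holobiont_error(2, 0.5, mode = "eq4"), 1.25)
  expect_equal(holobiont_error(0.4, c(0.1, 0.3), mode = "eq5"), 0.3)
  expect_equal(holobiont_error(3.3, numeric(0), mode = "eq4"), 3.3)
  expect_equal(holobiont_error(3.3, numeric(0), mode = "eq5"), 3.3)
  # the modes coincide for a single microbe...
  for (i in 1:20) {
    hh <- runif(1, 0, 10)
    mm <- runif(1, 0, 10)
    expect_equal(
      holobiont_error(hh, mm, "eq4"),
      holobiont_error(hh, mm, "eq5")
    )
  }
  # ...and only the size-independent mode is invariant under duplicating
  # the whole microbiota
  m <- runif(3, 0, 5)
  expect_equal(
    holobiont_error(1, c(m, m), "eq5"),
    holobiont_error(1, m, "eq5")
  )
  expect_false(isTRUE(all.equal(
    holobiont_error(1, c(m, m), "eq4"),
    holobiont_error(1, m, "eq4")
  )))
})

test_that("niche error reproduces hand-evaluated cases", {
  # one microbe, one task: plain two-network average
  expect_equal(niche_error(0.4, 0.6), 0.5)
  expect_equal(niche_error(c(0, 0), matrix(0, 2, 2)), 0)
  # two microbes, two tasks, hand evaluation
  m <- rbind(c(0.2, 0.4), c(0.6, 0.8))
  expect_equal(niche_error(c(0.8, 1.2), m), (1.0 + 0.3 + 0.7) / 3)
  expect_error(niche_error(numeric(0), m), "task")
})

test_that("adaptation threshold comparison is inclusive", {
  expect_true(is_well_adapted(1.0, 1.0))
  expect_true(is_well_adapted(0, 0))
  expect_false(is_well_adapted(1.0001, 1.0))
})

test_that("evaluate_holobiont totals equal independently recomputed ones", {
  set.seed(42)
  host <- build_random_network(10, 2, 4)
  mics <- list(build_random_network(8, 2, 3), build_random_network(8, 2, 3))
  h <- new_holobiont(host, mics)
  ts <- generate_task_set(3, 2, 4, t_max = 12)
  ic <- generate_initial_conditions(3, 10)
  rep_ <- evaluate_holobiont(h, ts, ic, mode = "eq5")
  # recompute every per-task error from raw trajectories via the R oracle
  for (tau in 1:3) {
    state0 <- c(list(ic[tau, ]), lapply(h$networks[-1L], `[[`, "init"))
    orc <- oracle_trajectory(h, state0, 12)
    r_host <- vapply(2:13, function(t) {
      sum(orc[[t]][[1L]][host$signal])
    }, numeric(1))
    expect_equal(
      rep_$host_per_task[tau],
      adaptation_error(r_host, ts$host[[tau]])
    )
    for (j in 1:2) {
      r_mic <- vapply(2:13, function(t) {
        sum(orc[[t]][[j + 1L]][h$networks[[j + 1L]]$signal])
      }, numeric(1))
      expect_equal(
        rep_$microbial_per_task[j, tau],
        adaptation_error(r_mic, ts$microbial[[j]])
      )
    }
  }
  expect_equal(rep_$host_total, mean(rep_$host_per_task))
  expect_equal(rep_$microbial_totals, rowMeans(rep_$microbial_per_task))
  expect_equal(
    rep_$holobiont_error,
    holobiont_error(rep_$host_total, rep_$microbial_totals, "eq5")
  )
  # with no cross edges, microbial errors are independent of the host task
  expect_equal(rep_$microbial_per_task[, 1L], rep_$microbial_per_task[, 2L])
})

test_that("specialized evaluation follows the niche error definition", {
  set.seed(43)
  host <- build_random_network(10, 2, 4)
  mics <- lapply(1:3, function(i) build_random_network(8, 2, 3))
  part <- make_niche_partition(3, 4, 2)
  h <- new_holobiont(host, mics, part)
  ts <- generate_task_set(4, 3, 4, t_max = 10)
  ic <- generate_initial_conditions(4, 10)
  rep_ <- evaluate_holobiont(h, ts, ic, scope = "full")
  expect_length(rep_$niche_errors, 2L)
  for (g in 1:2) {
    tasks <- part$task_assignment[[g]]
    mics_g <- which(part$niche == g)
    expect_equal(
      rep_$niche_errors[g],
      niche_error(
        rep_$host_per_task[tasks],
        rep_$microbial_per_task[mics_g, tasks, drop = FALSE]
      )
    )
  }
  expect_equal(rep_$holobiont_error, mean(rep_$niche_errors))
})

test_that("one niche covering all tasks matches non-specialized eq4", {
  set.seed(44)
  host <- build_random_network(10, 2, 4)
  mics <- lapply(1:2, function(i) build_random_network(8, 2, 3))
  ts <- generate_task_set(3, 2, 4, t_max = 10)
  ic <- generate_initial_conditions(3, 10)
  h_spec <- new_holobiont(host, mics, make_niche_partition(2, 3, 1))
  h_flat <- new_holobiont(host, mics)
  spec <- evaluate_holobiont(h_spec, ts, ic, scope = "full")
  flat <- evaluate_holobiont(h_flat, ts, ic, mode = "eq4")
  expect_equal(spec$holobiont_error, flat$holobiont_error)
})

test_that("niche partitions deal microbes and tasks as evenly as possible", {
  p <- make_niche_partition(25, 10, 10)
  expect_equal(sort(unique(p$niche)), 1:10)
  expect_true(all(table(p$niche) %in% 2:3))
  expect_equal(sort(unlist(p$task_assignment)), 1:10)
  expect_true(all(lengths(p$task_assignment) == 1L))
  p2 <- make_niche_partition(4, 10, 3)
  expect_true(all(lengths(p2$task_assignment) %in% 3:4))
  expect_error(make_niche_partition(2, 10, 5), "n_niches")
})

test_that("error bounds hold across random evaluations", {
  set.seed(45)
  for (i in 1:30) {
    h <- random_small_holobiont(n_networks = 2L, nodes_per_net = 4L)
    ts <- generate_task_set(2, 1, 3, t_max = 8)
    ic <- generate_initial_conditions(2, 4)
    rep_ <- evaluate_holobiont(h, ts, ic)
    errs <- c(
      rep_$host_per_task, rep_$microbial_per_task,
      rep_$holobiont_error
    )
    expect_true(all(errs >= 0))
    expect_true(all(rep_$host_per_task <= 2^2)) # |R - F| < Ns pointwise
  }
})
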