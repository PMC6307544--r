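# Mutation sampling, the four operators, wiring constraints and genotype
# invariants.

test_that("zero rates produce no events and rates match the binomial mean", {
  set.seed(10)
  h <- new_holobiont(
    build_random_network(50, 2, 12),
    list(build_random_network(50, 2, 12))
  )
  for (i in 1:5) {
    expect_equal(nrow(sample_mutations(h, 0, 0)), 0L)
  }
  # empirical mean of mutated host nodes vs mu * N over many draws
  n_draws <- 20000L
  counts <- vapply(seq_len(n_draws), function(i) {
    ev <- sample_mutations(h, 0.001, 0)
    nrow(ev)
  }, integer(1))
  expected <- 0.001 * 50
  se <- sqrt(expected / n_draws) # Poisson-scale standard error
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("operator classes are drawn with equal probability", {
  set.seed(12)
  h <- as_holobiont(build_random_network(30, 2, 5))
  ev <- dplyr::bind_rows(lapply(1:400, function(i) {
    sample_mutations(h, 0.8, 0)
  }))
  expect_gt(nrow(ev), 8000L)
  freq <- table(ev$kind) / nrow(ev)
  expect_equal(length(freq), 4L)
  expect_true(all(abs(freq - 0.25) < 0.02))
  dirs <- table(ev$direction[ev$kind == "rewire"])
  expect_true(all(abs(dirs / sum(dirs) - 0.5) < 0.03))
  expect_true(all(is.na(ev$direction[ev$kind == "flip_table_entry"])))
})

test_that("connection partners follow the wiring scheme", {
  set.seed(13)
  host <- build_random_network(6, 2, 2)
  mics <- lapply(1:4, function(i) build_random_network(6, 2, 2))
  # non-specialized: host reaches itself or the microbe with equal odds
  h1 <- new_holobiont(host, mics[1L])
  draws <- vapply(1:8000, function(i) {
    sample_connection_partner(h1, 1L)
  }, integer(1))
  expect_true(abs(mean(draws == 1L) - 0.5) < 0.02)
  # specialized: a microbe in niche 2 never reaches niche 1
  part <- make_niche_partition(4, 4, 2) # niches (1,2,1,2)
  h2 <- new_holobiont(host, mics, part)
  src <- which(part$niche == 2L)[1L] + 1L
  allowed <- c(1L, which(part$niche == 2L) + 1L)
  draws2 <- vapply(1:8000, function(i) {
    sample_connection_partner(h2, src)
  }, integer(1))
  expect_true(all(draws2 %in% allowed))
  expect_true(all(table(draws2) > 0L))
  # no microbes: always the host
  h0 <- as_holobiont(host)
  expect_true(all(vapply(1:50, function(i) {
    sample_connection_partner(h0, 1L)
  }, integer(1)) == 1L))
})

test_that("add_connection doubles the table preserving the old half", {
  set.seed(14)
  net <- build_random_network(6, 2, 2)
  h <- as_holobiont(net)
  ev <- tibble::tibble(
    network = 1L, node = 3L, kind = "add_connection",
    direction = "in"
  )
  h2 <- apply_mutations(h, ev)
  expect_true(attr(h2, "applied"))
  nd_old <- h$networks[[1L]]$nodes[[3L]]
  nd_new <- h2$networks[[1L]]$nodes[[3L]]
  expect_length(nd_new$reg_node, 3L)
  expect_length(nd_new$table, 8L)
  # new regulator is the most significant bit: its 0-half is the old table
  expect_equal(nd_new$table[1:4], nd_old$table)
  expect_equal(nd_new$reg_node[-1L], nd_old$reg_node)
  expect_equal(h2$networks[[1L]]$mutation_count, 1)
})

test_that("remove then re-add leaves the removed-regulator-0 restriction", {
  # k = 1 identity node: removing its regulator keeps the regulator = 0
  # half, i.e. a constant-0 node
  net <- build_random_network(4, 1, 2)
  net$nodes[[2L]]$reg_node <- 3L
  net$nodes[[2L]]$table <- c(0L, 1L) # identity
  h <- as_holobiont(net)
  ev <- tibble::tibble(
    network = 1L, node = 2L, kind = "remove_connection",
    direction = "in"
  )
  h2 <- apply_mutations(h, ev)
  nd <- h2$networks[[1L]]$nodes[[2L]]
  expect_length(nd$reg_node, 0L)
  expect_equal(nd$table, 0L)
})

test_that("flip_table_entry is an involution at a fixed entry", {
  set.seed(15)
  net <- build_random_network(5, 2, 2)
  h <- as_holobiont(net)
  ev <- tibble::tibble(
    network = 1L, node = 1L, kind = "flip_table_entry",
    direction = NA_character_
  )
  h1 <- apply_mutations(h, ev)
  changed <- which(h1$networks[[1L]]$nodes[[1L]]$table !=
    h$networks[[1L]]$nodes[[1L]]$table)
  expect_length(changed, 1L)
  # flipping until the same entry is hit again restores the table
  tbl <- h1$networks[[1L]]$nodes[[1L]]$table
  tbl[changed] <- 1L - tbl[changed]
  expect_equal(tbl, h$networks[[1L]]$nodes[[1L]]$table)
})

test_that("impossible events are no-ops and do not count as mutations", {
  net <- build_random_network(4, 0, 2) # no edges at all
  h <- as_holobiont(net)
  evs <- tibble::tibble(
    network = 1L, node = 2L,
    kind = c("remove_connection", "rewire", "rewire"),
    direction = c("in", "in", "out")
  )
  h2 <- apply_mutations(h, evs)
  expect_equal(as.logical(attr(h2, "applied")), c(FALSE, FALSE, FALSE))
  expect_equal(h2$networks[[1L]]$mutation_count, 0)
  # the in-degree cap turns add proposals into no-ops
  net2 <- build_random_network(6, 2, 2)
  h3 <- as_holobiont(net2)
  ev <- tibble::tibble(
    network = 1L, node = 1L, kind = "add_connection",
    direction = "in"
  )
  for (i in 1:10) h3 <- apply_mutations(h3, ev, k_max = 3L)
  expect_length(h3$networks[[1L]]$nodes[[1L]]$reg_node, 3L)
  expect_lt(h3$networks[[1L]]$mutation_count, 10)
})

test_that("rewire conserves the global edge count", {
  set.seed(16)
  h <- new_holobiont(
    build_random_network(8, 2, 2),
    list(build_random_network(8, 2, 2))
  )
  n_edges <- nrow(network_edges(h))
  for (i in 1:40) {
    ev <- tibble::tibble(
      network = sample(1:2, 1L), node = sample(1:8, 1L),
      kind = "rewire", direction = sample(c("in", "out"), 1L)
    )
    h <- apply_mutations(h, ev)
    expect_equal(nrow(network_edges(h)), n_edges)
  }
})

test_that("genotype invariants survive 10^4 random mutation events", {
  set.seed(17)
  part <- make_niche_partition(3, 3, 3)
  h <- new_holobiont(
    build_random_network(10, 2, 3),
    lapply(1:3, function(i) build_random_network(10, 2, 3)),
    part
  )
  applied_total <- 0
  for (batch in 1:100) {
    ev <- sample_mutations(h, 0.25, 0.25)
    if (nrow(ev) == 0L) next
    h <- apply_mutations(h, ev)
    applied_total <- applied_total + sum(attr(h, "applied"))
  }
  expect_gt(applied_total, 500)
  expect_valid_holobiont(h)
  # mutation counters equal the number of applied events
  expect_equal(
    sum(vapply(h$networks, `[[`, numeric(1), "mutation_count")),
    applied_total
  )
  # the specialized wiring constraint is never violated
  edges <- network_edges(h)
  cross <- edges[edges$src_network != edges$dst_network &
    edges$src_network != 1L & edges$dst_network != 1L, ]
  if (nrow(cross) > 0L) {
    expect_true(all(
      part$niche[cross$src_network - 1L] ==
        part$niche[cross$dst_network - 1L]
    ))
  }
})

test_that("microbial-to-host applied-event ratio tracks the rate ratio", {
  set.seed(18)
  h <- new_holobiont(
    build_random_network(20, 2, 4),
    list(build_random_network(20, 2, 4))
  )
  counts <- c(host = 0, microbe = 0)
  for (i in 1:4000) {
    ev <- sample_mutations(h, 0.01, 0.1)
    if (nrow(ev) == 0L) next
    h2 <- apply_mutations(h, ev)
    ap <- attr(h2, "applied")
    counts["host"] <- counts["host"] + sum(ap[ev$network == 1L])
    counts["microbe"] <- counts["microbe"] + sum(ap[ev$network == 2L])
  }
  ratio <- counts["microbe"] / counts["host"]
  expect_gt(ratio, 10 * 0.8)
  expect_lt(ratio, 10 * 1.2)
})
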