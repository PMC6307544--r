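# Boolean network genotypes and holobiont composites.
#
# A network is a list of nodes; each node carries an ordered regulator list
# (pairs of network index + node index, both 1-based) and a truth table of
# length 2^k indexed with the first-listed regulator as the most significant
# bit.  A holobiont bundles one host network (position 1) with PM microbial
# networks (positions 2..PM+1); regulator references are absolute positions
# within the holobiont, which lets edges cross network boundaries.

#' Build a random Boolean (Kauffman) network
#'
#' Constructs a random network in which every node has exactly `in_degree`
#' distinct regulators drawn uniformly from the network's own nodes
#' (self-loops permitted, duplicate edges not), a truth table drawn uniformly
#' from all Boolean functions of its regulators, a uniform-random initial
#' condition, and `n_signal` distinct signal nodes whose summed activity
#' defines the network's output signal.
#'
#' @param n_nodes Number of nodes `N`.
#' @param in_degree Number of regulators per node `K` (default 2, the
#'   critical connectivity for random Boolean networks).
#' @param n_signal Number of signal nodes `Ns`.
#' @return A `bn_network` object.
#' @examples
#' net <- build_random_network(12, in_degree = 2, n_signal = 4)
#' lengths(lapply(net$nodes, `[[`, "table"))  # all 2^2 = 4
#' @export
build_random_network <- function(n_nodes, in_degree = 2, n_signal) {
  if (n_signal > n_nodes) {
    abort("`n_signal` must not exceed `n_nodes`.")
  }
  if (in_degree < 0 || in_degree >= n_nodes) {
    abort("`in_degree` must be in [0, n_nodes): regulators are distinct.")
  }
  nodes <- lapply(seq_len(n_nodes), function(i) {
    regs <- sample.int(n_nodes, in_degree)
    list(
      reg_net = rep(1L, in_degree),
      reg_node = as.integer(regs),
      table = sample(0:1, 2L^in_degree, replace = TRUE)
    )
  })
  structure(
    list(
      nodes = nodes,
      signal = sort(sample.int(n_nodes, n_signal)),
      init = sample(0:1, n_nodes, replace = TRUE),
      mutation_count = 0
    ),
    class = "bn_network"
  )
}

#' Assemble a holobiont from standalone networks
#'
#' The host occupies position 1 and microbes positions `2..PM+1`. Each input
#' network must be standalone (all its regulator references pointing to
#' itself, i.e. network index 1); microbe self-references are remapped to the
#' microbe's position in the holobiont.
#'
#' @param host A `bn_network`, the host.
#' @param microbes List of `bn_network` objects, the microbiota (may be
#'   empty).
#' @param niche_partition Optional niche partition created by
#'   [make_niche_partition()]; required for the specialized interaction
#'   scheme.
#' @return A `holobiont` object.
#' @export
new_holobiont <- function(host, microbes = list(), niche_partition = NULL) {
  stopifnot(inherits(host, "bn_network"))
  nets <- c(list(host), microbes)
  for (i in seq_along(nets)) {
    refs <- unlist(lapply(nets[[i]]$nodes, `[[`, "reg_net"))
    if (length(refs) && !all(refs == 1L)) {
      abort(paste0(
        "network ", i, " is not standalone (has cross-network references); ",
        "holobionts must be assembled from standalone parts"
      ))
    }
    if (i > 1L) {
      nets[[i]]$nodes <- lapply(nets[[i]]$nodes, function(nd) {
        nd$reg_net <- rep(as.integer(i), length(nd$reg_net))
        nd
      })
    }
  }
  niche <- NULL
  task_assignment <- NULL
  if (!is.null(niche_partition)) {
    if (niche_partition$n_microbes != length(microbes)) {
      abort("niche partition does not match the number of microbes")
    }
    niche <- niche_partition$niche
    task_assignment <- niche_partition$task_assignment
  }
  structure(
    list(
      networks = nets,
      niche = niche,
      task_assignment = task_assignment,
      detached = NULL
    ),
    class = "holobiont"
  )
}

#' @export
print.bn_network <- function(x, ...) {
  ks <- vapply(x$nodes, function(nd) length(nd$reg_node), integer(1))
  cat(
    "<bn_network> ", length(x$nodes), " nodes, ",
    length(x$signal), " signal nodes, mean in-degree ",
    format(mean(ks), digits = 3), ", ", x$mutation_count,
    " accumulated mutations\n",
    sep = ""
  )
  invisible(x)
}

#' @export
print.holobiont <- function(x, ...) {
  cat(
    "<holobiont> host + ", length(x$networks) - 1L, " microbial network(s)",
    if (!is.null(x$niche)) {
      paste0(", ", max(x$niche), " niche(s)")
    } else {
      ""
    },
    if (!is.null(x$detached) && any(x$detached)) {
      paste0(", ", sum(x$detached), " network(s) detached")
    } else {
      ""
    },
    "\n",
    sep = ""
  )
  invisible(x)
}

#' Coerce to a holobiont
#'
#' A standalone network becomes a holobiont with no microbiota, so the same
#' dynamics entry points apply to both.
#'
#' @param x A `bn_network` or `holobiont`.
#' @return A `holobiont`.
#' @export
as_holobiont <- function(x) {
  if (inherits(x, "holobiont")) {
    return(x)
  }
  new_holobiont(x)
}

#' Number of microbial networks in a holobiont
#' @param holobiont A `holobiont`.
#' @return Integer count `PM`.
#' @export
n_microbes <- function(holobiont) {
  length(holobiont$networks) - 1L
}

detached_mask <- function(holobiont) {
  holobiont$detached %||% logical(0)
}

# Assign a possibly-NULL holobiont field without dropping the element, so
# object shapes stay identical across construction, evolution and
# serialization round-trips.
set_field <- function(h, name, value) {
  h[name] <- list(value)
  h
}

# Preserve R-side-only fields when a holobiont has round-tripped through the
# compiled core (which carries networks + niche only).
restore_fields <- function(new, old) {
  new <- set_field(new, "task_assignment", old$task_assignment)
  set_field(new, "detached", old$detached)
}

#' One synchronous update of a holobiont
#'
#' Every node's next value is its truth table evaluated on the current values
#' of its regulators; the update is simultaneous across all networks. Nodes
#' with no regulators keep their current value. Networks marked as detached
#' (see [disconnect_networks()]) have their cross-boundary regulator values
#' read as 0.
#'
#' @param holobiont A `holobiont` (or `bn_network`).
#' @param state List with one 0/1 integer vector per network (a single
#'   vector is accepted for a lone network).
#' @return The next global state, in the same shape.
#' @export
synchronous_step <- function(holobiont, state) {
  holobiont <- as_holobiont(holobiont)
  if (!is.list(state)) state <- list(state)
  state <- lapply(state, as.integer)
  cpp_step(unclass(holobiont), state, detached_mask(holobiont))
}

#' Run a deterministic trajectory of a holobiont
#'
#' The global initial state is the host's initial condition for the selected
#' task concatenated with each microbe's own fixed initial condition; the
#' system is then iterated for `t_max` synchronous steps.
#'
#' @param holobiont A `holobiont` (or `bn_network`).
#' @param t_max Number of time steps (the trajectory covers `t = 0..t_max`).
#' @param task_index Which host task's initial condition to use.
#' @param init_conditions Optional matrix of host initial conditions (one row
#'   per task, see [generate_initial_conditions()]); defaults to the host's
#'   own stored initial condition.
#' @return A `holo_trajectory`: list of (t_max+1) x N 0/1 matrices, one per
#'   network, with rows `t = 0..t_max`.
#' @export
run_trajectory <- function(holobiont, t_max, task_index = 1L,
                           init_conditions = NULL) {
  holobiont <- as_holobiont(holobiont)
  host_init <- if (is.null(init_conditions)) {
    holobiont$networks[[1L]]$init
  } else {
    if (task_index < 1L || task_index > nrow(init_conditions)) {
      abort("`task_index` out of range for the supplied initial conditions")
    }
    init_conditions[task_index, ]
  }
  states <- cpp_run_trajectory(
    unclass(holobiont), as.integer(host_init),
    as.integer(t_max), detached_mask(holobiont)
  )
  structure(list(states = states, t_max = t_max), class = "holo_trajectory")
}

#' Output signal of a network along a trajectory
#'
#' Sums the states of the network's signal nodes at each time step
#' `t = 1..t_max` (the initial state at `t = 0` is not part of the evaluated
#' signal).
#'
#' @param holobiont The `holobiont` (or `bn_network`) the trajectory was run
#'   on.
#' @param trajectory A `holo_trajectory` from [run_trajectory()].
#' @param network Position of the network in the holobiont (1 = host).
#' @return Integer vector `R(t)` for `t = 1..t_max`, bounded by `[0, Ns]`.
#' @export
output_signal <- function(holobiont, trajectory, network = 1L) {
  holobiont <- as_holobiont(holobiont)
  sig <- holobiont$networks[[network]]$signal
  m <- trajectory$states[[network]]
  if (trajectory$t_max == 0L) {
    return(integer(0))
  }
  as.integer(rowSums(m[-1L, sig, drop = FALSE]))
}

#' @export
as_tibble.holo_trajectory <- function(x, ...) {
  purrr::imap_dfr(x$states, function(m, i) {
    tibble::tibble(
      network = as.integer(i),
      t = rep(0:(nrow(m) - 1L), ncol(m)),
      node = rep(seq_len(ncol(m)), each = nrow(m)),
      state = as.integer(m)
    )
  })
}

#' Wiring of a holobiont as a tidy edge list
#'
#' @param holobiont A `holobiont` (or `bn_network`).
#' @return A tibble with one row per regulatory edge: `src_network`,
#'   `src_node`, `dst_network`, `dst_node`. Suitable for export as TSV and
#'   inspection with standard graph tools.
#' @export
network_edges <- function(holobiont) {
  holobiont <- as_holobiont(holobiont)
  purrr::imap_dfr(holobiont$networks, function(nw, i) {
    purrr::imap_dfr(nw$nodes, function(nd, n) {
      tibble::tibble(
        src_network = as.integer(nd$reg_net),
        src_node = as.integer(nd$reg_node),
        dst_network = as.integer(i),
        dst_node = as.integer(n)
      )
    })
  })
}
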