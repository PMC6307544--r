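# Independent pure-R reference implementations used as oracles against the
# package's compiled dynamics, plus small fixture builders.  These are kept
# deliberately naive (explicit loops, full state enumeration) and share no
# code with the package internals.

# One synchronous update computed directly from the definitions.
oracle_step <- function(holobiont, state) {
  nets <- holobiont$networks
  lapply(seq_along(nets), function(i) {
    vapply(seq_along(nets[[i]]$nodes), function(n) {
      nd <- nets[[i]]$nodes[[n]]
      k <- length(nd$reg_node)
      if (k == 0L) {
        return(as.integer(state[[i]][n]))
      }
      bits <- vapply(seq_len(k), function(j) {
        state[[nd$reg_net[j]]][nd$reg_node[j]]
      }, numeric(1))
      idx <- sum(bits * 2^((k - 1):0)) # first regulator = MSB
      as.integer(nd$table[idx + 1L])
    }, integer(1))
  })
}

oracle_trajectory <- function(holobiont, state0, t_max) {
  states <- vector("list", t_max + 1L)
  states[[1L]] <- lapply(state0, as.integer)
  for (t in seq_len(t_max)) {
    states[[t + 1L]] <- oracle_step(holobiont, states[[t]])
  }
  states
}

# Full 2^n state-transition table for systems with few total nodes.
# Global states are encoded as integers over the concatenated node vector.
oracle_transition_table <- function(holobiont) {
  sizes <- vapply(holobiont$networks, function(nw) length(nw$nodes),
    integer(1)
  )
  n <- sum(sizes)
  stopifnot(n <= 14L)
  decode <- function(code) {
    bits <- as.integer(intToBits(code))[seq_len(n)]
    split(bits, rep(seq_along(sizes), sizes))
  }
  encode <- function(state) {
    sum(unlist(state) * 2^(seq_len(n) - 1L))
  }
  vapply(0:(2^n - 1L), function(code) {
    encode(oracle_step(holobiont, decode(code)))
  }, numeric(1))
}

encode_state <- function(state) {
  bits <- unlist(state)
  sum(bits * 2^(seq_along(bits) - 1L))
}

# A random small holobiont with genuinely cross-network wiring, built by
# direct list manipulation (independent of the mutation operators).
random_small_holobiont <- function(n_networks = 2L, nodes_per_net = 4L,
                                   n_signal = 2L, cross_prob = 0.3) {
  nets <- lapply(seq_len(n_networks), function(i) {
    build_random_network(nodes_per_net, in_degree = 2L, n_signal = n_signal)
  })
  h <- new_holobiont(nets[[1L]], nets[-1L])
  for (i in seq_len(n_networks)) {
    for (n in seq_len(nodes_per_net)) {
      nd <- h$networks[[i]]$nodes[[n]]
      for (j in seq_along(nd$reg_net)) {
        if (runif(1) < cross_prob) {
          tgt <- sample.int(n_networks, 1L)
          cand <- sample.int(nodes_per_net, 1L)
          dup <- any(nd$reg_net == tgt & nd$reg_node == cand)
          if (!dup) {
            nd$reg_net[j] <- tgt
            nd$reg_node[j] <- cand
          }
        }
      }
      h$networks[[i]]$nodes[[n]] <- nd
    }
  }
  h
}

random_state <- function(holobiont) {
  lapply(holobiont$networks, function(nw) {
    sample(0:1, length(nw$nodes), replace = TRUE)
  })
}

# Truth-table/regulator invariants that must hold after every operation.
expect_valid_holobiont <- function(h) {
  nn <- length(h$networks)
  for (i in seq_len(nn)) {
    for (nd in h$networks[[i]]$nodes) {
      k <- length(nd$reg_node)
      expect_length(nd$reg_net, k)
      expect_length(nd$table, 2L^k)
      expect_true(all(nd$table %in% 0:1))
      expect_true(all(nd$reg_net >= 1L & nd$reg_net <= nn))
      if (k > 1L) {
        expect_false(anyDuplicated(paste(nd$reg_net, nd$reg_node)) > 0L)
      }
    }
  }
  invisible(TRUE)
}

# A tiny configuration that evolves in well under a second.
tiny_config <- function(...) {
  defaults <- list(
    n_nodes = 16L, n_signal = 4L, pop_size = 20L,
    n_survivors = 4L, copies_per_survivor = 4L,
    max_generations = 20L
  )
  do.call(evolution_config, utils::modifyList(defaults, list(...)))
}
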