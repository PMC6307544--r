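# Mutation operators on holobiont genotypes.
#
# Four operator classes, drawn with equal probability for each mutated node:
# rewire one input/output connection (degree-conserving move of one edge
# endpoint), add a new input/output connection, remove one input/output
# connection, or flip one truth-table entry. New or moved edge endpoints may
# land in another network of the holobiont, subject to the wiring scheme
# (microbes under the specialized scheme may only reach the host and their
# own niche). Proposals that would duplicate an edge or exceed the in-degree
# cap are re-drawn a bounded number of times and then become no-ops; no-ops
# do not increment the mutation counter.

kind_levels <- c(
  "rewire", "add_connection", "remove_connection",
  "flip_table_entry"
)

#' Sample mutation events for every network of a holobiont
#'
#' Each node of each network is independently selected with probability
#' `mu_host` (host nodes) or `mu_microbe` (microbial nodes). Each selected
#' node receives one event whose class is drawn uniformly from the four
#' operator classes; the directional classes also draw an in/out direction
#' uniformly. Events are returned in a fixed network-then-node order.
#'
#' @param holobiont A `holobiont` (or `bn_network`).
#' @param mu_host Per-node mutation probability for the host.
#' @param mu_microbe Per-node mutation probability for microbes (default
#'   `10 * mu_host`, the faster microbial mutation supply).
#' @return Tibble with columns `network`, `node`, `kind`, `direction`.
#' @export
sample_mutations <- function(holobiont, mu_host,
                             mu_microbe = 10 * mu_host) {
  holobiont <- as_holobiont(holobiont)
  df <- cpp_sample_mutations(unclass(holobiont), mu_host, mu_microbe)
  tibble::tibble(
    network = as.integer(df$network),
    node = as.integer(df$node),
    kind = kind_levels[df$kind_code + 1L],
    direction = dplyr::case_when(
      is.na(df$dir_code) ~ NA_character_,
      df$dir_code == 0L ~ "in",
      TRUE ~ "out"
    )
  )
}

#' Apply mutation events to a holobiont
#'
#' Applies each event in order, drawing any remaining randomness (partner
#' networks and nodes, table entries, new truth-table bits) at application
#' time. Each applied event increments the target network's mutation
#' counter; proposals rejected after bounded retries are no-ops.
#'
#' @param holobiont A `holobiont` (or `bn_network`).
#' @param events Tibble from [sample_mutations()] (columns `network`,
#'   `node`, `kind`, `direction`).
#' @param k_max In-degree cap: add/rewire proposals that would push a node
#'   past `k_max` regulators are rejected (default 10).
#' @param table_policy_add,table_policy_remove Truth-table policies when a
#'   node's in-degree changes (see [evolution_config()]).
#' @return The mutated holobiont, with a logical attribute `"applied"`
#'   marking which events were applied.
#' @export
apply_mutations <- function(holobiont, events, k_max = 10L,
                            table_policy_add = c("random", "copy"),
                            table_policy_remove = c("zero", "random")) {
  table_policy_add <- match.arg(table_policy_add)
  table_policy_remove <- match.arg(table_policy_remove)
  holobiont <- as_holobiont(holobiont)
  kind_code <- match(events$kind, kind_levels) - 1L
  if (anyNA(kind_code)) {
    abort("unknown mutation kind in `events`")
  }
  dir_code <- ifelse(is.na(events$direction), NA_integer_,
    ifelse(events$direction == "in", 0L, 1L)
  )
  res <- cpp_apply_mutations(
    unclass(holobiont), as.integer(events$network),
    as.integer(events$node), as.integer(kind_code),
    as.integer(dir_code), as.integer(k_max),
    policy_code(table_policy_add, "copy"),
    policy_code(table_policy_remove, "random")
  )
  out <- restore_fields(res$holobiont, holobiont)
  attr(out, "applied") <- res$applied
  out
}

#' Sample a partner network for a new connection
#'
#' A host-side connection endpoint may land with equal probability in the
#' host itself or any microbial network. A microbe-side endpoint may land in
#' the host, itself, or any other microbe — restricted to its own niche
#' under the specialized wiring constraint.
#'
#' @param holobiont A `holobiont`.
#' @param source_network Position of the mutated network (1 = host).
#' @return Integer position of the partner network.
#' @export
sample_connection_partner <- function(holobiont, source_network) {
  holobiont <- as_holobiont(holobiont)
  cpp_pick_partner(unclass(holobiont), as.integer(source_network))
}
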