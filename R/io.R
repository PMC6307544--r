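# Configuration files, JSON serialization of genotypes, TSV result tables
# and run manifests.

config_field_names <- c(
  "n_nodes", "in_degree", "n_signal", "t_max", "pop_size", "n_microbes",
  "n_tasks", "n_niches", "mu_host", "gamma", "mu_microbe", "delta_a",
  "n_survivors", "copies_per_survivor", "aggregation", "scheme",
  "evaluation_scope", "max_generations", "k_max", "table_policy_add",
  "table_policy_remove", "mutate_survivors", "tie_break", "seed"
)

#' Load a simulation configuration from a file
#'
#' Reads a YAML or JSON configuration file, fills omitted keys with the
#' standard defaults (see [evolution_config()]) and validates the result.
#' Unknown keys are an error, named explicitly.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file. An empty file
#'   yields the full default configuration.
#' @return An `evolution_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path))
  }
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  vals <- vals %||% list()
  unknown <- setdiff(names(vals), config_field_names)
  if (length(unknown)) {
    abort(sprintf(
      "unknown configuration key(s): %s",
      paste(unknown, collapse = ", ")
    ))
  }
  do.call(evolution_config, vals)
}

#' Save a configuration to YAML
#'
#' @param config An `evolution_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  fields <- unclass(config)
  fields <- fields[!vapply(fields, is.null, logical(1))]
  yaml::write_yaml(fields, path)
  invisible(path)
}

schema_version <- 1L

bits_to_string <- function(x) paste(as.integer(x), collapse = "")

string_to_bits <- function(s) {
  as.integer(strsplit(s, "", fixed = TRUE)[[1L]])
}

network_label <- function(i) if (i == 1L) "H" else paste0("M", i - 1L)

network_to_json <- function(nw, i) {
  list(
    network_id = network_label(i),
    nodes = lapply(nw$nodes, function(nd) {
      list(
        regulators = purrr::map2(
          nd$reg_net, nd$reg_node,
          function(a, b) list(network = a, node = b)
        ),
        table = bits_to_string(nd$table)
      )
    }),
    signal_indices = as.integer(nw$signal),
    initial_condition = bits_to_string(nw$init),
    mutation_count = nw$mutation_count
  )
}

network_from_json <- function(nj) {
  structure(
    list(
      nodes = lapply(nj$nodes, function(nd) {
        regs <- nd$regulators
        list(
          reg_net = vapply(
            regs, function(r) as.integer(r$network), integer(1)
          ),
          reg_node = vapply(
            regs, function(r) as.integer(r$node), integer(1)
          ),
          table = string_to_bits(nd$table)
        )
      }),
      signal = as.integer(unlist(nj$signal_indices)),
      init = string_to_bits(nj$initial_condition),
      mutation_count = as.numeric(nj$mutation_count)
    ),
    class = "bn_network"
  )
}

holobiont_to_json <- function(h) {
  list(
    niche = if (is.null(h$niche)) NULL else as.integer(h$niche),
    task_assignment = if (is.null(h$task_assignment)) {
      NULL
    } else {
      lapply(h$task_assignment, as.integer)
    },
    networks = purrr::imap(h$networks, function(nw, i) {
      network_to_json(nw, as.integer(i))
    })
  )
}

holobiont_from_json <- function(hj) {
  structure(
    list(
      networks = lapply(hj$networks, network_from_json),
      niche = if (is.null(hj$niche)) NULL else as.integer(unlist(hj$niche)),
      task_assignment = if (is.null(hj$task_assignment)) {
        NULL
      } else {
        lapply(hj$task_assignment, function(v) as.integer(unlist(v)))
      },
      detached = NULL
    ),
    class = "holobiont"
  )
}

#' Serialize a population of holobionts to JSON
#'
#' The schema stores, for each network, the per-node regulator references
#' (network + node), truth tables and initial conditions as 0/1 strings,
#' signal indices and the accumulated-mutation counter; round-trips are
#' exact.
#'
#' @param population List of `holobiont` objects (a single holobiont or
#'   `bn_network` is wrapped).
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
save_population <- function(population, path) {
  if (inherits(population, c("holobiont", "bn_network"))) {
    population <- list(as_holobiont(population))
  }
  payload <- list(
    schema_version = schema_version,
    holobionts = lapply(population, function(h) {
      holobiont_to_json(as_holobiont(h))
    })
  )
  jsonlite::write_json(payload, path,
    auto_unbox = TRUE, null = "null", digits = NA
  )
  invisible(path)
}

#' Load a population of holobionts from JSON
#'
#' @param path A file written by [save_population()].
#' @return List of `holobiont` objects.
#' @export
load_population <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(payload$schema_version) ||
    payload$schema_version != schema_version) {
    abort(sprintf(
      "unsupported population schema version: %s (expected %d)",
      payload$schema_version %||% "<missing>", schema_version
    ))
  }
  lapply(payload$holobionts, holobiont_from_json)
}

#' Write per-generation records (or any tidy result table) as TSV
#'
#' Floating-point columns are written at fixed 1e-6 precision so files are
#' byte-stable across platforms; the table re-reads losslessly at that
#' precision with [read_records()].
#'
#' @param records A data frame (e.g. a `holo_evolution` records tibble).
#' @param path Output `.tsv` path.
#' @param append Append without repeating the header (for per-replicate
#'   streaming into one file).
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, append = FALSE) {
  out <- dplyr::mutate(
    tibble::as_tibble(records),
    dplyr::across(
      dplyr::where(is.double),
      ~ sprintf("%.6f", .x)
    )
  )
  readr::write_tsv(out, path,
    append = append, col_names = !append,
    progress = FALSE
  )
  invisible(path)
}

#' Read back a TSV written by [write_records()]
#'
#' @param path Input path.
#' @return A tibble.
#' @export
read_records <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Build a run manifest
#'
#' Captures everything needed to re-run an experiment exactly: the config
#' snapshot, seeds, package version and an inventory of output files with
#' checksums.
#'
#' @param config An `evolution_config`.
#' @param seeds Integer seeds the run consumed.
#' @param files Character vector of produced files.
#' @param started,finished POSIXct timestamps.
#' @return A `run_manifest` list, serializable with
#'   [jsonlite::write_json()].
#' @export
run_manifest <- function(config, seeds, files = character(0),
                         started = Sys.time(), finished = Sys.time()) {
  inventory <- lapply(files, function(f) {
    list(
      path = f,
      md5 = unname(tools::md5sum(f)),
      bytes = file.size(f)
    )
  })
  structure(
    list(
      package_version = as.character(utils::packageVersion("holosim")),
      config = unclass(config),
      seeds = as.integer(seeds),
      started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
      finished = format(finished, "%Y-%m-%dT%H:%M:%S%z"),
      files = inventory
    ),
    class = "run_manifest"
  )
}
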