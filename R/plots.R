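# broom-style accessors and ggplot2 visualizations for result objects.

#' @export
tidy.holo_evolution <- function(x, ...) {
  x$records
}

#' @export
glance.holo_evolution <- function(x, ...) {
  last <- x$records[nrow(x$records), ]
  tibble::tibble(
    n_generations = x$config$max_generations,
    first_crossing = first_crossing(x, x$config$delta_a),
    final_xi_h = last$xi_h,
    final_xi_m = last$xi_m,
    final_xi_l = last$xi_l,
    final_p_a = last$p_a,
    max_p_a = max(x$records$p_a),
    final_omega_h = last$omega_h
  )
}

#' @export
tidy.experiment_result <- function(x, ...) {
  x$records
}

#' @export
glance.experiment_result <- function(x, ...) {
  x$summary
}

evolution_long <- function(records, vars) {
  tidyr::pivot_longer(
    dplyr::select(
      records,
      dplyr::any_of(c("replicate", "generation", vars))
    ),
    cols = dplyr::all_of(vars),
    names_to = "statistic", values_to = "value"
  )
}

#' Plot the adaptation trajectory of an evolutionary run
#'
#' Draws the selected population statistics against generations, with the
#' adaptation threshold as a dashed reference line.
#'
#' @param object A `holo_evolution`.
#' @param vars Record columns to draw (default the mean host error
#'   `"xi_h"`; `"xi_m"`, `"xi_l"`, `"p_a"`, `"omega_h"` also available).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.holo_evolution <- function(object, vars = "xi_h", ...) {
  df <- evolution_long(object$records, vars)
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = .data$generation, y = .data$value,
      colour = .data$statistic
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(
      yintercept = object$config$delta_a,
      linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "generation", y = "population mean",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.holo_evolution
#' @export
autoplot.experiment_result <- function(object, vars = "xi_h", ...) {
  df <- evolution_long(object$records, vars)
  p <- ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = .data$generation, y = .data$value,
      group = interaction(.data$replicate, .data$statistic),
      colour = .data$statistic
    )
  ) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_hline(
      yintercept = object$spec$config$delta_a,
      linetype = "dashed"
    ) +
    ggplot2::labs(x = "generation", y = "population mean", colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(object$spec$sweep_param)) {
    p <- p + ggplot2::facet_wrap(object$spec$sweep_param)
  }
  p
}

#' Plot a diversity-loss curve
#'
#' @param sweep Tibble from [diversity_loss_sweep()].
#' @param delta_a Adaptation threshold reference line.
#' @return A ggplot object.
#' @export
plot_diversity_loss <- function(sweep, delta_a = 1) {
  ggplot2::ggplot(
    sweep,
    ggplot2::aes(x = .data$delta_n, y = .data$xi_h)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = delta_a, linetype = "dashed") +
    ggplot2::labs(
      x = "disconnected microbial networks",
      y = "mean host error"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
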