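# broom-style accessors and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a simulation run
#'
#' @param x A `"paracortex_sim"` object.
#' @param ... Unused.
#' @return The population time-series tibble.
#' @export
tidy.paracortex_sim <- function(x, ...) x$population

#' @rdname tidy.paracortex_sim
#' @export
glance.paracortex_sim <- function(x, ...) {
  p <- x$population
  tibble::tibble(
    N0 = x$config$N0,
    duration_days = x$config$duration_days,
    final_n = p$n_cells[nrow(p)],
    peak_n = max(p$n_cells),
    n_entries = as.integer(x$counters$total_entries),
    n_exits = as.integer(x$counters$total_exits),
    crowding_exceptions = as.integer(x$counters$crowding_exceptions),
    deferred_arrivals = as.integer(x$counters$deferred_arrivals)
  )
}

#' @export
tidy.transit_stats <- function(x, ...) x$histogram

#' @export
glance.transit_stats <- function(x, ...) {
  tibble::tibble(mean_h = x$mean_h, mean_min = x$mean_min,
                 n_closed = x$n_closed, n_open = x$n_open)
}

#' @export
tidy.exit_calibration <- function(x, ...) x$table

#' @export
glance.exit_calibration <- function(x, ...) {
  tibble::tibble(power_a = x$power_a, power_b = x$power_b,
                 P_E = x$P_E, T_res_min = x$T_res_min)
}

#' @export
tidy.beta_calibration <- function(x, ...) x$table

#' @export
glance.beta_calibration <- function(x, ...) {
  tibble::tibble(c0 = x$coeffs[1L], c1 = x$coeffs[2L], c2 = x$coeffs[3L],
                 N = x$N)
}

#' @export
glance.subset_experiment <- function(x, ...) {
  tibble::tibble(K_E = x$K_E, tagged_mean_h = x$stats$mean_h,
                 untagged_mean_h = x$untagged_stats$mean_h,
                 n_tagged = x$stats$n_closed)
}

#' Plot the population time course of a run
#'
#' @param object A `"paracortex_sim"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.paracortex_sim <- function(object, ...) {
  p <- object$population
  ggplot2::ggplot(p, ggplot2::aes(x = .data$t_min / 1440,
                                  y = .data$n_cells)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (days)", y = "T cell population",
                  title = sprintf("Blob population (N0 = %d)",
                                  object$config$N0))
}

#' Plot a transit-time distribution
#'
#' @param object A `"transit_stats"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.transit_stats <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = .data$bin_left_h,
                               y = .data$probability)) +
    ggplot2::geom_col(width = 1, fill = "grey35") +
    ggplot2::labs(x = "transit time (h)", y = "probability",
                  title = sprintf("Mean transit %.1f h", object$mean_h))
}

#' Plot a chemotaxis-index sweep
#'
#' @param object A `"ci_sweep"` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ci_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$strength, y = .data$CI)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "chemotactic strength |C|", y = "chemotaxis index")
}
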