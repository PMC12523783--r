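#' Plot a per-generation metric across schemes
#'
#' Replicate means with a mean +/- SD ribbon, one line per scheme (and
#' linetype per founder design when a `population` column is present).
#'
#' @param records tidy generation records (from [run_scheme()] or
#'   [run_experiment()]), with `scheme`, `generation`, optionally
#'   `replicate`/`population`, and the metric column.
#' @param metric column to plot (default `"mean_gv"`, the genotypic mean).
#' @return A ggplot object.
#' @export
plot_generation_metric <- function(records, metric = "mean_gv") {
  stopifnot(metric %in% names(records))
  if (!"replicate" %in% names(records)) records$replicate <- 1L
  grp <- c("scheme", "generation",
           intersect("population", names(records)))
  agg <- records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      mean = mean(.data[[metric]], na.rm = TRUE),
      sd = if (dplyr::n() > 1) sd(.data[[metric]], na.rm = TRUE) else
        NA_real_,
      .groups = "drop")
  p <- ggplot2::ggplot(agg, ggplot2::aes(x = .data$generation,
                                         y = .data$mean,
                                         colour = .data$scheme)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "generation", y = metric, colour = "scheme") +
    ggplot2::theme_minimal()
  if (any(is.finite(agg$sd)))
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - .data$sd,
                   ymax = .data$mean + .data$sd,
                   fill = .data$scheme),
      alpha = 0.15, colour = NA)
  if ("population" %in% names(agg))
    p <- p + ggplot2::facet_wrap(~population)
  p
}

#' @export
autoplot.gs_run <- function(object, metric = "mean_gv", ...) {
  plot_generation_metric(object$records, metric)
}

#' @export
autoplot.gs_experiment <- function(object, metric = "mean_gv", ...) {
  plot_generation_metric(object$records, metric)
}
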