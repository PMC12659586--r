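#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Forest plot of observed/expected ratios
#'
#' @param forest Tibble with `trial_id`, `model_id`, `ratio`, `lo`, `hi`
#'   (the `oe_forest` output of [run_pipeline()], or [tidy()] rows renamed).
#' @return A ggplot.
#' @export
plot_oe_forest <- function(forest) {
  ggplot2::ggplot(
    forest,
    ggplot2::aes(
      x = .data$ratio, y = .data$trial_id, colour = .data$model_id
    )
  ) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
      position = ggplot2::position_dodge(width = 0.5)
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "observed / expected (log scale)", y = NULL, colour = NULL,
      title = "Observed vs expected first events"
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot oe_result
#' @export
autoplot.oe_result <- function(object, ...) {
  df <- tidy(object)
  plot_oe_forest(tibble(
    trial_id = "trial", model_id = "model",
    ratio = df$ratio, lo = df$conf.low, hi = df$conf.high
  ))
}

#' Observed counts with the fitted distribution overlaid
#'
#' @param object A `fitted_count_dist`.
#' @param counts The counts it was fitted to.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fitted_count_dist
#' @export
autoplot.fitted_count_dist <- function(object, counts, ...) {
  kmax <- max(counts)
  obs <- tibble(
    count = 0:kmax,
    proportion = tabulate(counts + 1L, nbins = kmax + 1L) / length(counts)
  )
  fitted <- tibble(count = 0:kmax, proportion = count_dist_pmf(object, 0:kmax))
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$count, y = .data$proportion)) +
    ggplot2::geom_col(fill = "grey75") +
    ggplot2::geom_line(data = fitted, colour = "firebrick", linewidth = 1) +
    ggplot2::geom_point(data = fitted, colour = "firebrick") +
    ggplot2::labs(
      x = "comorbidity count", y = "proportion",
      title = paste0("Fitted ", object$family, " distribution")
    ) +
    ggplot2::theme_minimal()
}

#' Rate curves across comorbidity counts with their 95% band
#'
#' @param curves Output of [rate_curves()] (optionally with a `population`
#'   column to colour by).
#' @return A ggplot.
#' @export
plot_rate_curves <- function(curves) {
  has_pop <- "population" %in% names(curves)
  p <- ggplot2::ggplot(
    curves,
    if (has_pop) {
      ggplot2::aes(x = .data$count, y = .data$rate, colour = .data$population, fill = .data$population)
    } else {
      ggplot2::aes(x = .data$count, y = .data$rate)
    }
  ) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
      alpha = 0.2, colour = NA
    ) +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::labs(
      x = "comorbidity count", y = "events per person-year",
      title = "Event rate across the comorbidity spectrum"
    ) +
    ggplot2::theme_minimal()
  p
}

#' Eligible proportions per trial
#'
#' @param props Tibble `trial_id`, `eligible_proportion` (the
#'   `eligible_proportions` output of [run_pipeline()]).
#' @return A ggplot.
#' @export
plot_eligible_proportions <- function(props) {
  ggplot2::ggplot(
    props,
    ggplot2::aes(
      x = 100 * .data$eligible_proportion,
      y = stats::reorder(.data$trial_id, .data$eligible_proportion)
    )
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "% of community treated meeting eligibility criteria", y = NULL,
      title = "Trial eligibility in the community population"
    ) +
    ggplot2::theme_minimal()
}
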