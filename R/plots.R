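#' Plot a Kaplan-Meier curve
#'
#' Step-function survival curve with a pointwise confidence band.
#'
#' @param object A `stil_km` from [km_estimate()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stil_km <- function(object, ...) {
  df <- tidy(object)
  df0 <- dplyr::bind_rows(
    tibble::tibble(time = 0, estimate = 1, conf_low = 1, conf_high = 1),
    df[, c("time", "estimate", "conf_low", "conf_high")])
  ggplot2::ggplot(df0, ggplot2::aes(x = .data$time, y = .data$estimate)) +
    ggplot2::geom_step() +
    ggplot2::geom_step(ggplot2::aes(y = .data$conf_low), linetype = "dashed",
                       alpha = 0.6) +
    ggplot2::geom_step(ggplot2::aes(y = .data$conf_high),
                       linetype = "dashed", alpha = 0.6) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time", y = "Survival probability") +
    ggplot2::theme_minimal()
}

#' Plot Kaplan-Meier curves for two biomarker groups
#'
#' @param times,events Endpoint vectors.
#' @param groups Two-level factor (e.g. from [dichotomize()]).
#' @return A ggplot with one step curve per group.
#' @export
plot_km_groups <- function(times, events, groups) {
  g <- as.factor(groups)
  dfs <- lapply(levels(g), function(lv) {
    sel <- !is.na(g) & g == lv
    d <- tidy(km_estimate(times[sel], events[sel]))
    dplyr::bind_rows(tibble::tibble(time = 0, estimate = 1),
                     d[, c("time", "estimate")]) |>
      dplyr::mutate(group = lv)
  })
  ggplot2::ggplot(dplyr::bind_rows(dfs),
                  ggplot2::aes(x = .data$time, y = .data$estimate,
                               color = .data$group)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::scale_color_manual(values = c(low = "#2166ac",
                                           high = "#b2182b")) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (days)", y = "Survival probability",
                  color = "sTIL group") +
    ggplot2::theme_minimal()
}

#' Plot the cutpoint scan of a maximally selected rank statistic
#'
#' Absolute standardized log-rank statistic against candidate cutpoint,
#' with the selected cutpoint marked.
#'
#' @param object A `stil_cutpoint` from [maxstat_cutpoint()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stil_cutpoint <- function(object, ...) {
  ggplot2::ggplot(object$scan,
                  ggplot2::aes(x = .data$cutpoint,
                               y = abs(.data$statistic))) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$cutpoint, color = "#b2182b",
                        linetype = "dashed") +
    ggplot2::labs(x = "Candidate cutpoint (cells/mm^2)",
                  y = "|standardized log-rank statistic|") +
    ggplot2::theme_minimal()
}

#' Plot a local-density heatmap with ggplot2
#'
#' Convenience view of [local_density_heatmap()] output (for publication
#' figures; [render_heatmap()] writes the deterministic PNG artifact).
#'
#' @param heatmap Matrix from [local_density_heatmap()].
#' @param cal Optional [calibration()]; axes switch to millimetres.
#' @return A ggplot.
#' @export
plot_heatmap <- function(heatmap, cal = NULL) {
  df <- expand.grid(y = seq_len(nrow(heatmap)) - 1L,
                    x = seq_len(ncol(heatmap)) - 1L)
  df$density <- as.vector(heatmap)
  unit <- "px"
  if (!is.null(cal)) {
    df$x <- df$x * cal$microns_per_pixel / 1000
    df$y <- df$y * cal$microns_per_pixel / 1000
    unit <- "mm"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85",
                                  name = "cells/mm^2") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = paste0("x (", unit, ")"), y = paste0("y (", unit, ")")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
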