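#' Plot a single-cell trajectory
#'
#' Two stacked panels: the three state areas plus lumen area over time, and
#' wall thickness over time with the `WT*` threshold; the background shading
#' marks the enlargement and thickening phases.
#'
#' @param object A `tracheid_trajectory` from [simulate_cell()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tracheid_trajectory
#' @export
autoplot.tracheid_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[c("time", "CA", "LA", "WA", "LWA")],
    -"time",
    names_to = "variable", values_to = "area"
  )
  long$variable <- factor(
    long$variable,
    levels = c("CA", "LA", "WA", "LWA"),
    labels = c("Cell area", "Lumen area", "Wall area", "Lignified wall area")
  )
  t_enl <- attr(object, "t_enl_end")
  t_death <- attr(object, "t_death")
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$area, colour = .data$variable))
  if (isTRUE(attr(object, "died"))) {
    p <- p +
      ggplot2::annotate(
        "rect",
        xmin = 0, xmax = t_enl, ymin = -Inf, ymax = Inf,
        fill = "grey85", alpha = 0.5
      ) +
      ggplot2::annotate(
        "rect",
        xmin = t_enl, xmax = t_death, ymin = -Inf, ymax = Inf,
        fill = "grey70", alpha = 0.5
      )
  }
  p +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(
      x = "Time since cell birth (d)",
      y = expression(Area ~ (mu * m^2)),
      colour = NULL,
      title = sprintf(
        "%s, S = %g", attr(object, "species") %||% "", attr(object, "S")
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a tracheidogram
#'
#' Lumen area, lumen radial diameter and wall thickness against relative
#' ring position, one panel per trait, latewood cells marked.
#'
#' @param object A `tracheidogram`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tracheidogram
#' @export
autoplot.tracheidogram <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[c("rel_position", "latewood", "LA", "LRD", "WT")],
    c("LA", "LRD", "WT"),
    names_to = "trait", values_to = "value"
  )
  long$trait <- factor(
    long$trait,
    levels = c("LA", "LRD", "WT"),
    labels = c("Lumen area (um2)", "Lumen radial diameter (um)", "Wall thickness (um)")
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(.data$rel_position, .data$value, colour = .data$latewood)
  ) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~trait, ncol = 1, scales = "free_y") +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "#4477aa", `TRUE` = "#aa3333"),
      labels = c(`FALSE` = "earlywood", `TRUE` = "latewood")
    ) +
    ggplot2::labs(
      x = "Relative ring position", y = NULL, colour = NULL,
      title = attr(object, "species") %||% NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot calibration agreement
#'
#' Observed against fitted trait values, one panel per trait, with the 1:1
#' line.
#'
#' @param object A `tracheid_fit` from [calibrate_tracheids()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tracheid_fit
#' @export
autoplot.tracheid_fit <- function(object, ...) {
  df <- dplyr::bind_rows(lapply(c("LA", "LRD", "WT"), function(tr) {
    tibble(
      trait = tr,
      simulated = object$simulated[[tr]],
      observed = object$observed[[tr]]
    )
  }))
  ggplot2::ggplot(df, ggplot2::aes(.data$simulated, .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(size = 0.8, colour = "#4477aa") +
    ggplot2::facet_wrap(~trait, scales = "free") +
    ggplot2::labs(x = "Simulated", y = "Observed") +
    ggplot2::theme_minimal()
}
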