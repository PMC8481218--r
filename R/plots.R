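#' Plot an indicator with its confidence band and small-scale signals
#'
#' @param object a [confidence_band()].
#' @param ... ignored.
#' @return A ggplot.
#' @method autoplot confidence_band
#' @export
autoplot.confidence_band <- function(object, ...) {
  b <- as_tibble(object)
  sig <- small_scale_signals(object)
  p <- ggplot2::ggplot(b[b$valid, ], ggplot2::aes(x = .data$axis)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(y = .data$value)) +
    ggplot2::labs(x = "axis", y = attr(object, "indicator"),
                  title = attr(object, "level_label"))
  if (nrow(sig)) {
    p <- p + ggplot2::geom_point(data = sig,
                                 ggplot2::aes(y = .data$value,
                                              colour = .data$kind), size = 3) +
      ggplot2::scale_colour_manual(values = c(peak = "firebrick",
                                              trough = "steelblue"))
  }
  p
}

#' Plot an indicator series
#'
#' @param object an `indicator_series`.
#' @param ... ignored.
#' @method autoplot indicator_series
#' @export
autoplot.indicator_series <- function(object, ...) {
  ggplot2::ggplot(object[object$valid, ],
                  ggplot2::aes(x = .data$axis, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "axis", y = indicator_name(object))
}

#' Plot zone structure along the axis
#'
#' @param object a `zone_labeling`.
#' @param ... ignored.
#' @method autoplot zone_labeling
#' @export
autoplot.zone_labeling <- function(object, ...) {
  z <- as_tibble(object)
  ggplot2::ggplot(z) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$axis_start,
                                    xmax = .data$axis_end,
                                    ymin = 0, ymax = 1, fill = .data$role),
                       colour = "white") +
    ggplot2::geom_text(ggplot2::aes(
      x = (.data$axis_start + .data$axis_end) / 2, y = 0.5,
      label = .data$dominant), na.rm = TRUE) +
    ggplot2::scale_y_continuous(NULL, breaks = NULL) +
    ggplot2::labs(x = "axis", fill = "zone role")
}

#' Plot principal-component sample scores
#'
#' @param object a [pca_covariance()] result.
#' @param components which two components to show.
#' @param ... ignored.
#' @method autoplot pca_result
#' @export
autoplot.pca_result <- function(object, components = c(1, 2), ...) {
  sc <- tidy(object, matrix = "scores")
  nm <- paste0("PC", components)
  ggplot2::ggplot(sc, ggplot2::aes(x = .data[[nm[1]]], y = .data[[nm[2]]])) +
    ggplot2::geom_path(colour = "grey70") +
    ggplot2::geom_point() +
    ggplot2::labs(x = nm[1], y = nm[2])
}
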