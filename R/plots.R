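#' Plot per-element intercepted PPFD against height
#'
#' Leaves are drawn at their mean vertex height, coloured by kind; error
#' bars show the Monte Carlo standard error.
#'
#' @param object an `irradiance_map` from [trace_scene()].
#' @param mesh the traced [triangle_mesh()] (for element heights).
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.irradiance_map <- function(object, mesh = NULL, ...) {
  df <- object$elements
  if (!is.null(mesh)) {
    hz <- vapply(df$element_id, function(eid) {
      sel <- mesh$element_id == eid
      vids <- unique(as.vector(mesh$triangles[sel, ]))
      mean(mesh$vertices[vids, 3])
    }, 0)
    df$height <- hz
    ggplot2::ggplot(df, ggplot2::aes(x = .data$ppfd, y = .data$height,
                                     colour = .data$kind)) +
      ggplot2::geom_point() +
      ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ppfd - .data$se,
                                           xmax = .data$ppfd + .data$se),
                              height = 0) +
      ggplot2::labs(x = "intercepted PPFD (umol m^-2 s^-1)",
                    y = "height (m)", colour = NULL)
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$element_id, y = .data$ppfd,
                                     colour = .data$kind)) +
      ggplot2::geom_point() +
      ggplot2::labs(x = "element", y = "intercepted PPFD (umol m^-2 s^-1)",
                    colour = NULL)
  }
}

#' Plot a chamber rate series
#'
#' @param object a `rate_series` from [drawdown_to_rate()].
#' @param ... unused.
#' @return A ggplot of rate against time.
#' @export
autoplot.rate_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time / 3600,
                                       y = .data$rate)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)",
                  y = "whole-plant rate (umolCO2 m^-2 s^-1)")
}

#' Plot a whole-plant CO2-response curve
#'
#' @param object a `co2_response` from [co2_response()].
#' @param ... unused.
#' @return A ggplot of rate against CO2.
#' @export
autoplot.co2_response <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$co2, y = .data$rate)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "CO2 (umol mol^-1)",
                  y = "whole-plant rate (umolCO2 m^-2 s^-1)")
}

#' Plot a diurnal whole-plant rate course
#'
#' @param object a `diurnal_rates` tibble from [run_diurnal_experiment()].
#' @param ... unused.
#' @return A ggplot of rate against local hour.
#' @export
autoplot.diurnal_rates <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$hour, y = .data$rate)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "local hour",
                  y = "whole-plant rate (umolCO2 m^-2 s^-1)")
}

#' Plot measured vs estimated rates with the 1:1 line
#'
#' @param object a `validation_report` from [validation_metrics()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.validation_report <- function(object, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(x = .data$measured,
                                             y = .data$estimated)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(
      x = "measured rate (umolCO2 m^-2 s^-1)",
      y = "estimated rate (umolCO2 m^-2 s^-1)",
      subtitle = sprintf("R^2 = %.3f, RMSE = %.3f (n = %d)",
                         object$r_squared, object$rmse, object$n))
}

#' 2D projection of the canopy, optionally coloured by intercepted PPFD
#'
#' Draws every leaf triangle in front (x-z) or top (x-y) view; with an
#' irradiance map, leaves are filled by their mean intercepted PPFD —
#' the per-leaf light map of the traced scene.
#'
#' @param plant a [build_plant()] result or `canopy_scene`.
#' @param map optional `irradiance_map`.
#' @param view `"front"` or `"top"`.
#' @return A ggplot.
#' @export
plot_canopy <- function(plant, map = NULL, view = c("front", "top")) {
  view <- match.arg(view)
  mesh <- if (inherits(plant, "canopy3d") || inherits(plant, "canopy_scene")) {
    plant$mesh
  } else plant
  sel <- which(mesh$element_id %in%
                 mesh$elements$element_id[mesh$elements$kind == "leaf"])
  tri <- mesh$triangles[sel, , drop = FALSE]
  ax <- if (view == "front") c(1, 3) else c(1, 2)
  poly <- tibble::tibble(
    tri = rep(seq_len(nrow(tri)), each = 3),
    element_id = rep(mesh$element_id[sel], each = 3),
    x = mesh$vertices[as.vector(t(tri)), ax[1]],
    y = mesh$vertices[as.vector(t(tri)), ax[2]])
  p <- ggplot2::ggplot(poly, ggplot2::aes(x = .data$x, y = .data$y,
                                          group = .data$tri))
  if (!is.null(map)) {
    ppfd_of <- setNames(map$elements$ppfd, map$elements$element_id)
    poly$ppfd <- ppfd_of[as.character(poly$element_id)]
    p <- ggplot2::ggplot(poly,
                         ggplot2::aes(x = .data$x, y = .data$y,
                                      group = .data$tri,
                                      fill = .data$ppfd)) +
      ggplot2::scale_fill_viridis_c(name = "PPFD")
  }
  p + ggplot2::geom_polygon(colour = NA) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = if (view == "front") "x (m)" else "x (m)",
                  y = if (view == "front") "z (m)" else "y (m)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
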