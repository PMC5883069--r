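#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_point geom_line
#'   geom_abline geom_ribbon scale_fill_viridis_c coord_fixed labs theme_minimal
#'   facet_wrap
NULL

#' @export
ggplot2::autoplot

indicator_label <- function(ind) {
  switch(ind,
    fvfm = "Fv/Fm",
    phipsii = "PhiPSII",
    r550_510 = "550/510",
    ind
  )
}

#' Plot an indicator map as a pseudo-color panel
#'
#' ggplot2 version of [render_pseudocolor()]: fixed per-indicator scales so
#' day-series panels are comparable; undefined pixels are blank.
#'
#' @param object An `indicator_map`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot indicator_map
#' @export
autoplot.indicator_map <- function(object, ...) {
  scale <- INDICATOR_SCALES[[object$indicator]]
  df <- tibble::tibble(
    row = rep(seq_len(nrow(object$values)), times = ncol(object$values)),
    col = rep(seq_len(ncol(object$values)), each = nrow(object$values)),
    value = as.vector(object$values)
  )
  ggplot(df, aes(x = .data$col, y = -.data$row, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c(limits = scale, na.value = "black",
                         name = indicator_label(object$indicator)) +
    coord_fixed() +
    labs(x = NULL, y = NULL) +
    theme_minimal()
}

#' Plot an indicator trajectory (day series of plant summaries)
#'
#' One panel per indicator: the plant-mean with a +/- one spatial standard
#' deviation ribbon over days, the tidy analogue of per-day boxplots.
#'
#' @param summaries Tidy summary tibble (columns `day`, `indicator`, `mean`,
#'   `std`) as produced by [summarize_maps()] or [run_pipeline()].
#' @return A ggplot object.
#' @export
plot_trajectory <- function(summaries) {
  df <- dplyr::mutate(summaries,
                      indicator = vapply(.data$indicator, indicator_label,
                                         character(1)))
  ggplot(df, aes(x = .data$day, y = .data$mean)) +
    geom_ribbon(aes(ymin = .data$mean - .data$std,
                    ymax = .data$mean + .data$std), alpha = 0.25) +
    geom_line() +
    geom_point() +
    facet_wrap(~indicator, scales = "free_y") +
    labs(x = "day", y = "plant mean (+/- spatial sd)") +
    theme_minimal()
}

#' Plot the nitrogen calibration fit
#'
#' Scatter of the (total nitrogen, Fv/Fm) pairs with the fitted line.
#'
#' @param object A `nitrogen_calibration`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot nitrogen_calibration
#' @export
autoplot.nitrogen_calibration <- function(object, ...) {
  df <- tibble::as_tibble(object$fit$model)
  ggplot(df, aes(x = .data$total_n, y = .data$fvfm)) +
    geom_point() +
    geom_abline(intercept = object$intercept, slope = object$slope,
                colour = "steelblue") +
    labs(x = "total nitrogen (mg N / g dw)", y = "Fv/Fm",
         subtitle = sprintf("R^2 = %.3f, n = %d", object$r_squared, object$n)) +
    theme_minimal()
}

#' Plot the drought calibration curve
#'
#' @param object A `drought_curve`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot drought_curve
#' @export
autoplot.drought_curve <- function(object, ...) {
  a <- object$anchors
  grid <- tibble::tibble(
    water_potential = seq(min(a$water_potential), max(a$water_potential),
                          length.out = 200)
  )
  grid$phipsii <- phipsii_at(object, grid$water_potential)
  ggplot(grid, aes(x = .data$water_potential, y = .data$phipsii)) +
    geom_line() +
    geom_point(data = a) +
    labs(x = "leaf water potential (MPa)", y = "PhiPSII") +
    theme_minimal()
}
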