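# ggplot2 views of paths, coefficient models and error reports.

#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_path geom_line
#'   geom_point geom_col facet_wrap labs coord_equal theme_minimal
NULL

#' Plot a pixel backbone path
#'
#' @param object An `sl_path`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.sl_path <- function(object, ...) {
  ggplot(object, aes(x = .data$x, y = .data$y)) +
    geom_tile(fill = "grey80", colour = "grey55", linewidth = 0.2) +
    geom_path(colour = "#2166ac", linewidth = 0.5) +
    coord_equal() +
    labs(x = "x (pixels)", y = "y (pixels)") +
    theme_minimal()
}

#' Plot coefficient lines over resolution
#'
#' @param object An `sl_coef_model`.
#' @param r Resolutions at which to draw the lines (defaults to the
#'   calibrated range).
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.sl_coef_model <- function(object, r = NULL, ...) {
  rng <- attr(object, "r_range") %||% c(5.1, 7.8)
  r <- r %||% seq(rng[1], rng[2], length.out = 20)
  d <- tidyr::expand_grid(shape = object$shape, r = r) |>
    dplyr::left_join(as_tibble(unclass(object)), by = "shape") |>
    dplyr::mutate(
      k = .data$m * .data$r + .data$b,
      shape = factor(.data$shape, levels = paste0("k", 1:12))
    )
  ggplot(d, aes(x = .data$r, y = .data$k)) +
    geom_line(colour = "#2166ac") +
    facet_wrap(~shape, scales = "free_y") +
    labs(x = "resolution r (nm/pixel)", y = "coefficient k(r)") +
    theme_minimal()
}

#' Plot an estimator error report
#'
#' @param object An `sl_error_report` from [evaluate_estimators()].
#' @param ... Ignored.
#' @return A ggplot of relative errors by estimator and contour length.
#' @export
autoplot.sl_error_report <- function(object, ...) {
  ggplot(object, aes(x = factor(.data$l_c), y = .data$relative_pct,
                     fill = .data$estimator)) +
    geom_col(position = "dodge") +
    labs(x = "true contour length (nm)", y = "relative error of the mean (%)",
         fill = "estimator") +
    theme_minimal()
}
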