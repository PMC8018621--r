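#' Plot methods
#'
#' `autoplot()` on a `surge_experiment` draws the daily CI curves per
#' acuity level with the busy phase shaded; `plot_quality_curve()` draws
#' the corresponding quality drop-and-restoration curves. `autoplot()` on
#' a `ci_piecewise_fit` draws the fitted two-segment response of maximum
#' CI to the growth ratio, with the observed points when the fit retains
#' them.
#'
#' @param object A `surge_experiment` or `ci_piecewise_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @name surge-plots
NULL

busy_shade <- function(scenario) {
  busy <- scenario$profile$day[scenario$profile$phase == "busy"]
  if (length(busy) == 0) return(NULL)
  ggplot2::annotate(
    "rect", xmin = min(busy) - 0.5, xmax = max(busy) + 0.5,
    ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "grey40"
  )
}

#' @rdname surge-plots
#' @method autoplot surge_experiment
#' @export
autoplot.surge_experiment <- function(object, ...) {
  ggplot2::ggplot(object$daily,
                  ggplot2::aes(x = .data$day, y = .data$ci_mean,
                               colour = .data$acuity)) +
    busy_shade(object$scenario) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      title = sprintf("Daily Crowdedness Index: %s (P = %.2f)",
                      object$scenario$name, object$scenario$growth_ratio),
      x = "Day", y = "Crowdedness Index", colour = "Acuity"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname surge-plots
#' @param result A `surge_experiment`.
#' @export
plot_quality_curve <- function(result, ...) {
  stopifnot(inherits(result, "surge_experiment"))
  ggplot2::ggplot(result$daily,
                  ggplot2::aes(x = .data$day, y = .data$q,
                               colour = .data$acuity)) +
    busy_shade(result$scenario) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      title = sprintf("Emergency care quality: %s (P = %.2f)",
                      result$scenario$name, result$scenario$growth_ratio),
      x = "Day", y = "Quality", colour = "Acuity"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname surge-plots
#' @method autoplot ci_piecewise_fit
#' @export
autoplot.ci_piecewise_fit <- function(object, ...) {
  cf <- object$coefficients
  levels <- unique(cf$acuity)
  lo <- max(1, min(object$data$growth_ratio %||% 1))
  hi <- max(object$data$growth_ratio %||% 2.3, object$breakpoint + 0.5)
  grid <- tidyr::expand_grid(
    acuity = levels,
    growth_ratio = seq(lo, hi, length.out = 200)
  )
  grid$max_ci <- purrr::map2_dbl(grid$growth_ratio, grid$acuity,
                                 function(p, a) predict_max_ci(object, p, a))
  pl <- ggplot2::ggplot(grid,
                        ggplot2::aes(x = .data$growth_ratio,
                                     y = .data$max_ci,
                                     colour = .data$acuity)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$breakpoint,
                        linetype = "dotted", colour = "grey50") +
    ggplot2::labs(x = "Patient growth ratio P",
                  y = "Maximum Crowdedness Index", colour = "Acuity") +
    ggplot2::theme_minimal()
  if (!is.null(object$data)) {
    pts <- object$data
    if (!"acuity" %in% names(pts)) pts$acuity <- "all"
    pl <- pl + ggplot2::geom_point(data = pts)
  }
  pl
}
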