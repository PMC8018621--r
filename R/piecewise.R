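#' Two-segment linear model of maximum CI versus growth ratio
#'
#' The maximum Crowdedness Index responds to the patient growth ratio `P`
#' along two linear regimes joined at a knee: a gentle slope while the
#' hospital absorbs the surge, and a steep one once demand outruns service
#' capacity. The knee is fixed (default `P* = 1.4`, the alarm threshold
#' for the modelled hospital), not estimated. `fit_piecewise()` fits the
#' lower segment to points with `P <= P*` and the upper segment to points
#' with `P >= P*` by independent least squares; the breakpoint itself
#' belongs to both segments.
#'
#' @param data A data frame with columns `growth_ratio` and `max_ci`, and
#'   optionally `acuity` (a separate fit per level) and `segment`
#'   (`"lower"`/`"upper"`, pinning a point to one segment — useful when
#'   the two segments carry distinct values at the shared breakpoint;
#'   otherwise points are split by position relative to `P*`).
#' @param breakpoint Knee position `P*` (default 1.4).
#' @return A `ci_piecewise_fit` object; see [tidy()], [glance()],
#'   [predict_max_ci()] and [autoplot()] methods.
#' @examples
#' pts <- tibble::tibble(
#'   growth_ratio = c(1, 1.4, 1.6, 2),
#'   max_ci = c(0.33, 3.83, 23.4, 62.7)
#' )
#' fit <- fit_piecewise(pts)
#' predict_max_ci(fit, 1.5)
#' @export
fit_piecewise <- function(data, breakpoint = 1.4) {
  if (!is.data.frame(data) ||
      !all(c("growth_ratio", "max_ci") %in% names(data))) {
    abort("data must have columns growth_ratio and max_ci")
  }
  if (!"acuity" %in% names(data)) data$acuity <- "all"
  fits <- data |>
    dplyr::group_by(.data$acuity) |>
    dplyr::group_map(function(d, key) {
      if ("segment" %in% names(d)) {
        if (!all(d$segment %in% c("lower", "upper"))) {
          abort("segment labels must be 'lower' or 'upper'")
        }
        lo <- d[d$segment == "lower", ]
        hi <- d[d$segment == "upper", ]
      } else {
        lo <- d[d$growth_ratio <= breakpoint, ]
        hi <- d[d$growth_ratio >= breakpoint, ]
      }
      if (nrow(lo) < 2 || nrow(hi) < 2) {
        abort(sprintf(
          paste0("need at least 2 points on each side of the breakpoint ",
                 "(level %s has %d below, %d above; P* counts on both sides)"),
          key$acuity, nrow(lo), nrow(hi)
        ))
      }
      m_lo <- lm(max_ci ~ growth_ratio, data = lo)
      m_hi <- lm(max_ci ~ growth_ratio, data = hi)
      # R^2 from residuals directly; summary.lm warns on exact fits
      r2 <- function(m, d) {
        tss <- sum((d$max_ci - mean(d$max_ci))^2)
        if (tss == 0) return(1)
        1 - sum(stats::residuals(m)^2) / tss
      }
      tibble::tibble(
        acuity = key$acuity,
        segment = c("lower", "upper"),
        intercept = c(coef(m_lo)[1], coef(m_hi)[1]),
        slope = c(coef(m_lo)[2], coef(m_hi)[2]),
        r_squared = c(r2(m_lo, lo), r2(m_hi, hi)),
        n = c(nrow(lo), nrow(hi))
      )
    }) |>
    dplyr::bind_rows()
  new_piecewise_fit(breakpoint, fits, data = data)
}

#' @rdname fit_piecewise
#' @param coefficients A tibble with columns `acuity`, `segment`
#'   (`"lower"`/`"upper"`), `intercept` and `slope`, for constructing a
#'   fit from known coefficients instead of data.
#' @export
piecewise_fit <- function(coefficients, breakpoint = 1.4) {
  needed <- c("acuity", "segment", "intercept", "slope")
  if (!is.data.frame(coefficients) || !all(needed %in% names(coefficients))) {
    abort("coefficients must have columns acuity, segment, intercept, slope")
  }
  if (!all(c("lower", "upper") %in% coefficients$segment)) {
    abort("coefficients must include a lower and an upper segment")
  }
  new_piecewise_fit(breakpoint, tibble::as_tibble(coefficients))
}

new_piecewise_fit <- function(breakpoint, coefficients, data = NULL) {
  wide <- tidyr::pivot_wider(
    coefficients[, c("acuity", "segment", "slope")],
    names_from = "segment", values_from = "slope"
  )
  if (any(wide$upper <= wide$lower)) {
    warn("upper-segment slope does not exceed the lower slope; no knee steepening")
  }
  structure(
    list(breakpoint = breakpoint, coefficients = coefficients, data = data),
    class = "ci_piecewise_fit"
  )
}

#' Predict the maximum CI at a growth ratio
#'
#' Evaluates the lower segment for `P <= P*` and the upper segment above.
#'
#' @param fit A `ci_piecewise_fit`.
#' @param growth_ratio Numeric vector of growth ratios, all `>= 1`.
#' @param level Acuity level to evaluate, required when the fit holds
#'   several.
#' @return Numeric vector of predicted maximum CI values.
#' @export
predict_max_ci <- function(fit, growth_ratio, level = NULL) {
  stopifnot(inherits(fit, "ci_piecewise_fit"))
  if (any(growth_ratio < 1)) abort("growth_ratio must be >= 1")
  cf <- fit$coefficients
  levels <- unique(cf$acuity)
  if (is.null(level)) {
    if (length(levels) > 1) {
      abort(paste0("fit holds several levels; pick one of: ",
                   paste(levels, collapse = ", ")))
    }
    level <- levels
  }
  if (!level %in% levels) abort(paste0("no fit for level ", level))
  lo <- cf[cf$acuity == level & cf$segment == "lower", ]
  hi <- cf[cf$acuity == level & cf$segment == "upper", ]
  ifelse(growth_ratio <= fit$breakpoint,
         lo$intercept + lo$slope * growth_ratio,
         hi$intercept + hi$slope * growth_ratio)
}

#' @export
predict.ci_piecewise_fit <- function(object, newdata, ...) {
  if (is.numeric(newdata)) {
    return(predict_max_ci(object, newdata))
  }
  purrr::pmap_dbl(
    newdata[, c("growth_ratio", intersect("acuity", names(newdata)))],
    function(growth_ratio, acuity = NULL) {
      predict_max_ci(object, growth_ratio, acuity)
    }
  )
}

#' @export
print.ci_piecewise_fit <- function(x, ...) {
  cat(sprintf("<ci_piecewise_fit> knee at P* = %.3g\n", x$breakpoint))
  print(x$coefficients, ...)
  invisible(x)
}

#' Tidy a piecewise max-CI fit
#'
#' @param x A `ci_piecewise_fit`.
#' @param ... Unused.
#' @return A tibble with one row per (level, segment, term) and an
#'   `estimate` column, in the broom style.
#' @method tidy ci_piecewise_fit
#' @export
tidy.ci_piecewise_fit <- function(x, ...) {
  x$coefficients |>
    tidyr::pivot_longer(c("intercept", "slope"),
                        names_to = "term", values_to = "estimate") |>
    dplyr::select(dplyr::any_of(c("acuity", "segment", "term", "estimate")))
}

#' @rdname tidy.ci_piecewise_fit
#' @return `glance()`: a one-row-per-level tibble with the breakpoint, the
#'   segment slopes and the jump `|lower(P*) - upper(P*)|` at the knee.
#' @method glance ci_piecewise_fit
#' @export
glance.ci_piecewise_fit <- function(x, ...) {
  cf <- x$coefficients
  cf |>
    dplyr::group_by(.data$acuity) |>
    dplyr::summarise(
      breakpoint = x$breakpoint,
      lower_slope = .data$slope[.data$segment == "lower"],
      upper_slope = .data$slope[.data$segment == "upper"],
      knee_jump = abs(
        (.data$intercept[.data$segment == "lower"] +
           .data$slope[.data$segment == "lower"] * x$breakpoint) -
          (.data$intercept[.data$segment == "upper"] +
             .data$slope[.data$segment == "upper"] * x$breakpoint)
      ),
      .groups = "drop"
    )
}
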