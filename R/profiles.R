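#' Arrival profiles
#'
#' An arrival profile gives, for each simulated day, the expected number of
#' non-urgent (AL3--AL5) arrivals at the modelled hospital together with a
#' phase label. Days are 1440-minute windows. A surge profile has exactly
#' two `lead` days at the normal rate, four `busy` days carrying the
#' earthquake casualty surge, and `recovery` days at the normal rate that
#' pad the horizon out to 12--20 days so the quality recovery curve is
#' fully observed.
#'
#' `normal_profile()` builds a constant profile (default 278 AL3--AL5
#' arrivals per day, the reference normal-day census). `seismic_profile()`
#' builds a surge profile for a patient growth ratio `P >= 1`, the ratio of
#' total patient visits (including the diverted urgent share) during the
#' four busy days to the normal volume over the same duration.
#'
#' For growth ratios 1.4 and 1.6 the busy-day AL3--AL5 totals are the
#' reference calibration tables (`366, 411, 334, 284` and
#' `449, 509, 371, 298`). For any other ratio the busy days are built by a
#' scaling rule: the expected surge excess of generated patients over the
#' busy phase, `(P - 1) * 4 * base / 0.90`, is spread over the four days in
#' proportion to the reference 1.6-ratio excess-over-normal shape and
#' converted to AL3--AL5 arrivals with the seismic-mix share 0.83, on top
#' of the normal base rate.
#'
#' @param n_days Number of days (`normal_profile`).
#' @param daily_al345_total Expected AL3--AL5 arrivals per normal day.
#' @return A tibble with columns `day` (1-based), `phase`
#'   (`lead`/`busy`/`recovery`), and `expected` (AL3--AL5 arrivals).
#' @examples
#' normal_profile(3)
#' seismic_profile(1.6)
#' @export
normal_profile <- function(n_days, daily_al345_total = 278) {
  if (!is.numeric(n_days) || length(n_days) != 1 || n_days < 1 ||
      n_days != floor(n_days)) {
    abort("n_days must be a positive integer")
  }
  if (!is.numeric(daily_al345_total) || length(daily_al345_total) != 1 ||
      daily_al345_total < 0) {
    abort("daily_al345_total must be a non-negative number")
  }
  tibble::tibble(
    day = seq_len(n_days),
    phase = "lead",
    expected = as.numeric(daily_al345_total)
  )
}

# reference busy-day AL3-AL5 totals for the two calibrated growth ratios
GR1_BUSY <- c(366, 411, 334, 284)
GR2_BUSY <- c(449, 509, 371, 298)
AL345_SHARE_NORMAL <- 0.90
AL345_SHARE_SEISMIC <- 0.83

#' @rdname normal_profile
#' @param growth_ratio Growth ratio `P >= 1`.
#' @param base Expected AL3--AL5 arrivals per normal day (default 278).
#' @param horizon_days Total days including 2 lead + 4 busy; default 12 for
#'   `P <= 1.6`, 16 for `P <= 1.9`, 20 beyond (longer surges need longer
#'   recovery tails).
#' @export
seismic_profile <- function(growth_ratio, base = 278, horizon_days = NULL) {
  if (!is.numeric(growth_ratio) || length(growth_ratio) != 1 ||
      growth_ratio < 1) {
    abort("growth_ratio must be a number >= 1")
  }
  if (is.null(horizon_days)) horizon_days <- default_horizon(growth_ratio)
  if (horizon_days < 6) abort("horizon_days must cover 2 lead + 4 busy days")
  busy <- busy_day_totals(growth_ratio, base)
  n_rec <- horizon_days - 6
  tibble::tibble(
    day = seq_len(horizon_days),
    phase = rep(c("lead", "busy", "recovery"), times = c(2, 4, n_rec)),
    expected = c(rep(base, 2), busy, rep(base, n_rec))
  )
}

default_horizon <- function(growth_ratio) {
  if (growth_ratio <= 1.6) 12L else if (growth_ratio <= 1.9) 16L else 20L
}

busy_day_totals <- function(growth_ratio, base = 278) {
  if (isTRUE(all.equal(growth_ratio, 1.4)) && base == 278) return(GR1_BUSY)
  if (isTRUE(all.equal(growth_ratio, 1.6)) && base == 278) return(GR2_BUSY)
  shape <- (GR2_BUSY - 278) / sum(GR2_BUSY - 278)
  excess_generated <- (growth_ratio - 1) * 4 * base / AL345_SHARE_NORMAL
  base + AL345_SHARE_SEISMIC * excess_generated * shape
}

validate_profile <- function(profile) {
  if (!is.data.frame(profile) ||
      !all(c("day", "phase", "expected") %in% names(profile))) {
    abort("arrival profile must have columns day, phase, expected")
  }
  if (any(profile$expected < 0)) abort("expected arrival counts must be >= 0")
  if (!all(profile$phase %in% c("lead", "busy", "recovery"))) {
    abort("phase must be one of lead/busy/recovery")
  }
  if (any(profile$phase == "busy")) {
    busy_days <- profile$day[profile$phase == "busy"]
    if (length(busy_days) != 4 || !identical(as.integer(busy_days), 3:6)) {
      abort("a surge profile must have exactly 4 busy days on days 3-6")
    }
  }
  invisible(profile)
}

validate_intraday_weights <- function(w) {
  if (is.null(w)) return(NULL)
  if (!is.numeric(w) || length(w) != 24 || any(w < 0) ||
      abs(sum(w) - 1) > 1e-9) {
    abort("intraday_weights must be 24 non-negative hourly weights summing to 1")
  }
  w
}

#' Generate arrival times from a profile
#'
#' Arrivals follow a non-homogeneous Poisson process: the number of
#' arrivals on day `d` is Poisson with mean `expected[d]`, placed within
#' the day either uniformly (default) or according to 24 hourly weights.
#'
#' @param profile A profile tibble from [normal_profile()] or
#'   [seismic_profile()].
#' @param intraday_weights Optional 24 non-negative hourly weights summing
#'   to 1; `NULL` (default) spreads arrivals uniformly within each day.
#' @return Sorted numeric vector of arrival times in minutes since the
#'   start of the simulation, all within `[0, 1440 * nrow(profile))`.
#' @examples
#' set.seed(1)
#' length(generate_arrival_times(normal_profile(1, 278)))
#' @export
generate_arrival_times <- function(profile, intraday_weights = NULL) {
  validate_profile(profile)
  w <- validate_intraday_weights(intraday_weights)
  counts <- rpois(nrow(profile), profile$expected)
  n <- sum(counts)
  if (n == 0) return(numeric(0))
  day0 <- rep(profile$day - 1, counts)
  if (is.null(w)) {
    offsets <- runif(n, 0, 1440)
  } else {
    hour <- sample.int(24, n, replace = TRUE, prob = w) - 1
    offsets <- hour * 60 + runif(n, 0, 60)
  }
  sort(day0 * 1440 + offsets)
}
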