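#' Daily Crowdedness Index
#'
#' The Crowdedness Index (CI) of acuity level `AL` on day `j` is the mean
#' door-to-doctor time of the level's patients arriving on day `j` and
#' eventually treated, divided by the level's advised maximum waiting time
#' (30/60/120 minutes for AL3/AL4/AL5). CI of 1 means patients waited, on
#' average, exactly as long as advised; above 1 the hospital fails to
#' treat in time. Patients are attributed to their arrival day even when
#' treated the next day; untreated (horizon-censored) and diverted
#' patients are excluded.
#'
#' @param patients Patient records from [simulate_replication()] (a
#'   `replication` column, if present, is kept as a grouping).
#' @param level Optional single level among AL3/AL4/AL5; with `day`,
#'   returns the scalar CI.
#' @param day Optional 1-based arrival day; with `level`, returns the
#'   scalar CI.
#' @return A tibble with columns `replication` (if present), `day`,
#'   `acuity`, `ci`, `n_treated`, `n_arrivals`; days with no treated
#'   patients of a level have `ci = NA` (never 0). If both `level` and
#'   `day` are given, the scalar CI.
#' @examples
#' pts <- tibble::tibble(
#'   acuity = "AL3", path = "P2", t0_arrival = 0,
#'   t3_treatment_start = 30, treated = TRUE
#' )
#' daily_ci(pts, level = "AL3", day = 1) # exactly 1
#' @export
daily_ci <- function(patients, level = NULL, day = NULL) {
  needed <- c("acuity", "t0_arrival", "t3_treatment_start")
  if (!all(needed %in% names(patients))) {
    abort("patients must have columns acuity, t0_arrival, t3_treatment_start")
  }
  if (!is.null(level) && !level %in% AL_TREATED) {
    abort("level must be one of AL3/AL4/AL5")
  }
  pts <- dplyr::mutate(
    patients,
    day = floor(.data$t0_arrival / 1440) + 1,
    wait = .data$t3_treatment_start - .data$t0_arrival,
    treated = if ("treated" %in% names(patients)) .data$treated
              else !is.na(.data$t3_treatment_start)
  )
  pts <- dplyr::filter(pts, .data$acuity %in% AL_TREATED)
  grp <- intersect(c("replication", "day", "acuity"), names(pts))
  tab <- pts |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      n_arrivals = dplyr::n(),
      n_treated = sum(.data$treated),
      ci = ifelse(
        sum(.data$treated) > 0,
        mean(.data$wait[.data$treated]) /
          unname(advised_max_wait(.data$acuity[1])),
        NA_real_
      ),
      .groups = "drop"
    ) |>
    dplyr::relocate(dplyr::all_of(grp), "ci", "n_treated", "n_arrivals")
  if (!is.null(level) && !is.null(day)) {
    hit <- tab$acuity == level & tab$day == day
    if (!any(hit)) return(NA_real_)
    return(tab$ci[hit][1])
  }
  if (!is.null(level)) tab <- dplyr::filter(tab, .data$acuity == level)
  if (!is.null(day)) tab <- dplyr::filter(tab, .data$day == day)
  tab
}

#' Care Quality from the Crowdedness Index
#'
#' Quality is the reciprocal of CI capped at 1: `Q = min(1 / CI, 1)`.
#' `Q = 1` means the hospital functions properly (patients treated within
#' the advised time on average); any value below 1 signals degraded
#' emergency care. A CI of 0 maps to full quality; missing CI propagates.
#'
#' @param ci Numeric vector of non-negative CI values (NA allowed).
#' @return Numeric vector of qualities in `(0, 1]`.
#' @examples
#' quality_from_ci(c(0.5, 2)) # 1.0, 0.5
#' @export
quality_from_ci <- function(ci) {
  if (any(ci < 0, na.rm = TRUE)) abort("ci must be non-negative")
  ifelse(is.na(ci), NA_real_, ifelse(ci <= 1, 1, 1 / ci))
}

#' Aggregate daily metrics across replications
#'
#' For each day and acuity level, the aggregated CI is the mean across
#' replications of the replication-level daily CI (replications with no
#' treated patients of that level on that day are skipped for that cell),
#' and Quality is computed from the aggregated CI. This mirrors averaging
#' the daily crowding curves of many independent simulated hospitals.
#'
#' @param patients Combined patient records of one or more replications
#'   (must carry a `replication` column for more than one).
#' @param horizon_days Number of days the output must span; days with no
#'   arrivals appear with `NA` CI.
#' @return A tibble with columns `day`, `acuity`, `ci_mean`, `ci_sd`
#'   (across replications), `q`, `n_treated`, `n_arrivals` (per-replication
#'   means), `n_reps` (replications contributing a defined CI).
#' @export
aggregate_daily <- function(patients, horizon_days = NULL) {
  if (!is.data.frame(patients) || nrow(patients) == 0) {
    abort("patients must be a non-empty data frame of patient records")
  }
  per_rep <- daily_ci(patients)
  if (!"replication" %in% names(per_rep)) {
    per_rep$replication <- 1L
  }
  if (is.null(horizon_days)) horizon_days <- max(per_rep$day)
  grid <- tidyr::expand_grid(
    day = seq_len(horizon_days),
    acuity = AL_TREATED
  )
  agg <- per_rep |>
    dplyr::group_by(.data$day, .data$acuity) |>
    dplyr::summarise(
      ci_mean = if (all(is.na(.data$ci))) NA_real_
                else mean(.data$ci, na.rm = TRUE),
      ci_sd = stats::sd(.data$ci[!is.na(.data$ci)]),
      n_treated = mean(.data$n_treated),
      n_arrivals = mean(.data$n_arrivals),
      n_reps = sum(!is.na(.data$ci)),
      .groups = "drop"
    )
  grid |>
    dplyr::left_join(agg, by = c("day", "acuity")) |>
    dplyr::mutate(
      n_reps = dplyr::coalesce(.data$n_reps, 0L),
      q = quality_from_ci(.data$ci_mean)
    ) |>
    dplyr::relocate("day", "acuity", "ci_mean", "ci_sd", "q")
}

#' Maximum Crowdedness Index over the horizon
#'
#' @param metrics A daily-metrics tibble from [aggregate_daily()] (or any
#'   tibble with `day`, `acuity` and a `ci_mean` or `ci` column).
#' @param level One of AL3/AL4/AL5, or `NULL` for all three.
#' @return The maximum CI over days (missing days ignored); a named vector
#'   over levels when `level` is `NULL`.
#' @export
max_ci <- function(metrics, level = NULL) {
  col <- if ("ci_mean" %in% names(metrics)) "ci_mean" else "ci"
  if (!all(c("day", "acuity", col) %in% names(metrics))) {
    abort("metrics must have day, acuity and ci_mean (or ci) columns")
  }
  levels <- if (is.null(level)) AL_TREATED else level
  if (!all(levels %in% AL_TREATED)) abort("level must be among AL3/AL4/AL5")
  out <- vapply(levels, function(lev) {
    x <- metrics[[col]][metrics$acuity == lev]
    x <- x[!is.na(x)]
    if (length(x) == 0) {
      abort(sprintf("no defined CI values for level %s", lev))
    }
    max(x)
  }, numeric(1))
  if (is.null(level)) out else unname(out)
}

#' Recovery duration: number of quality-impaired days
#'
#' Counts the days on which any acuity level's Quality falls below 1, at
#' full precision (a day with Q = 0.999 is impaired). For a surge
#' scenario this equals the length of the quality drop-and-restoration
#' period; a hospital that always treats within the advised times scores
#' 0.
#'
#' @param metrics A tibble with columns `day`, `acuity` and `q` (e.g. from
#'   [aggregate_daily()], or quality columns of an external table pivoted
#'   long). Missing `q` values are ignored.
#' @return Integer number of impaired days.
#' @examples
#' recovery_duration(tibble::tibble(
#'   day = c(1, 1, 2, 2), acuity = "AL3", q = c(1, 1, 0.9, 1)
#' ))
#' @export
recovery_duration <- function(metrics) {
  if (!all(c("day", "q") %in% names(metrics))) {
    abort("metrics must have day and q columns")
  }
  impaired <- metrics |>
    dplyr::group_by(.data$day) |>
    dplyr::summarise(
      impaired = any(.data$q < 1, na.rm = TRUE), .groups = "drop"
    )
  sum(impaired$impaired)
}

#' Score an external patient event log
#'
#' Computes daily metrics, per-level maximum CI and the recovery duration
#' from an event-log CSV (or an equivalent data frame) with columns
#' `replication`, `patient_id`, `acuity`, `path`, `t0_arrival`,
#' `t3_treatment_start`, `depart_time`, `arrival_day`, `censored_flag`
#' (times in minutes). Rows with a missing treatment start (including all
#' diverted patients) count as untreated; `censored_flag` is
#' informational.
#'
#' @param events Path to a CSV file, or a data frame.
#' @param horizon_days Optional horizon override (defaults to the last
#'   arrival day present).
#' @return A list with `daily` (the aggregated metrics tibble), `max_ci`
#'   (named per level) and `recovery_days`.
#' @export
score_event_log <- function(events, horizon_days = NULL) {
  if (is.character(events)) {
    events <- readr::read_csv(events, show_col_types = FALSE)
  }
  needed <- c("acuity", "t0_arrival", "t3_treatment_start")
  if (!all(needed %in% names(events))) {
    abort(paste0("event log must have columns: ",
                 paste(needed, collapse = ", ")))
  }
  if (!"treated" %in% names(events)) {
    events$treated <- !is.na(events$t3_treatment_start)
  }
  daily <- aggregate_daily(events, horizon_days)
  list(
    daily = daily,
    max_ci = setNames(
      vapply(AL_TREATED, function(l) max_ci(daily, l), numeric(1)),
      AL_TREATED
    ),
    recovery_days = recovery_duration(daily)
  )
}
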