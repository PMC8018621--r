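#' Scenario configuration
#'
#' A scenario bundles everything one simulation run needs: the arrival
#' profile, the per-phase patient mixes (normal mix on lead/recovery days,
#' seismic mix on busy days), the path-assignment table, station
#' capacities, service-time distributions, the replication count and the
#' master seed.
#'
#' @param name Scenario label.
#' @param growth_ratio Growth ratio `P >= 1`; `P = 1` yields a pure
#'   normal-operations scenario.
#' @param daily_total Expected AL3--AL5 arrivals per normal day.
#' @param horizon_days Total simulated days; defaults to 12 for
#'   `P <= 1.6`, 16 for `P <= 1.9`, 20 beyond.
#' @param busy_day_totals Optional length-4 override of the busy-day
#'   AL3--AL5 totals.
#' @param normal_mix,seismic_mix Named acuity proportions (see
#'   [patient_mix()]).
#' @param paths Path-assignment table (see [path_table()]).
#' @param stations A [station_set()].
#' @param service_times A [service_config()].
#' @param replications Number of independent replications (default 300).
#' @param seed Master seed; each replication uses an independently derived
#'   RNG substream.
#' @param intraday_weights Optional 24 hourly arrival weights; `NULL`
#'   spreads arrivals uniformly within each day.
#' @return A validated `scenario_config` object.
#' @examples
#' scenario_config(growth_ratio = 1.6)
#' builtin_scenario("GR1")
#' @export
scenario_config <- function(name = NULL,
                            growth_ratio = 1,
                            daily_total = 278,
                            horizon_days = NULL,
                            busy_day_totals = NULL,
                            normal_mix = patient_mix("normal"),
                            seismic_mix = patient_mix("seismic"),
                            paths = path_table(),
                            stations = station_set(),
                            service_times = service_config(),
                            replications = 300L,
                            seed = 1L,
                            intraday_weights = NULL) {
  if (!is.numeric(growth_ratio) || length(growth_ratio) != 1 ||
      growth_ratio < 1) {
    abort("growth_ratio must be a number >= 1")
  }
  if (!is.numeric(daily_total) || daily_total <= 0) {
    abort("daily_total must be a positive number")
  }
  if (!is.numeric(replications) || replications < 1 ||
      replications != floor(replications)) {
    abort("replications must be a positive integer")
  }
  if (is.null(horizon_days)) {
    horizon_days <- if (growth_ratio > 1) default_horizon(growth_ratio) else 12L
  }
  if (!is.numeric(horizon_days) || horizon_days < 6 ||
      horizon_days != floor(horizon_days)) {
    abort("horizon_days must be an integer >= 6 (2 lead + 4 busy days)")
  }
  normal_mix <- validate_mix(normal_mix, "normal_mix")
  seismic_mix <- validate_mix(seismic_mix, "seismic_mix")
  paths <- validate_path_table(paths)
  if (!inherits(stations, "station_set")) {
    abort("stations must be a station_set()")
  }
  if (!inherits(service_times, "service_config")) {
    abort("service_times must be a service_config()")
  }
  intraday_weights <- validate_intraday_weights(intraday_weights)

  if (growth_ratio > 1) {
    profile <- seismic_profile(growth_ratio, base = daily_total,
                               horizon_days = horizon_days)
    if (!is.null(busy_day_totals)) {
      if (length(busy_day_totals) != 4 || any(busy_day_totals < 0)) {
        abort("busy_day_totals must be 4 non-negative daily totals")
      }
      profile$expected[profile$phase == "busy"] <- as.numeric(busy_day_totals)
    }
  } else {
    profile <- normal_profile(horizon_days, daily_total)
  }
  if (is.null(name)) {
    name <- if (growth_ratio > 1) sprintf("GR%.2g", growth_ratio) else "normal"
  }
  structure(
    list(
      name = name, growth_ratio = growth_ratio, daily_total = daily_total,
      horizon_days = as.integer(horizon_days), profile = profile,
      normal_mix = normal_mix, seismic_mix = seismic_mix, paths = paths,
      stations = stations, service_times = service_times,
      replications = as.integer(replications), seed = as.integer(seed),
      intraday_weights = intraday_weights
    ),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    "<scenario_config> %s: growth ratio %.2f, %d days, %d replications, seed %d\n",
    x$name, x$growth_ratio, x$horizon_days, x$replications, x$seed
  ))
  busy <- x$profile$expected[x$profile$phase == "busy"]
  if (length(busy) > 0) {
    cat("  busy-day AL3-AL5 totals:", paste(round(busy, 1), collapse = ", "), "\n")
  } else {
    cat("  constant", x$daily_total, "AL3-AL5 arrivals/day\n")
  }
  invisible(x)
}

BUILTIN_RATIOS <- c(normal = 1, GR1 = 1.4, GR2 = 1.6, GR3 = 1.9, GR4 = 2.3)

#' @rdname scenario_config
#' @param scenario One of `"normal"`, `"GR1"` (P = 1.4), `"GR2"` (1.6),
#'   `"GR3"` (1.9), `"GR4"` (2.3).
#' @param ... Overrides passed on to [scenario_config()].
#' @export
builtin_scenario <- function(scenario = names(BUILTIN_RATIOS), ...) {
  scenario <- match.arg(scenario)
  scenario_config(name = scenario,
                  growth_ratio = unname(BUILTIN_RATIOS[scenario]), ...)
}

SCENARIO_KEYS <- c(
  "name", "growth_ratio", "daily_total", "horizon_days", "busy_day_totals",
  "normal_mix", "seismic_mix", "path_table", "capacities", "service_times",
  "replications", "seed", "intraday_weights"
)

#' Load a scenario configuration from YAML or JSON
#'
#' Reads a scenario file, fills unspecified keys with the reference
#' defaults, validates every invariant and rejects unknown keys. Recognised
#' keys: `name`, `growth_ratio`, `daily_total`, `horizon_days`,
#' `busy_day_totals`, `normal_mix`, `seismic_mix`, `path_table` (rows per
#' acuity of path probabilities), `capacities` (per service kind; `"Inf"`
#' allowed), `service_times` (per service kind:
#' `{family, shape, scale}` or `{family, min, mode, max}`), `replications`,
#' `seed`, `intraday_weights`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `scenario_config`.
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) abort(paste0("scenario file not found: ", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(raw)) abort("scenario file must contain a mapping of keys")
  unknown <- setdiff(names(raw), SCENARIO_KEYS)
  if (length(unknown) > 0) {
    abort(paste0("unknown scenario keys: ", paste(unknown, collapse = ", ")))
  }
  args <- list()
  for (key in c("name", "growth_ratio", "daily_total", "horizon_days",
                "busy_day_totals", "replications", "seed",
                "intraday_weights")) {
    if (!is.null(raw[[key]])) args[[key]] <- raw[[key]]
  }
  if (!is.null(raw$normal_mix)) args$normal_mix <- unlist(raw$normal_mix)
  if (!is.null(raw$seismic_mix)) args$seismic_mix <- unlist(raw$seismic_mix)
  if (!is.null(raw$path_table)) {
    pt <- raw$path_table
    if (is.data.frame(pt)) {
      args$paths <- tibble::as_tibble(pt)
    } else {
      args$paths <- tibble::tibble(
        acuity = names(pt),
        P1 = purrr::map_dbl(pt, ~ .x$P1 %||% 0),
        P2 = purrr::map_dbl(pt, ~ .x$P2 %||% 0),
        P3 = purrr::map_dbl(pt, ~ .x$P3 %||% 0),
        P4 = purrr::map_dbl(pt, ~ .x$P4 %||% 0)
      )
    }
  }
  if (!is.null(raw$capacities)) {
    caps <- lapply(raw$capacities, function(k) {
      if (identical(k, "Inf") || identical(k, ".inf")) Inf else k
    })
    unknown_caps <- setdiff(names(caps), SERVICE_KINDS)
    if (length(unknown_caps) > 0) {
      abort(paste0("capacities: unknown service kind: ",
                   paste(unknown_caps, collapse = ", ")))
    }
    args$stations <- do.call(station_set, caps)
  }
  if (!is.null(raw$service_times)) {
    st <- raw$service_times
    unknown_st <- setdiff(names(st), SERVICE_KINDS)
    if (length(unknown_st) > 0) {
      abort(paste0("service_times: unknown service kind: ",
                   paste(unknown_st, collapse = ", ")))
    }
    specs <- lapply(st, parse_dist_spec)
    defaults <- service_config()
    for (kind in SERVICE_KINDS) {
      if (is.null(specs[[kind]])) specs[[kind]] <- defaults[[kind]]
    }
    args$service_times <- do.call(service_config, specs[SERVICE_KINDS])
  }
  do.call(scenario_config, args)
}

parse_dist_spec <- function(spec) {
  if (is.null(spec$family)) {
    abort("each service_times entry needs a 'family' (gamma or triangular)")
  }
  switch(spec$family,
    gamma = dist_gamma(spec$shape, spec$scale),
    triangular = dist_triangular(spec$min, spec$mode, spec$max),
    abort(paste0("unknown service-time family: ", spec$family))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
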