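#' Run a replicated scenario experiment
#'
#' Runs `scenario$replications` independent replications (each on its own
#' derived RNG substream of the master seed, so the full experiment is
#' deterministic given the configuration and seed), aggregates daily
#' metrics across replications, and summarises the maximum CI per level
#' and the recovery duration. A warning is emitted if more than 0.1% of
#' in-hospital patients are horizon-censored; with the default horizons
#' (12--20 days) censoring is negligible.
#'
#' @param scenario A [scenario_config()].
#' @param replications,seed Optional overrides of the scenario's values.
#' @param keep_events Keep the combined patient event log in the result
#'   (memory-heavy for large runs; default `FALSE`).
#' @param progress Print a progress line every 50 replications.
#' @return A `surge_experiment` object: a list with `scenario`, `daily`
#'   (the [aggregate_daily()] tibble), `max_ci` (named per level),
#'   `max_ci_of_rep_max` (mean-of-per-replication-maxima variant),
#'   `recovery_days`, `replications`, `seed`, `elapsed_secs` and
#'   optionally `events`.
#' @examples
#' sc <- builtin_scenario("normal", replications = 2, seed = 7)
#' res <- run_experiment(sc)
#' glance(res)
#' @export
run_experiment <- function(scenario, replications = NULL, seed = NULL,
                           keep_events = FALSE, progress = FALSE) {
  stopifnot(inherits(scenario, "scenario_config"))
  if (!is.null(replications)) scenario$replications <- as.integer(replications)
  if (!is.null(seed)) scenario$seed <- as.integer(seed)
  t_start <- proc.time()[["elapsed"]]
  streams <- replication_streams(scenario$seed, scenario$replications)
  reps <- vector("list", scenario$replications)
  for (r in seq_len(scenario$replications)) {
    reps[[r]] <- simulate_replication(scenario, replication = r,
                                      rng_state = streams[[r]])
    if (progress && r %% 50 == 0) {
      message(sprintf("  replication %d/%d", r, scenario$replications))
    }
  }
  events <- dplyr::bind_rows(reps)
  inside <- events$path != "P4"
  cens_frac <- if (any(inside)) mean(!events$treated[inside]) else 0
  if (cens_frac > 0.001) {
    warn(sprintf(
      "%.2f%% of in-hospital patients untreated at horizon end; consider a longer horizon",
      100 * cens_frac
    ))
  }
  daily <- aggregate_daily(events, scenario$horizon_days)
  per_rep <- daily_ci(events)
  rep_max <- per_rep |>
    dplyr::filter(!is.na(.data$ci)) |>
    dplyr::group_by(.data$replication, .data$acuity) |>
    dplyr::summarise(m = max(.data$ci), .groups = "drop") |>
    dplyr::group_by(.data$acuity) |>
    dplyr::summarise(m = mean(.data$m), .groups = "drop")
  structure(
    list(
      scenario = scenario,
      daily = daily,
      max_ci = setNames(
        vapply(AL_TREATED, function(l) max_ci(daily, l), numeric(1)),
        AL_TREATED
      ),
      max_ci_of_rep_max = setNames(
        rep_max$m[match(AL_TREATED, rep_max$acuity)], AL_TREATED
      ),
      recovery_days = recovery_duration(daily),
      replications = scenario$replications,
      seed = scenario$seed,
      n_patients = nrow(events),
      censored_fraction = cens_frac,
      elapsed_secs = proc.time()[["elapsed"]] - t_start,
      events = if (keep_events) events else NULL
    ),
    class = "surge_experiment"
  )
}

#' @export
print.surge_experiment <- function(x, ...) {
  cat(sprintf(
    "<surge_experiment> %s (P = %.2f): %d replications, seed %d, %.1fs\n",
    x$scenario$name, x$scenario$growth_ratio, x$replications, x$seed,
    x$elapsed_secs
  ))
  cat("  max CI:",
      paste(sprintf("%s %.2f", AL_TREATED, x$max_ci), collapse = ", "), "\n")
  cat("  recovery duration:", x$recovery_days, "impaired day(s)\n")
  invisible(x)
}

#' Tidy and summarise an experiment
#'
#' @param x A `surge_experiment`.
#' @param ... Unused.
#' @return `tidy()`: the daily metrics tibble with the scenario name and
#'   growth ratio attached. `glance()`: a one-row tibble with the headline
#'   results.
#' @method tidy surge_experiment
#' @export
tidy.surge_experiment <- function(x, ...) {
  dplyr::mutate(x$daily, scenario = x$scenario$name,
                growth_ratio = x$scenario$growth_ratio, .before = 1)
}

#' @rdname tidy.surge_experiment
#' @method glance surge_experiment
#' @export
glance.surge_experiment <- function(x, ...) {
  tibble::tibble(
    scenario = x$scenario$name,
    growth_ratio = x$scenario$growth_ratio,
    replications = x$replications,
    seed = x$seed,
    horizon_days = x$scenario$horizon_days,
    max_ci_al3 = x$max_ci[["AL3"]],
    max_ci_al4 = x$max_ci[["AL4"]],
    max_ci_al5 = x$max_ci[["AL5"]],
    recovery_days = x$recovery_days,
    n_patients = x$n_patients,
    censored_fraction = x$censored_fraction
  )
}

#' Sweep growth ratios and fit the piecewise response
#'
#' Runs one experiment per growth ratio and fits, per acuity level, the
#' two-segment linear model of maximum CI versus growth ratio.
#'
#' @param growth_ratios Numeric vector including at least 2 values at or
#'   below the breakpoint and 2 at or above it.
#' @param base_scenario Scenario whose settings (mixes, capacities,
#'   service times, replications, seed) are reused at every ratio; its
#'   growth ratio and horizon are replaced per run.
#' @param breakpoint Knee for the piecewise fit (default 1.4).
#' @param progress Print one line per completed scenario.
#' @return A `surge_sweep` list: `results` (one `surge_experiment` per
#'   ratio), `points` (tibble of growth ratio, level, max CI), `fit` (a
#'   `ci_piecewise_fit` over all levels).
#' @export
run_sweep <- function(growth_ratios, base_scenario = scenario_config(),
                      breakpoint = 1.4, progress = FALSE) {
  if (sum(growth_ratios <= breakpoint) < 2 ||
      sum(growth_ratios >= breakpoint) < 2) {
    abort("growth_ratios must include 2 values on each side of the breakpoint")
  }
  results <- purrr::map(growth_ratios, function(p) {
    sc <- scenario_config(
      growth_ratio = p,
      daily_total = base_scenario$daily_total,
      normal_mix = base_scenario$normal_mix,
      seismic_mix = base_scenario$seismic_mix,
      paths = base_scenario$paths,
      stations = base_scenario$stations,
      service_times = base_scenario$service_times,
      replications = base_scenario$replications,
      seed = base_scenario$seed,
      intraday_weights = base_scenario$intraday_weights
    )
    if (progress) message(sprintf("running %s ...", sc$name))
    run_experiment(sc)
  })
  points <- purrr::map_dfr(results, function(res) {
    tibble::tibble(
      scenario = res$scenario$name,
      growth_ratio = res$scenario$growth_ratio,
      acuity = AL_TREATED,
      max_ci = unname(res$max_ci)
    )
  })
  fit <- fit_piecewise(points, breakpoint = breakpoint)
  structure(list(results = results, points = points, fit = fit),
            class = "surge_sweep")
}

#' @export
print.surge_sweep <- function(x, ...) {
  cat(sprintf("<surge_sweep> %d scenarios\n", length(x$results)))
  print(x$fit)
  invisible(x)
}

#' Write experiment outputs to a directory
#'
#' Writes `daily_metrics.csv` (day, level, CI mean and SD across
#' replications, quality, treated and arrival counts), `summary.json`
#' (maximum CI per level under both aggregation variants, recovery days,
#' seed, replication count) and `manifest.json` (a configuration echo
#' sufficient to re-run the experiment). If the experiment kept its event
#' log, `events.csv` is written too.
#'
#' @param result A `surge_experiment`.
#' @param out_dir Output directory (created if needed).
#' @param events Write the patient event log when available.
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(result, out_dir, events = TRUE) {
  stopifnot(inherits(result, "surge_experiment"))
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok || file.access(out_dir, mode = 2) != 0) {
    abort(paste0("cannot write to output directory: ", out_dir))
  }
  paths <- character(0)

  daily_path <- file.path(out_dir, "daily_metrics.csv")
  readr::write_csv(
    dplyr::transmute(
      result$daily,
      day = .data$day, level = .data$acuity,
      ci_mean = .data$ci_mean, ci_sd_across_reps = .data$ci_sd,
      q = .data$q, n_treated = .data$n_treated,
      n_arrivals = .data$n_arrivals
    ),
    daily_path
  )
  paths <- c(paths, daily_path)

  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(
    list(
      scenario = result$scenario$name,
      growth_ratio = result$scenario$growth_ratio,
      replications = result$replications,
      seed = result$seed,
      horizon_days = result$scenario$horizon_days,
      max_ci = as.list(result$max_ci),
      max_ci_of_rep_max = as.list(result$max_ci_of_rep_max),
      recovery_days = result$recovery_days,
      n_patients = result$n_patients,
      censored_fraction = result$censored_fraction
    ),
    summary_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  paths <- c(paths, summary_path)

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    scenario_manifest(result$scenario, result),
    manifest_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  paths <- c(paths, manifest_path)

  if (events && !is.null(result$events)) {
    events_path <- file.path(out_dir, "events.csv")
    readr::write_csv(
      dplyr::transmute(
        result$events,
        replication = .data$replication, patient_id = .data$patient_id,
        acuity = .data$acuity, path = .data$path,
        t0_arrival = .data$t0_arrival,
        t3_treatment_start = ifelse(.data$treated,
                                    .data$t3_treatment_start, NA_real_),
        depart_time = .data$depart_time,
        arrival_day = .data$arrival_day + 1,
        censored_flag = .data$censored
      ),
      events_path
    )
    paths <- c(paths, events_path)
  }
  invisible(paths)
}

scenario_manifest <- function(sc, result = NULL) {
  list(
    package_version = as.character(utils::packageVersion("edsurge")),
    name = sc$name,
    growth_ratio = sc$growth_ratio,
    daily_total = sc$daily_total,
    horizon_days = sc$horizon_days,
    busy_day_totals = sc$profile$expected[sc$profile$phase == "busy"],
    normal_mix = as.list(sc$normal_mix),
    seismic_mix = as.list(sc$seismic_mix),
    path_table = sc$paths,
    capacities = lapply(unclass(sc$stations), function(k) {
      if (is.infinite(k)) "Inf" else k
    }),
    service_times = lapply(unclass(sc$service_times), unclass),
    replications = sc$replications,
    seed = sc$seed,
    intraday_weights = sc$intraday_weights,
    elapsed_secs = if (!is.null(result)) result$elapsed_secs else NULL
  )
}
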