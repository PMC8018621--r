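#' Serve a FIFO queue with a fixed number of identical servers
#'
#' Core queueing primitive of the simulator: patients enter a station's
#' queue at known times and are served first-in-first-out by `capacity`
#' identical servers (no acuity priority, no preemption). With unbounded
#' capacity service starts at entry.
#'
#' @param entry Non-decreasing numeric vector of queue-entry times
#'   (minutes).
#' @param service Numeric vector of service durations (minutes).
#' @param capacity Positive integer number of servers, or `Inf`.
#' @return Numeric vector of service start times; service ends at
#'   `start + service`.
#' @examples
#' fifo_serve(c(0, 1), c(3, 3), capacity = 1) # second waits until 3
#' @export
fifo_serve <- function(entry, service, capacity) {
  if (length(entry) != length(service)) {
    abort("entry and service must have the same length")
  }
  if (length(entry) == 0) return(numeric(0))
  if (is.infinite(capacity)) return(as.numeric(entry))
  fifo_serve_cpp(as.numeric(entry), as.numeric(service),
                 as.integer(capacity))
}

#' Assign acuity levels and flow paths to arriving patients
#'
#' Draws each patient's acuity level from the given mix and the
#' in-hospital path from that level's row of the path table, so the joint
#' law of (acuity, path) is the product of the two. Urgent (AL12) patients
#' always map to the diversion path P4.
#'
#' @param n Number of patients.
#' @param mix Named acuity proportions summing to 1 (see [patient_mix()]).
#' @param paths Path table (see [path_table()]).
#' @return A tibble with columns `acuity` and `path`.
#' @examples
#' set.seed(1)
#' table(assign_acuity_and_path(1000, patient_mix("normal"))$path)
#' @export
assign_acuity_and_path <- function(n, mix, paths = path_table()) {
  mix <- validate_mix(mix)
  paths <- validate_path_table(paths)
  if (n == 0) return(tibble::tibble(acuity = character(), path = character()))
  acuity <- AL_ALL[sample.int(4L, n, replace = TRUE, prob = mix[AL_ALL])]
  pm <- as.matrix(paths[, PATHS])
  rownames(pm) <- paths$acuity
  path <- character(n)
  for (lev in AL_ALL) {
    idx <- which(acuity == lev)
    if (length(idx) == 0) next
    path[idx] <- PATHS[sample.int(4L, length(idx), replace = TRUE,
                                  prob = pm[lev, ])]
  }
  tibble::tibble(acuity = acuity, path = path)
}

#' Route patients through the hospital stations
#'
#' Given arrivals with assigned acuity and path, computes every station
#' entry/exit time under FIFO queueing with the configured capacities.
#' The station sequences are: P1 triage, consultation, depart; P2 triage,
#' consultation, observation, depart; P3 triage, consultation, lab,
#' observation, depart; P4 diverted at generation (no in-hospital
#' timestamps). Treatment starts when consultation begins (`t3`); a
#' patient's waiting time `t3 - t0` therefore spans the triage queue,
#' triage service and the consultation queue (door-to-doctor time).
#'
#' This is the deterministic-given-draws core of [simulate_replication()];
#' calling it directly is useful for hand-traceable schedules and for
#' scoring externally supplied arrival sets.
#'
#' @param arrivals A data frame with columns `arrival_time` (minutes),
#'   `acuity` and `path`.
#' @param stations A [station_set()].
#' @param service_times A [service_config()].
#' @param horizon_end Simulation horizon in minutes; patients whose
#'   treatment has not started before the horizon are marked untreated
#'   (`treated = FALSE`), and patients still in-system are `censored`.
#'   Default `Inf` disables censoring.
#' @return A tibble, one row per patient, with arrival/station/departure
#'   timestamps in minutes (`NA` where a station is not on the path).
#' @export
simulate_patient_flow <- function(arrivals, stations = station_set(),
                                  service_times = service_config(),
                                  horizon_end = Inf) {
  if (!is.data.frame(arrivals) ||
      !all(c("arrival_time", "acuity", "path") %in% names(arrivals))) {
    abort("arrivals must have columns arrival_time, acuity, path")
  }
  n <- nrow(arrivals)
  ord <- order(arrivals$arrival_time)
  arrivals <- arrivals[ord, , drop = FALSE]
  out <- tibble::tibble(
    patient_id = seq_len(n),
    acuity = as.character(arrivals$acuity),
    path = as.character(arrivals$path),
    t0_arrival = as.numeric(arrivals$arrival_time),
    arrival_day = floor(as.numeric(arrivals$arrival_time) / 1440),
    t1_triage_start = NA_real_, t2_triage_end = NA_real_,
    t3_treatment_start = NA_real_, t4_treatment_end = NA_real_,
    t5_lab_start = NA_real_, t6_lab_end = NA_real_,
    t7_obs_start = NA_real_, t8_obs_end = NA_real_,
    depart_time = NA_real_
  )
  inside <- out$path != "P4"
  if (any(inside)) {
    # triage: all in-hospital patients, FIFO by arrival
    idx <- which(inside)
    tri_svc <- sample_service_time("triage", service_times, length(idx))
    tri_start <- fifo_serve(out$t0_arrival[idx], tri_svc, stations$triage)
    out$t1_triage_start[idx] <- tri_start
    out$t2_triage_end[idx] <- tri_start + tri_svc

    # consultation: FIFO by triage completion
    con_entry <- out$t2_triage_end[idx]
    oc <- idx[order(con_entry)]
    con_svc <- sample_service_time("consultation", service_times, length(oc))
    con_start <- fifo_serve(out$t2_triage_end[oc], con_svc,
                            stations$consultation)
    out$t3_treatment_start[oc] <- con_start
    out$t4_treatment_end[oc] <- con_start + con_svc

    # lab/imaging: P3 only, FIFO by consultation completion
    p3 <- which(out$path == "P3")
    if (length(p3) > 0) {
      ol <- p3[order(out$t4_treatment_end[p3])]
      lab_svc <- sample_service_time("lab", service_times, length(ol))
      lab_start <- fifo_serve(out$t4_treatment_end[ol], lab_svc, stations$lab)
      out$t5_lab_start[ol] <- lab_start
      out$t6_lab_end[ol] <- lab_start + lab_svc
    }

    # observation: P2 after consultation, P3 after lab
    p2 <- which(out$path == "P2")
    obs_idx <- c(p2, p3)
    if (length(obs_idx) > 0) {
      obs_entry <- c(out$t4_treatment_end[p2], out$t6_lab_end[p3])
      oo <- order(obs_entry)
      obs_svc <- sample_service_time("observation", service_times,
                                     length(obs_idx))
      obs_start <- fifo_serve(obs_entry[oo], obs_svc[oo],
                              stations$observation)
      out$t7_obs_start[obs_idx[oo]] <- obs_start
      out$t8_obs_end[obs_idx[oo]] <- obs_start + obs_svc[oo]
    }

    out$depart_time <- dplyr::case_when(
      out$path == "P1" ~ out$t4_treatment_end,
      out$path %in% c("P2", "P3") ~ out$t8_obs_end,
      TRUE ~ NA_real_
    )
  }
  out$treated <- inside & !is.na(out$t3_treatment_start) &
    out$t3_treatment_start < horizon_end
  out$censored <- inside &
    (!out$treated | (!is.na(out$depart_time) & out$depart_time > horizon_end))
  out
}

#' Simulate one replication of a scenario
#'
#' Generates arrivals from the scenario's profile (non-homogeneous Poisson
#' process), assigns acuity and path with the phase-appropriate mix
#' (normal mix on lead/recovery days, seismic mix on busy days), and
#' routes the in-hospital patients through the stations. Diverted (P4)
#' patients appear in the output with arrival data only; they consume no
#' resources of the modelled hospital but count towards the growth-ratio
#' patient total.
#'
#' The profile's daily expectations are AL3--AL5 arrivals; the total
#' number of generated patients on a day is Poisson with mean
#' `expected / (1 - AL12 share)` of that day's mix, so the AL3--AL5
#' arrival count has the configured mean by thinning.
#'
#' @param scenario A [scenario_config()].
#' @param seed Optional integer seed for this replication (defaults to the
#'   scenario master seed). Used via an isolated RNG state.
#' @param replication Replication index recorded in the output.
#' @param rng_state Internal: a full L'Ecuyer-CMRG `.Random.seed` state
#'   vector for substream execution (overrides `seed`).
#' @return A tibble of patient records (see [simulate_patient_flow()])
#'   with `replication` and `patient_id` columns; attribute
#'   `horizon_end` holds the horizon in minutes.
#' @examples
#' sc <- builtin_scenario("normal", replications = 1)
#' rep1 <- simulate_replication(sc, seed = 42)
#' mean(waiting_time(dplyr::filter(rep1, treated)))
#' @export
simulate_replication <- function(scenario, seed = NULL, replication = 1L,
                                 rng_state = NULL) {
  stopifnot(inherits(scenario, "scenario_config"))
  run <- function() {
    phase <- scenario$profile$phase
    mixes <- list(
      lead = scenario$normal_mix, recovery = scenario$normal_mix,
      busy = scenario$seismic_mix
    )
    share <- vapply(phase, function(p) 1 - mixes[[p]][["AL12"]], numeric(1))
    total_profile <- scenario$profile
    total_profile$expected <- total_profile$expected / share

    arrival_time <- generate_arrival_times(total_profile,
                                           scenario$intraday_weights)
    day <- pmin(floor(arrival_time / 1440) + 1, nrow(scenario$profile))
    acuity <- character(length(arrival_time))
    path <- character(length(arrival_time))
    for (ph in unique(phase)) {
      idx <- which(phase[day] == ph)
      if (length(idx) == 0) next
      drawn <- assign_acuity_and_path(length(idx), mixes[[ph]],
                                      scenario$paths)
      acuity[idx] <- drawn$acuity
      path[idx] <- drawn$path
    }
    simulate_patient_flow(
      tibble::tibble(arrival_time = arrival_time, acuity = acuity,
                     path = path),
      stations = scenario$stations,
      service_times = scenario$service_times,
      horizon_end = scenario$horizon_days * 1440
    )
  }
  res <- if (!is.null(rng_state)) {
    with_rng_state(rng_state, run())
  } else {
    with_preserved_rng({
      set.seed(if (is.null(seed)) scenario$seed else seed)
      run()
    })
  }
  res <- tibble::add_column(res, replication = as.integer(replication),
                            .before = 1)
  attr(res, "horizon_end") <- scenario$horizon_days * 1440
  res
}

#' Door-to-doctor waiting time
#'
#' The interval from a patient's arrival (`t0`) to the start of treatment
#' (`t3`), spanning the triage queue, triage service and the consultation
#' queue. Untreated (diverted or horizon-censored) patients yield `NA`
#' with a warning, never a silent 0.
#'
#' @param patients A patient tibble from [simulate_patient_flow()] or
#'   [simulate_replication()].
#' @return Numeric vector of waiting times in minutes.
#' @export
waiting_time <- function(patients) {
  if (!all(c("t0_arrival", "t3_treatment_start") %in% names(patients))) {
    abort("patients must have t0_arrival and t3_treatment_start columns")
  }
  w <- patients$t3_treatment_start - patients$t0_arrival
  untreated <- if ("treated" %in% names(patients)) {
    !patients$treated
  } else {
    is.na(patients$t3_treatment_start)
  }
  if (any(untreated)) {
    w[untreated] <- NA_real_
    warn(sprintf(
      "%d untreated patient(s) have no waiting time (returned NA)",
      sum(untreated)
    ))
  }
  w
}
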