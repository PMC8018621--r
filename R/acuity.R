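#' Acuity levels and triage constants
#'
#' The simulated hospital receives patients triaged into five acuity levels
#' (AL1 most urgent, AL5 least). The modelled general emergency
#' responsibility hospital treats the non-urgent levels AL3--AL5; AL1 and
#' AL2 arrivals ("AL12") are diverted to higher-ranked hospitals at
#' generation. Each non-urgent level has a regulatory advised maximum
#' waiting time for treatment: 30 minutes for AL3, 60 for AL4 and 120 for
#' AL5. These constants are the denominators of the Crowdedness Index.
#'
#' @return `acuity_levels()` returns the character vector of level codes.
#' @examples
#' acuity_levels()
#' advised_max_wait("AL4")
#' @name acuity
NULL

# canonical ordering used throughout: diverted level last
AL_TREATED <- c("AL3", "AL4", "AL5")
AL_ALL <- c("AL3", "AL4", "AL5", "AL12")
PATHS <- c("P1", "P2", "P3", "P4")
SERVICE_KINDS <- c("triage", "consultation", "observation", "lab")

ADVISED_MAX_WAIT <- c(AL3 = 30, AL4 = 60, AL5 = 120)

#' @rdname acuity
#' @export
acuity_levels <- function() AL_ALL

#' @rdname acuity
#' @param level Character vector of acuity codes among `"AL3"`, `"AL4"`,
#'   `"AL5"`. Requesting the advised wait for `"AL12"` is an error: diverted
#'   urgent patients have no waiting-time target in the modelled hospital.
#' @return `advised_max_wait()` returns the advised maximum waiting time in
#'   minutes, named by level.
#' @export
advised_max_wait <- function(level) {
  level <- as.character(level)
  bad <- setdiff(unique(level), names(ADVISED_MAX_WAIT))
  if (length(bad) > 0) {
    abort(paste0(
      "advised maximum waiting time is defined only for AL3/AL4/AL5, not: ",
      paste(bad, collapse = ", ")
    ))
  }
  ADVISED_MAX_WAIT[level]
}

#' Patient-mix and path-assignment probabilities
#'
#' `patient_mix()` returns the proportion of arriving patients in each
#' acuity class under normal operations or during the post-earthquake busy
#' phase (urgent AL1/AL2 arrivals rise from 10% to 17% of the total after a
#' damaging earthquake). `path_table()` returns, for each acuity class, the
#' probability of each in-hospital path:
#'
#' * `P1`: triage, consultation, depart (75% of AL5);
#' * `P2`: triage, consultation, observation (76% of AL3/AL4, 25% of AL5);
#' * `P3`: triage, consultation, lab/imaging, observation (24% of AL3/AL4);
#' * `P4`: diverted at generation to a higher-ranked hospital (all AL12).
#'
#' @param condition `"normal"` or `"seismic"`.
#' @return `patient_mix()`: a named numeric vector over
#'   `AL3/AL4/AL5/AL12` summing to 1. `path_table()`: a tibble with one row
#'   per acuity level and probability columns `P1`--`P4`, each row summing
#'   to 1.
#' @examples
#' patient_mix("seismic")
#' path_table()
#' @export
patient_mix <- function(condition = c("normal", "seismic")) {
  condition <- match.arg(condition)
  switch(condition,
    normal  = c(AL3 = 0.52, AL4 = 0.32, AL5 = 0.06, AL12 = 0.10),
    seismic = c(AL3 = 0.50, AL4 = 0.30, AL5 = 0.03, AL12 = 0.17)
  )
}

#' @rdname patient_mix
#' @export
path_table <- function() {
  tibble::tibble(
    acuity = AL_ALL,
    P1 = c(0,    0,    0.75, 0),
    P2 = c(0.76, 0.76, 0.25, 0),
    P3 = c(0.24, 0.24, 0,    0),
    P4 = c(0,    0,    0,    1)
  )
}

validate_mix <- function(mix, what = "patient mix") {
  if (!is.numeric(mix) || is.null(names(mix))) {
    abort(paste0(what, " must be a named numeric vector"))
  }
  extra <- setdiff(names(mix), AL_ALL)
  if (length(extra) > 0) {
    abort(paste0(what, " has unknown acuity levels: ", paste(extra, collapse = ", ")))
  }
  full <- setNames(numeric(length(AL_ALL)), AL_ALL)
  full[names(mix)] <- mix
  if (any(full < 0)) abort(paste0(what, " has negative proportions"))
  if (abs(sum(full) - 1) > 1e-9) {
    abort(sprintf("%s must sum to 1 (got %.10g)", what, sum(full)))
  }
  full
}

validate_path_table <- function(pt) {
  if (!is.data.frame(pt) || !all(c("acuity", PATHS) %in% names(pt))) {
    abort("path table must have columns acuity, P1, P2, P3, P4")
  }
  if (!setequal(pt$acuity, AL_ALL)) {
    abort("path table must have one row per acuity level AL3/AL4/AL5/AL12")
  }
  pm <- as.matrix(pt[, PATHS])
  if (any(pm < 0)) abort("path table has negative proportions")
  rs <- rowSums(pm)
  if (any(abs(rs - 1) > 1e-9)) {
    abort(sprintf(
      "path table rows must sum to 1; offending acuity: %s",
      paste(pt$acuity[abs(rs - 1) > 1e-9], collapse = ", ")
    ))
  }
  if (pm[match("AL12", pt$acuity), "P4"] != 1) {
    abort("AL12 patients must always be diverted (P4 probability 1)")
  }
  if (any(pm[match(c("AL3", "AL4"), pt$acuity), "P1"] != 0) ||
      any(pm[match(c("AL3", "AL4"), pt$acuity), "P4"] != 0)) {
    abort("AL3/AL4 patients may only take paths P2 or P3")
  }
  if (any(pm[match("AL5", pt$acuity), c("P3", "P4")] != 0)) {
    abort("AL5 patients may only take paths P1 or P2")
  }
  pt[match(AL_ALL, pt$acuity), c("acuity", PATHS)]
}
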