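#' Service-time distributions
#'
#' Each station's service time is drawn from a configurable distribution:
#' a gamma (parameterised by shape and scale, in minutes) or a triangular
#' (minimum, mode, maximum, in minutes). Defaults reproduce the reference
#' parameterisation of a general emergency responsibility hospital:
#'
#' | service       | distribution            | mean (min) |
#' |---------------|-------------------------|------------|
#' | triage        | gamma(shape 4.5, scale 0.7) | 3.15   |
#' | consultation  | triangular(15, 45, 90)  | 50         |
#' | observation   | triangular(0, 15, 60)   | 25         |
#' | lab           | triangular(30, 75, 120) | 75         |
#'
#' A gamma with `shape = 1` is exponential, which is convenient for
#' queueing-theory cross-checks. A triangular with `min == mode == max` is
#' a constant, convenient for deterministic schedules.
#'
#' @param triage,consultation,observation,lab Distribution specs as
#'   returned by [dist_gamma()] or [dist_triangular()].
#' @return A `service_config` list with one distribution spec per service
#'   kind (`triage`, `consultation`, `observation`, `lab`).
#' @examples
#' cfg <- service_config()
#' mean(sample_service_time("consultation", cfg, n = 1e4)) # about 50
#' @export
service_config <- function(triage = dist_gamma(4.5, 0.7),
                           consultation = dist_triangular(15, 45, 90),
                           observation = dist_triangular(0, 15, 60),
                           lab = dist_triangular(30, 75, 120)) {
  cfg <- list(
    triage = triage, consultation = consultation,
    observation = observation, lab = lab
  )
  for (kind in SERVICE_KINDS) {
    spec <- cfg[[kind]]
    if (!inherits(spec, "edsurge_dist")) {
      abort(sprintf(
        "service '%s' must be a dist_gamma() or dist_triangular() spec", kind
      ))
    }
  }
  structure(cfg, class = "service_config")
}

#' @rdname service_config
#' @param shape,scale Gamma shape and scale; both strictly positive.
#'   The mean is `shape * scale` minutes.
#' @export
dist_gamma <- function(shape, scale) {
  if (!is.numeric(shape) || !is.numeric(scale) || shape <= 0 || scale <= 0) {
    abort("gamma parameters (shape, scale) must be strictly positive")
  }
  structure(list(family = "gamma", shape = shape, scale = scale),
            class = "edsurge_dist")
}

#' @rdname service_config
#' @param min,mode,max Triangular support and mode, `min <= mode <= max`,
#'   all non-negative.
#' @export
dist_triangular <- function(min, mode, max) {
  if (!is.numeric(min) || !is.numeric(mode) || !is.numeric(max) ||
      min < 0 || !(min <= mode && mode <= max)) {
    abort("triangular parameters must satisfy 0 <= min <= mode <= max")
  }
  structure(list(family = "triangular", min = min, mode = mode, max = max),
            class = "edsurge_dist")
}

dist_mean <- function(spec) {
  switch(spec$family,
    gamma = spec$shape * spec$scale,
    triangular = (spec$min + spec$mode + spec$max) / 3
  )
}

# inverse-CDF triangular sampler; degenerate support returns the constant
rtriangular <- function(n, min, mode, max) {
  if (max == min) return(rep(min, n))
  u <- runif(n)
  fc <- (mode - min) / (max - min)
  lower <- u < fc
  x <- numeric(n)
  x[lower] <- min + sqrt(u[lower] * (max - min) * (mode - min))
  x[!lower] <- max - sqrt((1 - u[!lower]) * (max - min) * (max - mode))
  x
}

#' Draw service times for one station
#'
#' @param kind One of `"triage"`, `"consultation"`, `"observation"`,
#'   `"lab"`.
#' @param config A [service_config()].
#' @param n Number of draws.
#' @return Numeric vector of `n` non-negative durations in minutes.
#' @export
sample_service_time <- function(kind, config = service_config(), n = 1L) {
  if (!is.character(kind) || length(kind) != 1 || !kind %in% SERVICE_KINDS) {
    abort(sprintf(
      "unknown service kind '%s'; expected one of %s",
      paste(kind, collapse = ","), paste(SERVICE_KINDS, collapse = ", ")
    ))
  }
  spec <- config[[kind]]
  switch(spec$family,
    gamma = rgamma(n, shape = spec$shape, scale = spec$scale),
    triangular = rtriangular(n, spec$min, spec$mode, spec$max)
  )
}

#' Station resource capacities
#'
#' Capacity is the number of patients a station can serve simultaneously;
#' one "resource unit" aggregates all labour and devices needed to serve
#' one patient. Defaults: a single triage/registration desk, 13
#' consultation/treatment units, 6 lab/imaging units, and unbounded
#' observation (any vacant space can hold a resting patient).
#'
#' @param triage,consultation,lab Positive integer capacities.
#' @param observation Positive integer or `Inf` (default) for unbounded.
#' @return A `station_set` list of capacities per service kind.
#' @examples
#' station_set()
#' station_set(consultation = 20)
#' @export
station_set <- function(triage = 1L, consultation = 13L, lab = 6L,
                        observation = Inf) {
  caps <- list(
    triage = triage, consultation = consultation,
    lab = lab, observation = observation
  )
  for (kind in names(caps)) {
    k <- caps[[kind]]
    ok <- is.numeric(k) && length(k) == 1 &&
      (is.infinite(k) || (k >= 1 && k == floor(k)))
    if (!ok) {
      abort(sprintf(
        "capacity for '%s' must be a positive integer or Inf (got %s)",
        kind, format(k)
      ))
    }
  }
  structure(caps, class = "station_set")
}
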