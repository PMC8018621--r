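pt_row <- function(acuity, wait, day = 1, rep = NULL) {
  t0 <- (day - 1) * 1440 + 10
  tibble::tibble(
    replication = rep %||% 1L, acuity = acuity, path = "P2",
    t0_arrival = t0, t3_treatment_start = t0 + wait, treated = TRUE
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("daily CI is mean wait over the advised maximum", {
  expect_equal(daily_ci(pt_row("AL3", 30), "AL3", 1), 1)
  two <- dplyr::bind_rows(pt_row("AL3", 15), pt_row("AL3", 45))
  expect_equal(daily_ci(two, "AL3", 1), 1) # mean 30 over T = 30
  expect_equal(daily_ci(pt_row("AL5", 60), "AL5", 1), 0.5)
  expect_equal(daily_ci(pt_row("AL4", 90), "AL4", 1), 1.5)
})

test_that("patients are attributed to their arrival day and empty days are NA", {
  # arrives late on day 1, treated on day 2: counts for day 1
  late <- tibble::tibble(
    acuity = "AL3", path = "P2", t0_arrival = 1430,
    t3_treatment_start = 1490, treated = TRUE
  )
  expect_equal(daily_ci(late, "AL3", 1), 2)
  expect_true(is.na(daily_ci(late, "AL3", 2)))
  # untreated patients never contribute a zero
  cens <- dplyr::mutate(late, treated = FALSE)
  expect_true(is.na(daily_ci(cens, "AL3", 1)))
  tab <- daily_ci(dplyr::bind_rows(late, cens))
  expect_equal(tab$n_arrivals, 2)
  expect_equal(tab$n_treated, 1)
})

test_that("quality is the capped reciprocal of CI", {
  expect_equal(quality_from_ci(2), 0.5)
  expect_equal(quality_from_ci(0.5), 1)
  expect_equal(quality_from_ci(0), 1)
  expect_equal(quality_from_ci(c(1, NA, 4)), c(1, NA, 0.25))
  expect_error(quality_from_ci(-0.1), "non-negative")
  # round-trip against a published daily value: CI = 1/0.21703
  expect_equal(quality_from_ci(1 / 0.21703), 0.21703)
})

test_that("CI scales as 4:2:1 across levels for identical waiting times", {
  waits <- c(20, 35, 50)
  pts <- dplyr::bind_rows(lapply(c("AL3", "AL4", "AL5"), function(l) {
    dplyr::bind_rows(lapply(waits, function(w) pt_row(l, w)))
  }))
  tab <- daily_ci(pts)
  ci <- setNames(tab$ci, tab$acuity)
  expect_equal(unname(ci["AL3"] / ci["AL4"]), 2)
  expect_equal(unname(ci["AL4"] / ci["AL5"]), 2)
})

test_that("aggregation averages per-replication CIs and skips empty cells", {
  one <- dplyr::bind_rows(pt_row("AL3", 30), pt_row("AL4", 30, day = 2))
  agg1 <- aggregate_daily(one, horizon_days = 2)
  expect_equal(nrow(agg1), 6) # 2 days x 3 levels
  expect_equal(agg1$ci_mean[agg1$day == 1 & agg1$acuity == "AL3"], 1)
  expect_true(is.na(agg1$ci_mean[agg1$day == 1 & agg1$acuity == "AL5"]))

  two <- dplyr::bind_rows(
    pt_row("AL3", 6, rep = 1L), # CI 0.2
    pt_row("AL3", 12, rep = 2L) # CI 0.4
  )
  agg2 <- aggregate_daily(two, horizon_days = 1)
  expect_equal(agg2$ci_mean[agg2$acuity == "AL3"], 0.3)
  expect_equal(agg2$n_reps[agg2$acuity == "AL3"], 2L)
  # a replication with no AL3 patients that day is skipped, not zeroed
  three <- dplyr::bind_rows(two, pt_row("AL4", 30, rep = 3L))
  agg3 <- aggregate_daily(three, horizon_days = 1)
  expect_equal(agg3$ci_mean[agg3$acuity == "AL3"], 0.3)
  expect_error(aggregate_daily(tibble::tibble()), "non-empty")
})

test_that("maximum CI ignores missing days and validates emptiness", {
  m <- tibble::tibble(
    day = rep(1:3, each = 3),
    acuity = rep(c("AL3", "AL4", "AL5"), 3),
    ci_mean = c(0.3, 0.2, 0.1, NA, 2, 0.4, 0.5, 1, 0.2)
  )
  expect_equal(max_ci(m, "AL3"), 0.5)
  expect_equal(max_ci(m, "AL4"), 2)
  expect_equal(max_ci(m), c(AL3 = 0.5, AL4 = 2, AL5 = 0.4))
  flat <- tibble::tibble(day = 1:12, acuity = "AL3", ci_mean = 0.3)
  expect_equal(max_ci(flat, "AL3"), 0.3)
  none <- tibble::tibble(day = 1, acuity = "AL3", ci_mean = NA_real_)
  expect_error(max_ci(none, "AL3"), "no defined CI")
})

test_that("recovery duration counts impaired days in the published tables", {
  expect_equal(recovery_duration(reference_quality_gr1()), 3) # days 3-5
  expect_equal(recovery_duration(reference_quality_gr2()), 5) # days 3-7
  allq1 <- tibble::tibble(day = 1:10, acuity = "AL3", q = 1)
  expect_equal(recovery_duration(allq1), 0)
  # full precision: Q = 0.97913 counts as impaired
  g2 <- reference_quality_gr2()
  expect_lt(g2$q[g2$day == 7 & g2$acuity == "AL3"], 1)
})

test_that("external event logs are scored like internal runs", {
  sc <- tiny_scenario("GR1", replications = 2)
  res <- run_experiment(sc, keep_events = TRUE)
  out <- withr::local_tempdir()
  write_outputs(res, out, events = TRUE)
  scored <- score_event_log(file.path(out, "events.csv"),
                            horizon_days = sc$horizon_days)
  expect_equal(scored$max_ci[["AL3"]], res$max_ci[["AL3"]])
  expect_equal(scored$recovery_days, res$recovery_days)
  expect_error(score_event_log(tibble::tibble(x = 1)), "columns")
})
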