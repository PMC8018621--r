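test_that("experiments are deterministic given configuration and seed", {
  sc <- tiny_scenario("GR1", replications = 4, seed = 13)
  a <- run_experiment(sc)
  b <- run_experiment(sc)
  expect_identical(a$daily, b$daily)
  expect_identical(a$max_ci, b$max_ci)
  expect_identical(glance(a), glance(b))
  d <- run_experiment(sc, seed = 14)
  expect_false(identical(a$max_ci, d$max_ci))
  # outputs written twice are bitwise identical
  o1 <- withr::local_tempdir()
  o2 <- withr::local_tempdir()
  write_outputs(a, o1, events = FALSE)
  write_outputs(b, o2, events = FALSE)
  expect_identical(
    readLines(file.path(o1, "daily_metrics.csv")),
    readLines(file.path(o2, "daily_metrics.csv"))
  )
})

test_that("replication substreams make replications independent", {
  s <- edsurge:::replication_streams(1, 4)
  expect_equal(length(s), 4)
  expect_false(identical(s[[1]], s[[2]]))
  # substream r is reproducible without running the earlier ones
  s2 <- edsurge:::replication_streams(1, 2)
  expect_identical(s[[2]], s2[[2]])
})

test_that("across-replication noise of the aggregate shrinks like 1/sqrt(R)", {
  sc <- tiny_scenario("normal", replications = 36, seed = 3)
  res <- run_experiment(sc, keep_events = TRUE)
  per_rep <- daily_ci(res$events) |>
    dplyr::filter(acuity == "AL3", day == 3)
  sd_rep <- stats::sd(per_rep$ci)
  # group the 36 replications into 6 blocks of 6: block means must scatter
  # about sqrt(6) more tightly than single replications
  blocks <- tapply(per_rep$ci, (seq_len(nrow(per_rep)) - 1) %/% 6, mean)
  expect_equal(stats::sd(blocks), sd_rep / sqrt(6), tolerance = 0.6)
})

test_that("glance and tidy summarise an experiment", {
  res <- run_experiment(tiny_scenario("GR1", replications = 2))
  g <- glance(res)
  expect_equal(g$scenario, "GR1")
  expect_equal(g$growth_ratio, 1.4)
  expect_equal(g$replications, 2L)
  td <- tidy(res)
  expect_equal(nrow(td), 12 * 3)
  expect_true(all(c("scenario", "day", "acuity", "ci_mean", "q") %in%
                    names(td)))
})

test_that("normal operations stay uncrowded and unimpaired", {
  res <- run_experiment(tiny_scenario("normal", replications = 10, seed = 2))
  expect_equal(res$recovery_days, 0)
  expect_true(all(res$daily$ci_mean < 0.6, na.rm = TRUE))
  expect_true(all(res$daily$q == 1, na.rm = TRUE))
})

test_that("a growth-ratio sweep fits two segments per level", {
  base <- scenario_config(replications = 4, seed = 8)
  sw <- run_sweep(c(1, 1.2, 1.4, 1.6, 1.9), base)
  expect_s3_class(sw$fit, "ci_piecewise_fit")
  expect_equal(nrow(sw$points), 5 * 3)
  cf <- sw$fit$coefficients
  expect_setequal(unique(cf$acuity), c("AL3", "AL4", "AL5"))
  g <- glance(sw$fit)
  expect_true(all(g$upper_slope > g$lower_slope))
  # aggregated maxima are non-decreasing in the growth ratio
  al3 <- sw$points[sw$points$acuity == "AL3", ]
  expect_true(all(diff(al3$max_ci[order(al3$growth_ratio)]) > -0.5))
  expect_error(run_sweep(c(1, 1.4), base), "each side")
})

test_that("written outputs honour the committed schemas", {
  schema <- jsonlite::read_json(
    system.file("schema", "outputs.json", package = "edsurge"),
    simplifyVector = TRUE
  )
  sc <- tiny_scenario("GR1", replications = 2)
  res <- run_experiment(sc, keep_events = TRUE)
  out <- withr::local_tempdir()
  paths <- write_outputs(res, out, events = TRUE)
  expect_true(all(file.exists(paths)))

  daily <- readr::read_csv(file.path(out, "daily_metrics.csv"),
                           show_col_types = FALSE)
  expect_equal(names(daily), schema[["daily_metrics.csv"]])
  expect_equal(nrow(daily), sc$horizon_days * 3)

  events <- readr::read_csv(file.path(out, "events.csv"),
                            show_col_types = FALSE)
  expect_equal(names(events), schema[["events.csv"]])

  summary <- jsonlite::read_json(file.path(out, "summary.json"))
  expect_setequal(names(summary), schema[["summary.json"]])
})

test_that("the manifest re-runs to an identical summary", {
  sc <- tiny_scenario("GR1", replications = 3, seed = 19)
  res <- run_experiment(sc)
  out <- withr::local_tempdir()
  write_outputs(res, out)
  mf <- jsonlite::read_json(file.path(out, "manifest.json"),
                            simplifyVector = TRUE)
  sc2 <- scenario_config(
    name = mf$name, growth_ratio = mf$growth_ratio,
    daily_total = mf$daily_total, horizon_days = mf$horizon_days,
    busy_day_totals = mf$busy_day_totals,
    replications = mf$replications, seed = mf$seed
  )
  res2 <- run_experiment(sc2)
  expect_equal(res$max_ci, res2$max_ci)
  expect_equal(res$daily, res2$daily)
})

test_that("long waits trigger the censoring warning on short horizons", {
  sc <- scenario_config(growth_ratio = 2.3, horizon_days = 7,
                        replications = 1, seed = 4)
  expect_warning(run_experiment(sc), "untreated at horizon end")
})
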