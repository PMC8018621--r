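test_that("acuity and path assignment follows the product law", {
  set.seed(21)
  n <- 1e5
  drawn <- assign_acuity_and_path(n, patient_mix("normal"))
  freq <- table(factor(drawn$path, levels = c("P1", "P2", "P3", "P4"))) / n
  # expected path shares under normal mix x path table:
  # P1 = .06*.75, P2 = .84*.76 + .06*.25, P3 = .84*.24, P4 = .10
  expected <- c(P1 = 0.045, P2 = 0.6534, P3 = 0.2016, P4 = 0.10)
  for (p in names(expected)) {
    se <- sqrt(expected[[p]] * (1 - expected[[p]]) / n)
    expect_equal(unname(freq[[p]]), expected[[p]],
                 tolerance = 5 * se / expected[[p]])
  }
  # AL12 always diverts
  expect_true(all(drawn$path[drawn$acuity == "AL12"] == "P4"))
  expect_true(all(drawn$acuity[drawn$path == "P4"] == "AL12"))

  # pure AL3 mix: paths only P2 (76%) / P3 (24%)
  al3 <- assign_acuity_and_path(2e4, c(AL3 = 1))
  expect_setequal(unique(al3$path), c("P2", "P3"))
  expect_equal(mean(al3$path == "P2"), 0.76, tolerance = 0.02)

  # degenerate point mass
  pt <- path_table()
  pt[pt$acuity == "AL5", c("P1", "P2")] <- list(1, 0)
  one <- assign_acuity_and_path(50, c(AL5 = 1), pt)
  expect_true(all(one$acuity == "AL5" & one$path == "P1"))

  expect_error(assign_acuity_and_path(5, c(AL3 = 0.5)), "sum to 1")
  expect_error(assign_acuity_and_path(5, c(AL3 = 1.5, AL4 = -0.5)),
               "negative")
})

test_that("the FIFO queue core agrees with a pure-R reference", {
  set.seed(31)
  for (cap in c(1, 2, 5, 13)) {
    entry <- sort(runif(400, 0, 500))
    svc <- rexp(400, 1 / 10)
    expect_equal(fifo_serve(entry, svc, cap), ref_fifo(entry, svc, cap))
  }
  expect_equal(fifo_serve(numeric(0), numeric(0), 3), numeric(0))
  # unbounded capacity: service starts at entry
  e <- sort(runif(50, 0, 10))
  expect_equal(fifo_serve(e, rep(1, 50), Inf), e)
  expect_error(fifo_serve(c(2, 1), c(1, 1), 1), "sorted")
})

test_that("without contention the wait equals the patient's own triage time", {
  arr <- tibble::tibble(
    arrival_time = sort(runif(200, 0, 1440)),
    acuity = sample(c("AL3", "AL4", "AL5"), 200, replace = TRUE),
    path = "P2"
  )
  flow <- simulate_patient_flow(
    arr,
    stations = station_set(triage = Inf, consultation = Inf, lab = Inf),
    service_times = service_config()
  )
  expect_equal(flow$t3_treatment_start - flow$t0_arrival,
               flow$t2_triage_end - flow$t1_triage_start)
})

test_that("a two-patient contention schedule matches the hand trace", {
  # triage 3 min (1 desk), consultation 50 min (13 units); arrivals at 0, 1
  # patient 1: triage 0-3, treatment starts 3 -> wait 3
  # patient 2: triage 3-6 (desk busy), treatment starts 6 -> wait 5
  flow <- simulate_patient_flow(
    tibble::tibble(arrival_time = c(0, 1), acuity = "AL3", path = "P1"),
    stations = station_set(),
    service_times = const_service_config(triage = 3, consultation = 50)
  )
  expect_equal(waiting_time(flow), c(3, 5))
  expect_equal(flow$t1_triage_start, c(0, 3))
  expect_equal(flow$t2_triage_end, c(3, 6))
  expect_equal(flow$t3_treatment_start, c(3, 6))
  expect_equal(flow$depart_time, c(53, 56))
})

test_that("a constant-service multi-station schedule matches the hand trace", {
  # single consultation unit, constant services (triage 2, consult 30,
  # lab 20, obs 5); arrivals 0/10/20, the last on the lab+observation path
  cfg <- const_service_config(triage = 2, consultation = 30,
                              observation = 5, lab = 20)
  flow <- simulate_patient_flow(
    tibble::tibble(arrival_time = c(0, 10, 20),
                   acuity = c("AL3", "AL4", "AL3"),
                   path = c("P2", "P2", "P3")),
    stations = station_set(consultation = 1),
    service_times = cfg
  )
  expect_equal(flow$t2_triage_end, c(2, 12, 22))
  # consultation serialises: 2-32, 32-62, 62-92
  expect_equal(flow$t3_treatment_start, c(2, 32, 62))
  expect_equal(flow$t4_treatment_end, c(32, 62, 92))
  # P2 go straight to observation; P3 via lab
  expect_equal(flow$t7_obs_start, c(32, 62, 112))
  expect_equal(flow$t5_lab_start, c(NA, NA, 92))
  expect_equal(flow$depart_time, c(37, 67, 117))
})

test_that("the simulated M/M/c queue matches the Erlang-C closed form", {
  lambda <- 0.2
  mu <- 1 / 15
  c_srv <- 4 # utilisation 0.75
  set.seed(51)
  horizon <- 1e5 # simulated minutes
  wq <- replicate(40, {
    n_arr <- rpois(1, lambda * horizon)
    entry <- sort(runif(n_arr, 0, horizon))
    svc <- rexp(n_arr, mu)
    start <- fifo_serve(entry, svc, c_srv)
    mean((start - entry)[entry > 2000]) # discard warm-up
  })
  expect_equal(mean(wq), erlang_c_wq(lambda, mu, c_srv), tolerance = 0.05)
})

test_that("replications conserve patients and keep timestamps consistent", {
  sc <- tiny_scenario("GR1", replications = 1)
  pts <- simulate_replication(sc, seed = 17)
  # conservation across paths
  expect_equal(sum(table(pts$path)), nrow(pts))
  expect_setequal(unique(pts$path), c("P1", "P2", "P3", "P4"))
  # diverted patients never touch a station
  p4 <- dplyr::filter(pts, path == "P4")
  expect_true(all(p4$acuity == "AL12"))
  expect_true(all(is.na(p4$t1_triage_start)))
  expect_true(all(is.na(p4$depart_time)))
  # timestamps non-decreasing along every path
  inside <- dplyr::filter(pts, path != "P4")
  ts <- as.matrix(inside[, c(
    "t0_arrival", "t1_triage_start", "t2_triage_end", "t3_treatment_start",
    "t4_treatment_end", "t5_lab_start", "t6_lab_end", "t7_obs_start",
    "t8_obs_end", "depart_time"
  )])
  diffs <- apply(ts, 1, function(r) diff(r[!is.na(r)]))
  expect_true(all(unlist(diffs) >= 0))
  # arrival day bookkeeping
  expect_equal(pts$arrival_day, floor(pts$t0_arrival / 1440))
})

test_that("bounded stations never exceed their capacity", {
  sc <- tiny_scenario("GR2", replications = 1)
  pts <- simulate_replication(sc, seed = 23)
  expect_lte(max_concurrency(pts$t1_triage_start, pts$t2_triage_end), 1)
  expect_lte(max_concurrency(pts$t3_treatment_start, pts$t4_treatment_end),
             13)
  expect_lte(max_concurrency(pts$t5_lab_start, pts$t6_lab_end), 6)
})

test_that("FIFO service makes waiting times symmetric across acuity levels", {
  sc <- tiny_scenario("normal", replications = 25)
  res <- run_experiment(sc, keep_events = TRUE)
  by_level <- res$events |>
    dplyr::filter(treated) |>
    dplyr::group_by(acuity) |>
    dplyr::summarise(w = mean(t3_treatment_start - t0_arrival))
  expect_equal(nrow(by_level), 3)
  expect_lt(max(by_level$w) - min(by_level$w), 0.5)
})

test_that("waiting_time subtracts timestamps and flags untreated patients", {
  pts <- tibble::tibble(
    t0_arrival = c(100, 50, 0),
    t3_treatment_start = c(109, 50, NA),
    treated = c(TRUE, TRUE, FALSE)
  )
  expect_warning(w <- waiting_time(pts), "untreated")
  expect_equal(w, c(9, 0, NA))
  expect_equal(waiting_time(pts[1:2, ]), c(9, 0))
})

test_that("a replication is reproducible from its seed", {
  sc <- tiny_scenario("GR1")
  a <- simulate_replication(sc, seed = 5)
  b <- simulate_replication(sc, seed = 5)
  expect_identical(a, b)
  c2 <- simulate_replication(sc, seed = 6)
  expect_false(identical(a, c2))
})
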