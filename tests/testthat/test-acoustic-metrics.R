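ts_utc <- function(x) as.POSIXct(x, tz = "UTC")

test_that("monitoring windows intersect deployment, battery and period", {
  rx <- tibble::tibble(receiver_id = "R1",
                       deploy_start = ts_utc("2014-01-01 10:00"),
                       deploy_end = ts_utc("2014-12-31 23:00"))
  tx <- tibble::tibble(transmitter_id = "T1",
                       activation = ts_utc("2014-03-01 12:00"),
                       battery_days = 730)
  w <- monitoring_windows(rx, tx)
  expect_equal(w$monitored_days, 306) # Mar 1 - Dec 31 2014
  # disjoint: tag dead before deployment
  tx2 <- tibble::tibble(transmitter_id = "T2",
                        activation = ts_utc("2012-01-01"),
                        battery_days = 100)
  expect_equal(monitoring_windows(rx, tx2)$monitored_days, 0)
  expect_error(monitoring_windows(
    rx, tibble::tibble(transmitter_id = "T3",
                       activation = ts_utc("2014-01-01"),
                       battery_days = NA)), "battery")
})

test_that("potential detection days sum over transmitter-receiver pairs", {
  # boundaries at local midnight (UTC-10): 10:00 UTC
  rx <- tibble::tibble(receiver_id = c("R1", "R2"),
                       deploy_start = rep(ts_utc("2014-02-01 10:00"), 2),
                       deploy_end = rep(ts_utc("2014-05-12 09:59"), 2))
  tx <- tibble::tibble(transmitter_id = c("T1", "T2"),
                       activation = rep(ts_utc("2013-06-01"), 2),
                       battery_days = c(3650, 3650))
  w <- monitoring_windows(rx, tx)
  expect_equal(nrow(w), 4)
  expect_equal(sum(w$monitored_days), 400) # 2 tags x 2 receivers x 100 d
})

test_that("visit segmentation follows the gap and location-change rules", {
  t0 <- ts_utc("2014-06-01 08:00")
  d1 <- tibble::tibble(time = t0 + c(0, 10, 20) * 60,
                       transmitter_id = "T1", receiver_id = "R1")
  v1 <- segment_visits(d1)
  expect_equal(nrow(v1), 1)
  expect_equal(v1$duration_min, 20)
  expect_equal(v1$n_detections, 3L)
  # 40-min gap: two single-detection visits at the 7.7-min convention
  d2 <- tibble::tibble(time = t0 + c(0, 40) * 60,
                       transmitter_id = "T1", receiver_id = "R1")
  v2 <- segment_visits(d2)
  expect_equal(v2$duration_min, c(7.7, 7.7))
  # location change closes the visit even within 30 min
  d3 <- tibble::tibble(time = t0 + c(0, 5, 10) * 60,
                       transmitter_id = "T1",
                       receiver_id = c("RA", "RB", "RA"))
  v3 <- segment_visits(d3)
  expect_equal(nrow(v3), 3)
  expect_equal(v3$receiver_id, c("RA", "RB", "RA"))
  # a gap of exactly 30 min starts a new visit
  d4 <- tibble::tibble(time = t0 + c(0, 30) * 60,
                       transmitter_id = "T1", receiver_id = "R1")
  expect_equal(nrow(segment_visits(d4)), 2)
})

test_that("segmentation partitions detections identically to the oracle", {
  for (seed in 1:25) {
    log <- random_detection_log(seed, n = 40)
    got <- segment_visits(log)
    want <- oracle_split_visits(log)
    expect_same_partition(got, want)
    # partition property: visit detection counts sum to the log size
    expect_equal(sum(got$n_detections), nrow(log))
  }
})

test_that("the single-detection convention reflects the slowest duty cycle", {
  expect_equal(single_detection_minutes(), 7.7)
  expect_equal(single_detection_minutes(3.6, 230), round(463.6 / 60, 1))
})

test_that("SFI is days detected over monitored days, as a percentage", {
  rx <- tibble::tibble(receiver_id = "R1",
                       deploy_start = ts_utc("2014-01-01 10:00"),
                       deploy_end = ts_utc("2014-04-11 09:59"))
  tx <- tibble::tibble(transmitter_id = "T1",
                       activation = ts_utc("2014-01-01 10:00"),
                       battery_days = 3650)
  w <- monitoring_windows(rx, tx)
  expect_equal(w$monitored_days, 100)
  det <- tibble::tibble(
    time = ts_utc("2014-01-05 22:00") + (0:9) * 86400 * 3,
    transmitter_id = "T1", receiver_id = "R1")
  s <- compute_sfi(det, w)
  expect_equal(s$days_detected, 10L)
  expect_equal(s$sfi, 10)
  # zero detections
  s0 <- compute_sfi(det[0, ], w)
  expect_equal(s0$sfi, 0)
  # monotone in detection days for a fixed window
  s2 <- compute_sfi(det[1:5, ], w)
  expect_lt(s2$sfi, s$sfi)
})

test_that("SFI recovers a programmed daily visiting probability", {
  n_days <- 400; p <- 0.3
  det <- simulate_visit_schedule("T1", "R1", as.Date("2014-01-01"),
                                 n_days, p_daily = p, seed = 77)
  rx <- tibble::tibble(receiver_id = "R1",
                       deploy_start = min(det$time) - 86400 * 30,
                       deploy_end = max(det$time) + 86400 * 30)
  tx <- tibble::tibble(transmitter_id = "T1",
                       activation = rx$deploy_start, battery_days = 3650)
  w <- monitoring_windows(
    rx, tx, period = c(ts_utc("2014-01-01 10:00"),
                       ts_utc("2014-01-01 10:00") + n_days * 86400 - 1))
  expect_equal(w$monitored_days, n_days)
  s <- compute_sfi(det, w)
  sigma <- 100 * sqrt(p * (1 - p) / n_days)
  expect_lt(abs(s$sfi - 100 * p), 3 * sigma)
})

test_that("SFI converts to the equivalent revisit interval", {
  expect_equal(sfi_equivalent_revisit_interval(20), 5)
  expect_equal(sfi_equivalent_revisit_interval(10), 10)
  expect_equal(sfi_equivalent_revisit_interval(100), 1)
  expect_error(sfi_equivalent_revisit_interval(0))
})

test_that("detection-day frequency and co-detection summaries count days", {
  base <- as.Date("2014-01-01")
  mk_det <- function(day_idx, tx) tibble::tibble(
    time = ts_utc(paste(base + day_idx, "22:00:00")), # mid-day local
    transmitter_id = tx, receiver_id = "R1")
  det <- dplyr::bind_rows(
    mk_det(0:61, "T1"),          # 62 days with T1
    mk_det(30:54, "T2"))         # 25 of those days also have T2
  expect_equal(detection_day_frequency(det, "R1", monitored_days = 100), 62)
  expect_equal(detection_day_frequency(det[0, ], "R1",
                                       monitored_days = 100), 0)
  cd <- codetection_summary(det, "R1", monitored_days = 100)
  expect_equal(cd$pct_multi_shark_days, 25)
  expect_equal(cd$max_sharks_per_day, 2L)
  # 8 transmitters on one day
  det8 <- dplyr::bind_rows(lapply(paste0("S", 1:8), function(tx)
    mk_det(0, tx)))
  expect_equal(codetection_summary(det8, "R1")$max_sharks_per_day, 8L)
  one <- codetection_summary(mk_det(0:9, "T1"), "R1")
  expect_equal(one$pct_multi_shark_days, 0)
})

test_that("per-shark summaries use mean-excluding-zero where specified", {
  sfi <- tibble::tibble(transmitter_id = "T1",
                        receiver_id = c("R1", "R2", "R3"),
                        days_detected = c(0L, 10L, 20L),
                        monitored_days = c(100L, 100L, 100L),
                        sfi = c(0, 10, 20))
  t0 <- ts_utc("2014-06-01 00:00")
  visits <- tibble::tibble(
    transmitter_id = "T1",
    receiver_id = c("R3", "R3", "R2"),
    start = t0 + c(0, 3600 * 24, 3600 * 48),
    end = t0 + c(5 * 60, 3600 * 24 + 7.7 * 60, 3600 * 48 + 700.7 * 60),
    duration_min = c(5, 7.7, 700.7),
    n_detections = c(2L, 1L, 12L))
  sm <- shark_summaries(visits, sfi)
  expect_equal(sm$mean_sfi_excl_zero, 15) # zeros excluded
  expect_equal(sm$max_sfi, 20)
  expect_equal(sm$max_visit_min, 700.7)
  expect_equal(sm$mean_visit_min, mean(c(5, 7.7, 700.7))) # zeros n/a here
  expect_equal(sm$most_visited, "R3")
  expect_equal(length(sm$absence_from_home_h[[1]]), 1)
  single <- shark_summaries(visits[3, ], sfi)
  expect_true(single$single_visit)
  expect_equal(length(single$absence_from_home_h[[1]]), 0)
})

test_that("a resident shark outscores a transient at its home receiver", {
  det_res <- simulate_visit_schedule("RES", "HOME", as.Date("2014-01-01"),
                                     200, p_daily = 0.5, seed = 5)
  det_tra <- simulate_visit_schedule("TRA", "HOME", as.Date("2014-01-01"),
                                     200, p_daily = 0.05, seed = 6)
  rx <- tibble::tibble(receiver_id = "HOME",
                       deploy_start = ts_utc("2013-12-31 00:00"),
                       deploy_end = ts_utc("2014-07-30 00:00"))
  tx <- tibble::tibble(transmitter_id = c("RES", "TRA"),
                       activation = rep(ts_utc("2013-12-31 00:00"), 2),
                       battery_days = c(3650, 3650))
  w <- monitoring_windows(rx, tx)
  s <- compute_sfi(dplyr::bind_rows(det_res, det_tra), w)
  expect_gt(s$sfi[s$transmitter_id == "RES"],
            s$sfi[s$transmitter_id == "TRA"])
})

test_that("detections and residency tables round-trip through CSV", {
  log <- random_detection_log(3, n = 30)
  path <- withr::local_tempfile(fileext = ".csv")
  write_detections_csv(log, path)
  back <- read_detections_csv(path)
  expect_equal(nrow(back), 30)
  expect_equal(back$transmitter_id, log$transmitter_id)
  v <- segment_visits(log)
  vpath <- withr::local_tempfile(fileext = ".csv")
  write_residency_csv(v, vpath)
  expect_equal(nrow(readr::read_csv(vpath, show_col_types = FALSE)), nrow(v))
})
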