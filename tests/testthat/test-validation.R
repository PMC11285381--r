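ts_at <- function(day, hm) {
  as.POSIXct(paste0("2024-01-0", day, " ", hm, ":00"), tz = "UTC")
}

ev_row <- function(kind, time, subject = "S1") {
  tibble::tibble(subject_id = subject, kind = kind, timestamp = time)
}

mk_rows <- function(times, subject = "S1") {
  tibble::tibble(subject_id = subject, timestamp = times)
}

test_that("minutes-since-midnight applies the after-midnight SOT rule", {
  expect_equal(to_minutes(ts_at(2, "00:30"), "SOT"), 1470)
  expect_equal(to_minutes(ts_at(1, "23:45"), "SOT"), 1425)
  expect_equal(to_minutes(ts_at(1, "06:45"), "WOT"), 405)
  # WOTs are never rolled over
  expect_equal(to_minutes(ts_at(1, "00:30"), "WOT"), 30)
  m <- to_minutes(c(ts_at(1, "01:00"), ts_at(1, "13:00")), "SOT")
  expect_true(all(m >= 0 & m < 2880))
})

test_that("multiple candidates: latest wins for SOT, earliest for WOT", {
  sot <- ev_row("SOT", ts_at(1, "23:00"))
  m <- match_markers(sot, mk_rows(c(ts_at(1, "22:00"), ts_at(1, "22:30"))))
  expect_equal(m$marker_time, ts_at(1, "22:30"))
  expect_equal(m$diff, 1380 - 1350)

  wot <- ev_row("WOT", ts_at(1, "06:30"))
  m2 <- match_markers(wot, mk_rows(c(ts_at(1, "06:40"), ts_at(1, "07:30"))))
  expect_equal(m2$marker_time, ts_at(1, "06:40"))
  expect_equal(m2$diff, -10)
})

test_that("the 180 min matching window is inclusive at the boundary", {
  ev <- ev_row("WOT", ts_at(1, "06:00"))
  far <- match_markers(ev, mk_rows(ts_at(1, "09:01")))   # 181 min
  expect_true(is.na(far$marker_time))
  edge <- match_markers(ev, mk_rows(ts_at(1, "09:00")))  # 180 min
  expect_equal(edge$marker_time, ts_at(1, "09:00"))
})

test_that("a marker pairs with at most one event; counts add up", {
  ev <- dplyr::bind_rows(
    ev_row("WOT", ts_at(1, "06:30")),
    ev_row("SOT", ts_at(1, "08:00"))  # unusual, but within 180 of 06:40
  )
  m <- match_markers(ev, mk_rows(ts_at(1, "06:40")))
  expect_equal(sum(!is.na(m$marker_time)), 1)
  expect_equal(m$marker_time[1], ts_at(1, "06:40"))  # earlier event got it

  expect_equal(nrow(m), 2)  # matched + unmatched = all events
  empty <- match_markers(ev, mk_rows(ts_at(1, "06:40"))[0, ])
  expect_true(all(is.na(empty$marker_time)))
})

test_that("SOT/WOT selection is mirrored when roles are reversed", {
  times <- c(ts_at(1, "22:10"), ts_at(1, "23:20"))
  at <- ts_at(1, "23:00")
  sot_pick <- match_markers(ev_row("SOT", at), mk_rows(times))$marker_time
  wot_pick <- match_markers(ev_row("WOT", at), mk_rows(times))$marker_time
  expect_equal(sot_pick, max(times))
  expect_equal(wot_pick, min(times))
})

test_that("agreement summary computes bias, limits and MAE per kind", {
  m <- tibble::tibble(
    kind = "WOT",
    diff = c(-2, 0, 2)
  )
  s <- summarize_agreement(dplyr::mutate(m, subject_id = "S1"))
  expect_equal(s$bias, 0)
  expect_equal(s$mae, 2)

  cst <- summarize_agreement(tibble::tibble(kind = "SOT", diff = rep(7, 5)))
  expect_equal(cst$bias, 7)
  expect_equal(cst$loa_low, 7)
  expect_equal(cst$loa_high, 7)
  expect_equal(cst$mae, 7)

  none <- summarize_agreement(tibble::tibble(kind = "SOT",
                                             diff = NA_real_))
  expect_equal(none$n_pairs, 0)
})

test_that("swapping estimate and marker columns negates the bias", {
  withr::local_seed(61)
  m <- tibble::tibble(
    kind = "SOT",
    est_min = 1380 + rnorm(40, 0, 15),
    marker_min = 1380 + rnorm(40, 0, 15)
  )
  m$diff <- m$est_min - m$marker_min
  swapped <- dplyr::mutate(m, diff = marker_min - est_min)
  expect_equal(summarize_agreement(swapped)$bias,
               -summarize_agreement(m)$bias)
})

test_that("marker noise with zero bias yields the expected agreement", {
  sim <- simulate_cohort(n_subjects = 10, seed = 9)
  s <- summarize_agreement(match_markers(sim$truth, sim$markers))
  # markers = truth + N(0, 10 min): bias ~ 0, LoA ~ +/- 19.6 min
  expect_true(all(abs(s$bias) < 3))
  expect_equal(s$loa_high - s$bias, rep(19.6, 2), tolerance = 0.3)
  expect_true(all(s$match_rate > 0.6 & s$match_rate < 0.95))
})
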