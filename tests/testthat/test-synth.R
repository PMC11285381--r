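test_that("same seed gives bit-identical simulations", {
  a <- simulate_subject(subject_params(seed = 5))
  b <- simulate_subject(subject_params(seed = 5))
  expect_identical(a$activity, b$activity)
  expect_identical(a$truth, b$truth)
  expect_identical(a$markers, b$markers)
  c_ <- simulate_subject(subject_params(seed = 6))
  expect_false(identical(a$activity$activity, c_$activity$activity))
})

test_that("the noise-free limit reproduces the deterministic schedule", {
  p <- subject_params(day_jitter_sd = 0, p0_wake = 0, p0_sleep = 0,
                      marker_sd = 0, marker_dropout = 0, winddown_min = 0,
                      seed = 1)
  sim <- simulate_subject(p)
  expect_identical(sort(sim$markers$timestamp), sort(sim$truth$timestamp))
  expect_identical(sim$truth$kind, rep(c("WOT", "SOT"), 7))
  expect_true(all(sim$activity$activity > 0))

  # regimes exactly follow the schedule: sleep epochs have the small scale
  mins <- as.numeric(difftime(sim$activity$timestamp,
                              sim$activity$timestamp[1], units = "mins"))
  sleep <- rep(FALSE, length(mins))
  ev <- sim$truth
  ev_min <- as.numeric(difftime(ev$timestamp, sim$activity$timestamp[1],
                                units = "mins"))
  lo <- c(0, ev_min[ev$kind == "SOT"])
  hi <- c(ev_min[ev$kind == "WOT"], max(mins) + 1)
  for (j in seq_along(lo)) sleep[mins >= lo[j] & mins < hi[j]] <- TRUE
  m_sleep <- mean(sim$activity$activity[sleep])
  m_wake <- mean(sim$activity$activity[!sleep])
  expect_equal(m_sleep, 0.8 * 10, tolerance = 0.15)
  expect_equal(m_wake, 0.8 * 200, tolerance = 0.05)
})

test_that("zero inflation and wake scale match their nominal values", {
  sim <- simulate_subject(subject_params(seed = 12, winddown_min = 0))
  ev <- sim$truth
  t0 <- sim$activity$timestamp[1]
  mins <- as.numeric(difftime(sim$activity$timestamp, t0, units = "mins"))
  ev_min <- as.numeric(difftime(ev$timestamp, t0, units = "mins"))
  lo <- c(0, ev_min[ev$kind == "SOT"])
  hi <- c(ev_min[ev$kind == "WOT"], max(mins) + 1)
  sleep <- rep(FALSE, length(mins))
  for (j in seq_along(lo)) sleep[mins >= lo[j] & mins < hi[j]] <- TRUE

  z <- mean(sim$activity$activity[sleep] == 0)
  n_sleep <- sum(sleep)
  expect_lt(abs(z - 0.6), 4 * sqrt(0.6 * 0.4 / n_sleep))

  # Gamma scale MLE on wake epochs (zeros removed) recovers theta_wake;
  # pool three subjects so the MLE's sampling error sits well inside 5%
  wake_pos <- unlist(lapply(c(12, 13, 14), function(s) {
    sm <- simulate_subject(subject_params(seed = s, winddown_min = 0))
    ev2 <- sm$truth
    t02 <- sm$activity$timestamp[1]
    m2 <- as.numeric(difftime(sm$activity$timestamp, t02, units = "mins"))
    e2 <- as.numeric(difftime(ev2$timestamp, t02, units = "mins"))
    lo2 <- c(0, e2[ev2$kind == "SOT"])
    hi2 <- c(e2[ev2$kind == "WOT"], max(m2) + 1)
    slp <- rep(FALSE, length(m2))
    for (j in seq_along(lo2)) slp[m2 >= lo2[j] & m2 < hi2[j]] <- TRUE
    v <- sm$activity$activity[!slp]
    v[v > 0]
  }))
  theta_hat <- mean(wake_pos) / estimate_gamma_shape(wake_pos)
  expect_lt(abs(theta_hat - 200) / 200, 0.05)
})

test_that("generated recordings pass screening from four days up", {
  for (d in c(4, 7)) {
    sim <- simulate_subject(subject_params(n_days = d, seed = 3))
    expect_true(screen_actigraphy(sim$activity)$passed)
  }
})

test_that("parameter contracts reject infeasible schedules", {
  expect_error(subject_params(mean_sot = 400, mean_wot = 420),
               class = "circacp_error_contract")
  expect_error(subject_params(theta_wake = 5, theta_sleep = 10),
               class = "circacp_error_contract")
  expect_error(subject_params(p0_wake = 0.7, p0_sleep = 0.5),
               class = "circacp_error_contract")
  expect_error(subject_params(mean_sot = 460, mean_wot = 420,
                              winddown_min = 60),
               class = "circacp_error_parameter")
})

test_that("cohorts are reproducible and write the io dialects", {
  dir <- withr::local_tempdir()
  a <- simulate_cohort(n_subjects = 3, seed = 2, n_days = 4,
                       out_dir = dir)
  b <- simulate_cohort(n_subjects = 3, seed = 2, n_days = 4)
  expect_identical(a$activity, b$activity)
  expect_equal(length(unique(a$activity$subject_id)), 3)

  back <- read_actigraphy(file.path(dir, "actigraphy.csv"))
  expect_equal(back, a$activity)
  expect_equal(read_markers(file.path(dir, "markers.csv")), a$markers)
  tr <- read_swots(file.path(dir, "truth.csv"))
  expect_equal(nrow(tr), nrow(a$truth))
})
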