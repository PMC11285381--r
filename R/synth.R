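#' Parameters for one simulated subject
#'
#' Describes a monophasic night sleeper whose activity is a
#' pseudo-cyclostationary zero-inflated Gamma process: wake epochs draw 0
#' with probability `p0_wake`, otherwise Gamma(scale `theta_wake`, shape
#' `xi`); sleep epochs analogously with `p0_sleep` and `theta_sleep`
#' (zero inflation is heavier and the scale far smaller at night). Each
#' day's true sleep and wake onsets jitter around their means by
#' `day_jitter_sd`. A sedentary wind-down regime of `winddown_min` minutes
#' at intermediate scale `theta_winddown` precedes every true sleep onset,
#' reproducing the after-hours stillness that makes sleep onsets harder to
#' pin down than wake onsets. Button-press markers are the true onsets
#' plus Gaussian error (`marker_sd`), each forgotten with probability
#' `marker_dropout`.
#'
#' @param subject_id Subject identifier.
#' @param mean_sot,mean_wot Mean sleep/wake onset, minutes since midnight
#'   (defaults 23:00 and 07:00; `mean_wot < mean_sot`).
#' @param day_jitter_sd Day-to-day onset SD, minutes; default 20.
#' @param theta_wake,theta_sleep,theta_winddown Gamma scales (counts);
#'   defaults 200, 10 and 45 (wind-down at the geometric mean of the two
#'   regimes). Must satisfy `theta_wake > theta_sleep > 0`.
#' @param xi Common Gamma shape; default 0.8.
#' @param p0_wake,p0_sleep Zero-inflation probabilities; defaults 0.1 and
#'   0.6, with `p0_sleep >= p0_wake`.
#' @param winddown_min Wind-down duration before each sleep onset,
#'   minutes; default 30 (0 disables).
#' @param n_days Number of simulated days; default 7.
#' @param epoch_s Epoch length, 30 or 60 s; default 60.
#' @param marker_sd Marker timing error SD, minutes; default 10.
#' @param marker_dropout Probability a marker is never pressed; default
#'   0.2.
#' @param start_time Series start (`POSIXct`, a midnight).
#' @param seed Optional integer seed used by [simulate_subject()].
#' @return A `subject_params` list.
#' @export
subject_params <- function(subject_id = "S01",
                           mean_sot = 1380, mean_wot = 420,
                           day_jitter_sd = 20,
                           theta_wake = 200, theta_sleep = 10,
                           theta_winddown = 45,
                           xi = 0.8,
                           p0_wake = 0.1, p0_sleep = 0.6,
                           winddown_min = 30,
                           n_days = 7, epoch_s = 60,
                           marker_sd = 10, marker_dropout = 0.2,
                           start_time = as.POSIXct("2024-01-01 00:00:00",
                                                   tz = "UTC"),
                           seed = NULL) {
  if (!(theta_wake > theta_sleep && theta_sleep > 0)) {
    stop_contract("need theta_wake > theta_sleep > 0.")
  }
  if (p0_wake < 0 || p0_wake > 1 || p0_sleep < 0 || p0_sleep > 1 ||
      p0_sleep < p0_wake) {
    stop_contract("need 0 <= p0_wake <= p0_sleep <= 1.")
  }
  if (!(mean_wot < mean_sot)) {
    stop_contract("need mean_wot < mean_sot (monophasic night sleep).")
  }
  if (mean_sot - winddown_min <= mean_wot) {
    stop_circacp("infeasible schedule: wind-down begins before wake onset",
                 class = "circacp_error_parameter")
  }
  if (!epoch_s %in% c(30, 60)) {
    stop_contract("`epoch_s` must be 30 or 60.")
  }
  if (n_days < 1) {
    stop_contract("`n_days` must be at least 1.")
  }
  structure(
    list(
      subject_id = subject_id, mean_sot = mean_sot, mean_wot = mean_wot,
      day_jitter_sd = day_jitter_sd, theta_wake = theta_wake,
      theta_sleep = theta_sleep, theta_winddown = theta_winddown,
      xi = xi, p0_wake = p0_wake, p0_sleep = p0_sleep,
      winddown_min = winddown_min, n_days = n_days, epoch_s = epoch_s,
      marker_sd = marker_sd, marker_dropout = marker_dropout,
      start_time = start_time, seed = seed
    ),
    class = "subject_params"
  )
}

#' Simulate one subject's actigraphy with ground truth
#'
#' Generates `n_days * 1440 + 360` minutes of activity starting at a
#' midnight (so the subject begins asleep) and ending at 06:00 after the
#' final night (so the last sleep onset has data on both sides), the true
#' alternating WOT/SOT event sequence, and noisy self-report markers.
#' Fully reproducible from the seed.
#'
#' @param params A [subject_params()] object.
#' @param seed Integer seed; defaults to `params$seed`.
#' @return A list with elements `activity` (actigraphy tibble), `truth`
#'   (event tibble, `source = "truth"`), `markers` (marker tibble) and
#'   `params`.
#' @examples
#' sim <- simulate_subject(subject_params(seed = 7))
#' head(sim$truth)
#' @export
simulate_subject <- function(params, seed = params$seed) {
  if (!inherits(params, "subject_params")) {
    stop_contract("`params` must come from subject_params().")
  }
  if (is.null(seed)) {
    stop_contract("a seed is required for reproducible simulation.")
  }
  withr::with_seed(as.integer(seed), simulate_subject_impl(params))
}

simulate_subject_impl <- function(p) {
  n_min <- p$n_days * 1440 + 360
  day0 <- (seq_len(p$n_days) - 1) * 1440
  wot <- round(day0 + p$mean_wot + rnorm(p$n_days, 0, p$day_jitter_sd))
  sot <- round(day0 + p$mean_sot + rnorm(p$n_days, 0, p$day_jitter_sd))
  if (any(wot >= sot - p$winddown_min) ||
      any(sot[-p$n_days] >= wot[-1]) ||
      any(wot < day0) || any(sot >= day0 + 1740)) {
    stop_circacp("infeasible jittered schedule; reduce day_jitter_sd",
                 class = "circacp_error_parameter")
  }

  # regime per minute: start of recording (midnight) is inside a sleep bout
  regime <- rep("wake", n_min)
  bounds_sleep <- cbind(c(0, sot), c(wot, n_min))  # [lo, hi) minutes
  for (j in seq_len(nrow(bounds_sleep))) {
    lo <- bounds_sleep[j, 1]
    hi <- min(bounds_sleep[j, 2], n_min)
    if (lo < hi) regime[(lo + 1):hi] <- "sleep"
  }
  if (p$winddown_min > 0) {
    for (s in sot) {
      lo <- max(0, s - p$winddown_min)
      hi <- min(s, n_min)
      if (lo < hi) regime[(lo + 1):hi] <- "winddown"
    }
  }

  per_min <- 60 / p$epoch_s
  n_epochs <- n_min * per_min
  ereg <- rep(regime, each = per_min)
  scale_of <- c(wake = p$theta_wake, sleep = p$theta_sleep,
                winddown = p$theta_winddown)
  p0_of <- c(wake = p$p0_wake, sleep = p$p0_sleep, winddown = p$p0_wake)
  # per-epoch scale: counts are additive, so a 30 s epoch carries half the
  # 60 s scale
  theta <- scale_of[ereg] * (p$epoch_s / 60)
  zero <- rbinom(n_epochs, 1, p0_of[ereg]) == 1
  values <- ifelse(zero, 0, rgamma(n_epochs, shape = p$xi, scale = theta))

  ts <- p$start_time + p$epoch_s * (seq_len(n_epochs) - 1)
  activity <- tibble::tibble(
    subject_id = p$subject_id, timestamp = ts, activity = values
  )

  ev_min <- as.vector(rbind(wot, sot))  # WOT_1, SOT_1, WOT_2, ...
  ev_kind <- rep(c("WOT", "SOT"), times = p$n_days)
  ev_time <- p$start_time + 60 * ev_min
  truth <- tibble::tibble(
    subject_id = p$subject_id,
    kind = ev_kind,
    timestamp = ev_time,
    minutes_since_midnight = to_minutes(ev_time, ev_kind),
    source = "truth",
    day = rep(seq_len(p$n_days), each = 2)
  )

  noise <- round(rnorm(length(ev_min), 0, p$marker_sd))
  kept <- rbinom(length(ev_min), 1, 1 - p$marker_dropout) == 1
  markers <- tibble::tibble(
    subject_id = p$subject_id,
    timestamp = sort((p$start_time + 60 * (ev_min + noise))[kept])
  )

  list(activity = activity, truth = truth, markers = markers, params = p)
}

#' Simulate a cohort with between-subject variation
#'
#' Draws per-subject mean onset times around the cohort means (SD
#' `between_sd` minutes, reflecting habitual-schedule differences between
#' people), then simulates each subject with a seed derived
#' deterministically from the cohort seed. Optionally writes the cohort to
#' disk in the package's CSV dialects (`actigraphy.csv`, `markers.csv`,
#' `truth.csv`).
#'
#' @param n_subjects Number of subjects; default 20.
#' @param seed Cohort seed.
#' @param between_sd Between-subject SD of mean onset times, minutes;
#'   default 45.
#' @param out_dir Optional directory to write the cohort CSVs to.
#' @param ... Overrides passed to [subject_params()] for every subject.
#' @return A list with combined tibbles `activity`, `truth`, `markers` and
#'   the list of per-subject `params`.
#' @export
simulate_cohort <- function(n_subjects = 20, seed = 1, between_sd = 45,
                            out_dir = NULL, ...) {
  seed <- as.integer(seed)
  shifts <- withr::with_seed(seed, {
    tibble::tibble(
      sot = rnorm(n_subjects, 0, between_sd),
      wot = rnorm(n_subjects, 0, between_sd)
    )
  })
  dots <- list(...)
  base_sot <- dots$mean_sot %||% 1380
  base_wot <- dots$mean_wot %||% 420
  dots$mean_sot <- NULL
  dots$mean_wot <- NULL

  sims <- purrr::map(seq_len(n_subjects), function(i) {
    args <- c(
      list(
        subject_id = sprintf("S%02d", i),
        mean_sot = round(base_sot + shifts$sot[i]),
        mean_wot = round(base_wot + shifts$wot[i]),
        seed = (seed + i * 131071L) %% 2147483647L
      ),
      dots
    )
    simulate_subject(do.call(subject_params, args))
  })

  out <- list(
    activity = purrr::map_dfr(sims, "activity"),
    truth = purrr::map_dfr(sims, "truth"),
    markers = purrr::map_dfr(sims, "markers"),
    params = purrr::map(sims, "params")
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    act <- dplyr::mutate(out$activity, timestamp = format(
      .data$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC"))
    readr::write_csv(act, file.path(out_dir, "actigraphy.csv"))
    mk <- dplyr::mutate(out$markers, timestamp = format(
      .data$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC"))
    readr::write_csv(mk, file.path(out_dir, "markers.csv"))
    write_swots(out$truth, file.path(out_dir, "truth.csv"))
  }
  out
}
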