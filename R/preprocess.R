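#' Find continuous wearing periods
#'
#' A wearing period is a maximal contiguous stretch of epochs containing no
#' run of consecutive zero counts longer than `max_zero_run_min` minutes.
#' Zero-runs exceeding the cap are taken as device-off time: they split the
#' recording and belong to no period. A run of exactly `max_zero_run_min`
#' minutes does not split. Periods made up entirely of zeros carry no
#' evidence of wear and are dropped.
#'
#' @param data Actigraphy tibble (see [as_actigraphy()]); may hold several
#'   subjects.
#' @param epoch_s Seconds per epoch.
#' @param max_zero_run_min Longest zero-run (minutes) tolerated inside a
#'   wearing period; default 120.
#' @return A tibble with one row per period: `subject_id`, `start_idx`
#'   (1-based, inclusive), `end_idx` (exclusive), `duration_min`. Periods
#'   are ordered and non-overlapping within subject.
#' @export
find_wear_periods <- function(data, epoch_s = 60, max_zero_run_min = 120) {
  if (is.numeric(data)) {
    data <- tibble::tibble(subject_id = "1", timestamp = NA, activity = data)
  }
  dplyr::group_by(data, .data$subject_id) |>
    dplyr::reframe(wear_periods_vec(.data$activity, epoch_s,
                                    max_zero_run_min))
}

wear_periods_vec <- function(values, epoch_s, max_zero_run_min) {
  empty <- tibble::tibble(start_idx = integer(), end_idx = integer(),
                          duration_min = numeric())
  n <- length(values)
  if (n == 0) {
    return(empty)
  }
  r <- rle(values == 0)
  # epochs inside a zero-run strictly longer than the cap split the record
  splits <- r$values & (r$lengths * epoch_s / 60 > max_zero_run_min)
  in_period <- rep(!splits, r$lengths)
  pr <- rle(in_period)
  hi <- cumsum(pr$lengths)
  lo <- hi - pr$lengths + 1L
  keep <- pr$values
  lo <- lo[keep]
  hi <- hi[keep]
  # drop all-zero periods: no evidence the device was worn
  nz <- vapply(seq_along(lo),
               function(i) any(values[lo[i]:hi[i]] > 0), logical(1))
  lo <- lo[nz]
  hi <- hi[nz]
  tibble::tibble(
    start_idx = lo,
    end_idx = hi + 1L,
    duration_min = (hi + 1L - lo) * epoch_s / 60
  )
}

#' Screen a recording for inclusion
#'
#' A subject's recording is usable for circadian-cycle detection when the
#' total recording time is at least `min_total_min` minutes and the longest
#' continuous wearing period is at least `min_period_min` minutes (defaults:
#' 5760 min = 4 days for both).
#'
#' @inheritParams find_wear_periods
#' @param min_total_min Minimum total recording length, minutes.
#' @param min_period_min Minimum longest-wearing-period length, minutes.
#' @return One row per subject: `subject_id`, `passed`, `total_min`,
#'   `longest_start_idx`, `longest_end_idx`, `longest_min`, `reason`
#'   (`""` when passed, otherwise which rule failed).
#' @export
screen_actigraphy <- function(data, epoch_s = 60,
                              min_total_min = 5760,
                              min_period_min = 5760,
                              max_zero_run_min = 120) {
  if (is.numeric(data)) {
    data <- tibble::tibble(subject_id = "1", timestamp = NA, activity = data)
  }
  dplyr::group_by(data, .data$subject_id) |>
    dplyr::reframe(screen_vec(.data$activity, epoch_s, min_total_min,
                              min_period_min, max_zero_run_min))
}

screen_vec <- function(values, epoch_s, min_total_min, min_period_min,
                       max_zero_run_min) {
  total_min <- length(values) * epoch_s / 60
  wp <- wear_periods_vec(values, epoch_s, max_zero_run_min)
  if (nrow(wp) > 0) {
    best <- wp[which.max(wp$duration_min), ]
  } else {
    best <- tibble::tibble(start_idx = NA_integer_, end_idx = NA_integer_,
                           duration_min = 0)
  }
  if (total_min < min_total_min) {
    passed <- FALSE
    reason <- sprintf("total<%g", min_total_min)
  } else if (best$duration_min < min_period_min) {
    passed <- FALSE
    reason <- sprintf("longest_period<%g", min_period_min)
  } else {
    passed <- TRUE
    reason <- ""
  }
  tibble::tibble(
    passed = passed,
    total_min = total_min,
    longest_start_idx = best$start_idx,
    longest_end_idx = best$end_idx,
    longest_min = best$duration_min,
    reason = reason
  )
}

#' Aggregate 30 s epochs to 60 s epochs
#'
#' Sums each consecutive pair of 30 s activity counts into one 60 s count
#' (counts are additive intensities per epoch). A trailing unpaired epoch is
#' dropped with a warning. Total counts are conserved up to that truncation.
#'
#' @param data Actigraphy tibble at 30 s epochs.
#' @param epoch_s Epoch length of `data`; must be 30.
#' @return Actigraphy tibble at 60 s epochs, with each aggregated epoch
#'   stamped at the time of the first epoch of its pair.
#' @export
aggregate_epochs <- function(data, epoch_s = 30) {
  if (!identical(as.numeric(epoch_s), 30)) {
    stop_contract("`aggregate_epochs()` expects 30 s epochs.")
  }
  if (is.numeric(data)) {
    data <- tibble::tibble(
      subject_id = "1",
      timestamp = as.POSIXct("2000-01-01", tz = "UTC") +
        30 * (seq_along(data) - 1),
      activity = data
    )
  }
  dplyr::group_by(data, .data$subject_id) |>
    dplyr::reframe({
      v <- .data$activity
      ts <- .data$timestamp
      n <- length(v)
      if (n < 2) {
        stop_contract("cannot aggregate fewer than two 30 s epochs.")
      }
      if (n %% 2 == 1) {
        warn(sprintf(
          "odd number of 30 s epochs for subject %s; dropping trailing epoch",
          .data$subject_id[1]
        ))
        v <- v[-n]
        ts <- ts[-n]
        n <- n - 1L
      }
      odd <- seq(1L, n, by = 2L)
      tibble::tibble(timestamp = ts[odd], activity = v[odd] + v[odd + 1L])
    })
}
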