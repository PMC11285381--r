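#' Convert event timestamps to minutes since midnight
#'
#' Events are placed on a minutes-since-midnight scale for agreement
#' analysis. Because bedtimes straddle midnight, sleep onsets stamped after
#' midnight but before `sot_rollover_hour` (default noon) belong to the
#' previous evening and get 1440 min added, keeping one night's bedtimes on
#' a contiguous scale; wake onsets are never shifted. Timestamps are
#' truncated to whole minutes first.
#'
#' @param time `POSIXct` event times.
#' @param kind `"SOT"` or `"WOT"`, recycled along `time`.
#' @param sot_rollover_hour Clock hour before which an SOT counts as the
#'   previous night; default 12.
#' @return Minutes in `[0, 2880)`.
#' @examples
#' to_minutes(as.POSIXct("2024-01-02 00:30:00", tz = "UTC"), "SOT")  # 1470
#' @export
to_minutes <- function(time, kind, sot_rollover_hour = 12) {
  time <- floor_minute(time)
  mins <- as.numeric(difftime(time, lubridate::floor_date(time, "day"),
                              units = "mins"))
  kind <- rep_len(kind, length(mins))
  add <- kind == "SOT" & mins < sot_rollover_hour * 60
  mins + 1440 * add
}

#' Match detected onset events to self-reported markers
#'
#' Pairs each estimated sleep/wake onset with the most plausible button
#' press: candidate markers are those within `window_min` minutes
#' (inclusive) of the event. When several markers qualify, the latest is
#' kept for a sleep onset and the earliest for a wake onset — subjects tend
#' to press the button, potter about, and press again closer to actually
#' falling asleep, while on waking the first press is the informative one.
#' Each marker pairs with at most one event; exclusivity is enforced
#' greedily in chronological event order.
#'
#' @param events Event tibble (columns `subject_id`, `kind`, `timestamp`),
#'   e.g. from [detect_sw()]; one or many subjects.
#' @param markers Marker tibble (`subject_id`, `timestamp`), e.g. from
#'   [read_markers()].
#' @param window_min Maximum event-to-marker gap in minutes; default 180.
#' @param sot_rollover_hour Passed to [to_minutes()].
#' @return One row per event: `subject_id`, `kind`, `day` (event date),
#'   `event_time`, `marker_time` (`NA` when unmatched), `est_min`,
#'   `marker_min`, `diff` = `est_min - marker_min`. Unmatched events keep
#'   `NA` marker columns so match rates can be computed downstream.
#' @export
match_markers <- function(events, markers, window_min = 180,
                          sot_rollover_hour = 12) {
  if (nrow(events) == 0) {
    return(tibble::tibble(
      subject_id = character(), kind = character(),
      day = as.Date(character()),
      event_time = as.POSIXct(character(), tz = "UTC"),
      marker_time = as.POSIXct(character(), tz = "UTC"),
      est_min = numeric(), marker_min = numeric(), diff = numeric()
    ))
  }
  events <- dplyr::arrange(events, .data$subject_id, .data$timestamp)
  purrr::map_dfr(split(events, events$subject_id), function(ev) {
    mk <- markers$timestamp[markers$subject_id == ev$subject_id[1]]
    mk <- sort(floor_minute(mk))
    used <- logical(length(mk))
    rows <- vector("list", nrow(ev))
    for (i in seq_len(nrow(ev))) {
      et <- floor_minute(ev$timestamp[i])
      gap <- abs(as.numeric(difftime(mk, et, units = "mins")))
      cand <- which(!used & gap <= window_min)
      marker_time <- as.POSIXct(NA, tz = "UTC")
      if (length(cand) > 0) {
        pick <- if (ev$kind[i] == "SOT") max(cand) else min(cand)
        used[pick] <- TRUE
        marker_time <- mk[pick]
      }
      est_min <- to_minutes(et, ev$kind[i], sot_rollover_hour)
      marker_min <- if (is.na(marker_time)) NA_real_ else {
        to_minutes(marker_time, ev$kind[i], sot_rollover_hour)
      }
      rows[[i]] <- tibble::tibble(
        subject_id = ev$subject_id[i],
        kind = ev$kind[i],
        day = as.Date(et),
        event_time = et,
        marker_time = marker_time,
        est_min = est_min,
        marker_min = marker_min,
        diff = est_min - marker_min
      )
    }
    dplyr::bind_rows(rows)
  })
}

#' Summarise event-marker agreement
#'
#' Bland–Altman statistics per event kind: bias (mean difference between
#' estimated and marker minutes), 95% limits of agreement (bias ± 1.96 SD
#' of the differences), median absolute error, and the fraction of
#' estimated events that found a marker.
#'
#' @param matches Output of [match_markers()] (unmatched rows included —
#'   they feed the match-rate denominator).
#' @return One row per kind: `kind`, `n_events`, `n_pairs`, `match_rate`,
#'   `bias`, `sd_diff`, `loa_low`, `loa_high`, `mae` (all minutes).
#' @export
summarize_agreement <- function(matches) {
  dplyr::group_by(matches, .data$kind) |>
    dplyr::summarize(
      n_events = dplyr::n(),
      n_pairs = sum(!is.na(.data$diff)),
      match_rate = .data$n_pairs / .data$n_events,
      bias = mean(.data$diff, na.rm = TRUE),
      sd_diff = sd(.data$diff, na.rm = TRUE),
      loa_low = .data$bias - 1.96 * .data$sd_diff,
      loa_high = .data$bias + 1.96 * .data$sd_diff,
      mae = median(abs(.data$diff), na.rm = TRUE),
      .groups = "drop"
    )
}
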