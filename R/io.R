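#' Validate an in-memory actigraphy table
#'
#' Checks and normalises a long-format actigraphy table: one row per epoch,
#' columns `subject_id`, `timestamp`, `activity`. Rows are sorted by subject
#' and time; within each subject the timestamps must form a gapless grid of
#' `epoch_s`-second epochs (epoch `i` covers the half-open interval
#' `[timestamp_i, timestamp_i + epoch_s)`). Missing epochs are never imputed
#' silently: fill them with zeros upstream if the gap is known non-wear.
#'
#' @param data A data frame with columns `subject_id`, `timestamp`
#'   (`POSIXct` or ISO 8601 character, minute precision), `activity`
#'   (non-negative finite counts).
#' @param epoch_s Seconds per epoch, 30 or 60.
#' @return A tibble with columns `subject_id` (character), `timestamp`
#'   (`POSIXct`), `activity` (double), sorted by subject then time.
#' @export
as_actigraphy <- function(data, epoch_s = 60) {
  if (!is.data.frame(data)) {
    stop_contract("`data` must be a data frame.")
  }
  need <- c("subject_id", "timestamp", "activity")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    stop_parse(sprintf("missing required column(s): %s",
                       paste(miss, collapse = ", ")))
  }
  if (!epoch_s %in% c(30, 60)) {
    stop_contract("`epoch_s` must be 30 or 60.")
  }

  ts <- parse_timestamps(data$timestamp)
  act <- as.numeric(data$activity)
  bad <- which(!is.finite(act) | act < 0)
  if (length(bad) > 0) {
    stop_validation(sprintf(
      "negative or non-finite activity at row(s) %s",
      paste(head(bad, 5), collapse = ", ")
    ))
  }

  out <- tibble::tibble(
    subject_id = as.character(data$subject_id),
    timestamp = ts,
    activity = act
  )
  out <- dplyr::arrange(out, .data$subject_id, .data$timestamp)

  # per-subject grid checks
  for (sid in unique(out$subject_id)) {
    tsub <- out$timestamp[out$subject_id == sid]
    if (anyDuplicated(tsub)) {
      stop_validation(sprintf("duplicate timestamps for subject %s", sid))
    }
    d <- as.numeric(diff(tsub), units = "secs")
    gaps <- which(d != epoch_s)
    if (length(gaps) > 0) {
      iv <- paste(
        format(tsub[gaps], "%Y-%m-%d %H:%M"), "to",
        format(tsub[gaps + 1], "%Y-%m-%d %H:%M")
      )
      stop_gap(sprintf(
        "subject %s has %d gap(s) in the %d s epoch grid: %s",
        sid, length(gaps), epoch_s,
        paste(head(iv, 3), collapse = "; ")
      ), intervals = iv)
    }
  }
  out
}

parse_timestamps <- function(x) {
  if (inherits(x, "POSIXct")) {
    return(lubridate::with_tz(x, "UTC"))
  }
  ts <- lubridate::parse_date_time(
    as.character(x),
    orders = c("Ymd HMS", "Ymd HM"),
    tz = "UTC", quiet = TRUE
  )
  bad <- which(is.na(ts) & !is.na(x))
  if (length(bad) > 0) {
    stop_parse(sprintf(
      "malformed timestamp at row(s) %s (e.g. \"%s\")",
      paste(head(bad, 5), collapse = ", "), x[bad[1]]
    ))
  }
  ts
}

#' Read actigraphy recordings from CSV
#'
#' The on-disk dialect is a UTF-8 comma-separated file with a mandatory
#' header `subject_id,timestamp,activity`; timestamps are ISO 8601 at
#' minute precision, local clock time without timezone. Rows may appear in
#' any order; the reader sorts them.
#'
#' @inheritParams as_actigraphy
#' @param path Path to the CSV file.
#' @return A validated actigraphy tibble (see [as_actigraphy()]).
#' @seealso [read_markers()], [write_swots()]
#' @export
read_actigraphy <- function(path, epoch_s = 60) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      timestamp = readr::col_character(),
      activity = readr::col_double()
    )
  )
  as_actigraphy(raw, epoch_s = epoch_s)
}

#' Read self-reported event markers from CSV
#'
#' Markers are the button presses a subject makes at bed and wake times.
#' Dialect: header `subject_id,timestamp`, ISO 8601 minute-precision
#' timestamps. An empty file (header only) is a valid empty marker list —
#' some subjects never press the button.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `subject_id`, `timestamp`, sorted.
#' @export
read_markers <- function(path) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      timestamp = readr::col_character()
    )
  )
  out <- tibble::tibble(
    subject_id = as.character(raw$subject_id),
    timestamp = parse_timestamps(raw$timestamp)
  )
  dplyr::arrange(out, .data$subject_id, .data$timestamp)
}

#' Write and read detected sleep/wake onset events
#'
#' Events round-trip losslessly through this CSV dialect:
#' `subject_id,kind,timestamp,minutes_since_midnight,source` with `kind` in
#' `{SOT, WOT}` and `source` in `{circacp, cosinor_rough, marker, truth}`.
#'
#' @param events A tibble of events as produced by [detect_sw()].
#' @param path Output CSV path.
#' @return `events`, invisibly (for `write_swots`); the events tibble (for
#'   `read_swots`).
#' @export
write_swots <- function(events, path) {
  need <- c("subject_id", "kind", "timestamp", "minutes_since_midnight",
            "source")
  miss <- setdiff(need, names(events))
  if (length(miss) > 0) {
    stop_contract(sprintf("events are missing column(s): %s",
                          paste(miss, collapse = ", ")))
  }
  out <- dplyr::mutate(
    events[, need],
    timestamp = format(.data$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  )
  readr::write_csv(out, path)
  invisible(events)
}

#' @rdname write_swots
#' @export
read_swots <- function(path) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      kind = readr::col_character(),
      timestamp = readr::col_character(),
      minutes_since_midnight = readr::col_double(),
      source = readr::col_character()
    )
  )
  bad_kind <- setdiff(unique(raw$kind), c("SOT", "WOT"))
  if (length(bad_kind) > 0) {
    stop_validation(sprintf("unknown event kind(s): %s",
                            paste(bad_kind, collapse = ", ")))
  }
  dplyr::mutate(tibble::as_tibble(raw),
                timestamp = parse_timestamps(.data$timestamp))
}
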