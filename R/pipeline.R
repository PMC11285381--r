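#' Build per-transition search windows from rough circadian transitions
#'
#' Each rough transition from the dichotomized cosinor curve anchors one
#' search window expected to contain exactly one true sleep/wake
#' transition. Window edges are the midpoints between consecutive rough
#' transitions (the series ends for the outermost), so under monophasic
#' sleep every window straddles exactly one true onset. Windows shorter
#' than `min_window` epochs are dropped with a warning — too little data
#' on either side of the anchor for a stable change-point fit.
#'
#' @param transitions Tibble with `index` (1-based epoch of the new
#'   state) and `direction` (`"to_sleep"`/`"to_wake"`), as in
#'   [dichotomize()] output, or a `rough_cycle` object.
#' @param n Series length in epochs.
#' @param min_window Minimum window length in epochs; default 240 (4 h at
#'   60 s epochs).
#' @return Tibble of half-open windows: `lo`, `hi` (`[lo, hi)`, 1-based),
#'   `direction`, `anchor`.
#' @export
build_windows <- function(transitions, n, min_window = 240) {
  if (inherits(transitions, "rough_cycle")) {
    transitions <- transitions$transitions
  }
  if (nrow(transitions) == 0) {
    stop_circacp("no circadian transitions: cannot build search windows",
                 class = "circacp_error_no_rhythm")
  }
  a <- transitions$index
  mids <- floor((a[-length(a)] + a[-1]) / 2)
  lo <- c(1L, mids)
  hi <- c(mids, n + 1L)
  win <- tibble::tibble(
    lo = as.integer(lo), hi = as.integer(hi),
    direction = transitions$direction,
    anchor = as.integer(a)
  )
  short <- win$hi - win$lo < min_window
  if (any(short)) {
    warn(sprintf(
      "dropping %d search window(s) shorter than %d epochs",
      sum(short), min_window
    ))
    win <- win[!short, ]
  }
  win
}

# One round of change-point detection over a set of windows. Returns the
# windows tibble with k_hat (window coords), k_global (last epoch of the
# old regime, series coords), theta estimates, xi and delta_bic appended.
detect_in_windows <- function(y, windows, lambda, min_seg, eps) {
  res <- purrr::map(seq_len(nrow(windows)), function(j) {
    seg <- y[windows$lo[j]:(windows$hi[j] - 1L)]
    cp <- detect_cp(seg, lambda = lambda, min_seg = min_seg, eps = eps)
    tibble::tibble(
      k_hat = cp$k_hat,
      k_global = windows$lo[j] - 1L + cp$k_hat,
      theta1_hat = cp$theta1_hat, theta2_hat = cp$theta2_hat,
      xi = cp$xi, delta_bic = cp$delta_bic
    )
  })
  dplyr::bind_cols(windows, dplyr::bind_rows(res))
}

#' Second-round refinement of detected change points
#'
#' Rebuilds the search windows using midpoints between consecutive
#' *first-round* change points (replacing the cosinor anchors, which can
#' sit well off the true onsets and bias the window edges), then re-runs
#' the change-point search once in each new window, re-estimating the
#' Gamma shape per window. A refined location replaces the first-round one
#' only when its window is long enough to search (at least `2 * min_seg`
#' epochs); otherwise the first-round location is kept.
#'
#' @param first_round Tibble from the first detection round (columns `lo`,
#'   `hi`, `direction`, `anchor`, `k_global`, ordered by `k_global`).
#' @param y Activity counts for the whole series.
#' @param lambda,min_seg,eps Change-point parameters (see [detect_cp()]).
#' @return A tibble of the same shape with refined windows and locations.
#' @export
refine_cps <- function(first_round, y, lambda = 50, min_seg = 30,
                       eps = 0.1) {
  m <- nrow(first_round)
  if (m == 0) {
    return(first_round)
  }
  n <- length(y)
  kg <- first_round$k_global
  mids <- as.integer(floor((kg[-m] + kg[-1]) / 2))
  lo <- c(1L, mids)
  hi <- c(mids, n + 1L)
  out <- first_round
  for (j in seq_len(m)) {
    if (hi[j] - lo[j] < 2 * min_seg) {
      next  # window too short to re-search; keep the first-round location
    }
    seg <- y[lo[j]:(hi[j] - 1L)]
    cp <- detect_cp(seg, lambda = lambda, min_seg = min_seg, eps = eps)
    out$lo[j] <- lo[j]
    out$hi[j] <- hi[j]
    out$k_hat[j] <- cp$k_hat
    out$k_global[j] <- lo[j] - 1L + cp$k_hat
    out$theta1_hat[j] <- cp$theta1_hat
    out$theta2_hat[j] <- cp$theta2_hat
    out$xi[j] <- cp$xi
    out$delta_bic[j] <- cp$delta_bic
  }
  out
}

#' Detect sleep/wake onsets for one subject
#'
#' Runs the full detection chain on a screened single-subject series at
#' 60 s epochs: cosinor fit, dichotomization into rough circadian cycles,
#' per-cycle search windows, Gamma change-point detection in each window,
#' one second-round refinement pass, and conversion of the refined change
#' points to calendar-time onset events. The event is placed at the start
#' of epoch `k_global + 1`, the first epoch of the new regime. A
#' Calinski–Harabasz QC comparison of the rough and refined segmentations
#' is attached.
#'
#' @param data Single-subject actigraphy tibble at 60 s epochs (pass 30 s
#'   data through [aggregate_epochs()] first).
#' @param period_min,lower_fraction Cosinor parameters (see
#'   [fit_cosinor()], [dichotomize()]).
#' @param lambda,min_seg,eps Change-point parameters (see [detect_cp()]).
#' @param min_window Minimum search-window length, epochs.
#' @param ch_threshold QC flag threshold (see [qc_evaluate()]).
#' @param cosinor_method Solver for [fit_cosinor()].
#' @param check_screening Assert that the series passes
#'   [screen_actigraphy()] before detecting (the caller should normally
#'   have screened already and sliced to the longest wearing period).
#' @return An object of class `sw_detection`: list with `subject_id`,
#'   `events` (tibble: `subject_id`, `kind`, `timestamp`,
#'   `minutes_since_midnight`, `source = "circacp"`, `epoch`, `window_lo`,
#'   `window_hi`), `fit`, `rough`, `windows` (refined, with change-point
#'   columns), `qc` (one-row tibble), `n`, `epoch_s`, `start_time`.
#'   Supports [tidy()], [glance()], [autoplot()].
#' @export
detect_subject <- function(data, period_min = 1440, lower_fraction = 0.18,
                           lambda = 50, min_seg = 30, eps = 0.1,
                           min_window = 240, ch_threshold = 100,
                           cosinor_method = "linear",
                           check_screening = TRUE) {
  y <- pull_activity(data)
  n <- length(y)
  if (!is.data.frame(data) || !"timestamp" %in% names(data)) {
    stop_contract("`data` must be an actigraphy tibble with timestamps.")
  }
  epoch_s <- as.numeric(difftime(data$timestamp[2], data$timestamp[1],
                                 units = "secs"))
  if (!identical(epoch_s, 60)) {
    stop_contract(
      "detection runs on 60 s epochs; aggregate 30 s data first.")
  }
  subject_id <- as.character(data$subject_id[1] %||% "1")
  start_time <- data$timestamp[1]
  if (check_screening) {
    sc <- screen_actigraphy(data, epoch_s = 60)
    if (!all(sc$passed)) {
      stop_contract(sprintf(
        "series fails screening (%s); screen and slice before detection",
        sc$reason[!sc$passed][1]
      ))
    }
  }

  fit <- fit_cosinor(y, period_min = period_min, method = cosinor_method)
  rough <- dichotomize(fit, lower_fraction = lower_fraction)
  if (nrow(rough$transitions) == 0) {
    stop_circacp("dichotomized curve never changes state: no rhythm",
                 class = "circacp_error_no_rhythm")
  }
  windows <- build_windows(rough, n, min_window = min_window)
  if (nrow(windows) == 0) {
    stop_circacp("all search windows dropped: no events detectable",
                 class = "circacp_error_no_events")
  }

  round1 <- detect_in_windows(y, windows, lambda, min_seg, eps)
  round2 <- refine_cps(round1, y, lambda = lambda, min_seg = min_seg,
                       eps = eps)

  ev_epoch <- round2$k_global + 1L   # first epoch of the new regime
  ev_kind <- ifelse(round2$direction == "to_sleep", "SOT", "WOT")
  ev_time <- start_time + 60 * round2$k_global
  events <- tibble::tibble(
    subject_id = subject_id,
    kind = ev_kind,
    timestamp = ev_time,
    minutes_since_midnight = to_minutes(ev_time, ev_kind),
    source = "circacp",
    epoch = ev_epoch,
    window_lo = round2$lo,
    window_hi = round2$hi
  )
  if (nrow(events) > 1 &&
      any(events$kind[-1] == events$kind[-nrow(events)])) {
    warn(paste(
      "detected events do not strictly alternate SOT/WOT",
      "(short circadian cycles were dropped)"
    ))
  }

  rough_lab <- ifelse(rough$state == "nocturnal", "sleep", "wake")
  pro_lab <- sw_labels(n, ev_epoch, round2$direction)
  qc <- if (length(unique(pro_lab)) == 2 && length(unique(rough_lab)) == 2) {
    qc_evaluate(y, rough_lab, pro_lab, threshold = ch_threshold)
  } else {
    tibble::tibble(ch_cos = NA_real_, ch_pro = NA_real_,
                   delta = NA_real_, flagged = NA)
  }

  structure(
    list(
      subject_id = subject_id, events = events, fit = fit, rough = rough,
      windows = round2, qc = qc, n = n, epoch_s = 60,
      start_time = start_time, activity = y
    ),
    class = "sw_detection"
  )
}

#' @export
print.sw_detection <- function(x, ...) {
  cat(sprintf(
    "<sw_detection> subject %s: %d events over %d epochs (CH delta = %.1f%s)\n",
    x$subject_id, nrow(x$events), x$n, x$qc$delta,
    if (isTRUE(x$qc$flagged)) ", FLAGGED" else ""
  ))
  invisible(x)
}

#' @export
tidy.sw_detection <- function(x, ...) {
  x$events
}

#' @export
glance.sw_detection <- function(x, ...) {
  tibble::tibble(
    subject_id = x$subject_id,
    n_epochs = x$n,
    n_events = nrow(x$events),
    mes = x$fit$mes, amp = x$fit$amp, phi = x$fit$phi,
    ch_cos = x$qc$ch_cos, ch_pro = x$qc$ch_pro,
    ch_delta = x$qc$delta, flagged = x$qc$flagged
  )
}

#' Detect sleep/wake onsets for a cohort
#'
#' Screens every subject ([screen_actigraphy()]), slices each passing
#' recording to its longest continuous wearing period, runs
#' [detect_subject()] on it, and binds the resulting events. Subjects
#' failing screening (or raising a no-rhythm error) contribute no events
#' but appear in the per-subject QC table.
#'
#' @param data Actigraphy tibble at 60 s epochs, one or many subjects.
#' @param ... Passed to [detect_subject()].
#' @param min_total_min,min_period_min,max_zero_run_min Screening
#'   thresholds (see [screen_actigraphy()]).
#' @return A tibble of detected events across subjects. The per-subject
#'   summary (screening outcome, event counts, Calinski–Harabasz QC) is
#'   attached as attribute `"qc"`.
#' @examples
#' \donttest{
#' sim <- simulate_cohort(n_subjects = 2, seed = 1)
#' events <- detect_sw(sim$activity)
#' attr(events, "qc")
#' }
#' @export
detect_sw <- function(data, ..., min_total_min = 5760,
                      min_period_min = 5760, max_zero_run_min = 120) {
  subjects <- unique(data$subject_id)
  all_events <- list()
  qc_rows <- list()
  for (sid in subjects) {
    sub <- data[data$subject_id == sid, ]
    sc <- screen_actigraphy(sub, epoch_s = 60,
                            min_total_min = min_total_min,
                            min_period_min = min_period_min,
                            max_zero_run_min = max_zero_run_min)
    if (!sc$passed) {
      inform(sprintf("subject %s screened out: %s", sid, sc$reason))
      qc_rows[[sid]] <- tibble::tibble(
        subject_id = sid, passed = FALSE, reason = sc$reason,
        n_events = 0L, ch_cos = NA_real_, ch_pro = NA_real_,
        ch_delta = NA_real_, flagged = NA
      )
      next
    }
    sub <- sub[sc$longest_start_idx:(sc$longest_end_idx - 1L), ]
    det <- tryCatch(
      detect_subject(sub, ..., check_screening = FALSE),
      circacp_error_no_rhythm = function(e) e,
      circacp_error_no_events = function(e) e,
      circacp_error_degenerate = function(e) e
    )
    if (inherits(det, "condition")) {
      inform(sprintf("subject %s: %s", sid, conditionMessage(det)))
      qc_rows[[sid]] <- tibble::tibble(
        subject_id = sid, passed = TRUE, reason = "no_rhythm",
        n_events = 0L, ch_cos = NA_real_, ch_pro = NA_real_,
        ch_delta = NA_real_, flagged = NA
      )
      next
    }
    all_events[[sid]] <- det$events
    g <- glance(det)
    qc_rows[[sid]] <- tibble::tibble(
      subject_id = sid, passed = TRUE, reason = "",
      n_events = g$n_events, ch_cos = g$ch_cos, ch_pro = g$ch_pro,
      ch_delta = g$ch_delta, flagged = g$flagged
    )
  }
  events <- dplyr::bind_rows(all_events)
  attr(events, "qc") <- dplyr::bind_rows(qc_rows)
  events
}
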