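# Internal error helpers. Every condition raised by the package carries the
# class "circacp_error" plus a specific subclass so callers can test for the
# failure mode rather than match message text.

stop_circacp <- function(message, class, ...) {
  abort(message, class = c(class, "circacp_error"), ...)
}

stop_contract <- function(message, ...) {
  stop_circacp(message, class = "circacp_error_contract", ...)
}

stop_validation <- function(message, ...) {
  stop_circacp(message, class = "circacp_error_validation", ...)
}

stop_parse <- function(message, ...) {
  stop_circacp(message, class = "circacp_error_parse", ...)
}

stop_gap <- function(message, ...) {
  stop_circacp(message, class = "circacp_error_gap", ...)
}

stop_degenerate <- function(message, ...) {
  stop_circacp(message, class = "circacp_error_degenerate", ...)
}

# Extract the activity vector from a numeric vector or a single-subject
# actigraphy data frame.
pull_activity <- function(data, arg = "data") {
  if (is.numeric(data)) {
    return(as.numeric(data))
  }
  if (is.data.frame(data)) {
    if (!"activity" %in% names(data)) {
      stop_contract(sprintf("`%s` must have an `activity` column.", arg))
    }
    if ("subject_id" %in% names(data) &&
        length(unique(data$subject_id)) > 1L) {
      stop_contract(sprintf(
        "`%s` contains %d subjects; supply one subject at a time.",
        arg, length(unique(data$subject_id))
      ))
    }
    return(as.numeric(data$activity))
  }
  stop_contract(sprintf("`%s` must be a numeric vector or a data frame.", arg))
}

# Minute-precision timestamp: drop seconds (sub-minute precision is
# truncated before any minute arithmetic).
floor_minute <- function(x) {
  lubridate::floor_date(x, unit = "minute")
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
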