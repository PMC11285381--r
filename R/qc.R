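#' Calinski–Harabasz index for a two-class sleep/wake labelling
#'
#' The variance-ratio criterion for `k = 2` clusters over one-dimensional
#' activity counts:
#' \deqn{CH = \frac{SSB}{\sum_j SSW_j} \cdot \frac{n - 2}{2 - 1}}
#' with \eqn{SSB = \sum_j n_j (\mu_j - \mu)^2} the between-cluster and
#' \eqn{SSW_j = \sum_{i \in j} (y_i - \mu_j)^2} the within-cluster sums of
#' squares. Higher values mean better-separated sleep and wake clusters.
#' Invariant to affine transforms of the counts and to swapping the two
#' labels.
#'
#' @param values Activity counts.
#' @param labels Binary labelling of the same length (any two-level vector,
#'   e.g. `"sleep"`/`"wake"`); both classes must be present.
#' @return The CH value; `Inf` when the clusters are perfectly separated
#'   (zero within-cluster variance but distinct means), 0 when the cluster
#'   means coincide.
#' @examples
#' ch_index(c(1, 3, 7, 9), c("a", "a", "b", "b"))  # 18
#' @export
ch_index <- function(values, labels) {
  values <- as.numeric(values)
  n <- length(values)
  if (length(labels) != n) {
    stop_contract("`values` and `labels` must have the same length.")
  }
  lv <- unique(labels)
  if (length(lv) != 2) {
    stop_contract(sprintf(
      "labels must contain exactly 2 classes (found %d).", length(lv)
    ))
  }
  mu <- mean(values)
  ssb <- 0
  ssw <- 0
  for (l in lv) {
    v <- values[labels == l]
    m <- mean(v)
    ssb <- ssb + length(v) * (m - mu)^2
    ssw <- ssw + sum((v - m)^2)
  }
  if (ssb == 0) {
    return(0)
  }
  if (ssw == 0) {
    return(Inf)
  }
  ssb / ssw * (n - 2)
}

#' Flag likely detection errors by comparing segmentations
#'
#' Computes the Calinski–Harabasz index for the rough cosinor labelling
#' (`ch_cos`) and the refined change-point labelling (`ch_pro`) over the
#' same activity counts. When the refined segmentation fails to improve
#' cluster separation by at least `threshold` (default 100), the detection
#' likely contains errors — typically a subject without a usable circadian
#' rhythm — and the subject is flagged.
#'
#' @param values Activity counts (raw, not zero-adjusted).
#' @param rough_labels Binary per-epoch labels from the dichotomized
#'   cosinor curve.
#' @param circacp_labels Binary per-epoch labels implied by the detected
#'   onset events.
#' @param threshold Flag when `ch_pro - ch_cos` falls below this; default
#'   100.
#' @return One-row tibble: `ch_cos`, `ch_pro`, `delta`, `flagged`.
#' @export
qc_evaluate <- function(values, rough_labels, circacp_labels,
                        threshold = 100) {
  ch_cos <- ch_index(values, rough_labels)
  ch_pro <- ch_index(values, circacp_labels)
  delta <- ch_pro - ch_cos
  tibble::tibble(
    ch_cos = ch_cos,
    ch_pro = ch_pro,
    delta = delta,
    flagged = delta < threshold
  )
}

# Epoch-level sleep/wake labels implied by an alternating event sequence.
# `event_idx` is the first epoch of each new regime, `direction` the regime
# entered ("to_sleep"/"to_wake"); epochs before the first event get the
# opposite of its direction.
sw_labels <- function(n, event_idx, direction) {
  if (length(event_idx) == 0) {
    stop_contract("need at least one event to label epochs.")
  }
  lab <- character(n)
  first <- if (direction[1] == "to_sleep") "wake" else "sleep"
  lab[seq_len(event_idx[1] - 1)] <- first
  bounds <- c(event_idx, n + 1L)
  for (j in seq_along(event_idx)) {
    lab[seq.int(bounds[j], bounds[j + 1] - 1L)] <-
      if (direction[j] == "to_sleep") "sleep" else "wake"
  }
  lab
}
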