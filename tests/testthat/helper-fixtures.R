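# Shared fixtures and independent oracles, all built in code.

midnight <- function(day = "2024-01-01") {
  as.POSIXct(paste(day, "00:00:00"), tz = "UTC")
}

# Long-format actigraphy tibble from a vector of counts.
make_series <- function(values, epoch_s = 60, subject_id = "S1",
                        start = midnight()) {
  tibble::tibble(
    subject_id = subject_id,
    timestamp = start + epoch_s * (seq_along(values) - 1),
    activity = as.numeric(values)
  )
}

# Write an actigraphy tibble to a temp CSV in the package dialect.
write_actigraphy_csv <- function(data, path = withr::local_tempfile(
                                   fileext = ".csv",
                                   .local_envir = parent.frame())) {
  out <- dplyr::mutate(data, timestamp = format(timestamp,
                                                "%Y-%m-%d %H:%M:%S"))
  readr::write_csv(out, path)
  path
}

# First-principles change-point oracle: exhaustive penalized -2 log L1
# from full Gamma log-densities, same candidate range and tie-break as
# detect_cp(). Independent of the reduced-objective implementation.
cp_oracle <- function(y, xi, lambda = 50, min_seg = 30) {
  n <- length(y)
  ks <- seq.int(min_seg, n - min_seg)
  obj <- vapply(ks, function(k) {
    th1 <- sum(y[1:k]) / (k * xi)
    th2 <- sum(y[(k + 1):n]) / ((n - k) * xi)
    ll <- sum(dgamma(y[1:k], shape = xi, scale = th1, log = TRUE)) +
      sum(dgamma(y[(k + 1):n], shape = xi, scale = th2, log = TRUE))
    -2 * ll + 2 * log(n) + lambda * (2 * k / n - 1)^2 * log(n)
  }, numeric(1))
  ord <- order(obj, abs(ks - n / 2), ks)
  list(k_hat = ks[ord[1]], ks = ks, obj = obj)
}

# A random Gamma window with (possibly) one scale change, for oracle tests.
random_window <- function(n = NULL) {
  n <- n %||% sample(60:200, 1)
  xi <- runif(1, 0.5, 3)
  th1 <- exp(runif(1, 0, log(100)))
  th2 <- exp(runif(1, 0, log(100)))
  k <- sample(30:(n - 30), 1)
  y <- c(rgamma(k, shape = xi, scale = th1),
         rgamma(n - k, shape = xi, scale = th2))
  list(y = y, n = n, true_k = k)
}

`%||%` <- rlang::`%||%`
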