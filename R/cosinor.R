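#' Fit a cosinor model to an activity series
#'
#' The cosinor model describes the circadian rhythm of activity as
#' \deqn{r(t) = mes + amp \cdot \cos((t - \phi) \, 2\pi / T)}
#' with `mes` the midline estimating statistic of rhythm (counts), `amp`
#' the amplitude (counts), `phi` the acrophase (time of peak activity, in
#' epochs from the series start) and `T` the period, fixed at 1440 min for
#' a 24 h rhythm at 60 s epochs. Parameters are estimated by least squares.
#'
#' Two solvers are available. `"linear"` (the default) rewrites the model
#' as a harmonic regression on \eqn{\cos(2\pi t/T)} and \eqn{\sin(2\pi
#' t/T)} and solves it exactly by ordinary least squares — for fixed `T`
#' this is the global optimum. `"gauss_newton"` minimises the nonlinear
#' objective directly with Levenberg–Marquardt, multi-started over the
#' acrophase (the default initializer plus `phi` at 0, T/4, T/2, 3T/4,
#' keeping the best SSE) because the objective is non-convex in `phi`.
#' Both agree to high precision on well-behaved data.
#'
#' @param data A single-subject actigraphy tibble (see [as_actigraphy()])
#'   at 60 s epochs, or a numeric vector of counts. The time index `t` is
#'   the 1-based epoch index from the series start; `phi` shares that
#'   origin and is reported modulo `period_min`.
#' @param period_min Rhythm period in minutes (= epochs at 60 s); default
#'   1440.
#' @param method `"linear"` or `"gauss_newton"`.
#' @param init Named start values `c(mes, amp, phi)` for the iterative
#'   solver; the default `(500, 550, 227)` reflects typical adult wrist
#'   actigraphy and is only an optimizer seed.
#' @param huber If `TRUE`, replace least squares by a Huber M-estimate
#'   (robust to heavy-tailed activity bursts); linear solver only.
#' @param max_iter Iteration cap for the iterative solver.
#' @return An object of class `cosinor_fit`: a list with elements `mes`,
#'   `amp` (always `>= 0`), `phi` (in `[0, period_min)`), `period`, `sse`,
#'   `fitted`, `n`, `method`. Supports [tidy()], [glance()], [autoplot()].
#' @examples
#' t <- 1:4320
#' y <- 300 + 250 * cos((t - 900) * 2 * pi / 1440)
#' fit <- fit_cosinor(y)
#' glance(fit)
#' @export
fit_cosinor <- function(data, period_min = 1440,
                        method = c("linear", "gauss_newton"),
                        init = c(mes = 500, amp = 550, phi = 227),
                        huber = FALSE, max_iter = 200) {
  y <- pull_activity(data)
  n <- length(y)
  if (n < 3) {
    stop_contract("cosinor fit needs at least 3 epochs.")
  }
  TT <- period_min
  if (!is_scalar_number(TT) || TT <= 0) {
    stop_contract("`period_min` must be a positive number.")
  }
  if (n < 2 * TT) {
    warn(sprintf(
      "series covers %.1f cycles; at least 2 are recommended for a stable fit",
      n / TT
    ))
  }
  method <- match.arg(method)
  t <- seq_len(n)
  w <- 2 * pi / TT

  if (method == "linear") {
    cb <- cos(w * t)
    sb <- sin(w * t)
    if (huber) {
      f <- MASS::rlm(y ~ cb + sb, psi = MASS::psi.huber, maxit = max_iter)
    } else {
      f <- lm(y ~ cb + sb)
    }
    b <- coef(f)
    mes <- unname(b[1])
    # amp*cos(w(t - phi)) = amp*cos(w*phi)*cos(wt) + amp*sin(w*phi)*sin(wt)
    amp <- unname(sqrt(b[2]^2 + b[3]^2))
    phi <- if (amp > 0) unname(atan2(b[3], b[2])) / w else 0
  } else {
    starts <- list(
      c(mes = unname(init["mes"]), amp = unname(init["amp"]),
        phi = unname(init["phi"])),
      c(mes = mean(y), amp = stats::sd(y) * sqrt(2), phi = 0),
      c(mes = mean(y), amp = stats::sd(y) * sqrt(2), phi = TT / 4),
      c(mes = mean(y), amp = stats::sd(y) * sqrt(2), phi = TT / 2),
      c(mes = mean(y), amp = stats::sd(y) * sqrt(2), phi = 3 * TT / 4)
    )
    best <- NULL
    last_iterate <- NULL
    for (s in starts) {
      f <- tryCatch(
        minpack.lm::nlsLM(
          y ~ mes + amp * cos((t - phi) * w),
          start = as.list(s),
          control = minpack.lm::nls.lm.control(maxiter = max_iter)
        ),
        error = function(e) NULL
      )
      if (is.null(f)) next
      sse <- sum(stats::resid(f)^2)
      last_iterate <- coef(f)
      if (is.null(best) || sse < best$sse) {
        best <- list(coef = coef(f), sse = sse)
      }
    }
    if (is.null(best)) {
      stop_circacp("cosinor solver failed to converge from any start",
                   class = "circacp_error_fit",
                   last_iterate = last_iterate)
    }
    mes <- unname(best$coef["mes"])
    amp <- unname(best$coef["amp"])
    phi <- unname(best$coef["phi"])
  }

  # normalise: amp >= 0 (cos symmetry: -a cos(x) = a cos(x + pi)), phi in [0, T)
  if (amp < 0) {
    amp <- -amp
    phi <- phi + TT / 2
  }
  phi <- phi %% TT
  fitted <- mes + amp * cos((t - phi) * w)

  structure(
    list(
      mes = mes, amp = amp, phi = phi, period = TT,
      sse = sum((y - fitted)^2), fitted = fitted, n = n,
      method = method
    ),
    class = "cosinor_fit"
  )
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf(
    "<cosinor_fit> n = %d, period = %g min\n  mes = %.2f  amp = %.2f  phi = %.1f min  (sse = %.4g)\n",
    x$n, x$period, x$mes, x$amp, x$phi, x$sse
  ))
  invisible(x)
}

#' @export
tidy.cosinor_fit <- function(x, ...) {
  tibble::tibble(
    term = c("mes", "amp", "phi", "period"),
    estimate = c(x$mes, x$amp, x$phi, x$period)
  )
}

#' @export
glance.cosinor_fit <- function(x, ...) {
  tibble::tibble(
    mes = x$mes, amp = x$amp, phi = x$phi, period = x$period,
    sse = x$sse, n = x$n, method = x$method
  )
}

#' Dichotomize a fitted cosinor curve into rough circadian cycles
#'
#' Splits the fitted curve into nocturnal and diurnal states by
#' thresholding at the lower `lower_fraction` of its range: epochs where
#' the fitted value is strictly below
#' `min(fitted) + lower_fraction * (max(fitted) - min(fitted))` are
#' nocturnal, ties and above are diurnal. The default 0.18 reflects the
#' roughly one-fifth of the day an ageing adult spends asleep. The state
#' changes give rough sleep-to-wake and wake-to-sleep transitions that seed
#' the change-point search.
#'
#' @param fit A [cosinor_fit][fit_cosinor()].
#' @param lower_fraction Fraction of the fitted range treated as nocturnal,
#'   in (0, 1); default 0.18.
#' @return An object of class `rough_cycle`: list with `state` (character,
#'   `"nocturnal"`/`"diurnal"` per epoch), `transitions` (tibble with
#'   `index` = first epoch of the new state, `direction` in
#'   `{"to_sleep", "to_wake"}`), and `threshold`. Supports [tidy()].
#' @export
dichotomize <- function(fit, lower_fraction = 0.18) {
  if (!inherits(fit, "cosinor_fit")) {
    stop_contract("`fit` must be a cosinor_fit.")
  }
  if (!is_scalar_number(lower_fraction) ||
      lower_fraction <= 0 || lower_fraction >= 1) {
    stop_contract("`lower_fraction` must lie strictly between 0 and 1.")
  }
  f <- fit$fitted
  rng <- range(f)
  if (fit$amp <= 0 || rng[1] == rng[2]) {
    stop_degenerate(
      "flat fitted curve (amplitude ~ 0): no circadian rhythm to dichotomize"
    )
  }
  threshold <- rng[1] + lower_fraction * (rng[2] - rng[1])
  nocturnal <- f < threshold
  state <- ifelse(nocturnal, "nocturnal", "diurnal")
  chg <- which(state[-1] != state[-length(state)]) + 1L
  transitions <- tibble::tibble(
    index = chg,
    direction = ifelse(state[chg] == "nocturnal", "to_sleep", "to_wake")
  )
  structure(
    list(state = state, transitions = transitions, threshold = threshold),
    class = "rough_cycle"
  )
}

#' @export
print.rough_cycle <- function(x, ...) {
  cat(sprintf(
    "<rough_cycle> %d epochs, %d transitions, threshold = %.2f\n",
    length(x$state), nrow(x$transitions), x$threshold
  ))
  invisible(x)
}

#' @export
tidy.rough_cycle <- function(x, ...) {
  x$transitions
}
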