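noiseless <- function(n = 4320, mes = 300, amp = 250, phi = 900,
                      TT = 1440) {
  t <- seq_len(n)
  mes + amp * cos((t - phi) * 2 * pi / TT)
}

test_that("both solvers recover exact parameters on noiseless input", {
  y <- noiseless()
  for (m in c("linear", "gauss_newton")) {
    f <- fit_cosinor(y, method = m)
    expect_lt(abs(f$mes - 300) / 300, 1e-6)
    expect_lt(abs(f$amp - 250) / 250, 1e-6)
    expect_lt(abs(f$phi - 900) / 900, 1e-6)
    expect_lt(f$sse, 1e-10)
  }
  fl <- fit_cosinor(y, method = "linear")
  fn <- fit_cosinor(y, method = "gauss_newton")
  expect_lt(max(abs(c(fl$mes - fn$mes, fl$amp - fn$amp,
                      fl$phi - fn$phi))), 1e-8)
})

test_that("mean recovered parameters match truth under i.i.d. noise", {
  withr::local_seed(21)
  est <- t(replicate(50, {
    y <- noiseless(n = 2880) + rnorm(2880, 0, 40)
    f <- fit_cosinor(y)
    c(f$mes, f$amp, f$phi)
  }))
  se <- apply(est, 2, sd) / sqrt(nrow(est))
  truth <- c(300, 250, 900)
  expect_true(all(abs(colMeans(est) - truth) < 4 * se + 0.05))
})

test_that("fit normalisation and degenerate limits behave", {
  y <- noiseless()
  f <- fit_cosinor(y, method = "gauss_newton")
  expect_gte(f$amp, 0)
  expect_true(f$phi >= 0 && f$phi < 1440)
  # SSE at the optimum no worse than at the default initializer
  t <- seq_along(y)
  sse_init <- sum((y - (500 + 550 * cos((t - 227) * 2 * pi / 1440)))^2)
  expect_lte(f$sse, sse_init)

  const <- suppressWarnings(fit_cosinor(rep(5, 3000)))
  expect_lt(const$amp, 1e-8)
  expect_equal(const$mes, 5, tolerance = 1e-8)

  expect_error(fit_cosinor(c(1, 2)), class = "circacp_error_contract")
})

test_that("dichotomization matches the closed-form nocturnal fraction", {
  y <- noiseless(n = 1440)  # exactly one period
  f <- suppressWarnings(fit_cosinor(y))
  rc <- dichotomize(f, lower_fraction = 0.18)
  frac <- mean(rc$state == "nocturnal")
  expect_lt(abs(frac - (1 - acos(2 * 0.18 - 1) / pi)), 2 / 1440)
  expect_equal(rc$threshold, f$mes - 0.64 * f$amp, tolerance = 1e-6)

  rc5 <- dichotomize(f, lower_fraction = 0.5)
  expect_lt(abs(mean(rc5$state == "nocturnal") - 0.5), 2 / 1440)
})

test_that("dichotomization is shift-invariant and alternates directions", {
  withr::local_seed(31)
  y <- noiseless(n = 4320) + rnorm(4320, 0, 30)
  f <- fit_cosinor(y)
  f_shift <- f
  f_shift$fitted <- f$fitted + 123.4
  f_shift$mes <- f$mes + 123.4
  a <- dichotomize(f)
  b <- dichotomize(f_shift)
  expect_identical(a$state, b$state)

  d <- a$transitions$direction
  expect_true(all(d[-1] != d[-length(d)]))
  expect_lte(abs(sum(d == "to_sleep") - sum(d == "to_wake")), 1)

  flat <- suppressWarnings(fit_cosinor(rep(7, 3000)))
  expect_error(dichotomize(flat), class = "circacp_error_degenerate")
  expect_error(dichotomize(f, lower_fraction = 1),
               class = "circacp_error_contract")
})

test_that("tidy and glance expose the fitted parameters", {
  f <- fit_cosinor(noiseless())
  td <- tidy(f)
  expect_named(td, c("term", "estimate"))
  expect_equal(td$estimate[td$term == "amp"], f$amp)
  g <- glance(f)
  expect_equal(g$n, 4320)
})
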