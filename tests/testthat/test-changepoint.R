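test_that("zero adjustment floors counts and preserves order", {
  expect_equal(adjust_zeros(c(0, 2, 0), eps = 0.1), c(0.1, 2, 0.1))
  y <- c(3.5, 1, 200)
  expect_identical(adjust_zeros(y), y)
  expect_error(adjust_zeros(c(1, 2), eps = 0),
               class = "circacp_error_contract")
  expect_error(adjust_zeros(c(-1, 2)), class = "circacp_error_validation")
})

test_that("gamma shape MLE recovers known shapes", {
  withr::local_seed(41)
  y <- rgamma(1e5, shape = 2, scale = 3)
  expect_equal(estimate_gamma_shape(y), 2, tolerance = 0.02)

  e <- rexp(1e5, rate = 1 / 5)  # exponential = Gamma shape 1
  expect_equal(estimate_gamma_shape(e), 1, tolerance = 0.02)

  expect_error(estimate_gamma_shape(rep(4, 100)),
               class = "circacp_error_degenerate")
  expect_error(estimate_gamma_shape(rgamma(5, 2)),
               class = "circacp_error_contract")
})

test_that("gamma shape MLE agrees with an independent full-MLE fit", {
  withr::local_seed(42)
  y <- rgamma(2000, shape = 0.8, scale = 120)
  ref <- suppressWarnings(MASS::fitdistr(y, "gamma"))$estimate[["shape"]]
  expect_equal(estimate_gamma_shape(y), ref, tolerance = 1e-4)
})

test_that("edge penalty vanishes at the window midpoint for any lambda", {
  withr::local_seed(43)
  y <- adjust_zeros(rgamma(100, 1, scale = 4))
  for (lam in c(0, 1, 50, 1000)) {
    expect_equal(mic(y, 50, xi = 1, lambda = lam),
                 mic(y, 50, xi = 1, lambda = 0))
  }
  expect_error(mic(y, 100, xi = 1), class = "circacp_error_contract")
  expect_error(mic(y, 50, xi = -1), class = "circacp_error_contract")
})

test_that("reduced objective equals the full likelihood up to a constant", {
  withr::local_seed(44)
  for (rep in 1:10) {
    w <- random_window()
    y <- adjust_zeros(w$y)
    xi <- estimate_gamma_shape(y)
    ks <- 30:(w$n - 30)
    reduced <- mic(y, ks, xi, lambda = 0)
    full <- cp_oracle(y, xi, lambda = 0)$obj
    diffs <- reduced - full
    expect_lt(max(diffs) - min(diffs), 1e-7)
  }
})

test_that("detected location equals the exhaustive-likelihood oracle", {
  withr::local_seed(45)
  for (rep in 1:25) {
    w <- random_window()
    y <- adjust_zeros(w$y)
    xi <- estimate_gamma_shape(y)
    got <- detect_cp(w$y, xi = xi)
    expect_identical(got$k_hat, cp_oracle(y, xi)$k_hat)
  }
})

test_that("a noise-free step is located exactly", {
  y <- c(rep(1, 100), rep(100, 100))
  res <- detect_cp(y)
  expect_identical(res$k_hat, 100L)
  expect_lt(res$theta1_hat, res$theta2_hat)
  expect_error(detect_cp(rep(1, 40), min_seg = 30),
               class = "circacp_error_window_too_short")
})

test_that("location is invariant to rescaling counts with fixed shape", {
  withr::local_seed(46)
  y <- c(rgamma(120, 1, scale = 3), rgamma(80, 1, scale = 40))
  base <- detect_cp(y, xi = 1)$k_hat
  for (c_ in c(0.01, 7, 1000)) {
    expect_identical(detect_cp(c_ * y, xi = 1, eps = 0.1 * c_)$k_hat, base)
  }
})

test_that("the edge penalty pulls homogeneous-window estimates centreward", {
  withr::local_seed(47)
  dev <- t(replicate(100, {
    y <- rgamma(200, 1, scale = 10)
    c(pen = abs(detect_cp(y, lambda = 50)$k_hat - 100),
      free = abs(detect_cp(y, lambda = 0)$k_hat - 100))
  }))
  expect_lt(mean(dev[, "pen"]), mean(dev[, "free"]))
})

test_that("detection is deterministic and consistent as windows grow", {
  withr::local_seed(48)
  y <- c(rgamma(100, 1, scale = 2), rgamma(100, 1, scale = 80))
  expect_identical(glance(detect_cp(y)), glance(detect_cp(y)))

  med_rel <- vapply(c(100, 400, 1600), function(n) {
    errs <- replicate(50, {
      yy <- c(rgamma(n / 2, 1, scale = 2), rgamma(n / 2, 1, scale = 80))
      abs(detect_cp(yy)$k_hat - n / 2) / n
    })
    median(errs)
  }, numeric(1))
  expect_true(all(diff(med_rel) <= 0))
})
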