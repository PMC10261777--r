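test_that("Peleg curve reproduces hand-computed values and its limit", {
  p <- peleg_params(k1 = 8.13, k2 = 0.146)
  expect_identical(peleg_moisture(0, 0.37, p), 0.37)
  # hand arithmetic: 0.10 + 10 / (8.13 + 0.146 * 10)
  expect_equal(peleg_moisture(10, 0.10, p), 0.10 + 10 / 9.59, tolerance = 1e-12)
  expect_equal(peleg_moisture(1e9, 0.10, p), 0.10 + 1 / 0.146, tolerance = 1e-6)

  expect_equal(peleg_equilibrium(1, 1), 2.0)
  expect_equal(round(peleg_equilibrium(0, 0.176), 3), 5.682)
  expect_lt(abs(peleg_equilibrium(0, 0.146) - 6.848) / 6.848, 0.001)
})

test_that("Peleg curve is strictly increasing and bounded by Xw0 + 1/k2", {
  set.seed(11)
  t <- seq(0, 300, length.out = 500)
  for (i in 1:25) {
    p <- peleg_params(runif(1, 0.5, 15), runif(1, 0.05, 0.5))
    Xw0 <- runif(1, 0, 0.5)
    X <- peleg_moisture(t, Xw0, p)
    expect_true(all(diff(X) > 0))
    expect_true(all(X < Xw0 + 1 / p$k2))
  }
})

test_that("Weibull curve hits 1 - exp(-1) of total change at t = beta for any shape", {
  for (alpha in c(0.3, 0.6, 1.0, 2.0)) {
    p <- weibull_params(alpha, beta = 23.18, Xeq = 3.1)
    Xw0 <- 0.1
    expect_equal(weibull_moisture(0, Xw0, p), Xw0, tolerance = 1e-14)
    frac <- (weibull_moisture(p$beta, Xw0, p) - Xw0) / (p$Xeq - Xw0)
    expect_equal(frac, 1 - exp(-1), tolerance = 1e-12)
  }
  # normalized residual stays in (0, 1] on t >= 0
  set.seed(12)
  t <- seq(0, 200, length.out = 200)
  for (i in 1:10) {
    p <- weibull_params(runif(1, 0.2, 3), runif(1, 5, 80), runif(1, 2, 7))
    r <- (weibull_moisture(t, 0.1, p) - p$Xeq) / (0.1 - p$Xeq)
    # exp(-(t/beta)^alpha) lies in (0, 1]; allow underflow to 0 at huge t
    expect_true(all(r >= 0 & r <= 1 + 1e-12))
  }
})

test_that("Weibull with alpha = 1 is the single-exponential model", {
  p <- weibull_params(1, beta = 20, Xeq = 4)
  expect_equal(weibull_moisture(20, 0, p), 4 * (1 - exp(-1)), tolerance = 1e-12)
  t <- seq(0, 120, by = 3)
  expect_equal(weibull_moisture(t, 0.2, p),
               4 + (0.2 - 4) * exp(-t / 20), tolerance = 1e-12)
})

test_that("logarithmic curve passes through Xeq at 1/k and Xw0 at e/k", {
  set.seed(13)
  for (i in 1:10) {
    p <- proposed_params(k = runif(1, 0.01, 1), Xeq = runif(1, -3, 3))
    Xw0 <- runif(1, 0, 0.5)
    expect_equal(proposed_moisture(1 / p$k, Xw0, p), p$Xeq, tolerance = 1e-12)
    expect_equal(proposed_moisture(exp(1) / p$k, Xw0, p), Xw0, tolerance = 1e-12)
  }
  # hand arithmetic: k * t = 1 makes the log vanish
  expect_equal(proposed_moisture(20, 0.1, proposed_params(0.05, -2.0)), -2.0,
               tolerance = 1e-12)
  # linear in ln t with slope Xw0 - Xeq
  p <- proposed_params(0.07, -1.2)
  slope <- (proposed_moisture(40, 0.1, p) - proposed_moisture(10, 0.1, p)) /
    (log(40) - log(10))
  expect_equal(slope, 0.1 - (-1.2), tolerance = 1e-12)
})

test_that("model evaluators reject invalid domains and parameters", {
  p <- peleg_params(8, 0.2)
  expect_error(peleg_moisture(-1, 0.1, p), "time")
  expect_error(peleg_moisture(NaN, 0.1, p), "finite")
  expect_error(proposed_moisture(0, 0.1, proposed_params(0.05, -2)), "> 0")
  expect_error(proposed_moisture(-5, 0.1, proposed_params(0.05, -2)), "> 0")
  expect_error(weibull_moisture(-1, 0.1, weibull_params(1, 10, 3)), "time")
  expect_error(peleg_params(0, 0.2), "k1")
  expect_error(peleg_params(5, -1), "k2")
  expect_error(weibull_params(0, 10, 3), "alpha")
  expect_error(weibull_params(1, 10, -0.5), "Xeq")
  expect_error(proposed_params(-0.1, 2), "k")
  expect_error(peleg_equilibrium(0.1, 0), "k2")
})
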