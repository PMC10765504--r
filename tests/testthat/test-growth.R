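test_that("logistic fit recovers generating parameters on noiseless data", {
  t <- 0:10
  K <- 70e8; N0 <- 5.28e8; r <- 1.2
  fit <- fit_logistic(t, logistic_curve(t, K, N0, r))
  expect_equal(fit$K, K, tolerance = 1e-6)
  expect_equal(fit$N0, N0, tolerance = 1e-6)
  expect_equal(fit$r, r, tolerance = 1e-6)
  # closed-form half-capacity time from the generating parameters
  expect_equal(fit$t_mid, log((K - N0) / N0) / r, tolerance = 1e-6)
  expect_equal(fit$t_stationary, 2 * fit$t_mid)
})

test_that("logistic fit refuses degenerate series", {
  expect_error(fit_logistic(0:9, rep(1e8, 10)), "no growth signal")
  expect_error(fit_logistic(0:9, seq(1e9, 1e8, length.out = 10)),
               "no growth signal")
  expect_error(fit_logistic(0:3, c(1, 2, 3, 4) * 1e8), "at least 5")
  expect_error(fit_logistic(0:5, c(-1, 2, 3, 4, 5, 6)), "positive")
})

test_that("exponential window starts at t0 or at a detected die-off bottom", {
  t <- 0:10
  rising <- logistic_curve(t, 70e8, 5e8, 0.8)
  fit <- fit_logistic(t, rising)
  w <- exponential_window(t, rising, fit)
  expect_equal(w[1], 0)
  expect_equal(w[2], fit$t_stationary)

  # D/S-like: 25% die-off on day 1, then regrowth
  dip <- c(20e8, logistic_curve(0:9, 60e8, 15e8, 0.9))
  fitd <- fit_logistic(t[-1], dip[-1])
  wd <- exponential_window(t, dip, fitd)
  expect_equal(wd[1], 1)

  # a shallow (within-noise) dip does not move the window start
  shallow <- rising; shallow[2] <- rising[1] * 0.97
  ws <- exponential_window(t, shallow, fit)
  expect_equal(ws[1], 0)
})

test_that("specific growth rate is the exact ln-slope", {
  t <- 0:4
  expect_equal(specific_growth_rate(t, 2e8 * exp(0.19 * t), c(0, 4)), 0.19)
  expect_equal(specific_growth_rate(t, rep(3e8, 5), c(0, 4)), 0)
  expect_equal(specific_growth_rate(c(0, 1), c(1, exp(1)), c(0, 1)), 1)
  expect_error(specific_growth_rate(t, c(1, 2, 0, 4, 5), c(0, 4)),
               "nonpositive")
})

test_that("mu never exceeds r and approaches r as N0/K shrinks", {
  # with a fixed sampling grid, a shrinking N0/K pushes t_mid beyond the
  # observations so the window sees pure exponential growth and mu -> r
  t <- seq(0, 12, by = 0.5)
  r <- 0.9
  gaps <- c()
  for (ratio in c(1e-2, 1e-3, 1e-4, 1e-5)) {
    y <- logistic_curve(t, 1e10, 1e10 * ratio, r)
    fit <- fit_logistic(t, y)
    w <- exponential_window(t, y, fit)
    mu <- specific_growth_rate(t, y, w)
    expect_lte(mu, fit$r + 1e-9)
    gaps <- c(gaps, fit$r - mu)
  }
  expect_true(all(diff(gaps) < 0))  # gap shrinks as N0/K shrinks
  expect_lt(gaps[4] / r, 0.05)     # and mu is within 5% of r at 1e-5
})

test_that("interpolation is exact at knots and refuses extrapolation", {
  expect_equal(interpolate_at(c(0, 2), c(10, 20), 1), 15)
  expect_equal(interpolate_at(c(0, 2, 5), c(10, 20, 50), 2), 20)
  expect_error(interpolate_at(c(0, 2), c(10, 20), -1), "outside")
})

test_that("excess integration matches closed-form triangle areas", {
  # linear rise 0 -> 1 over [0, 6]: area 3; normalized 0.5
  expect_equal(integrate_excess(c(0, 6), c(0, 1), c(0, 6), 0, "above"), 3)
  expect_equal(integrate_excess(c(0, 6), c(0, 1), c(0, 6), 0, "above",
                                normalize = TRUE), 0.5)
  # linear fall 100 -> 95 below baseline 100: area 15
  expect_equal(integrate_excess(c(0, 6), c(100, 95), c(0, 6), 100, "below"),
               15)
  expect_equal(integrate_excess(c(0, 6), rep(7, 2), c(0, 6), 7, "above"), 0)
  # partial window uses interpolated endpoints
  expect_equal(integrate_excess(c(0, 6), c(0, 6), c(1, 3), 0, "above"), 4)
})

test_that("trapezoidal integrals track an adaptive-quadrature oracle on smooth curves", {
  f <- function(t) 5 + 2 * sin(t / 2) + 0.1 * t^2
  t <- seq(0, 10, by = 0.1)
  ours <- integrate_excess(t, f(t), c(0.25, 9.75), baseline = 0,
                           sign = "above")
  oracle <- stats::integrate(f, 0.25, 9.75, rel.tol = 1e-10)$value
  expect_lt(abs(ours - oracle) / oracle, 0.01)
})

test_that("cell-to-carbon conversion uses 20 fg C per cell and 12.011 g per mol", {
  # 1e9 cells * 20e-15 g / 12.011 g mol-1 * 1e6 umol mol-1
  expect_equal(bacterial_carbon(1e9), 1.6651, tolerance = 1e-4)
  expect_equal(bacterial_carbon(0), 0)
  expect_equal(bacterial_carbon(17.6e8), 2.9307, tolerance = 1e-4)
  expect_equal(bacterial_carbon(1e9, fg_per_cell = 40),
               2 * bacterial_carbon(1e9))
  expect_error(bacterial_carbon(-1), ">= 0")
})

test_that("BGE equals the closed-form ratio on linear trajectories", {
  t <- c(0, 6)
  # BC rises 0 -> 1 umol C; DOC falls 100 -> 95: 3 / 15 = 20%
  pa <- t / 6 / bacterial_carbon(1) * 1  # abundance whose BC rises 0 -> 1
  fit <- list(t_mid = 3, t_stationary = 6)
  res <- compute_bge(t, pa, t, c(100, 95), fit, window = c(0, 6))
  expect_equal(res$bge, 0.2)
  expect_equal(res$bge_percent, 20)
  expect_identical(res$flag, "ok")

  # constant abundance: zero BGE
  res0 <- compute_bge(t, c(5, 5), t, c(100, 95), fit, window = c(0, 6))
  expect_equal(res0$bge, 0)

  # constant DOC: undefined, flagged
  resna <- compute_bge(t, pa, t, c(100, 100), fit, window = c(0, 6))
  expect_true(is.nan(resna$bge))
  expect_identical(resna$flag, "no net DOC removal")
})

test_that("BGE is invariant to a DOC offset and consistent time rescaling", {
  t <- c(0, 2, 4, 6)
  pa <- c(1e8, 3e8, 6e8, 8e8)
  doc <- c(100, 98, 95, 94)
  fit <- list(t_mid = 3, t_stationary = 6)
  a <- compute_bge(t, pa, t, doc, fit, window = c(0, 6))
  b <- compute_bge(t, pa, t, doc + 37, fit, window = c(0, 6))
  expect_equal(a$bge, b$bge)
  # hours instead of days: ratio unchanged
  c_ <- compute_bge(t * 24, pa, t * 24, doc, fit, window = c(0, 144))
  expect_equal(a$bge, c_$bge)
})

test_that("window rate matches an independent normal-equations oracle", {
  expect_equal(window_rate(0:19, 100 - 0.79 * (0:19), 0, 19), -0.79)
  expect_equal(window_rate(0:5, rep(4, 6), 0, 5), 0)
  t <- seq(-3, 3, by = 0.5)
  v <- 2 + 0.3 * t + 0.05 * t^2
  ours <- window_rate(t, v, -3, 3)
  X <- cbind(1, t)
  beta <- solve(t(X) %*% X, t(X) %*% v)  # brute-force normal equations
  expect_equal(ours, unname(beta[2, 1]))
})

test_that("fit_growth recovers configured rates for all treatments of a noiseless bundle", {
  b <- generate_experiment(default_config(noise_scale = 0), seed = 11)
  fits <- fit_growth(b$timeseries)
  mu <- tapply(fits$mu, fits$treatment, mean)
  expect_equal(unname(mu[["S/S"]]), 0.03, tolerance = 1e-4)
  expect_equal(unname(mu[["S/D"]]), 0.19, tolerance = 1e-4)
  expect_equal(unname(mu[["D/S"]]), 0.11, tolerance = 1e-4)
  expect_equal(unique(fits$exp_duration[fits$treatment == "S/D"]), 4.9,
               tolerance = 1e-6)
  expect_true(all(fits$mu <= fits$r))
})
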