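# PDF damped-oscillator model of the E-wave: closed forms, derived indexes,
# and Levenberg-Marquardt inversion.

table1 <- list(k = 211, c = 16.6, x_o = 9.6)

test_that("closed-form velocity matches adaptive ODE integration in all regimes", {
  draws <- c(draw_pdf_params(12, seed = 101),
             list(do.call(pdf_params, table1)))
  for (p in draws) {
    t_end <- if (damping_regime(p$k, p$c) == "under")
      pi / sqrt(p$k - p$c^2 / 4) else 6 / sqrt(p$k)
    tt <- seq(0, t_end, length.out = 300)
    v <- pdf_velocity(p, tt)
    v_ode <- ode_pdf_speed(p$k, p$c, p$x_o, tt)
    expect_lt(max(abs(v - v_ode)), 1e-8 * max(v))
  }
})

test_that("velocity vanishes at rest, for zero load, and decays for c > 0", {
  p0 <- pdf_params(k = 211, c = 16.6, x_o = 0)
  expect_equal(pdf_velocity(p0, seq(0, 1, by = 0.01)), rep(0, 101))
  p <- do.call(pdf_params, table1)
  expect_identical(pdf_velocity(p, 0), 0)
  expect_lt(pdf_velocity(p, 5), 1e-8 * pdf_derived_indexes(p)$E_peak)
})

test_that("domain and validation errors are raised", {
  p <- do.call(pdf_params, table1)
  expect_error(pdf_velocity(p, c(-0.1, 0.1)), "negative")
  expect_error(pdf_params(k = -1, c = 1, x_o = 1), "'k'")
  expect_error(pdf_params(k = 1, c = -1, x_o = 1), "'c'")
  expect_error(pdf_params(k = 1, c = 1, x_o = -1), "'x_o'")
})

test_that("initial force equals k*x_o and the initial acceleration limit", {
  p <- do.call(pdf_params, table1)
  expect_equal(pdf_initial_force(p), 211 * 9.6)  # = 2025.6 cm/s^2
  expect_equal(pdf_initial_force(pdf_params(211, 16.6, 0)), 0)
  for (dt in 10^seq(-3, -6)) {
    expect_equal(pdf_velocity(p, dt) / dt, pdf_initial_force(p),
                 tolerance = 20 * dt)
  }
})

test_that("derived indexes follow their exact formulas and E_peak matches a grid argmax", {
  p <- do.call(pdf_params, table1)
  di <- pdf_derived_indexes(p)
  expect_identical(di$F_i, di$peak_gradient)
  expect_identical(di$potential_energy, di$F_i * p$x_o / 2)
  expect_equal(di$potential_energy, 0.5 * 211 * 9.6^2)  # 9722.88 cm^2/s^2
  tt <- seq(0, pi / sqrt(p$k - p$c^2 / 4), length.out = 200001)
  expect_equal(di$E_peak, max(pdf_velocity(p, tt)), tolerance = 1e-6)
  z <- pdf_derived_indexes(pdf_params(211, 16.6, 0))
  expect_equal(c(z$F_i, z$potential_energy, z$E_peak), c(0, 0, 0))
})

test_that("velocity is continuous across the critical-damping boundary", {
  k <- 211
  eps <- 1e-8 * k
  below <- pdf_params(k, sqrt(4 * k - eps), 9.6)
  above <- pdf_params(k, sqrt(4 * k + eps), 9.6)
  tt <- seq(0.001, 0.4, length.out = 100)
  expect_lt(max(abs(pdf_velocity(below, tt) - pdf_velocity(above, tt))) /
              max(pdf_velocity(below, tt)), 1e-6)
})

test_that("x_o scales velocity and initial force exactly (scale covariance)", {
  tt <- seq(0, 0.3, by = 0.005)
  for (p in draw_pdf_params(5, seed = 202)) {
    p2 <- pdf_params(p$k, p$c, 3.7 * p$x_o)
    expect_equal(pdf_velocity(p2, tt), 3.7 * pdf_velocity(p, tt),
                 tolerance = 1e-14)
    expect_equal(pdf_initial_force(p2), 3.7 * pdf_initial_force(p),
                 tolerance = 1e-14)
  }
})

test_that("mechanical energy is non-increasing for damped motion", {
  for (p in draw_pdf_params(6, seed = 303)) {
    if (p$c == 0) next
    tt <- seq(0, 0.6, length.out = 400)
    st <- diastkin:::.pdf_state(p, tt)
    energy <- 0.5 * st$v^2 + 0.5 * p$k * st$x^2
    expect_true(all(diff(energy) <= 1e-9 * energy[1]))
  }
})

test_that("noiseless round-trip recovers parameters in all damping regimes", {
  cases <- list(do.call(pdf_params, table1),          # under
                pdf_params(211, 2 * sqrt(211), 9.6),  # critical
                pdf_params(120, 3 * sqrt(120), 8),    # over
                pdf_params(211, 0, 9.6))              # undamped boundary
  for (p in cases) {
    t_end <- if (damping_regime(p$k, p$c) == "under")
      pi / sqrt(max(p$k - p$c^2 / 4, 1e-9)) else 5 / sqrt(p$k)
    tt <- seq(0, t_end, by = 1 / 200)
    fit <- fit_pdf(ewave_contour(tt, pdf_velocity(p, tt)))
    expect_true(fit$converged)
    expect_lt(abs(fit$params$k / p$k - 1), 1e-6)
    expect_lt(abs(fit$params$x_o / p$x_o - 1), 1e-6)
    if (p$c > 0) expect_lt(abs(fit$params$c / p$c - 1), 1e-6)
    else expect_lt(abs(fit$params$c), 1e-6 * sqrt(p$k))
  }
})

test_that("fit is independent of the starting point for noiseless input", {
  p <- do.call(pdf_params, table1)
  tt <- seq(0, 0.26, by = 1 / 200)
  ct <- ewave_contour(tt, pdf_velocity(p, tt))
  f1 <- fit_pdf(ct)
  f2 <- fit_pdf(ct, init = pdf_params(k = 80, c = 2, x_o = 4))
  expect_equal(unlist(f1$params), unlist(f2$params), tolerance = 1e-8)
})

test_that("degenerate contours are rejected", {
  tt <- seq(0, 0.25, by = 1 / 200)
  expect_error(fit_pdf(ewave_contour(tt, rep(0, length(tt)))), "flat")
  expect_error(fit_pdf(ewave_contour(tt[1:5], rep(1, 5))), "at least")
  expect_error(ewave_contour(c(0, 0.01, 0.03), c(0, 1, 2)), "uniform")
})

test_that("mean parameter recovery under 5% velocity noise is within 2%", {
  p <- do.call(pdf_params, table1)
  tt <- seq(0, pi / sqrt(p$k - p$c^2 / 4), by = 1 / 200)
  v0 <- pdf_velocity(p, tt)
  set.seed(424)
  est <- t(vapply(seq_len(100), function(i) {
    fit <- fit_pdf(ewave_contour(tt, v0 + rnorm(length(v0), 0, 0.05 * max(v0))))
    c(fit$params$k, fit$params$c, fit$params$x_o)
  }, numeric(3)))
  bias <- colMeans(est) / c(p$k, p$c, p$x_o) - 1
  expect_lt(max(abs(bias)), 0.02)
})
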