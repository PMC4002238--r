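# Chung kinematic model of isovolumic pressure decay: closed forms,
# phase-plane behaviour, terminal force, Weiss/logistic comparators, and
# Levenberg-Marquardt inversion.

t1 <- list(E_k = 1552, mu = 0.013, P_inf = -5, P_0 = 60, dPdt_0 = -1200)

test_that("closed form reproduces initial conditions and the ODE solution", {
  cp <- do.call(chung_params, t1)
  m0 <- chung_pressure(cp, 0)
  expect_identical(m0$P, 60)
  expect_identical(m0$dPdt, -1200)

  draws <- c(draw_chung_params(12, seed = 515), list(cp))
  for (p in draws) {
    tt <- seq(0, 0.1, length.out = 200)
    m <- chung_pressure(p, tt)
    o <- ode_chung(p$E_k, p$mu, p$P_inf, p$P_0, p$dPdt_0, tt)
    expect_lt(max(abs(m$P - o$P)) / max(abs(o$P)), 1e-8)
    expect_lt(max(abs(m$dPdt - o$dPdt)) / max(abs(o$dPdt)), 1e-8)
  }
})

test_that("inertia-negligible limit collapses to the Weiss exponential", {
  kappa <- 20                       # mu * E_k held fixed, 1/s
  tt <- seq(0, 0.15, length.out = 200)
  sup_err <- vapply(c(1e-3, 1e-4, 1e-5), function(mu) {
    p <- chung_params(E_k = kappa / mu, mu = mu, P_inf = -5, P_0 = 60,
                      dPdt_0 = -kappa * 65)
    ref <- -5 + 65 * exp(-kappa * tt)
    max(abs(chung_pressure(p, tt)$P - ref))
  }, numeric(1))
  expect_lt(sup_err[3] / 65, 1e-3)      # relative to the decay amplitude
  expect_true(all(diff(sup_err) < 0))   # converges monotonically as mu -> 0
})

test_that("parameter validation rejects non-physical values", {
  expect_error(chung_params(-1, 0.01, -5, 60, -1200), "E_k")
  expect_error(chung_params(1552, 0, -5, 60, -1200), "mu")
  expect_error(chung_pressure(do.call(chung_params, t1), -0.01), "negative")
})

test_that("phase plane passes through the initial condition and is curvilinear", {
  cp <- do.call(chung_params, t1)
  expect_equal(phase_plane(cp, 60), -1200, tolerance = 1e-6)
  # dP/dt minimum lies strictly inside (P_inf, P_0)
  rest <- chung_params(1552, 0.013, -4, 90, 0)
  tt <- seq(0, 0.3, by = 1e-5)
  m <- chung_pressure(rest, tt)
  P_at_min <- m$P[which.min(m$dPdt)]
  expect_gt(P_at_min, rest$P_inf)
  expect_lt(P_at_min, rest$P_0)
  expect_error(phase_plane(cp, 1000), "monotone trajectory range")
})

test_that("phase plane converges to the Weiss line of slope -mu*E_k", {
  kappa <- 20
  Pg <- seq(5, 55, by = 2.5)
  for (mu in c(1e-3, 1e-4)) {
    p <- chung_params(E_k = kappa / mu, mu = mu, P_inf = -5, P_0 = 60,
                      dPdt_0 = -kappa * 65)
    line <- -kappa * (Pg - (-5))
    err <- max(abs(phase_plane(p, Pg) - line)) / max(abs(line))
    expect_lt(err, if (mu == 1e-4) 0.01 else 0.05)
  }
})

test_that("noiseless round-trip recovers the generating parameters", {
  cp <- do.call(chung_params, t1)
  tt <- seq(0, 0.06, by = 1e-3)
  m <- chung_pressure(cp, tt)
  tr <- pressure_trace(tt, m$P, LVEDP = 16)
  fit <- suppressWarnings(fit_chung(tr, c(0, length(tt)), dPdt = m$dPdt))
  expect_true(fit$converged)
  expect_lt(abs(fit$params$E_k / t1$E_k - 1), 1e-6)
  expect_lt(abs(fit$params$mu / t1$mu - 1), 1e-6)
  expect_lt(abs(fit$params$P_inf / t1$P_inf - 1), 1e-6)
  # and with free initial conditions
  fit2 <- suppressWarnings(fit_chung(tr, c(0, length(tt)), dPdt = m$dPdt,
                                     fit_ics = TRUE))
  expect_lt(abs(fit2$params$E_k / t1$E_k - 1), 1e-6)
  expect_lt(abs(fit2$params$P_0 / t1$P_0 - 1), 1e-6)
})

test_that("a pure exponential decay is fitted with slow eigenvalue 1/tau", {
  # a single exponential solves the model exactly for a one-parameter family
  # of (E_k, mu); the identifiable quantity is the slow decay eigenvalue
  tau <- 0.05
  tt <- seq(0, 0.2, by = 1e-3)
  P <- -5 + 65 * exp(-tt / tau)
  D <- -65 / tau * exp(-tt / tau)
  tr <- pressure_trace(tt, P, LVEDP = 16)
  fit <- suppressWarnings(fit_chung(tr, c(0, length(tt)), dPdt = D))
  a <- 1 / (2 * fit$params$mu)
  lam_slow <- a - sqrt(a^2 - fit$params$E_k)
  expect_lt(abs(lam_slow * tau - 1), 0.01)
  expect_lt(fit$rmse_P, 1e-6)
})

test_that("short windows and missing pre-minimum samples are flagged", {
  cp <- do.call(chung_params, t1)
  tt <- seq(0, 0.06, by = 1e-3)
  m <- chung_pressure(cp, tt)
  tr <- pressure_trace(tt, m$P, LVEDP = 16)
  expect_error(fit_chung(tr, c(0, 10), dPdt = m$dPdt), "at least 20")
  i_min <- which.min(m$dPdt)              # window opening at the minimum
  w <- capture_warnings(fit_chung(tr, c(i_min - 1L, length(tt)),
                                  dPdt = m$dPdt))
  expect_match(w, "pre-minimum", all = FALSE)
})

test_that("terminal force is P_MVO * MVA with correct unit conversion", {
  expect_identical(terminal_force(16), 64)                    # mmHg cm^2
  expect_identical(terminal_force(0), 0)
  expect_equal(terminal_force(16, unit = "dyn"), 16 * 1333.22 * 4)
  expect_equal(terminal_force(16, unit = "dyn"), 85326.08)
  expect_error(terminal_force(NA_real_), "missing")
  expect_error(terminal_force(numeric(0)), "missing")
  expect_error(terminal_force(16, MVA = 0), "positive")
})

test_that("Weiss tau is exact on exponential input and degrades with curvature", {
  tau <- 0.05
  tt <- seq(0, 0.15, by = 1e-3)
  P <- 60 * exp(-tt / tau)
  D <- -60 / tau * exp(-tt / tau)
  tr <- pressure_trace(tt, P, LVEDP = 1.5)
  est <- weiss_tau(tr, c(0, length(tt)), dPdt = D)
  expect_lt(abs(est$tau / tau - 1), 1e-6)
  expect_equal(est$r2, 1)
  # via the Savitzky-Golay derivative the estimate is still close
  est_sg <- weiss_tau(tr, c(0, length(tt)))
  expect_lt(abs(est_sg$tau / tau - 1), 1e-3)
  # constant pressure has no decay
  flat <- pressure_trace(tt, rep(30, length(tt)), LVEDP = 16)
  expect_error(weiss_tau(flat, c(0, length(tt)), dPdt = rep(0, length(tt))),
               "constant|no decay|non-negative")
  # strong curvature (4 mu^2 E_k near 1) leaves a sub-unity linear fit
  curved <- chung_params(1552, 0.013, -4, 90, 0)
  m <- chung_pressure(curved, tt)
  trc <- pressure_trace(tt, m$P, LVEDP = 16)
  est_c <- weiss_tau(trc, c(0, length(tt)), dPdt = m$dPdt)
  expect_lt(est_c$r2, 1 - 1e-4)
})

test_that("logistic tau round-trips and rejects flat input", {
  tau_L <- 0.03
  tt <- seq(0, 0.12, by = 1e-3)
  P <- 80 / (1 + exp(tt / tau_L)) + 2
  tr <- pressure_trace(tt, P, LVEDP = 3)
  est <- logistic_tau(tr, c(0, length(tt)))
  expect_true(est$converged)
  expect_lt(abs(est$tau_L / tau_L - 1), 1e-4)
  # exponential input: fit exists and converges
  Pe <- -5 + 65 * exp(-tt / 0.05)
  est_e <- logistic_tau(pressure_trace(tt, Pe, LVEDP = 16),
                        c(0, length(tt)))
  expect_true(est_e$converged)
  flat <- pressure_trace(tt, rep(30, length(tt)), LVEDP = 16)
  expect_error(logistic_tau(flat, c(0, length(tt))), "constant")
})

test_that("overdamped closed form stays finite deep into the Weiss limit", {
  p <- chung_params(E_k = 20 / 1e-6, mu = 1e-6, P_inf = -5, P_0 = 60,
                    dPdt_0 = -20 * 65)
  m <- chung_pressure(p, seq(0, 0.2, by = 1e-3))
  expect_true(all(is.finite(m$P)) && all(is.finite(m$dPdt)))
})
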