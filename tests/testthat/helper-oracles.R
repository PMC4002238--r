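# Independent oracles and fixture builders used across the suite.
# All expected values asserted in the tests are computed by these oracles
# (adaptive ODE integration, closed forms, brute-force grids), never by the
# code paths they check.

# Adaptive Runge-Kutta integration of the damped-oscillator recoil
# x'' + c x' + k x = 0, x(0) = x_o, x'(0) = 0; returns |x'| on `times`.
ode_pdf_speed <- function(k, c, x_o, times) {
  rhs <- function(t, y, p) list(c(y[2], -p$c * y[2] - p$k * y[1]))
  sol <- deSolve::ode(c(x = x_o, v = 0), times, rhs, list(k = k, c = c),
                      method = "lsoda", rtol = 1e-12, atol = 1e-12)
  abs(sol[, "v"])
}

# Adaptive integration of the pressure-decay equation
# P'' + (1/mu) P' + E_k (P - P_inf) = 0; returns both channels.
ode_chung <- function(E_k, mu, P_inf, P_0, dPdt_0, times) {
  rhs <- function(t, y, p)
    list(c(y[2], -(1 / p$mu) * y[2] - p$E_k * (y[1] - p$P_inf)))
  sol <- deSolve::ode(c(P = P_0, d = dPdt_0), times, rhs,
                      list(E_k = E_k, mu = mu, P_inf = P_inf),
                      method = "lsoda", rtol = 1e-12, atol = 1e-12)
  list(P = sol[, "P"], dPdt = sol[, "d"])
}

# Random parameter draws spanning the three damping regimes of the PDF model.
draw_pdf_params <- function(n, seed) {
  set.seed(seed)
  regime <- sample(c("under", "over", "critical"), n, replace = TRUE)
  lapply(seq_len(n), function(i) {
    k <- runif(1, 50, 400)
    c_par <- switch(regime[i],
      under = runif(1, 0, 1.8) * sqrt(k),
      over = runif(1, 2.2, 6) * sqrt(k),
      critical = 2 * sqrt(k))
    pdf_params(k = k, c = c_par, x_o = runif(1, 2, 15))
  })
}

# Random Chung parameter draws spanning overdamped through underdamped decay.
draw_chung_params <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    mu <- runif(1, 0.004, 0.04)
    ratio <- runif(1, 0.2, 4)            # 4 mu^2 E_k
    chung_params(E_k = ratio / (4 * mu^2), mu = mu,
                 P_inf = runif(1, -10, 2), P_0 = runif(1, 40, 100),
                 dPdt_0 = runif(1, -1500, 0))
  })
}

# Noiseless rendered Table-1-mean beat (pressure side), built directly from
# the closed form the way render_beat frames it: gentle shoulder, decay from
# rest at P_es down a little past LVEDP.
mean_beat_trace <- function(E_k = 1552, mu = 0.013, P_inf = -4, P_es = 90,
                            LVEDP = 16, fs = 1000, noise_sd = 0) {
  dt <- 1 / fs
  cp <- chung_params(E_k, mu, P_inf, P_0 = P_es, dPdt_0 = 0)
  t_dec <- seq(0, 1.2, by = dt)
  dec <- chung_pressure(cp, t_dec)
  keep <- seq_len(which(dec$P < LVEDP - 2)[1])
  P <- dec$P[keep]
  if (noise_sd > 0) P <- P + rnorm(length(P), 0, noise_sd)
  pressure_trace(t_dec[keep], P, LVEDP = LVEDP)
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)
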