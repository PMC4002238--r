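# Chung kinematic model of isovolumic pressure decay (IVPD):
#   P'' + (1/mu) P' + E_k (P - P_inf) = 0
# with elastic parameter E_k (1/s^2), relaxation parameter mu (s) and
# pressure asymptote P_inf (mmHg). The Weiss mono-exponential and the
# logistic models of isovolumic relaxation are its parametric limits in the
# pressure phase plane (dP/dt vs P).

#' Chung model parameter set
#'
#' Parameters and initial conditions of the kinematic model of isovolumic
#' pressure decay. `P_0` and `dPdt_0` are the pressure and its derivative at
#' the start of the fitted IVR window.
#'
#' @param E_k Elastic parameter, 1/s^2; positive.
#' @param mu Relaxation parameter, s; positive.
#' @param P_inf Pressure asymptote, mmHg; unconstrained in sign (negative
#'   asymptotes are physiologic).
#' @param P_0 Pressure at window start, mmHg.
#' @param dPdt_0 Pressure derivative at window start, mmHg/s.
#' @return An object of class `chung_params`.
#' @examples
#' chung_params(E_k = 1552, mu = 0.013, P_inf = -5, P_0 = 60, dPdt_0 = -1200)
#' @export
chung_params <- function(E_k, mu, P_inf, P_0, dPdt_0) {
  stopifnot(is.numeric(E_k), is.numeric(mu), is.numeric(P_inf),
            is.numeric(P_0), is.numeric(dPdt_0))
  if (!is.finite(E_k) || E_k <= 0) stop("chung_params: 'E_k' must be positive (1/s^2)")
  if (!is.finite(mu) || mu <= 0) stop("chung_params: 'mu' must be positive (s)")
  if (!is.finite(P_inf) || !is.finite(P_0) || !is.finite(dPdt_0))
    stop("chung_params: 'P_inf', 'P_0', 'dPdt_0' must be finite")
  structure(list(E_k = E_k, mu = mu, P_inf = P_inf, P_0 = P_0, dPdt_0 = dPdt_0),
            class = "chung_params")
}

#' @export
print.chung_params <- function(x, ...) {
  cat(sprintf(
    "Chung parameters: E_k = %.6g 1/s^2, mu = %.6g s, P_inf = %.6g mmHg\n",
    x$E_k, x$mu, x$P_inf))
  cat(sprintf("  window start: P_0 = %.6g mmHg, dP/dt_0 = %.6g mmHg/s\n",
              x$P_0, x$dPdt_0))
  invisible(x)
}

#' Chung model pressure and pressure derivative
#'
#' Exact closed-form solution of the damped second-order pressure-decay
#' equation and its derivative, evaluated at the requested times. The
#' effective damping rate is `1/mu`; the regime is overdamped when
#' `4 mu^2 E_k < 1`, underdamped when `> 1`, with a tolerance band treated
#' as critical. The overdamped branch is evaluated with expanded
#' exponentials so the inertia-negligible (Weiss) limit `mu -> 0` stays
#' finite.
#'
#' @param params A [chung_params] object.
#' @param t Times since window start, s; non-negative.
#' @return A list with numeric vectors `P` (mmHg) and `dPdt` (mmHg/s).
#' @examples
#' cp <- chung_params(1552, 0.013, -5, 60, -1200)
#' chung_pressure(cp, c(0, 0.02, 0.05))
#' @export
chung_pressure <- function(params, t) {
  stopifnot(inherits(params, "chung_params"), is.numeric(t))
  if (any(t < 0)) stop("chung_pressure: negative times are outside the model domain")
  a <- 1 / (2 * params$mu)
  Ek <- params$E_k
  y0 <- params$P_0 - params$P_inf
  v0 <- params$dPdt_0
  D <- a^2 - Ek
  B <- v0 + a * y0            # y'(0) + a y(0)
  C <- Ek * y0 + a * v0       # appears in y'(t)
  if (abs(D) <= .regime_tol * Ek) {           # critically damped band
    E <- exp(-a * t)
    y <- E * (y0 + B * t)
    dy <- E * (v0 - C * t)
  } else if (D > 0) {                          # overdamped (4 mu^2 E_k < 1)
    s <- sqrt(D)
    ep <- exp((s - a) * t); em <- exp(-(a + s) * t)
    y  <- 0.5 * ((y0 + B / s) * ep + (y0 - B / s) * em)
    dy <- 0.5 * ((v0 - C / s) * ep + (v0 + C / s) * em)
  } else {                                     # underdamped
    w <- sqrt(-D)
    E <- exp(-a * t)
    y  <- E * (y0 * cos(w * t) + (B / w) * sin(w * t))
    dy <- E * (v0 * cos(w * t) - (C / w) * sin(w * t))
  }
  list(P = params$P_inf + y, dPdt = dy)
}

#' Pressure phase-plane trajectory on a pressure grid
#'
#' Re-samples the parametric trajectory `(P(t), dP/dt(t))` of the Chung model
#' onto a monotone pressure grid, giving the pressure phase-plane (PPP) curve
#' `dP/dt` as a function of `P` over the initial monotone-decay segment
#' (from `P_0` down to the first turning point of `P`, or the asymptote).
#'
#' @param params A [chung_params] object.
#' @param P_grid Pressures (mmHg) at which to evaluate `dP/dt`; must lie
#'   within the monotone range of the trajectory.
#' @param n_dense Number of dense time samples used for the parametric sweep.
#' @return `dP/dt` in mmHg/s at each `P_grid` value.
#' @export
phase_plane <- function(params, P_grid, n_dense = 8192L) {
  stopifnot(inherits(params, "chung_params"))
  a <- 1 / (2 * params$mu)
  D <- a^2 - params$E_k
  # slowest decay rate: the slow eigenvalue (about mu*E_k when overdamped)
  rate <- if (D > 0) a - sqrt(D) else a
  t_max <- 30 / rate
  if (D < 0) t_max <- max(t_max, 2 * pi / sqrt(-D))
  tt <- seq(0, t_max, length.out = n_dense)
  tr <- chung_pressure(params, tt)
  # keep the initial strictly-decreasing segment of P
  inc <- which(diff(tr$P) >= 0)
  stop_i <- if (length(inc)) inc[1] else length(tt) - 1L
  P <- tr$P[1:(stop_i + 1L)]
  dP <- tr$dPdt[1:(stop_i + 1L)]
  lo <- min(P); hi <- max(P)
  if (any(P_grid < lo - 1e-9) || any(P_grid > hi + 1e-9))
    stop(sprintf(
      "phase_plane: requested pressures outside the monotone trajectory range [%.6g, %.6g] mmHg",
      lo, hi))
  stats::approx(x = rev(P), y = rev(dP), xout = P_grid, ties = "ordered")$y
}

#' Terminal force of isovolumic relaxation
#'
#' The model-predicted force at the end of IVR: the pressure at mitral valve
#' opening multiplied by the effective mitral valve area,
#' `F_t = P_MVO * MVA`. Left-atrial pressure is not routinely recorded at
#' catheterization, so `P_MVO` is conventionally approximated by LVEDP, and
#' the effective valve area is treated as the constant 4 cm^2.
#'
#' @param P_MVO Pressure at mitral valve opening, mmHg (typically LVEDP).
#' @param MVA Effective mitral valve area, cm^2 (default 4).
#' @param unit Reporting unit: `"mmHg_cm2"` (default) or `"dyn"`
#'   (1 mmHg = 1333.22 dyn/cm^2).
#' @return The terminal force in the requested unit.
#' @examples
#' terminal_force(16)              # 64 mmHg cm^2
#' terminal_force(16, unit = "dyn")
#' @export
terminal_force <- function(P_MVO, MVA = 4, unit = c("mmHg_cm2", "dyn")) {
  unit <- match.arg(unit)
  if (is.null(P_MVO) || length(P_MVO) == 0L || any(is.na(P_MVO)))
    stop("terminal_force: 'P_MVO' is missing (no LVEDP metadata and no explicit value)")
  stopifnot(is.numeric(P_MVO), is.numeric(MVA))
  if (any(MVA <= 0)) stop("terminal_force: 'MVA' must be positive")
  f <- P_MVO * MVA
  if (unit == "dyn") f * 1333.22 else f
}

#' Left-ventricular pressure trace for one beat
#'
#' Validates a uniformly sampled per-beat pressure recording with its LVEDP
#' metadata and identifiers.
#'
#' @param t Sample times, s, strictly increasing and uniformly spaced.
#' @param P Pressure samples, mmHg.
#' @param LVEDP End-diastolic pressure metadata, mmHg (proxy for the
#'   pressure at mitral valve opening).
#' @param subject_id,beat_id Identifiers.
#' @return An object of class `pressure_trace` with `t`, `P`, `sample_rate`,
#'   `LVEDP` and identifiers.
#' @export
pressure_trace <- function(t, P, LVEDP = NA_real_,
                           subject_id = NA_character_, beat_id = NA_character_) {
  stopifnot(is.numeric(t), is.numeric(P), length(t) == length(P))
  if (length(t) < 3L) stop("pressure_trace: need at least 3 samples")
  dt <- diff(t)
  if (any(dt <= 0)) stop("pressure_trace: times must be strictly increasing")
  if (max(dt) - min(dt) > 1e-9) stop("pressure_trace: sampling must be uniform")
  if (!is.na(LVEDP) && LVEDP >= max(P))
    stop("pressure_trace: LVEDP must lie below the trace maximum")
  structure(list(t = t, P = P, sample_rate = 1 / mean(dt), LVEDP = LVEDP,
                 subject_id = as.character(subject_id),
                 beat_id = as.character(beat_id)),
            class = "pressure_trace")
}

#' Fit the Chung model to an isovolumic pressure decay segment
#'
#' Levenberg-Marquardt estimation of `(E_k, mu, P_inf)` from the pressure and
#' pressure-derivative data of one IVR window, minimizing the joint weighted
#' residual over both channels. The default `weighting = "noise"` scales each
#' channel by the inverse of its estimated noise sd (pressure noise from
#' second differences; derivative noise from the differentiator's white-noise
#' gain, see [differentiate]), the generalized-least-squares choice; when the
#' derivative channel carries no noise-gain information the fallback
#' `"balance"` equalizes the two channels' sample variances instead. Explicit
#' numeric `weights` override either. Initial conditions `(P_0, dPdt_0)` are
#' taken from the first window sample, or freed as fit parameters with
#' `fit_ics = TRUE` (recommended for noisy data: the first-sample estimates
#' are themselves noisy and pinning them biases the fit).
#'
#' @param trace A [pressure_trace].
#' @param window An `ivr_window` from [extract_ivr_segment()], or an integer
#'   vector `c(start, end)` of 0-based half-open sample indices.
#' @param dPdt Optional measured pressure-derivative channel aligned with
#'   `trace$t`; computed by [differentiate()] when absent.
#' @param init Optional [chung_params] starting point.
#' @param weights Optional `c(P = , dPdt = )` residual weights overriding
#'   `weighting`.
#' @param weighting `"noise"` (default) or `"balance"`, see Details.
#' @param fit_ics Logical; also estimate `P_0` and `dPdt_0`.
#' @param control A [minpack.lm::nls.lm.control] list.
#' @return A list of class `chung_fit`: `params`, `rmse_P` (mmHg),
#'   `rmse_dPdt` (mmHg/s), `converged`, `niter`, plus identifiers.
#' @export
fit_chung <- function(trace, window, dPdt = NULL, init = NULL, weights = NULL,
                      weighting = c("noise", "balance"), fit_ics = FALSE,
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-15, ptol = 1e-15)) {
  stopifnot(inherits(trace, "pressure_trace"))
  idx <- .window_indices(window, length(trace$P))
  if (length(idx) < 20L)
    stop("fit_chung: window must contain at least 20 samples")
  if (is.null(dPdt)) dPdt <- differentiate(trace)
  stopifnot(length(dPdt) == length(trace$P))

  t <- trace$t[idx] - trace$t[idx[1]]
  P <- trace$P[idx]
  D <- dPdt[idx]
  if (which.min(D) == 1L)
    warning("fit_chung: window has no samples before the dP/dt minimum; ",
            "the model's distinguishing pre-minimum region is missing")

  weighting <- match.arg(weighting)
  gain <- attr(dPdt, "noise_gain")
  if (is.null(weights)) {
    if (weighting == "noise" && !is.null(gain)) {
      sigP <- .noise_sd(P)
      if (sigP < 0.02) {
        # essentially noiseless samples: a filter-derived dP/dt channel then
        # carries only stencil bias, no information beyond P itself -- fit
        # the pressure channel alone so the exact solution is recovered
        weights <- c(P = 1, dPdt = 0)
      } else {
        weights <- c(P = 1 / sigP, dPdt = 1 / (sigP * gain))
      }
    } else {
      vP <- stats::var(P); vD <- stats::var(D)
      weights <- c(P = 1, dPdt = if (vD > 0) sqrt(vP / vD) else 1)
    }
  }

  if (is.null(init)) {
    # slow-decay guess: treat the tail as exponential toward an asymptote
    tau0 <- max((max(P) - min(P)) / max(abs(D)), 0.01)
    init <- chung_params(E_k = 1500, mu = max(tau0 / 30, 2e-3),
                         P_inf = min(P) - 10, P_0 = P[1], dPdt_0 = D[1])
  } else stopifnot(inherits(init, "chung_params"))

  make_params <- function(par) {
    chung_params(E_k = par[["E_k"]], mu = par[["mu"]], P_inf = par[["P_inf"]],
                 P_0 = if (fit_ics) par[["P_0"]] else P[1],
                 dPdt_0 = if (fit_ics) par[["dPdt_0"]] else D[1])
  }
  resid_fn <- function(par) {
    m <- chung_pressure(make_params(par), t)
    c(weights[["P"]] * (m$P - P), weights[["dPdt"]] * (m$dPdt - D))
  }
  par0 <- c(E_k = init$E_k, mu = init$mu, P_inf = init$P_inf)
  lower <- c(E_k = 1e-6, mu = 1e-5, P_inf = -Inf)
  upper <- c(E_k = Inf, mu = Inf, P_inf = Inf)
  if (fit_ics) {
    par0 <- c(par0, P_0 = init$P_0, dPdt_0 = init$dPdt_0)
    lower <- c(lower, P_0 = -Inf, dPdt_0 = -Inf)
    upper <- c(upper, P_0 = Inf, dPdt_0 = Inf)
  }
  # the (E_k, mu) objective is multi-modal under noise (an undamped
  # quarter-wave can mimic a near-critical decay), so always multi-start
  # across damping regimes with a cheap exploration pass, then polish the
  # best minimizer at full precision
  explore <- minpack.lm::nls.lm.control(maxiter = 60, ftol = 1e-10,
                                        ptol = 1e-10)
  starts <- list(par0)
  for (mu0 in c(0.004, 0.013, 0.04)) {
    for (q in c(0.5, 0.95)) {        # 4 mu^2 E_k below / near critical
      p_alt <- par0
      p_alt[["mu"]] <- mu0
      p_alt[["E_k"]] <- q / (4 * mu0^2)
      starts[[length(starts) + 1L]] <- p_alt
    }
  }
  # Weiss-informed starts: the phase-plane OLS slope estimates the slow decay
  # rate mu*E_k, placing starts inside the flat hyperbolic valley that the
  # inertia-negligible (small-mu) limit lives in
  pp_slope <- tryCatch(unname(stats::coef(stats::lm(D ~ P))[2]),
                       error = function(e) NA_real_)
  if (is.finite(pp_slope) && pp_slope < 0) {
    for (mu0 in c(1e-3, 5e-3)) {
      p_alt <- par0
      p_alt[["mu"]] <- mu0
      p_alt[["E_k"]] <- -pp_slope / mu0
      starts[[length(starts) + 1L]] <- p_alt
    }
  }
  best <- NULL
  for (st in starts) {
    cand <- minpack.lm::nls.lm(par = st, lower = lower, upper = upper,
                               fn = resid_fn, control = explore)
    if (is.null(best) || cand$deviance < best$deviance) best <- cand
  }
  fit <- minpack.lm::nls.lm(par = best$par, lower = lower, upper = upper,
                            fn = resid_fn, control = control)
  if (fit$deviance > best$deviance) fit <- best
  params <- make_params(fit$par)
  m <- chung_pressure(params, t)
  structure(list(
    params = params,
    rmse_P = sqrt(mean((m$P - P)^2)),
    rmse_dPdt = sqrt(mean((m$dPdt - D)^2)),
    converged = fit$info %in% 1:3,
    niter = fit$niter,
    subject_id = trace$subject_id,
    beat_id = trace$beat_id), class = "chung_fit")
}

#' Weiss mono-exponential relaxation time-constant
#'
#' In the Weiss model the rate of pressure decline is proportional to
#' pressure itself, so the IVR segment is a straight line in the pressure
#' phase plane and `-1/tau` is the slope of the ordinary least-squares fit of
#' `dP/dt` against `P` on the window below peak `-dP/dt`, terminating just
#' above LVEDP.
#'
#' @param trace A [pressure_trace].
#' @param window Window (as in [fit_chung]) restricted to samples after the
#'   `dP/dt` minimum and above LVEDP.
#' @param dPdt Optional derivative channel; computed when absent.
#' @return A list of class `tau_estimate`: `tau` (s), `fit_window`
#'   (pressure range, mmHg), `r2`.
#' @export
weiss_tau <- function(trace, window, dPdt = NULL) {
  stopifnot(inherits(trace, "pressure_trace"))
  idx <- .window_indices(window, length(trace$P))
  if (is.null(dPdt)) dPdt <- differentiate(trace)
  P <- trace$P[idx]; D <- dPdt[idx]
  if (stats::var(P) < 1e-12)
    stop("weiss_tau: constant pressure in window, no decay to fit")
  fit <- stats::lm(D ~ P)
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0)
    stop("weiss_tau: non-negative phase-plane slope, no exponential decay")
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((D - mean(D))^2)
  structure(list(tau = -1 / slope,
                 fit_window = range(P),
                 r2 = r2), class = "tau_estimate")
}

#' Logistic relaxation time-constant
#'
#' In the logistic model the pressure decay rate is proportional to the
#' square of pressure, producing curvilinear phase-plane segments. The model
#' `P(t) = P_A / (1 + exp(t / tau_L)) + P_B` is fitted by nonlinear least
#' squares and `tau_L` returned.
#'
#' @inheritParams weiss_tau
#' @return A list of class `tau_estimate`: `tau_L` (s), `r2`, `converged`.
#' @export
logistic_tau <- function(trace, window, dPdt = NULL) {
  stopifnot(inherits(trace, "pressure_trace"))
  idx <- .window_indices(window, length(trace$P))
  t <- trace$t[idx] - trace$t[idx[1]]
  P <- trace$P[idx]
  if (stats::var(P) < 1e-12)
    stop("logistic_tau: constant pressure in window, nothing to fit")
  resid_fn <- function(par) {
    par[["P_A"]] / (1 + exp(t / par[["tau_L"]])) + par[["P_B"]] - P
  }
  span <- max(P) - min(P)
  fit <- minpack.lm::nls.lm(
    par = c(P_A = 2 * span, tau_L = max(t) / 3, P_B = min(P) - span / 2),
    lower = c(P_A = 1e-8, tau_L = 1e-5, P_B = -Inf),
    fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15, ptol = 1e-15))
  ss_res <- fit$deviance
  ss_tot <- sum((P - mean(P))^2)
  conv <- fit$info %in% 1:3
  if (!conv) warning("logistic_tau: nonlinear fit did not converge")
  structure(list(tau_L = fit$par[["tau_L"]],
                 r2 = 1 - ss_res / ss_tot,
                 converged = conv), class = "tau_estimate")
}
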