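# PDF (parametrized diastolic filling) model of the transmitral E-wave:
# recoil from rest of a unit-mass damped oscillator,
#   x'' + c x' + k x = 0,  x(0) = x_o,  x'(0) = 0,
# whose velocity magnitude |x'(t)| is fitted to the E-wave maximum-velocity
# envelope. Units: k in 1/s^2, c in 1/s, x_o in cm, velocities in cm/s.

# Relative half-discriminant tolerance below which (c, k) is treated as
# critically damped, so the closed form stays continuous across regimes.
.regime_tol <- 1e-9

#' PDF E-wave parameter set
#'
#' Constructs and validates the parameter triplet of the PDF damped-oscillator
#' model of early rapid filling: chamber stiffness `k` (1/s^2),
#' viscoelasticity/relaxation `c` (1/s) and initial load `x_o` (cm), all per
#' unit mass.
#'
#' @param k Stiffness parameter, 1/s^2; must be positive.
#' @param c Viscoelasticity/relaxation parameter, 1/s; must be non-negative.
#' @param x_o Initial load (displacement at mitral valve opening), cm;
#'   must be non-negative.
#' @return An object of class `pdf_params`.
#' @examples
#' pdf_params(k = 211, c = 16.6, x_o = 9.6)
#' @export
pdf_params <- function(k, c, x_o) {
  stopifnot(is.numeric(k), is.numeric(c), is.numeric(x_o),
            length(k) == 1L, length(c) == 1L, length(x_o) == 1L)
  if (!is.finite(k) || k <= 0)
    stop("pdf_params: 'k' must be a positive finite number (1/s^2)")
  if (!is.finite(c) || c < 0)
    stop("pdf_params: 'c' must be a non-negative finite number (1/s)")
  if (!is.finite(x_o) || x_o < 0)
    stop("pdf_params: 'x_o' must be a non-negative finite number (cm)")
  structure(list(k = k, c = c, x_o = x_o), class = "pdf_params")
}

#' @export
print.pdf_params <- function(x, ...) {
  cat(sprintf("PDF parameters: k = %.6g 1/s^2, c = %.6g 1/s, x_o = %.6g cm (%s-damped)\n",
              x$k, x$c, x$x_o, damping_regime(x$k, x$c)))
  invisible(x)
}

#' Damping regime of a damped oscillator
#'
#' Classifies `(k, c)` as underdamped (`c^2 < 4k`), overdamped (`c^2 > 4k`)
#' or critically damped, with a relative tolerance band around `c^2 = 4k`
#' inside which the motion is treated as critical so that evaluation is
#' numerically continuous across the boundary.
#'
#' @param k Stiffness, 1/s^2.
#' @param c Damping, 1/s.
#' @param tol Relative tolerance on `|c^2 - 4k|` (scaled by `k`) for the
#'   critical band.
#' @return One of `"under"`, `"over"`, `"critical"`.
#' @export
damping_regime <- function(k, c, tol = .regime_tol) {
  disc <- c^2 - 4 * k
  if (abs(disc) <= tol * k) "critical" else if (disc < 0) "under" else "over"
}

# Shared closed-form evaluation; returns list(x, v) with v = x'(t) (signed).
.pdf_state <- function(params, t) {
  k <- params$k; cc <- params$c; x_o <- params$x_o
  a <- cc / 2
  regime <- damping_regime(k, cc)
  E <- exp(-a * t)
  if (regime == "under") {
    w <- sqrt(k - a^2)
    x <- x_o * E * (cos(w * t) + (a / w) * sin(w * t))
    v <- -(k * x_o / w) * E * sin(w * t)
  } else if (regime == "over") {
    b <- sqrt(a^2 - k)
    # expanded exponentials avoid cosh/sinh overflow for strongly damped draws
    ep <- exp((b - a) * t); em <- exp(-(a + b) * t)
    x <- (x_o / 2) * ((1 + a / b) * ep + (1 - a / b) * em)
    v <- -(k * x_o / (2 * b)) * (ep - em)
  } else {
    x <- x_o * E * (1 + a * t)
    v <- -k * x_o * t * E
  }
  list(x = x, v = v)
}

#' PDF model velocity (E-wave envelope)
#'
#' Closed-form speed `|x'(t)|` of the damped oscillator released from rest at
#' displacement `x_o`, the model analogue of the E-wave maximum-velocity
#' envelope. The closed forms per damping regime (`sin/omega`, `sinh/beta`,
#' `t exp(-ct/2)`) are continuous across the regime boundary.
#'
#' @param params A [pdf_params] object.
#' @param t Times since E-wave onset, s; all must be `>= 0`.
#' @return Velocity magnitude in cm/s, same length as `t`.
#' @examples
#' p <- pdf_params(211, 16.6, 9.6)
#' pdf_velocity(p, seq(0, 0.25, by = 0.005))
#' @export
pdf_velocity <- function(params, t) {
  stopifnot(inherits(params, "pdf_params"), is.numeric(t))
  if (any(t < 0)) stop("pdf_velocity: negative times are outside the model domain")
  abs(.pdf_state(params, t)$v)
}

#' Initial force of early rapid filling
#'
#' The model-predicted force (per unit mass) driving the chamber at mitral
#' valve opening: the product of stiffness and initial displacement,
#' `F_i = k * x_o`, equal to the initial acceleration magnitude
#' `lim v(dt)/dt` of the recoiling oscillator.
#'
#' @param params A [pdf_params] object.
#' @return `F_i` in cm/s^2.
#' @examples
#' pdf_initial_force(pdf_params(211, 16.6, 9.6)) # 2025.6 cm/s^2
#' @export
pdf_initial_force <- function(params) {
  stopifnot(inherits(params, "pdf_params"))
  params$k * params$x_o
}

# Time of peak velocity, closed form per regime.
.pdf_peak_time <- function(params) {
  k <- params$k; a <- params$c / 2
  switch(damping_regime(k, params$c),
    under    = { w <- sqrt(k - a^2); atan2(w, a) / w },
    over     = { b <- sqrt(a^2 - k); atanh(b / a) / b },
    critical = 1 / a)
}

#' Derived indexes of the PDF model
#'
#' Physiologic indexes generated from the fitted parameters: the initial
#' force `F_i = k x_o` (identically the peak instantaneous A-V pressure
#' gradient analogue, per unit mass), the stored elastic (potential) energy
#' `1/2 k x_o^2` driving recoil/suction, the peak E-wave velocity and the
#' damping regime.
#'
#' @param params A [pdf_params] object.
#' @return A list with elements `F_i` (cm/s^2), `peak_gradient` (cm/s^2),
#'   `potential_energy` (cm^2/s^2), `E_peak` (cm/s), `damping_regime`.
#' @export
pdf_derived_indexes <- function(params) {
  stopifnot(inherits(params, "pdf_params"))
  F_i <- pdf_initial_force(params)
  E_peak <- if (params$x_o == 0) 0 else {
    if (params$c == 0) sqrt(params$k) * params$x_o
    else pdf_velocity(params, .pdf_peak_time(params))
  }
  list(F_i = F_i,
       peak_gradient = F_i,
       potential_energy = F_i * params$x_o / 2,
       E_peak = E_peak,
       damping_regime = damping_regime(params$k, params$c))
}

#' E-wave velocity contour
#'
#' Validates a sampled E-wave maximum-velocity envelope: times start at wave
#' onset (`t[1] = 0` up to noise), are strictly increasing and uniformly
#' spaced; velocities are envelope magnitudes (non-negative up to noise).
#'
#' @param t Sample times, s.
#' @param v Velocity magnitude samples, cm/s.
#' @param subject_id,beat_id Optional identifiers carried through fitting.
#' @return An object of class `ewave_contour` with fields `t`, `v`,
#'   `sample_rate` (Hz), and identifiers.
#' @export
ewave_contour <- function(t, v, subject_id = NA_character_, beat_id = NA_character_) {
  stopifnot(is.numeric(t), is.numeric(v), length(t) == length(v))
  if (length(t) < 3L) stop("ewave_contour: need at least 3 samples")
  dt <- diff(t)
  if (any(dt <= 0)) stop("ewave_contour: times must be strictly increasing")
  if (max(dt) - min(dt) > 1e-9) stop("ewave_contour: sampling must be uniform")
  structure(list(t = t, v = v, sample_rate = 1 / mean(dt),
                 subject_id = as.character(subject_id),
                 beat_id = as.character(beat_id)),
            class = "ewave_contour")
}

# Moment-based starting values: x_o from the velocity-time integral, k from
# the lobe duration of an undamped quarter wave, c from peak asymmetry.
.pdf_init_heuristic <- function(contour) {
  t <- contour$t - contour$t[1]
  v <- contour$v
  Tdur <- max(t)
  vti <- sum(diff(t) * (head(v, -1) + v[-1]) / 2)   # trapezoid
  k0 <- (pi / Tdur)^2
  x0 <- max(vti / 1.5, 1e-3)
  rho <- t[which.max(v)] / Tdur                     # 0.5 for undamped
  c0 <- max(0.5, 2 * sqrt(k0) * (1 - 2 * rho))
  pdf_params(k = k0, c = c0, x_o = x0)
}

#' Fit the PDF model to an E-wave contour
#'
#' Solves the inverse problem of diastole for one beat: Levenberg-Marquardt
#' least squares of the model speed `|x'(t)|` against the sampled envelope,
#' returning the unique `(k, c, x_o)` minimizing the sum of squared velocity
#' residuals.
#'
#' Starting values default to moment heuristics (`x_o` from the velocity-time
#' integral, `k` from the lobe duration, `c` from peak asymmetry); when the
#' first attempt fails to converge, a small grid of damping starts is tried
#' and the best minimizer kept.
#'
#' @param contour An [ewave_contour].
#' @param init Optional [pdf_params] starting point.
#' @param control A [minpack.lm::nls.lm.control] list.
#' @return A list of class `pdf_fit`: `params` ([pdf_params]), `rmse` (cm/s),
#'   `converged`, `niter`, `regime`, and the derived `F_i` (cm/s^2).
#' @examples
#' truth <- pdf_params(211, 16.6, 9.6)
#' tt <- seq(0, 0.25, by = 1 / 200)
#' fit <- fit_pdf(ewave_contour(tt, pdf_velocity(truth, tt)))
#' unlist(fit$params)
#' @export
fit_pdf <- function(contour, init = NULL,
                    control = minpack.lm::nls.lm.control(
                      maxiter = 500, ftol = 1e-15, ptol = 1e-15)) {
  stopifnot(inherits(contour, "ewave_contour"))
  t <- contour$t - contour$t[1]
  v <- contour$v
  if (length(t) < 10L)
    stop("fit_pdf: contour must have at least 10 samples")
  if (max(v) - min(v) < 1e-9 || max(abs(v)) < 1e-9)
    stop("fit_pdf: degenerate flat contour, cannot estimate parameters")
  if (!is.null(init)) stopifnot(inherits(init, "pdf_params"))

  resid_fn <- function(par) {
    pdf_velocity(pdf_params(par[["k"]], par[["c"]], par[["x_o"]]), t) - v
  }
  run <- function(start) {
    minpack.lm::nls.lm(
      par = c(k = start$k, c = start$c, x_o = start$x_o),
      lower = c(k = 1e-8, c = 0, x_o = 0),
      fn = resid_fn, control = control)
  }

  start <- if (is.null(init)) .pdf_init_heuristic(contour) else init
  fit <- run(start)
  # retry from a coarse damping grid if LM stalled or the fit is poor
  if (!(fit$info %in% 1:3) || sqrt(fit$deviance / length(v)) > 0.05 * max(v)) {
    k0 <- (pi / max(t))^2
    for (cf in c(0.1, 0.8, 2.2)) {
      alt <- run(pdf_params(k = k0, c = cf * sqrt(k0),
                            x_o = max(v) / sqrt(k0) * 1.5))
      if (alt$deviance < fit$deviance) fit <- alt
    }
  }

  par <- fit$par
  params <- pdf_params(par[["k"]], par[["c"]], par[["x_o"]])
  structure(list(
    params = params,
    F_i = pdf_initial_force(params),
    rmse = sqrt(fit$deviance / length(v)),
    converged = fit$info %in% 1:3,
    niter = fit$niter,
    regime = damping_regime(params$k, params$c),
    subject_id = contour$subject_id,
    beat_id = contour$beat_id), class = "pdf_fit")
}
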