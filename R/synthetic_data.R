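# Synthetic cohort generator: coupled IVR pressure segments and E-wave
# envelopes with the statistical structure of the study cohort
# (20 subjects, 15 beats/subject; truncated-normal parameter distributions),
# so that every pipeline stage can be exercised and parameter recovery
# verified without patient data.
#
# The force coupling is imposed at the force level, not on raw parameters:
# each beat's terminal force F_t = LVEDP * MVA (mmHg cm^2) is drawn first,
# and the E-wave load x_o is then adjusted so that the initial force
# F_i = k x_o (reported in m/s^2) satisfies
#   F_i = (F_t - intercept) / slope + Gaussian scatter.

# Truncated-normal draws by rejection; errors out when the truncation region
# has negligible mass (infeasible spec).
.rtrunc_norm <- function(n, mean, sd, lower = 0) {
  if (sd < 0) stop("negative SD in cohort spec")
  if (sd == 0) {
    if (mean < lower) stop("infeasible truncation: mean below lower bound with zero SD")
    return(rep(mean, n))
  }
  if (stats::pnorm(lower, mean, sd, lower.tail = FALSE) < 1e-6)
    stop(sprintf("infeasible truncation: N(%.4g, %.4g) has no mass above %.4g",
                 mean, sd, lower))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw > lower
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Specification of a synthetic diastolic cohort
#'
#' Collects every generator setting: cohort size, parameter means and SDs
#' (defaults are the study cohort's summary statistics), within-subject
#' beat-to-beat coefficient of variation, the force-coupling line and its
#' scatter, noise levels, sample rates and the seed.
#'
#' The coupling scatter defaults to the value calibrated from `target_R`:
#' with the scatter placed on `F_i` given `F_t`, the pooled Pearson
#' correlation is `R = 1 / sqrt(1 + slope^2 sigma^2 / Var(F_t))`, so
#' `sigma = sd(F_t)/slope * sqrt(1/R^2 - 1)` where `Var(F_t)` combines the
#' between-subject LVEDP variance and the within-subject beat jitter.
#'
#' @param n_subjects Number of subjects (default 20).
#' @param beats_per_subject Beats per subject (default 15).
#' @param params Named list of `c(mean, sd)` for `x_o` (cm), `k` (1/s^2),
#'   `c` (1/s), `E_k` (1/s^2), `mu` (s), `LVEDP` (mmHg), `HR` (bpm),
#'   `P_inf` (mmHg), and `P_es` (mmHg), the end-systolic pressure at
#'   aortic-valve closure from which the rendered isovolumic decay starts.
#'   Note `x_o` is reported for reference only: the realized per-beat `x_o`
#'   is set by the force coupling.
#' @param coupling List `slope`, `intercept` (force-continuity line
#'   `F_t = slope * F_i + intercept`), `target_R`, and optional `scatter_sd`
#'   (m/s^2) overriding the calibrated default.
#' @param noise List `pressure_sd` (mmHg) and `velocity_frac` (fraction of
#'   peak E-wave velocity).
#' @param rates List `pressure_hz`, `velocity_hz`.
#' @param beat_cv Within-subject beat-to-beat coefficient of variation.
#' @param mva_cm2 Effective mitral valve area, cm^2.
#' @param seed Integer seed; fixed seed implies byte-identical output.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 20L, beats_per_subject = 15L,
                        params = list(
                          x_o = c(9.6, 1.6), k = c(211, 44), c = c(16.6, 4.1),
                          E_k = c(1552, 763), mu = c(0.013, 0.009),
                          LVEDP = c(16, 4), HR = c(63, 6), P_inf = c(-4, 2),
                          P_es = c(90, 10)),
                        coupling = list(slope = 1.62, intercept = 1.32,
                                        target_R = 0.80, scatter_sd = NULL),
                        noise = list(pressure_sd = 0.5, velocity_frac = 0.05),
                        rates = list(pressure_hz = 1000, velocity_hz = 200),
                        beat_cv = 0.05, mva_cm2 = 4, seed = NULL) {
  defaults <- eval(formals(cohort_spec)$params)
  for (nm in names(defaults)) if (is.null(params[[nm]])) params[[nm]] <- defaults[[nm]]
  sds <- vapply(params, `[`, numeric(1), 2L)
  if (any(sds < 0)) stop("cohort_spec: parameter SDs must be non-negative")
  if (n_subjects < 1L || beats_per_subject < 1L)
    stop("cohort_spec: cohort dimensions must be positive")
  if (is.null(coupling$scatter_sd)) {
    var_Ft <- mva_cm2^2 *
      (params$LVEDP[2]^2 + (beat_cv * params$LVEDP[1])^2)
    coupling$scatter_sd <- sqrt(var_Ft) / coupling$slope *
      sqrt(1 / coupling$target_R^2 - 1)
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 beats_per_subject = as.integer(beats_per_subject),
                 params = params, coupling = coupling, noise = noise,
                 rates = rates, beat_cv = beat_cv, mva_cm2 = mva_cm2,
                 seed = seed), class = "cohort_spec")
}

# Physiologic feasibility of a subject's hemodynamic draw: the model decay
# started at 2*LVEDP must fall a couple of mmHg below LVEDP within about one
# cardiac cycle, else isovolumic relaxation would outlast diastole.
.decay_feasible <- function(E_k, mu, P_inf, LVEDP, P_es,
                            horizon = 1.0, margin = 2) {
  cp <- chung_params(E_k = E_k, mu = mu, P_inf = P_inf,
                     P_0 = P_es, dPdt_0 = 0)
  any(chung_pressure(cp, seq(0, horizon, by = 2e-3))$P < LVEDP - margin)
}

# Draw one beat's true parameters around given subject-level means.
.sample_beat <- function(subj, spec) {
  cv <- spec$beat_cv
  jit <- function(m, lower = 0) .rtrunc_norm(1L, m, cv * abs(m), lower)
  k     <- jit(subj$k)
  c_par <- jit(subj$c)
  E_k   <- jit(subj$E_k)
  mu    <- jit(subj$mu, lower = 1e-3)      # mu > 1 ms
  LVEDP <- jit(subj$LVEDP, lower = 1)
  P_es  <- jit(subj$P_es, lower = 2 * LVEDP + 5)
  F_t <- LVEDP * spec$mva_cm2
  F_i_ms2 <- (F_t - spec$coupling$intercept) / spec$coupling$slope +
    stats::rnorm(1L, 0, spec$coupling$scatter_sd)
  F_i_ms2 <- max(F_i_ms2, 0.5)
  x_o <- 100 * F_i_ms2 / k                 # F_i = k x_o in cm/s^2
  data.frame(k = k, c = c_par, x_o = x_o, E_k = E_k, mu = mu,
             LVEDP = LVEDP, HR = subj$HR, P_inf = subj$P_inf, P_es = P_es,
             F_t_true = F_t, F_i_true_m_s2 = F_i_ms2,
             F_i_true = k * x_o)
}

#' Draw a cohort of true beat-level parameters
#'
#' Subject-level parameter means are drawn from the cohort distributions
#' (truncated normal, positivity enforced and `mu > 1` ms); hemodynamic
#' draws whose model decay would not reach LVEDP within about one cardiac
#' cycle are rejected and re-drawn (count in attribute `subject_redraws`),
#' since such subjects could not exhibit isovolumic relaxation at all. Each
#' beat then adds within-subject jitter at coefficient of variation
#' `beat_cv`. The E-wave
#' load `x_o` of every beat is then set from the force-coupling line (see
#' [cohort_spec]), and all true values are retained for recovery testing.
#'
#' @param spec A [cohort_spec]. Its `seed`, when non-NULL, seeds the draw.
#' @return A data frame with one row per beat: identifiers, the true model
#'   parameters `k`, `c`, `x_o`, `E_k`, `mu`, `P_inf`, metadata `LVEDP`,
#'   `HR`, and the true forces `F_t_true` (mmHg cm^2), `F_i_true` (cm/s^2),
#'   `F_i_true_m_s2`.
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  p <- spec$params
  rows <- vector("list", spec$n_subjects * spec$beats_per_subject)
  irow <- 0L
  subject_redraws <- 0L
  for (s in seq_len(spec$n_subjects)) {
    repeat {
      subj <- list(
        k = .rtrunc_norm(1L, p$k[1], p$k[2]),
        c = .rtrunc_norm(1L, p$c[1], p$c[2]),
        E_k = .rtrunc_norm(1L, p$E_k[1], p$E_k[2]),
        mu = .rtrunc_norm(1L, p$mu[1], p$mu[2], lower = 1e-3),
        LVEDP = .rtrunc_norm(1L, p$LVEDP[1], p$LVEDP[2], lower = 2),
        HR = .rtrunc_norm(1L, p$HR[1], p$HR[2], lower = 30),
        P_inf = stats::rnorm(1L, p$P_inf[1], p$P_inf[2]),
        P_es = .rtrunc_norm(1L, p$P_es[1], p$P_es[2], lower = 45))
      if (.decay_feasible(subj$E_k, subj$mu, subj$P_inf, subj$LVEDP,
                          subj$P_es)) break
      subject_redraws <- subject_redraws + 1L
      if (subject_redraws > 100L * spec$n_subjects)
        stop("sample_cohort: cohort spec yields no feasible subjects")
    }
    for (b in seq_len(spec$beats_per_subject)) {
      irow <- irow + 1L
      row <- .sample_beat(subj, spec)
      row <- cbind(data.frame(subject_id = sprintf("S%02d", s),
                              beat_id = sprintf("b%02d", b),
                              stringsAsFactors = FALSE), row)
      rows[[irow]] <- row
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "subject_redraws") <- subject_redraws
  out
}

# Termination time of the rendered E-wave: end of the first velocity lobe
# (underdamped), or decay to 1% of peak velocity otherwise.
.ewave_end_time <- function(params) {
  a <- params$c / 2
  if (damping_regime(params$k, params$c) == "under") {
    w <- sqrt(params$k - a^2)
    pi / w
  } else {
    tp <- .pdf_peak_time(params)
    vp <- pdf_velocity(params, tp)
    f <- function(t) pdf_velocity(params, t) - 0.01 * vp
    stats::uniroot(f, c(tp, tp + 40 / max(a, 1e-6)))$root
  }
}

#' Render one synthetic beat
#'
#' Builds the observable signals for one beat of true parameters: an IVR
#' pressure segment from the Chung closed form, started from rest at the
#' beat's end-systolic pressure `P_es` (the aortic-valve-closure pressure)
#' and preceded by a short raised-cosine systolic shoulder (so that window
#' extraction is exercised), sampled until the pressure falls a little below
#' LVEDP; and an E-wave envelope from the PDF
#' closed form over its lobe duration. Additive Gaussian noise per the spec
#' (the envelope is clamped at zero, being a speed).
#'
#' @param beat A one-row data frame from [sample_cohort()].
#' @param spec The generating [cohort_spec].
#' @return A list: `trace` ([pressure_trace]), `contour` ([ewave_contour]),
#'   `dPdt_true` (exact model derivative over the trace, mmHg/s).
#' @export
render_beat <- function(beat, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  fs <- spec$rates$pressure_hz
  dt <- 1 / fs
  P0 <- if (!is.null(beat$P_es)) beat$P_es else 2 * beat$LVEDP
  cp <- chung_params(E_k = beat$E_k, mu = beat$mu, P_inf = beat$P_inf,
                     P_0 = P0, dPdt_0 = 0)
  t_dec <- seq(0, 1.2, by = dt)
  dec <- chung_pressure(cp, t_dec)
  # continue a few mmHg past LVEDP so the observed (noisy) trace still
  # crosses it and the IVR window can always be closed
  overshoot <- max(4 * spec$noise$pressure_sd, 2)
  cross <- which(dec$P < beat$LVEDP - overshoot)
  if (!length(cross))
    stop(structure(class = c("diastkin_render_error", "error", "condition"),
                   list(message = "render_beat: pressure decay never reaches LVEDP",
                        call = sys.call())))
  keep <- seq_len(cross[1])
  t_dec <- t_dec[keep]

  # gentle end-ejection shoulder: its peak |dP/dt| (amp*pi/(2*dur) ~ 120
  # mmHg/s) must stay well under any physiologic decay's dP/dt minimum so
  # window extraction anchors on the isovolumic fall, not the shoulder
  sh_dur <- 0.08; sh_amp <- 6
  t_sh <- seq(0, sh_dur - dt, by = dt)
  P_sh <- P0 + sh_amp * (0.5 + 0.5 * cos(pi * t_sh / sh_dur))
  d_sh <- -sh_amp * 0.5 * (pi / sh_dur) * sin(pi * t_sh / sh_dur)

  t_all <- c(t_sh, sh_dur + t_dec)
  P_true <- c(P_sh, dec$P[keep])
  d_true <- c(d_sh, dec$dPdt[keep])
  P_obs <- P_true + stats::rnorm(length(P_true), 0, spec$noise$pressure_sd)
  trace <- pressure_trace(t_all, P_obs, LVEDP = beat$LVEDP,
                          subject_id = beat$subject_id, beat_id = beat$beat_id)

  pp <- pdf_params(k = beat$k, c = beat$c, x_o = beat$x_o)
  t_e <- seq(0, .ewave_end_time(pp), by = 1 / spec$rates$velocity_hz)
  v_true <- pdf_velocity(pp, t_e)
  v_obs <- v_true + stats::rnorm(length(v_true), 0,
                                 spec$noise$velocity_frac * max(v_true))
  v_obs <- pmax(v_obs, 0)
  contour <- ewave_contour(t_e, v_obs,
                           subject_id = beat$subject_id, beat_id = beat$beat_id)
  list(trace = trace, contour = contour, dPdt_true = d_true)
}

#' Simulate a full synthetic cohort
#'
#' Draws true parameters with [sample_cohort()] and renders every beat with
#' [render_beat()]; beats whose pressure rendering is pathological (decay
#' never reaching LVEDP) are re-drawn around the same subject means, with
#' the re-draw count logged. With `dir` given, writes the long-format
#' `ewave.csv` (`subject_id,beat_id,time_s,velocity_cm_s`), `pressure.csv`
#' (`subject_id,beat_id,time_s,pressure_mmHg`), per-beat `meta.json`
#' (LVEDP, sample rates) and `truth.json` (all generating parameters).
#'
#' @param spec A [cohort_spec]; its seed drives all randomness.
#' @param dir Optional output directory (created if missing).
#' @return Invisibly, a list: `truth` (data frame), `beats` (list of
#'   rendered beats keyed `subject.beat`), `redraws` (count), `files`.
#' @export
simulate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  truth <- sample_cohort(spec)              # seeds the RNG stream
  beats <- vector("list", nrow(truth))
  redraws <- 0L
  for (i in seq_len(nrow(truth))) {
    repeat {
      rb <- tryCatch(render_beat(truth[i, ], spec),
                     diastkin_render_error = function(e) NULL)
      if (!is.null(rb)) break
      redraws <- redraws + 1L
      if (redraws > 50L) stop("simulate_cohort: too many pathological re-draws")
      subj <- as.list(truth[i, c("k", "c", "E_k", "mu", "LVEDP", "HR",
                                 "P_inf", "P_es")])
      new <- .sample_beat(subj, spec)
      truth[i, names(new)] <- new
    }
    beats[[i]] <- rb
  }
  names(beats) <- paste(truth$subject_id, truth$beat_id, sep = ".")

  files <- character()
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    ew <- do.call(rbind, lapply(beats, function(b) data.frame(
      subject_id = b$contour$subject_id, beat_id = b$contour$beat_id,
      time_s = b$contour$t, velocity_cm_s = b$contour$v,
      stringsAsFactors = FALSE)))
    pr <- do.call(rbind, lapply(beats, function(b) data.frame(
      subject_id = b$trace$subject_id, beat_id = b$trace$beat_id,
      time_s = b$trace$t, pressure_mmHg = b$trace$P,
      stringsAsFactors = FALSE)))
    meta <- lapply(seq_len(nrow(truth)), function(i) list(
      subject_id = truth$subject_id[i], beat_id = truth$beat_id[i],
      LVEDP_mmHg = truth$LVEDP[i],
      pressure_sample_rate_hz = spec$rates$pressure_hz,
      velocity_sample_rate_hz = spec$rates$velocity_hz))
    files <- file.path(dir, c("ewave.csv", "pressure.csv", "meta.json",
                              "truth.json"))
    utils::write.csv(ew, files[1], row.names = FALSE)
    utils::write.csv(pr, files[2], row.names = FALSE)
    jsonlite::write_json(meta, files[3], auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(truth, files[4], dataframe = "rows", digits = NA)
  }
  invisible(list(truth = truth, beats = beats, redraws = redraws,
                 files = files))
}
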