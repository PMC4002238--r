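# Pipeline plumbing: CSV/JSON round-tripping with named errors, per-beat fit
# drivers, and the end-to-end simulate -> fit-pdf -> fit-ivr -> analyze run
# with a provenance block. All numeric output fields carry explicit units in
# their names.

.check_columns <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("malformed CSV '%s': missing column(s) %s",
                 path, paste(sprintf("'%s'", miss), collapse = ", ")))
  df
}

#' Read a long-format E-wave CSV
#'
#' Expects columns `subject_id`, `beat_id`, `time_s`, `velocity_cm_s`
#' (header required); errors name the offending file and columns.
#'
#' @param path CSV path.
#' @return A data frame.
#' @export
read_ewave_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("input file not found: '%s'", path))
  .check_columns(utils::read.csv(path, stringsAsFactors = FALSE),
                 c("subject_id", "beat_id", "time_s", "velocity_cm_s"), path)
}

#' Read a long-format pressure CSV
#'
#' Expects columns `subject_id`, `beat_id`, `time_s`, `pressure_mmHg`.
#'
#' @param path CSV path.
#' @return A data frame.
#' @export
read_pressure_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("input file not found: '%s'", path))
  .check_columns(utils::read.csv(path, stringsAsFactors = FALSE),
                 c("subject_id", "beat_id", "time_s", "pressure_mmHg"), path)
}

#' Read per-beat metadata JSON
#'
#' @param path JSON path holding a list of records with `subject_id`,
#'   `beat_id`, `LVEDP_mmHg`.
#' @return A data frame keyed by subject and beat.
#' @export
read_beat_meta <- function(path) {
  if (!file.exists(path)) stop(sprintf("metadata file not found: '%s'", path))
  m <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  .check_columns(m, c("subject_id", "beat_id", "LVEDP_mmHg"), path)
}

#' Fit the PDF model to every beat of an E-wave table
#'
#' @param ewave Data frame from [read_ewave_csv()] (or equivalent).
#' @return Per-beat data frame: identifiers, `k_1_s2`, `c_1_s`, `x_o_cm`,
#'   `F_i` (cm/s^2), `F_i_m_s2`, `rmse_cm_s`, `converged`, `regime`. Beats
#'   whose fit errors out are dropped and logged in attribute `exclusions`.
#' @export
fit_pdf_beats <- function(ewave) {
  keys <- unique(ewave[, c("subject_id", "beat_id")])
  rows <- list(); excl <- character()
  for (i in seq_len(nrow(keys))) {
    sel <- ewave$subject_id == keys$subject_id[i] &
      ewave$beat_id == keys$beat_id[i]
    res <- tryCatch({
      ct <- ewave_contour(ewave$time_s[sel], ewave$velocity_cm_s[sel],
                          subject_id = keys$subject_id[i],
                          beat_id = keys$beat_id[i])
      f <- fit_pdf(ct)
      data.frame(subject_id = keys$subject_id[i], beat_id = keys$beat_id[i],
                 k_1_s2 = f$params$k, c_1_s = f$params$c,
                 x_o_cm = f$params$x_o,
                 F_i = f$F_i, F_i_m_s2 = f$F_i / 100,
                 rmse_cm_s = f$rmse, converged = f$converged,
                 regime = f$regime, stringsAsFactors = FALSE)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      excl <- c(excl, sprintf("excluded: subject %s beat %s (fit-pdf): %s",
                              keys$subject_id[i], keys$beat_id[i], res))
    } else rows[[length(rows) + 1L]] <- res
  }
  out <- do.call(rbind, rows)
  attr(out, "exclusions") <- excl
  out
}

#' Fit the Chung model and relaxation time-constants to every beat
#'
#' For each beat: Savitzky-Golay differentiation, Chung- and Weiss-mode IVR
#' window extraction, Levenberg-Marquardt Chung fit, Weiss and logistic
#' time-constants, and the terminal force `F_t = LVEDP * MVA`. The Chung fit
#' frees the initial conditions and fits against a lower-noise derivative
#' channel (window `fit_sg_window`) under noise-proportional weighting, while
#' window location uses the standard `sg_window` derivative; see the package
#' vignette for the rationale.
#'
#' @param pressure Data frame from [read_pressure_csv()].
#' @param meta Data frame from [read_beat_meta()] carrying per-beat LVEDP.
#' @param mva_cm2 Effective mitral valve area, cm^2.
#' @param sg_window,sg_order Differentiator settings (see [differentiate]).
#' @param fit_sg_window Filter length of the derivative channel used in the
#'   Chung fit (default 21, trading end-sample coverage for noise).
#' @param win_sg_window Filter length of the derivative used to locate the
#'   IVR window (default 31): threshold crossings on a noisy derivative are
#'   biased early by first passage, so window location benefits from heavier
#'   smoothing than the fit channel.
#' @param chung_start_fraction,weiss_margin_mmhg Window settings (see
#'   [extract_ivr_segment]).
#' @return Per-beat data frame: identifiers, `E_k_1_s2`, `mu_s`,
#'   `P_inf_mmHg`, `P_0_mmHg`, `dPdt_0_mmHg_s`, `F_t_mmHg_cm2`, `tau_s`,
#'   `tau_L_s`, `rmse_P_mmHg`, `rmse_dPdt_mmHg_s`, `converged`; exclusions
#'   in attribute `exclusions`.
#' @export
fit_ivr_beats <- function(pressure, meta, mva_cm2 = 4,
                          sg_window = 11L, sg_order = 3L,
                          fit_sg_window = 21L, win_sg_window = 31L,
                          chung_start_fraction = 0.25,
                          weiss_margin_mmhg = 1) {
  keys <- unique(pressure[, c("subject_id", "beat_id")])
  rows <- list(); excl <- character()
  for (i in seq_len(nrow(keys))) {
    sid <- keys$subject_id[i]; bid <- keys$beat_id[i]
    sel <- pressure$subject_id == sid & pressure$beat_id == bid
    res <- tryCatch({
      mrow <- meta[meta$subject_id == sid & meta$beat_id == bid, , drop = FALSE]
      if (nrow(mrow) != 1L)
        stop(sprintf("no unique metadata record for subject %s beat %s", sid, bid))
      tr <- pressure_trace(pressure$time_s[sel], pressure$pressure_mmHg[sel],
                           LVEDP = mrow$LVEDP_mmHg,
                           subject_id = sid, beat_id = bid)
      d <- differentiate(tr, sg_window = sg_window, sg_order = sg_order)
      d_win <- differentiate(tr, sg_window = win_sg_window, sg_order = sg_order)
      win_c <- extract_ivr_segment(tr, d_win, mode = "chung",
                                   chung_start_fraction = chung_start_fraction)
      win_w <- extract_ivr_segment(tr, d_win, mode = "weiss",
                                   weiss_margin_mmhg = weiss_margin_mmhg)
      d_fit <- differentiate(tr, sg_window = fit_sg_window, sg_order = sg_order)
      cf <- fit_chung(tr, win_c, dPdt = d_fit, fit_ics = TRUE)
      tw <- tryCatch(weiss_tau(tr, win_w, dPdt = d)$tau,
                     error = function(e) NA_real_)
      tl <- tryCatch(suppressWarnings(logistic_tau(tr, win_w)$tau_L),
                     error = function(e) NA_real_)
      data.frame(subject_id = sid, beat_id = bid,
                 E_k_1_s2 = cf$params$E_k, mu_s = cf$params$mu,
                 P_inf_mmHg = cf$params$P_inf, P_0_mmHg = cf$params$P_0,
                 dPdt_0_mmHg_s = cf$params$dPdt_0,
                 F_t_mmHg_cm2 = terminal_force(mrow$LVEDP_mmHg, mva_cm2),
                 tau_s = tw, tau_L_s = tl,
                 rmse_P_mmHg = cf$rmse_P, rmse_dPdt_mmHg_s = cf$rmse_dPdt,
                 converged = cf$converged, stringsAsFactors = FALSE)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      excl <- c(excl, sprintf("excluded: subject %s beat %s (fit-ivr): %s",
                              sid, bid, res))
    } else rows[[length(rows) + 1L]] <- res
  }
  out <- do.call(rbind, rows)
  attr(out, "exclusions") <- excl
  out
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full simulate / fit / analyze pipeline
#'
#' Executes the stages in order — synthetic cohort simulation, E-wave (PDF)
#' fitting, IVR (Chung) fitting, force pairing and regression — writing all
#' artifacts plus a provenance block into `config$out_dir`. Every source of
#' randomness flows from `config$seed`. Stages fail fast with stage-named
#' errors.
#'
#' @param config A list: `out_dir` (required), `seed` (default 1),
#'   `cohort` (argument list for [cohort_spec]), `orientation`
#'   (see [regress_forces]), `mva_cm2`, `sg_window`, `sg_order`,
#'   `chung_start_fraction`, `weiss_margin_mmhg`.
#' @return Invisibly, a list: `status` (0 on success), `dir`, `pairs`,
#'   `results`, `report`, `n_excluded`.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$out_dir)) stop("run_pipeline: config$out_dir is required")
  cfg <- utils::modifyList(list(
    seed = 1L, cohort = list(), orientation = "ft_on_fi", mva_cm2 = 4,
    sg_window = 11L, sg_order = 3L, chung_start_fraction = 0.25,
    weiss_margin_mmhg = 1), config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  data_dir <- file.path(cfg$out_dir, "data")

  spec <- .stage("simulate",
    do.call(cohort_spec, utils::modifyList(cfg$cohort, list(seed = cfg$seed))))
  sim <- .stage("simulate", simulate_cohort(spec, dir = data_dir))

  ewave <- .stage("fit-pdf", read_ewave_csv(file.path(data_dir, "ewave.csv")))
  pdf_fits <- .stage("fit-pdf", fit_pdf_beats(ewave))
  jsonlite::write_json(pdf_fits, file.path(cfg$out_dir, "pdf_fits.json"),
                       dataframe = "rows", digits = NA)

  pressure <- .stage("fit-ivr",
    read_pressure_csv(file.path(data_dir, "pressure.csv")))
  meta <- .stage("fit-ivr", read_beat_meta(file.path(data_dir, "meta.json")))
  ivr_fits <- .stage("fit-ivr", fit_ivr_beats(
    pressure, meta, mva_cm2 = cfg$mva_cm2, sg_window = cfg$sg_window,
    sg_order = cfg$sg_order, chung_start_fraction = cfg$chung_start_fraction,
    weiss_margin_mmhg = cfg$weiss_margin_mmhg))
  jsonlite::write_json(ivr_fits, file.path(cfg$out_dir, "ivr_fits.json"),
                       dataframe = "rows", digits = NA)

  pairs <- .stage("analyze", pair_beats(
    data.frame(subject_id = ivr_fits$subject_id, beat_id = ivr_fits$beat_id,
               F_t = ivr_fits$F_t_mmHg_cm2, stringsAsFactors = FALSE),
    data.frame(subject_id = pdf_fits$subject_id, beat_id = pdf_fits$beat_id,
               F_i = pdf_fits$F_i_m_s2, stringsAsFactors = FALSE)))
  results <- .stage("analyze",
    regress_forces(pairs, orientation = cfg$orientation, scope = "both"))
  rep <- force_report(results)

  subj <- results[results$scope == "subject", , drop = FALSE]
  utils::write.csv(subj[, c("subject_id", "slope", "intercept", "R", "n")],
                   file.path(cfg$out_dir, "per_subject.csv"), row.names = FALSE)
  pooled <- results[results$scope == "pooled", , drop = FALSE]
  jsonlite::write_json(
    list(slope = pooled$slope, intercept = pooled$intercept, R = pooled$R,
         n = pooled$n, orientation = pooled$orientation,
         unit_convention = pooled$unit_convention),
    file.path(cfg$out_dir, "pooled.json"), auto_unbox = TRUE, digits = NA)
  writeLines(rep$text, file.path(cfg$out_dir, "report.txt"))

  excl <- c(attr(pdf_fits, "exclusions"), attr(ivr_fits, "exclusions"),
            attr(pairs, "exclusions"))
  conv_lines <- c(
    sprintf("converged: %s %s pdf=%s", pdf_fits$subject_id, pdf_fits$beat_id,
            pdf_fits$converged),
    sprintf("converged: %s %s ivr=%s", ivr_fits$subject_id, ivr_fits$beat_id,
            ivr_fits$converged))
  log_lines <- c(
    sprintf("beats fitted: pdf=%d ivr=%d paired=%d",
            nrow(pdf_fits), nrow(ivr_fits), nrow(pairs)),
    sprintf("non-converged fits: pdf=%d ivr=%d",
            sum(!pdf_fits$converged), sum(!ivr_fits$converged)),
    sprintf("beats excluded: %d", length(excl)), excl,
    sprintf("pathological re-draws during simulation: %d", sim$redraws),
    conv_lines)
  writeLines(log_lines, file.path(cfg$out_dir, "run.log"))

  jsonlite::write_json(
    list(package = "diastkin",
         version = as.character(utils::packageVersion("diastkin")),
         seed = cfg$seed,
         config = cfg[setdiff(names(cfg), "out_dir")]),
    file.path(cfg$out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(status = 0L, dir = cfg$out_dir, pairs = pairs,
                 results = results, report = rep, n_excluded = length(excl)))
}
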