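# Force-continuity analysis: assemble per-beat pairs of the terminal force
# of isovolumic relaxation (F_t) and the initial force of early rapid
# filling (F_i), then run per-subject and pooled ordinary least-squares
# regressions of one force on the other. Physiologic continuity of the
# LV pressure contour across mitral valve opening predicts the two
# model-derived forces are linearly related within and across subjects.

#' Pair per-beat IVR and E-wave force estimates
#'
#' Inner join of the two per-beat fit tables on `(subject_id, beat_id)`.
#' Beats present on only one side are excluded and logged in the
#' `"exclusions"` attribute; duplicate beat keys are an error.
#'
#' @param ivr_fits Data frame with columns `subject_id`, `beat_id`, `F_t`.
#' @param pdf_fits Data frame with columns `subject_id`, `beat_id`, `F_i`.
#' @param unit_convention Tag recording the unit pair of `(F_t, F_i)`;
#'   carried into results and required to be uniform per regression.
#' @return A data frame of class `force_pairs` with columns `subject_id`,
#'   `beat_id`, `F_t`, `F_i`, `unit_convention`, and attribute `exclusions`
#'   (character vector of log lines, one per dropped beat).
#' @export
pair_beats <- function(ivr_fits, pdf_fits,
                       unit_convention = "Ft_mmHg_cm2__Fi_m_s2") {
  need <- function(df, cols, nm) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop(sprintf("pair_beats: '%s' is missing column(s): %s",
                   nm, paste(miss, collapse = ", ")))
  }
  need(ivr_fits, c("subject_id", "beat_id", "F_t"), "ivr_fits")
  need(pdf_fits, c("subject_id", "beat_id", "F_i"), "pdf_fits")
  key <- function(df) paste(df$subject_id, df$beat_id, sep = "\r")
  ki <- key(ivr_fits); kp <- key(pdf_fits)
  if (anyDuplicated(ki)) stop("pair_beats: duplicate beat keys in 'ivr_fits'")
  if (anyDuplicated(kp)) stop("pair_beats: duplicate beat keys in 'pdf_fits'")

  common <- intersect(ki, kp)
  excl <- c(
    sprintf("excluded: subject %s beat %s present only in ivr_fits",
            ivr_fits$subject_id[!(ki %in% common)],
            ivr_fits$beat_id[!(ki %in% common)]),
    sprintf("excluded: subject %s beat %s present only in pdf_fits",
            pdf_fits$subject_id[!(kp %in% common)],
            pdf_fits$beat_id[!(kp %in% common)]))
  ii <- match(common, ki); ip <- match(common, kp)
  out <- data.frame(subject_id = as.character(ivr_fits$subject_id[ii]),
                    beat_id = as.character(ivr_fits$beat_id[ii]),
                    F_t = ivr_fits$F_t[ii],
                    F_i = pdf_fits$F_i[ip],
                    unit_convention = unit_convention,
                    stringsAsFactors = FALSE)
  attr(out, "exclusions") <- excl
  class(out) <- c("force_pairs", class(out))
  out
}

# Closed-form simple linear regression of y on x with Pearson R.
.ols_line <- function(x, y, method = "ols") {
  n <- length(x)
  if (stats::var(x) <= 0)
    stop("regress_forces: zero variance in the predictor force")
  R <- stats::cor(x, y)
  if (method == "tls") {
    # total least squares: minor-axis direction of the centered cloud
    pc <- stats::prcomp(cbind(x, y), center = TRUE, scale. = FALSE)
    v <- pc$rotation[, 1]
    slope <- v[2] / v[1]
    intercept <- mean(y) - slope * mean(x)
  } else {
    fit <- stats::lm(y ~ x)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
  }
  list(slope = slope, intercept = intercept, R = R, n = n)
}

#' Regress one diastolic force on the other
#'
#' Ordinary least-squares linear regression of the per-beat force pairs, per
#' subject and/or pooled over all beats. Both orientations are supported:
#' `"ft_on_fi"` fits `F_t = slope * F_i + intercept` and `"fi_on_ft"` fits
#' `F_i = slope * F_t + intercept`; the Pearson correlation `R` is identical
#' in either orientation.
#'
#' @param pairs A `force_pairs` data frame from [pair_beats()].
#' @param orientation `"ft_on_fi"` (default) or `"fi_on_ft"`.
#' @param scope `"pooled"`, `"subject"`, or `"both"`.
#' @param method `"ols"` (default) or `"tls"` (total least squares).
#' @param min_n Minimum beats per regression unit (default 3).
#' @return A data frame of class `force_regression` with one row per
#'   regression: `scope`, `subject_id` (NA for pooled), `slope`, `intercept`,
#'   `R`, `n`, `orientation`, `method`, `unit_convention`.
#' @export
regress_forces <- function(pairs, orientation = c("ft_on_fi", "fi_on_ft"),
                           scope = c("both", "pooled", "subject"),
                           method = c("ols", "tls"), min_n = 3L) {
  orientation <- match.arg(orientation)
  scope <- match.arg(scope)
  method <- match.arg(method)
  stopifnot(inherits(pairs, "force_pairs"))
  if (length(unique(pairs$unit_convention)) != 1L)
    stop("regress_forces: mixed unit conventions in force pairs")
  uc <- pairs$unit_convention[1]

  xy <- function(df) {
    if (orientation == "ft_on_fi") list(x = df$F_i, y = df$F_t)
    else list(x = df$F_t, y = df$F_i)
  }
  row_of <- function(df, scope_lab, sid) {
    if (nrow(df) < min_n)
      stop(sprintf("regress_forces: fewer than %d beats for %s '%s'",
                   min_n, scope_lab, sid))
    d <- xy(df)
    l <- .ols_line(d$x, d$y, method)
    data.frame(scope = scope_lab, subject_id = sid, slope = l$slope,
               intercept = l$intercept, R = l$R, n = l$n,
               orientation = orientation, method = method,
               unit_convention = uc, stringsAsFactors = FALSE)
  }

  rows <- list()
  if (scope %in% c("both", "subject")) {
    for (sid in unique(pairs$subject_id))
      rows[[length(rows) + 1L]] <-
        row_of(pairs[pairs$subject_id == sid, , drop = FALSE], "subject", sid)
  }
  if (scope %in% c("both", "pooled"))
    rows[[length(rows) + 1L]] <- row_of(pairs, "pooled", NA_character_)
  out <- do.call(rbind, rows)
  class(out) <- c("force_regression", class(out))
  out
}

#' Render a force-continuity report
#'
#' Produces a per-subject table (slope, R, n) and the pooled regression line
#' in both a human-readable text rendering and a machine-readable list that
#' serializes to stable JSON.
#'
#' @param results A `force_regression` data frame from [regress_forces()].
#' @return A list of class `force_report` with elements `text` (character
#'   vector of lines) and `data` (list ready for [jsonlite::toJSON]).
#' @export
force_report <- function(results) {
  stopifnot(inherits(results, "force_regression"), nrow(results) >= 1L)
  subj <- results[results$scope == "subject", , drop = FALSE]
  pooled <- results[results$scope == "pooled", , drop = FALSE]
  fmt <- "%-10s %10.4f %12.4f %8.4f %5d"
  lines <- c(
    sprintf("Force-continuity regression (%s, %s; units: %s)",
            results$orientation[1], results$method[1],
            results$unit_convention[1]),
    sprintf("%-10s %10s %12s %8s %5s", "subject", "slope", "intercept", "R", "n"))
  if (nrow(subj))
    lines <- c(lines, sprintf(fmt, subj$subject_id, subj$slope,
                              subj$intercept, subj$R, subj$n))
  if (nrow(pooled))
    lines <- c(lines, sprintf(fmt, "pooled", pooled$slope, pooled$intercept,
                              pooled$R, pooled$n))
  data <- list(
    orientation = results$orientation[1],
    method = results$method[1],
    unit_convention = results$unit_convention[1],
    per_subject = subj[, c("subject_id", "slope", "intercept", "R", "n")],
    pooled = if (nrow(pooled))
      list(slope = pooled$slope, intercept = pooled$intercept,
           R = pooled$R, n = pooled$n) else NULL)
  structure(list(text = lines, data = data), class = "force_report")
}

#' @export
print.force_report <- function(x, ...) {
  cat(x$text, sep = "\n")
  invisible(x)
}
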