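# Signal preparation for raw per-beat pressure traces: smoothed numerical
# differentiation and extraction of the isovolumic-relaxation window in the
# two conventions used downstream (Chung-model window, Weiss-model window).
# Window indices follow a 0-based half-open [start, end) convention
# throughout, mirroring the fit-output JSON.

# Convert a window (ivr_window or c(start, end), 0-based half-open) to
# 1-based R indices, validating bounds.
.window_indices <- function(window, n) {
  if (inherits(window, "ivr_window")) {
    s <- window$start_index; e <- window$end_index
  } else if (is.numeric(window) && length(window) == 2L) {
    s <- window[1]; e <- window[2]
  } else stop("window must be an 'ivr_window' or c(start, end)")
  if (s < 0 || e > n || s >= e)
    stop(sprintf("invalid window [%d, %d) for trace of length %d", s, e, n))
  seq.int(s + 1L, e)
}

#' Smoothed derivative of a pressure trace
#'
#' Local-polynomial (Savitzky-Golay) differentiation of a uniformly sampled
#' pressure signal. Interior samples use the centered stencil; the filter's
#' end rows are one-sided stencils of the same polynomial order, and the
#' affected sample count is attached as the `"edge_samples"` attribute.
#'
#' @param trace A [pressure_trace], or a numeric pressure vector (then
#'   `dt` must be given).
#' @param sg_window Filter length in samples (odd, default 11).
#' @param sg_order Polynomial order (default 3; must be < `sg_window`).
#' @param dt Sample interval in s when `trace` is a bare vector.
#' @return `dP/dt` in mmHg/s, same length as the input, with attribute
#'   `edge_samples` giving the number of one-sided samples at each end.
#' @examples
#' tt <- seq(0, 0.5, by = 1e-3)
#' tr <- pressure_trace(tt, 60 * exp(-tt / 0.05), LVEDP = 1.5)
#' d <- differentiate(tr)
#' @export
differentiate <- function(trace, sg_window = 11L, sg_order = 3L, dt = NULL) {
  if (inherits(trace, "pressure_trace")) {
    P <- trace$P
    dts <- diff(trace$t)
    if (max(dts) - min(dts) > 1e-9)
      stop("differentiate: non-uniform sampling")
    dt <- mean(dts)
  } else {
    P <- trace
    if (is.null(dt)) stop("differentiate: 'dt' required for a bare vector")
  }
  if (length(P) < sg_window)
    stop(sprintf("differentiate: need at least %d samples", sg_window))
  if (sg_window %% 2L == 0L || sg_order >= sg_window)
    stop("differentiate: 'sg_window' must be odd and exceed 'sg_order'")
  d <- signal::sgolayfilt(P, p = sg_order, n = sg_window, m = 1L, ts = dt)
  attr(d, "edge_samples") <- (sg_window - 1L) %/% 2L
  # white-noise amplification of the interior derivative stencil: sd of the
  # derivative estimate per unit sd of sample noise
  Fm <- signal::sgolay(p = sg_order, n = sg_window, m = 1L, ts = dt)
  attr(d, "noise_gain") <- sqrt(sum(Fm[(sg_window + 1L) %/% 2L, ]^2))
  d
}

# Sample-noise sd of a uniformly sampled smooth signal, from robust fourth
# differences: the signal's own contribution is O(P'''' dt^4), negligible
# even for the fastest physiologic decays, and the median-based scale is
# insensitive to isolated junction artifacts.
.noise_sd <- function(x) stats::mad(diff(x, differences = 4)) / sqrt(70)

#' Extract the isovolumic-relaxation window from a pressure trace
#'
#' Locates the IVR fitting window for either model convention.
#'
#' * `mode = "chung"`: the window opens at the first post-peak-pressure
#'   sample where `dP/dt` has fallen below `chung_start_fraction` of the
#'   `dP/dt` minimum — i.e. at pressures greater than the pressure at which
#'   negative `dP/dt` is greatest, so the curved pre-minimum phase-plane
#'   region is included — and closes after the last sample with
#'   `P >= LVEDP` (the mitral-valve-opening proxy).
#' * `mode = "weiss"`: the window opens at the `dP/dt` minimum itself and
#'   closes after the last sample with `P >= LVEDP + weiss_margin_mmhg`
#'   ("just above LVEDP").
#'
#' For any trace the Chung-mode window contains the Weiss-mode window.
#'
#' @param trace A [pressure_trace] with LVEDP metadata.
#' @param dPdt Optional derivative channel from [differentiate()].
#' @param mode `"chung"` or `"weiss"`.
#' @param chung_start_fraction Fraction of the `dP/dt` minimum at which the
#'   Chung window opens (default 0.25).
#' @param weiss_margin_mmhg Margin above LVEDP terminating the Weiss window
#'   (default 1 mmHg).
#' @return An object of class `ivr_window`: `start_index`, `end_index`
#'   (0-based, half-open), `P_at_dPdt_min` (mmHg), `reason_codes`.
#' @export
extract_ivr_segment <- function(trace, dPdt = NULL, mode = c("chung", "weiss"),
                                chung_start_fraction = 0.25,
                                weiss_margin_mmhg = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(trace, "pressure_trace"))
  if (is.na(trace$LVEDP))
    stop("extract_ivr_segment: trace has no LVEDP metadata")
  if (is.null(dPdt)) dPdt <- differentiate(trace)
  P <- trace$P
  n <- length(P)
  reasons <- character()

  # keep clear of the one-sided differentiator stencils at the trace ends,
  # whose noise amplification can masquerade as the dP/dt minimum
  edge <- attr(dPdt, "edge_samples")
  if (is.null(edge)) edge <- 5L
  hi <- n - edge

  i_peak <- which.max(P[seq_len(hi)])
  post <- seq.int(i_peak, hi)
  i_min <- post[which.min(dPdt[post])]          # dP/dt minimum after peak P
  d_min <- dPdt[i_min]
  if (d_min >= 0)
    stop("extract_ivr_segment: no pressure decay after the peak")

  end_P <- if (mode == "weiss") trace$LVEDP + weiss_margin_mmhg else trace$LVEDP
  below <- which(P < end_P)
  below <- below[below > i_min]
  if (!length(below))
    stop(sprintf(
      "extract_ivr_segment: trace never falls below %.3g mmHg (LVEDP%s); cannot close the IVR window",
      end_P, if (mode == "weiss") " + margin" else ""))
  i_end <- below[1] - 1L                         # last sample with P >= end_P

  if (mode == "chung") {
    cand <- seq.int(i_peak, i_min)
    hit <- cand[dPdt[cand] <= chung_start_fraction * d_min]
    if (!length(hit)) {
      i_start <- i_min
      reasons <- c(reasons, "start_fraction_not_reached_before_minimum")
    } else i_start <- hit[1]
  } else {
    i_start <- i_min
  }
  if (i_start >= i_end)
    stop("extract_ivr_segment: empty IVR window (decay too short)")
  if (i_end == n) reasons <- c(reasons, "window_reaches_trace_end")

  structure(list(start_index = i_start - 1L,     # 0-based half-open
                 end_index = i_end,
                 P_at_dPdt_min = P[i_min],
                 reason_codes = reasons,
                 mode = mode), class = "ivr_window")
}

#' @export
print.ivr_window <- function(x, ...) {
  cat(sprintf("IVR window (%s mode): samples [%d, %d), P at dP/dt minimum = %.4g mmHg\n",
              x$mode, x$start_index, x$end_index, x$P_at_dPdt_min))
  if (length(x$reason_codes))
    cat("  notes:", paste(x$reason_codes, collapse = "; "), "\n")
  invisible(x)
}
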