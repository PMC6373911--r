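## Feature extraction: the performance metric (total mechanical energy)
## and the seven emulator inputs derived from a trace.

## Analysis window shared by the log-linear ventilation fit, the
## ventilatory slopes and threshold detection: the first 180 s (warm-up,
## work rate not increasing) and the final `tail_s` seconds before
## volitional exhaustion (respiratory compensation, erratic breathing)
## are excluded.
.fit_window <- function(trace, tail_s = 60) {
  mk <- trace_markers(trace)
  start <- max(mk[["warmup_start_s"]] + 180, mk[["ramp_start_s"]])
  end <- mk[["exhaustion_s"]] - tail_s
  c(start = unname(start), end = unname(end))
}

.window_idx <- function(trace, window) {
  which(trace$time >= window[1] & trace$time <= window[2])
}

#' Total energy transferred during the test
#'
#' The performance metric: the trapezoidal integral of work rate from the
#' start of the warm-up to volitional exhaustion, in kJ. Marker times that
#' fall between samples are handled by linear interpolation of the work
#' profile, so the integral is exact for piecewise-linear work profiles
#' and invariant to resampling.
#'
#' @param trace a [cpet_trace()].
#' @return Energy in kJ.
#' @export
total_energy <- function(trace) {
  mk <- trace_markers(trace)
  if (is.null(mk) || is.na(mk[["exhaustion_s"]]))
    stop_fmt("exhaustion marker missing; cannot integrate work")
  t0 <- mk[["warmup_start_s"]]; t1 <- mk[["exhaustion_s"]]
  idx <- trace$time > t0 & trace$time < t1
  tt <- c(t0, trace$time[idx], t1)
  ww <- c(stats::approx(trace$time, trace$work_rate, t0, rule = 2)$y,
          trace$work_rate[idx],
          stats::approx(trace$time, trace$work_rate, t1, rule = 2)$y)
  trapz(tt, ww) / 1000
}

#' Log-linear fit of ventilation against oxygen uptake
#'
#' Ventilation grows roughly exponentially with oxygen uptake during a
#' ramp test, so `log(VE)` is regressed on VO2 by ordinary least squares.
#' The fit ignores the first 180 s of the test (warm-up) and the final
#' 60 s before exhaustion (respiratory compensation); natural logarithms
#' are used throughout (the base only rescales intercept and slope
#' jointly).
#'
#' @param trace a [cpet_trace()].
#' @param tail_s seconds excluded before exhaustion (default 60).
#' @param min_samples minimum samples required in the window.
#' @return An object of class `ve_vo2_fit`: `alpha` (intercept), `beta`
#'   (slope per L/min of VO2), `r2`, `window` (seconds actually used) and
#'   `n`.
#' @export
fit_ve_vo2 <- function(trace, tail_s = 60, min_samples = 10) {
  win <- .fit_window(trace, tail_s)
  idx <- .window_idx(trace, win)
  if (length(idx) < min_samples)
    stop_fmt("fit window [%g, %g] s holds %d samples (< %d)",
             win[1], win[2], length(idx), min_samples)
  ve <- trace$ve[idx]
  bad <- which(ve <= 0)
  if (length(bad))
    stop_fmt("nonpositive VE at sample %d (t = %g s) inside fit window",
             idx[bad[1]], trace$time[idx[bad[1]]])
  x <- trace$vo2[idx]; y <- log(ve)
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, vo2 = x), y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else as.numeric(rss < 1e-12)
  structure(list(alpha = unname(fit$coefficients[1]),
                 beta = unname(fit$coefficients[2]),
                 r2 = min(max(r2, 0), 1), window = win, n = length(idx)),
            class = "ve_vo2_fit")
}

#' @export
print.ve_vo2_fit <- function(x, ...) {
  cat(sprintf("log(VE) = %.4f + %.4f * VO2   (R2 = %.3f, n = %d, window %g-%g s)\n",
              x$alpha, x$beta, x$r2, x$n, x$window[1], x$window[2]))
  invisible(x)
}

#' Oxygen uptake at a fixed ventilation
#'
#' Inverts the fitted exponential ventilation curve at a reference total
#' ventilation. The default reference is 0.822 L/s = 49.32 L/min, an
#' oxygen-uptake-efficiency measure: patients who reach a given
#' ventilation at higher VO2 use oxygen more efficiently.
#'
#' @param fit a [fit_ve_vo2()] result.
#' @param ve_ref reference ventilation, L/min.
#' @return VO2 (L/min) at which the fitted curve reaches `ve_ref`.
#' @export
vo2_at_ve <- function(fit, ve_ref = 49.32) {
  if (!is.finite(fit$beta) || fit$beta == 0)
    stop_fmt("degenerate fit: beta = 0, cannot invert the ventilation curve")
  (log(ve_ref) - fit$alpha) / fit$beta
}

#' Baseline breathing pattern
#'
#' Means of breathing frequency and tidal volume over the warm-up window
#' (3 min at minimal work rate), used as emulator inputs.
#'
#' @param trace a [cpet_trace()].
#' @return Named numeric vector `baseline_bf` (1/min), `baseline_vt` (L).
#' @export
baseline_ventilation <- function(trace) {
  mk <- trace_markers(trace)
  idx <- which(trace$time >= mk[["warmup_start_s"]] &
               trace$time <= mk[["ramp_start_s"]])
  if (!length(idx)) stop_fmt("warm-up window is empty")
  c(baseline_bf = mean(trace$bf[idx]), baseline_vt = mean(trace$vt[idx]))
}

#' Rates of change of breathing frequency and tidal volume
#'
#' OLS slopes of `bf` and `vt` regressed on VO2 (default) or on time over
#' the same exclusion window as [fit_ve_vo2()], quantifying how the
#' breathing pattern responds as metabolic demand rises.
#'
#' @param trace a [cpet_trace()].
#' @param against regress against `"vo2"` (per L/min of VO2; default,
#'   mirroring the ventilation-fit convention) or `"time"` (per second).
#' @param tail_s,min_samples window controls as in [fit_ve_vo2()].
#' @return Named numeric vector `bf_slope`, `vt_slope`.
#' @export
ventilatory_slopes <- function(trace, against = c("vo2", "time"),
                               tail_s = 60, min_samples = 10) {
  against <- match.arg(against)
  win <- .fit_window(trace, tail_s)
  idx <- .window_idx(trace, win)
  if (length(idx) < min_samples)
    stop_fmt("fit window [%g, %g] s holds %d samples (< %d)",
             win[1], win[2], length(idx), min_samples)
  x <- if (against == "vo2") trace$vo2[idx] else trace$time[idx]
  slope <- function(y) unname(stats::lm.fit(cbind(1, x), y)$coefficients[2])
  c(bf_slope = slope(trace$bf[idx]), vt_slope = slope(trace$vt[idx]))
}

#' Ratio of oxygen uptake to total ventilation over time
#'
#' @param trace a [cpet_trace()].
#' @return Data frame `time`, `ratio` (dimensionless) with the exhaustion
#'   time attached as attribute `exhaustion_s`.
#' @export
vo2_ve_ratio <- function(trace) {
  bad <- which(trace$ve <= 0)
  if (length(bad))
    stop_fmt("VE is zero/negative at sample %d; ratio undefined", bad[1])
  out <- data.frame(time = trace$time, ratio = trace$vo2 / trace$ve)
  attr(out, "exhaustion_s") <- trace_markers(trace)[["exhaustion_s"]]
  out
}

## The seven emulator inputs, in canonical order.
.predictor_names <- c("baseline_bf", "baseline_vt", "vo2_at_fixed_ve",
                      "fvc", "fev1", "bf_slope", "vt_slope")

#' Assemble the emulator feature vector for one patient
#'
#' Collects the seven predictors (baseline breathing frequency and tidal
#' volume, VO2 at a fixed ventilation, FVC, FEV1, and the rates of change
#' of breathing frequency and tidal volume), the detected gas-exchange
#' threshold as output variable, and auxiliary performance metrics.
#'
#' @param record a [cpet_patient()].
#' @param get a [detect_get()] result; computed from the trace if `NULL`.
#' @param ve_ref reference ventilation for [vo2_at_ve()], L/min.
#' @param slopes_against passed to [ventilatory_slopes()].
#' @return A one-row data frame of class `cpet_features` with attributes
#'   `predictors` (the seven input names) and `window` (fit window used).
#' @export
extract_features <- function(record, get = NULL, ve_ref = 49.32,
                             slopes_against = "vo2") {
  tr <- record$trace
  if (is.null(get)) get <- detect_get(tr)
  fit <- fit_ve_vo2(tr)
  base <- baseline_ventilation(tr)
  sl <- ventilatory_slopes(tr, against = slopes_against)
  mk <- trace_markers(tr)
  out <- data.frame(
    patient_id = record$patient_id,
    baseline_bf = unname(base["baseline_bf"]),
    baseline_vt = unname(base["baseline_vt"]),
    vo2_at_fixed_ve = vo2_at_ve(fit, ve_ref),
    fvc = record$fvc, fev1 = record$fev1,
    bf_slope = unname(sl["bf_slope"]),
    vt_slope = unname(sl["vt_slope"]),
    get_vo2 = get$get_vo2, get_time_s = get$get_time_s,
    total_energy_kJ = total_energy(tr),
    exhaustion_time_s = unname(mk[["exhaustion_s"]]),
    ve_fit_alpha = fit$alpha, ve_fit_beta = fit$beta, ve_fit_r2 = fit$r2)
  if (!all(is.finite(unlist(out[.predictor_names]))))
    stop_fmt("non-finite predictor for patient %s", record$patient_id)
  attr(out, "predictors") <- .predictor_names
  attr(out, "window") <- fit$window
  class(out) <- c("cpet_features", "data.frame")
  out
}

#' Feature table for a whole cohort
#'
#' @param cohort a [generate_cohort()] result, or a list of
#'   [cpet_patient()] records.
#' @param ... passed to [extract_features()].
#' @return A data frame with one row per patient, attribute `predictors`
#'   naming the seven emulator inputs.
#' @export
cohort_features <- function(cohort, ...) {
  patients <- if (inherits(cohort, "cpet_cohort")) cohort$patients else cohort
  rows <- lapply(patients, extract_features, ...)
  out <- do.call(rbind, lapply(rows, as.data.frame))
  attr(out, "predictors") <- .predictor_names
  class(out) <- c("cpet_features", "data.frame")
  out
}
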