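#' Automated gas-exchange threshold detection (V-slope)
#'
#' Locates the gas-exchange threshold (GET) as the breakpoint of a
#' continuous two-segment piecewise-linear least-squares fit of VCO2 on
#' VO2 over the ramp analysis window (first 180 s and final 60 s before
#' exhaustion excluded, as in the ventilation fits). Below the threshold,
#' CO2 output tracks O2 uptake through the respiratory quotient; above it,
#' bicarbonate buffering of lactate adds excess CO2, steepening the slope.
#'
#' Candidate knots lie on a grid over the central 10--90% of the windowed
#' VO2 range with step `knot_step` times the range; the knot minimising
#' the total residual sum of squares is selected. The two-segment model is
#' accepted over a single line by an F-test at level `alpha`
#' (2 extra parameters); on acceptance the threshold must also show a
#' steeper slope above than below, otherwise the result is flagged
#' invalid with a reason.
#'
#' The crossing time `get_time_s` is the first ramp-phase time at which a
#' lightly smoothed VO2 series (moving average of `smooth_s` seconds)
#' reaches the threshold, guarding against noise-triggered early
#' crossings.
#'
#' @param trace a [cpet_trace()].
#' @param knot_step knot grid step as a fraction of the VO2 range
#'   (default 0.01).
#' @param alpha F-test level for accepting the two-segment model.
#' @param smooth_s moving-average width (seconds) for the crossing-time
#'   series.
#' @param tail_s seconds excluded before exhaustion.
#' @param min_samples minimum samples required in the window (default 20).
#' @return An object of class `get_result`: `get_vo2` (L/min),
#'   `get_time_s`, `slope_below`, `slope_above`, `rss`, `rss_line`,
#'   `f_pvalue`, `valid`, `reason`, `window`, `n`.
#' @export
detect_get <- function(trace, knot_step = 0.01, alpha = 0.05,
                       smooth_s = 15, tail_s = 60, min_samples = 20) {
  win <- .fit_window(trace, tail_s)
  idx <- .window_idx(trace, win)
  n <- length(idx)
  if (n < min_samples)
    stop_fmt("analysis window [%g, %g] s holds %d samples (< %d)",
             win[1], win[2], n, min_samples)
  v <- trace$vo2[idx]; cc <- trace$vco2[idx]
  rng <- range(v)
  if (diff(rng) < 1e-12) stop_fmt("VO2 is constant over the window")

  knots <- seq(rng[1] + 0.1 * diff(rng), rng[1] + 0.9 * diff(rng),
               by = knot_step * diff(rng))
  rss_at <- function(k) {
    fit <- stats::lm.fit(cbind(1, v, pmax(v - k, 0)), cc)
    sum(fit$residuals^2)
  }
  rss_all <- vapply(knots, rss_at, 0)
  best <- which.min(rss_all)
  k <- knots[best]
  fit2 <- stats::lm.fit(cbind(1, v, pmax(v - k, 0)), cc)
  rss2 <- sum(fit2$residuals^2)
  b <- fit2$coefficients
  slope_below <- unname(b[2]); slope_above <- unname(b[2] + b[3])

  fit1 <- stats::lm.fit(cbind(1, v), cc)
  rss1 <- sum(fit1$residuals^2)
  ## two-segment model spends 2 extra df (excess slope + knot position);
  ## an RSS improvement at rounding-noise level is no breakpoint evidence
  if (rss1 - rss2 <= 1e-10 * max(rss1, .Machine$double.eps)) {
    fstat <- 0
  } else {
    fstat <- if (rss2 > 0) ((rss1 - rss2) / 2) / (rss2 / (n - 4)) else Inf
  }
  pval <- stats::pf(fstat, 2, n - 4, lower.tail = FALSE)

  valid <- TRUE; reason <- ""
  if (!(pval < alpha)) {
    valid <- FALSE
    reason <- sprintf("two-segment fit not better than a single line (F p = %.3g)",
                      pval)
  } else if (slope_above < slope_below) {
    valid <- FALSE
    reason <- "slope above candidate threshold not steeper than below"
  }

  ## first ramp-phase crossing of the smoothed VO2 series
  mk <- trace_markers(trace)
  ramp_idx <- which(trace$time >= mk[["ramp_start_s"]] &
                    trace$time <= mk[["exhaustion_s"]])
  dt <- stats::median(diff(trace$time[ramp_idx]))
  sm <- moving_average(trace$vo2[ramp_idx], round(smooth_s / dt))
  cross <- which(sm >= k)
  get_time <- if (length(cross)) trace$time[ramp_idx[cross[1]]] else NA_real_

  structure(list(get_vo2 = k, get_time_s = get_time,
                 slope_below = slope_below, slope_above = slope_above,
                 rss = rss2, rss_line = rss1, f_pvalue = pval,
                 valid = valid, reason = reason, window = win, n = n,
                 knots = knots, rss_profile = rss_all),
            class = "get_result")
}

#' @export
print.get_result <- function(x, ...) {
  cat(sprintf("Gas-exchange threshold (V-slope, two-segment fit, n = %d)\n",
              x$n))
  cat(sprintf("  GET = %.3f L/min at t = %s s; slopes %.3f below / %.3f above\n",
              x$get_vo2,
              if (is.na(x$get_time_s)) "NA" else sprintf("%g", x$get_time_s),
              x$slope_below, x$slope_above))
  cat(sprintf("  RSS %.4g (single line %.4g), F-test p = %.3g -> %s\n",
              x$rss, x$rss_line, x$f_pvalue,
              if (x$valid) "valid" else paste("INVALID:", x$reason)))
  invisible(x)
}

#' @export
plot.get_result <- function(x, trace, ...) {
  idx <- .window_idx(trace, x$window)
  v <- trace$vo2[idx]; cc <- trace$vco2[idx]
  graphics::plot(v, cc, pch = 16, cex = 0.4, col = "grey50",
                 xlab = expression(dot(V) * O[2] ~ "(L/min)"),
                 ylab = expression(dot(V) * CO[2] ~ "(L/min)"), ...)
  fit <- stats::lm.fit(cbind(1, v, pmax(v - x$get_vo2, 0)), cc)
  o <- order(v)
  graphics::lines(v[o], fit$fitted.values[o], col = "red3", lwd = 2)
  graphics::abline(v = x$get_vo2, lty = 2, col = "blue3")
  invisible(x)
}
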