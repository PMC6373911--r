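#' Construct a breath-by-breath CPET trace
#'
#' A `cpet_trace` is a data frame with one row per sample and the canonical
#' channels of a ramp-incremental cardiopulmonary exercise test, plus the
#' protocol phase markers stored as attributes. Canonical units are
#' litres per minute for the gas/ventilation flows (`vo2`, `vco2`, `ve`),
#' breaths per minute for `bf`, litres for tidal volume `vt`, watts for
#' `work_rate` and seconds for `time`.
#'
#' @param time sample times in seconds from test start, strictly increasing.
#' @param work_rate ergometer work rate, W.
#' @param vo2,vco2 oxygen uptake and carbon-dioxide output, L/min.
#' @param ve total (minute) ventilation, L/min.
#' @param bf breathing frequency, breaths/min.
#' @param vt tidal volume, L.
#' @param markers named numeric vector with elements `warmup_start_s`,
#'   `ramp_start_s`, `exhaustion_s`, `recovery_end_s` (seconds).
#' @param validate run [validate_cpet_trace()] on the result (default `TRUE`).
#' @param tol relative tolerance for the ventilation identity
#'   `ve == bf * vt` (passed to the validator).
#'
#' @return An object of class `cpet_trace` (a data frame).
#' @seealso [read_cpet_trace()], [resample_uniform()], [generate_patient()]
#' @export
cpet_trace <- function(time, work_rate, vo2, vco2, ve, bf, vt, markers,
                       validate = TRUE, tol = 0.1) {
  tr <- data.frame(time = as.numeric(time), work_rate = as.numeric(work_rate),
                   vo2 = as.numeric(vo2), vco2 = as.numeric(vco2),
                   ve = as.numeric(ve), bf = as.numeric(bf),
                   vt = as.numeric(vt))
  attr(tr, "markers") <- unlist(markers)[c("warmup_start_s", "ramp_start_s",
                                           "exhaustion_s", "recovery_end_s")]
  class(tr) <- c("cpet_trace", "data.frame")
  if (validate) validate_cpet_trace(tr, tol = tol)
  tr
}

#' Phase markers of a trace
#'
#' @param trace a [cpet_trace()].
#' @return Named numeric vector `warmup_start_s`, `ramp_start_s`,
#'   `exhaustion_s`, `recovery_end_s`.
#' @export
trace_markers <- function(trace) attr(trace, "markers")

#' Validate a CPET trace
#'
#' Checks the structural invariants every downstream stage assumes:
#' strictly increasing time, equal channel lengths, non-negative channels,
#' ordered phase markers, and the ventilation identity `ve = bf * vt`
#' within a relative tolerance (the identity holds exactly in theory and up
#' to measurement noise in metabolic-cart data).
#'
#' @param trace a [cpet_trace()].
#' @param tol maximum allowed value of `|ve - bf*vt| / max(ve, eps)`.
#' @return `trace`, invisibly; errors describe the first violation found.
#' @export
validate_cpet_trace <- function(trace, tol = 0.1) {
  required <- c("time", "work_rate", "vo2", "vco2", "ve", "bf", "vt")
  missing_ch <- setdiff(required, names(trace))
  if (length(missing_ch))
    stop_fmt("trace is missing required channel(s): %s",
             paste(missing_ch, collapse = ", "))
  if (anyNA(trace[required]))
    stop_fmt("trace contains missing values")
  if (any(diff(trace$time) <= 0))
    stop_fmt("time must be strictly increasing (first violation at row %d)",
             which(diff(trace$time) <= 0)[1] + 1L)
  for (ch in c("vo2", "vco2", "ve", "bf", "vt")) {
    neg <- which(trace[[ch]] < 0)
    if (length(neg))
      stop_fmt("channel '%s' negative at row %d", ch, neg[1])
  }
  mk <- trace_markers(trace)
  if (is.null(mk) || anyNA(mk))
    stop_fmt("trace markers warmup_start_s/ramp_start_s/exhaustion_s/recovery_end_s must all be set")
  if (!(mk["warmup_start_s"] <= mk["ramp_start_s"] &&
        mk["ramp_start_s"] < mk["exhaustion_s"] &&
        mk["exhaustion_s"] <= mk["recovery_end_s"]))
    stop_fmt("phase markers must satisfy warmup_start <= ramp_start < exhaustion <= recovery_end")
  resid <- abs(trace$ve - trace$bf * trace$vt) / pmax(trace$ve, 1e-12)
  if (any(resid > tol))
    stop_fmt("ventilation identity ve = bf*vt violated at row %d (relative residual %.3g > tol %.3g)",
             which.max(resid), max(resid), tol)
  invisible(trace)
}

#' Construct a patient record
#'
#' Bundles a CPET trace with the spirometry and protocol metadata the
#' analysis uses, and (for synthetic patients) the generator ground truth.
#'
#' @param patient_id character identifier.
#' @param age years.
#' @param fvc forced vital capacity, L.
#' @param fev1 forced expiratory volume in 1 s, L; must not exceed `fvc`.
#' @param ramp_rate ramp increment, W/min. The protocol prescribes
#'   10--25 W/min; values outside that range are allowed only with
#'   `allow_nonprotocol_ramp = TRUE`.
#' @param trace a [cpet_trace()].
#' @param truth optional named list of ground-truth values (synthetic
#'   cohorts only), e.g. `true_get_vo2`, `true_get_time_s`, `true_vo2max`
#'   and the generator parameters.
#' @param allow_nonprotocol_ramp permit ramp rates outside 10--25 W/min.
#' @return An object of class `cpet_patient`.
#' @export
cpet_patient <- function(patient_id, age, fvc, fev1, ramp_rate, trace,
                         truth = NULL, allow_nonprotocol_ramp = FALSE) {
  if (fev1 > fvc + 1e-9)
    stop_fmt("fev1 (%.3g L) must not exceed fvc (%.3g L)", fev1, fvc)
  if (!allow_nonprotocol_ramp && (ramp_rate < 10 || ramp_rate > 25))
    stop_fmt("ramp_rate %.3g W/min outside protocol range [10, 25]; set allow_nonprotocol_ramp = TRUE to override",
             ramp_rate)
  if (!is.null(truth)) {
    if (!is.null(truth$true_get_vo2) && !is.null(truth$true_vo2max) &&
        !(truth$true_get_vo2 > 0 && truth$true_get_vo2 < truth$true_vo2max))
      stop_fmt("ground truth must satisfy 0 < true_get_vo2 < true_vo2max")
  }
  structure(list(patient_id = as.character(patient_id), age = age,
                 fvc = fvc, fev1 = fev1, ramp_rate = ramp_rate,
                 trace = trace, truth = truth),
            class = "cpet_patient")
}

#' @export
print.cpet_patient <- function(x, ...) {
  mk <- trace_markers(x$trace)
  cat(sprintf("CPET patient record '%s'\n", x$patient_id))
  cat(sprintf("  age %.1f y, FVC %.2f L, FEV1 %.2f L, ramp %.3g W/min\n",
              x$age, x$fvc, x$fev1, x$ramp_rate))
  cat(sprintf("  trace: %d samples, warm-up %gs, ramp %gs, exhaustion %gs, recovery end %gs\n",
              nrow(x$trace), mk[1], mk[2], mk[3], mk[4]))
  if (!is.null(x$truth))
    cat(sprintf("  ground truth: GET %.3f L/min at %gs, VO2max %.3f L/min\n",
                x$truth$true_get_vo2, x$truth$true_get_time_s,
                x$truth$true_vo2max))
  invisible(x)
}

## column names of the on-disk CSV dialect
.trace_cols <- c(time = "t_s", work_rate = "work_W", vo2 = "vo2_Lmin",
                 vco2 = "vco2_Lmin", ve = "ve_Lmin", bf = "bf_permin",
                 vt = "vt_L")
.meta_keys <- c("patient_id", "age_y", "fvc_L", "fev1_L", "ramp_W_per_min",
                "warmup_start_s", "ramp_start_s", "exhaustion_s",
                "recovery_end_s")

## unit conversion factors into the canonical units
.unit_factor <- function(unit, channel) {
  u <- tolower(gsub("[. ]", "", unit))
  flow <- c("l/min" = 1, "lmin" = 1, "ml/min" = 1e-3, "mlmin" = 1e-3,
            "l/s" = 60, "ls" = 60)
  vol <- c("l" = 1, "ml" = 1e-3)
  tab <- if (channel == "vt") vol else flow
  if (!u %in% names(tab))
    stop_fmt("unsupported unit '%s' for channel '%s'", unit, channel)
  unname(tab[u])
}

#' Read a CPET trace file
#'
#' The on-disk format is a plain CSV with a `#`-prefixed metadata header of
#' `key: value` lines followed by a header row naming the channels
#' (`t_s, work_W, vo2_Lmin, vco2_Lmin, ve_Lmin, bf_permin, vt_L`).
#' Metadata keys: `patient_id, age_y, fvc_L, fev1_L, ramp_W_per_min,
#' warmup_start_s, ramp_start_s, exhaustion_s, recovery_end_s`; optional
#' `truth_*` keys carry synthetic ground truth through a round trip.
#'
#' @param path file to read.
#' @param dialect optional list: `delim` (default `","`) and `units`, a
#'   named character vector giving the units used in the file for any of
#'   `vo2`, `vco2`, `ve` (one of `"L/min"`, `"mL/min"`, `"L/s"`) and `vt`
#'   (`"L"` or `"mL"`); values are converted to the canonical units.
#' @param tol ventilation-identity tolerance passed to the validator.
#' @return A validated [cpet_patient()].
#' @export
read_cpet_trace <- function(path, dialect = list(), tol = 0.1) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  delim <- dialect$delim %||% ","
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  meta_lines <- sub("^#\\s*", "", lines[is_meta])
  kv <- regmatches(meta_lines, regexpr(":", meta_lines), invert = TRUE)
  meta <- stats::setNames(trimws(vapply(kv, `[`, "", 2L)),
                          trimws(vapply(kv, `[`, "", 1L)))
  missing_meta <- setdiff(.meta_keys, names(meta))
  if (length(missing_meta))
    stop_fmt("metadata header missing key(s): %s",
             paste(missing_meta, collapse = ", "))
  body <- lines[!is_meta]
  tab <- utils::read.csv(text = paste(body, collapse = "\n"), sep = delim,
                         check.names = FALSE)
  missing_ch <- setdiff(unname(.trace_cols), names(tab))
  if (length(missing_ch))
    stop_fmt("trace file missing required channel column(s): %s",
             paste(names(.trace_cols)[match(missing_ch, .trace_cols)],
                   collapse = ", "))
  chans <- lapply(names(.trace_cols), function(k) {
    v <- as.numeric(tab[[.trace_cols[[k]]]])
    u <- (dialect$units %||% character())[k]
    if (!is.na(u) && length(u)) v <- v * .unit_factor(u, k)
    v
  })
  names(chans) <- names(.trace_cols)
  markers <- as.numeric(meta[c("warmup_start_s", "ramp_start_s",
                               "exhaustion_s", "recovery_end_s")])
  names(markers) <- c("warmup_start_s", "ramp_start_s", "exhaustion_s",
                      "recovery_end_s")
  tr <- cpet_trace(chans$time, chans$work_rate, chans$vo2, chans$vco2,
                   chans$ve, chans$bf, chans$vt, markers, tol = tol)
  truth_keys <- grep("^truth_", names(meta), value = TRUE)
  truth <- NULL
  if (length(truth_keys)) {
    truth <- as.list(as.numeric(meta[truth_keys]))
    names(truth) <- sub("^truth_", "", truth_keys)
  }
  cpet_patient(meta[["patient_id"]], as.numeric(meta[["age_y"]]),
               as.numeric(meta[["fvc_L"]]), as.numeric(meta[["fev1_L"]]),
               as.numeric(meta[["ramp_W_per_min"]]), tr, truth = truth,
               allow_nonprotocol_ramp = TRUE)
}

#' Write a patient record to the CSV trace format
#'
#' Inverse of [read_cpet_trace()]; numeric fields are written at full
#' precision (15 significant digits) so a round trip is lossless to within
#' 1e-9 relative tolerance. Scalar numeric ground-truth fields are stored
#' as `truth_*` metadata keys.
#'
#' @param record a [cpet_patient()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cpet_trace <- function(record, path) {
  tr <- record$trace
  mk <- trace_markers(tr)
  num <- function(x) formatC(x, digits = 15, format = "g")
  meta <- c(patient_id = record$patient_id, age_y = num(record$age),
            fvc_L = num(record$fvc), fev1_L = num(record$fev1),
            ramp_W_per_min = num(record$ramp_rate),
            warmup_start_s = num(mk[["warmup_start_s"]]),
            ramp_start_s = num(mk[["ramp_start_s"]]),
            exhaustion_s = num(mk[["exhaustion_s"]]),
            recovery_end_s = num(mk[["recovery_end_s"]]))
  if (!is.null(record$truth)) {
    sc <- record$truth[vapply(record$truth, function(v)
      is.numeric(v) && length(v) == 1L, TRUE)]
    if (length(sc))
      meta <- c(meta, stats::setNames(vapply(sc, num, ""),
                                      paste0("truth_", names(sc))))
  }
  hdr <- sprintf("# %s: %s", names(meta), meta)
  body <- vapply(seq_len(nrow(tr)), function(i)
    paste(num(c(tr$time[i], tr$work_rate[i], tr$vo2[i], tr$vco2[i],
                tr$ve[i], tr$bf[i], tr$vt[i])), collapse = ","), "")
  writeLines(c(hdr, paste(unname(.trace_cols), collapse = ","), body), path)
  invisible(path)
}

#' Resample a trace onto a uniform grid
#'
#' Breath-by-breath data are irregular in time; fits and integrals need a
#' defined grid. All channels are linearly interpolated onto a uniform grid
#' from `warmup_start_s` to `recovery_end_s`; phase markers are preserved.
#' No smoothing is applied at this layer.
#'
#' @param trace a [cpet_trace()].
#' @param dt grid spacing in seconds (> 0 and smaller than the trace span).
#' @return A [cpet_trace()] on the uniform grid.
#' @export
resample_uniform <- function(trace, dt) {
  if (dt <= 0) stop_fmt("dt must be > 0")
  mk <- trace_markers(trace)
  span <- mk[["recovery_end_s"]] - mk[["warmup_start_s"]]
  if (dt > span)
    stop_fmt("dt (%g s) exceeds trace duration (%g s)", dt, span)
  grid <- seq(mk[["warmup_start_s"]], mk[["recovery_end_s"]], by = dt)
  interp <- function(y) stats::approx(trace$time, y, xout = grid,
                                      rule = 2)$y
  cpet_trace(grid, interp(trace$work_rate), interp(trace$vo2),
             interp(trace$vco2), interp(trace$ve), interp(trace$bf),
             interp(trace$vt), mk, validate = FALSE)
}

#' @export
print.cpet_trace <- function(x, ...) {
  mk <- trace_markers(x)
  cat(sprintf("CPET trace: %d samples over %g-%g s (ramp %g s, exhaustion %g s)\n",
              nrow(x), min(x$time), max(x$time), mk[["ramp_start_s"]],
              mk[["exhaustion_s"]]))
  print(utils::head(as.data.frame(x), 4L))
  if (nrow(x) > 4L) cat(sprintf("  ... %d more rows\n", nrow(x) - 4L))
  invisible(x)
}

#' @export
plot.cpet_trace <- function(x, ...) {
  mk <- trace_markers(x)
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  panel <- function(y, lab) {
    graphics::plot(x$time, y, type = "l", xlab = "time (s)", ylab = lab, ...)
    graphics::abline(v = mk[c("ramp_start_s", "exhaustion_s")],
                     lty = 3, col = "grey40")
  }
  panel(x$work_rate, "work rate (W)")
  panel(x$vo2, expression(dot(V) * O[2] ~ "(L/min)"))
  panel(x$ve, expression(dot(V)[E] ~ "(L/min)"))
  panel(x$vt, expression(V[T] ~ "(L)"))
  invisible(x)
}
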