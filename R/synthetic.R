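#' Configuration for the synthetic CF cohort generator
#'
#' Defines the virtual patient population and protocol used to stand in for
#' a real cohort of children and adolescents with cystic fibrosis
#' performing a ramp-incremental CPET: a 3-min warm-up at a low fixed work
#' rate, a ramp at 10--25 W/min chosen to elicit exhaustion in roughly ten
#' minutes, and a 5-min active recovery at 20 W. Each distributional
#' parameter is a `c(mean, sd, lower, upper)` truncated normal unless noted.
#'
#' @param n_patients cohort size (the motivating study used 15).
#' @param seed integer master seed; each patient derives a deterministic
#'   sub-seed from `(seed, index)`.
#' @param age years.
#' @param fvc forced vital capacity, L.
#' @param fev1_ratio FEV1/FVC ratio (dimensionless).
#' @param vo2_rest resting oxygen uptake, L/min.
#' @param efficiency aerobic efficiency dVO2/dW, L/min/W (about
#'   10 mL/min/W in cycling).
#' @param vo2max maximal oxygen uptake, L/min.
#' @param get_frac gas-exchange threshold as a fraction of VO2max.
#' @param rq respiratory quotient below the threshold (slope of VCO2 vs
#'   VO2).
#' @param excess_slope additional VCO2 slope above the threshold
#'   (excess CO2 from bicarbonate buffering), dimensionless.
#' @param ve_rest warm-up ventilation, L/min.
#' @param peak_ve_per_vo2 ventilatory equivalent for O2 at peak exercise
#'   (sets the exponential VE--VO2 relation jointly with `ve_rest`).
#' @param maxvt_frac peak tidal volume as a fraction of FVC (tidal volume
#'   is capacity-limited in CF).
#' @param vt_rest warm-up tidal volume, L.
#' @param vd_frac physiological dead-space fraction of tidal volume
#'   (used by the mechanistic stage to construct dead-space parameters).
#' @param warmup_power warm-up work rate, W (protocol: 10--20 W).
#' @param warmup_duration_s warm-up length, s.
#' @param target_ramp_s intended ramp duration, s (protocol: ~600 s); the
#'   per-patient ramp rate is derived from it and clipped to
#'   `ramp_rate_range`.
#' @param ramp_rate_range allowed ramp rates, W/min.
#' @param recovery_power,recovery_duration_s active recovery phase.
#' @param tau_vo2 first-order VO2 kinetics time constant, s (0 disables
#'   the lag, making the ramp response exactly affine in work rate).
#' @param rcp_surge fractional ventilation surge reached at exhaustion,
#'   emulating respiratory-compensation hyperventilation over the final
#'   `rcp_window_s` seconds (excluded from the log-linear fits).
#' @param rcp_window_s length of the pre-exhaustion surge window, s.
#' @param sd_vo2,sd_vco2 additive Gaussian noise SD on VO2/VCO2, L/min.
#' @param sdlog_ve multiplicative log-normal noise SD on VE.
#' @param dt_s sampling interval of the generated trace, s.
#' @param severity_loadings named numeric vector of correlation loadings
#'   on a latent disease-severity factor (standard normal, truncated to
#'   \[-2.5, 2.5\]). A loading `r` for parameter `p` shifts its mean by
#'   `r * sd * severity` and shrinks its residual SD to
#'   `sd * sqrt(1 - r^2)`, inducing the co-dependence seen in CF
#'   cohorts: more severe disease lowers lung capacity, aerobic ceiling
#'   and tidal-volume reserve while raising the dead-space fraction and
#'   the ventilatory equivalent. Set to an empty vector for independent
#'   draws.
#'
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 15L, seed = 1L,
                          age = c(14, 2.5, 9, 18),
                          fvc = c(3.0, 0.8, 1.6, 5.0),
                          fev1_ratio = c(0.75, 0.08, 0.5, 0.95),
                          vo2_rest = c(0.30, 0.04, 0.18, 0.45),
                          efficiency = c(0.0101, 0.0008, 0.008, 0.013),
                          vo2max = c(1.9, 0.45, 1.35, 3.1),
                          get_frac = c(0.55, 0.05, 0.42, 0.68),
                          rq = c(0.85, 0.03, 0.75, 0.95),
                          excess_slope = c(0.55, 0.10, 0.30, 0.90),
                          ve_rest = c(9, 1.2, 6, 13),
                          peak_ve_per_vo2 = c(30, 3, 22, 40),
                          maxvt_frac = c(0.50, 0.06, 0.35, 0.70),
                          vt_rest = c(0.55, 0.08, 0.35, 0.85),
                          vd_frac = c(0.30, 0.04, 0.18, 0.45),
                          warmup_power = 15, warmup_duration_s = 180,
                          target_ramp_s = 600,
                          ramp_rate_range = c(10, 25),
                          recovery_power = 20, recovery_duration_s = 300,
                          tau_vo2 = 30,
                          rcp_surge = 0.25, rcp_window_s = 60,
                          sd_vo2 = 0.03, sd_vco2 = 0.03, sdlog_ve = 0.04,
                          dt_s = 1,
                          severity_loadings = c(fvc = -0.6,
                                                fev1_ratio = -0.5,
                                                vo2max = -0.7,
                                                get_frac = -0.3,
                                                maxvt_frac = -0.4,
                                                vt_rest = -0.4,
                                                vd_frac = 0.6,
                                                peak_ve_per_vo2 = 0.4)) {
  cfg <- as.list(environment())
  if (cfg$n_patients < 1L) stop_fmt("n_patients must be >= 1")
  if (cfg$get_frac[1] >= 1 || cfg$get_frac[4] >= 1)
    stop_fmt("get_frac must lie strictly inside (0, 1)")
  if (cfg$maxvt_frac[4] > 1)
    stop_fmt("maxvt_frac must not exceed 1")
  for (nm in c("sd_vo2", "sd_vco2", "sdlog_ve"))
    if (cfg[[nm]] < 0) stop_fmt("%s must be >= 0", nm)
  if (cfg$warmup_power < 10 || cfg$warmup_power > 20)
    warning("warmup_power outside the 10-20 W protocol range")
  class(cfg) <- "cohort_config"
  cfg
}

## Draw one patient's physiological parameters; assumes RNG already
## seeded. A latent severity factor induces the clinical co-dependence
## between lung function, breathing pattern and aerobic capacity.
.draw_patient_params <- function(cfg) {
  sev <- rtnorm1(0, 1, -2.5, 2.5)
  loads <- cfg$severity_loadings %||% numeric()
  d <- function(nm) {
    p <- cfg[[nm]]
    r <- if (nm %in% names(loads)) loads[[nm]] else 0
    rtnorm1(p[1] + r * p[2] * sev, p[2] * sqrt(1 - r^2), p[3], p[4])
  }
  p <- list(severity = sev, age = d("age"), fvc = d("fvc"),
            fev1_ratio = d("fev1_ratio"), vo2_rest = d("vo2_rest"),
            efficiency = d("efficiency"), vo2max = d("vo2max"),
            get_frac = d("get_frac"), rq = d("rq"),
            excess_slope = d("excess_slope"), ve_rest = d("ve_rest"),
            peak_ve_per_vo2 = d("peak_ve_per_vo2"),
            maxvt_frac = d("maxvt_frac"), vt_rest = d("vt_rest"),
            vd_frac = d("vd_frac"))
  p$fev1 <- p$fev1_ratio * p$fvc
  ## keep resting tidal volume comfortably below the capacity ceiling
  vtmax <- p$maxvt_frac * p$fvc
  p$vt_rest <- min(p$vt_rest, 0.75 * vtmax)
  p
}

#' Generate one synthetic CF patient
#'
#' Builds a breath-by-breath trace on a uniform grid following the ramp
#' protocol: warm-up at a fixed low work rate, a linear ramp whose rate is
#' chosen (and clipped to the protocol range) so that the sampled VO2max is
#' reached in about `target_ramp_s` seconds, then active recovery. Oxygen
#' uptake follows the work profile through optional first-order kinetics;
#' VCO2 is piecewise linear in VO2 with a breakpoint at the true
#' gas-exchange threshold; ventilation is exponential in VO2 with a late
#' respiratory-compensation surge; tidal volume rises saturatingly toward
#' a fraction of FVC, and breathing frequency is `ve / vt` so the
#' ventilation identity holds exactly. Ground truth (threshold, VO2max,
#' generator parameters) is attached to the record.
#'
#' @param config a [cohort_config()].
#' @param index patient index, `1..n_patients`.
#' @return A [cpet_patient()] with a populated `truth` list.
#' @export
generate_patient <- function(config, index) {
  stopifnot(inherits(config, "cohort_config"))
  if (index < 1L || index > config$n_patients)
    stop_fmt("index %d outside 1..n_patients (%d)", index,
             config$n_patients)
  sub_seed <- (config$seed + 7919 * as.integer(index)) %% 2147483647L
  with_seed(sub_seed, .generate_patient_impl(config, index, sub_seed))
}

.generate_patient_impl <- function(cfg, index, sub_seed) {
  p <- .draw_patient_params(cfg)
  wp <- cfg$warmup_power
  vo2_warm <- p$vo2_rest + p$efficiency * wp
  ## clinician's ramp-rate choice: reach VO2max in ~target_ramp_s,
  ## rounded to a whole W/min and clipped to the protocol range
  rr_ideal <- 60 * (p$vo2max - vo2_warm) / (p$efficiency * cfg$target_ramp_s)
  ramp_rate <- min(max(round(rr_ideal), cfg$ramp_rate_range[1]),
                   cfg$ramp_rate_range[2])
  ramp_s <- 60 * (p$vo2max - vo2_warm) / (p$efficiency * ramp_rate)
  t_ramp <- cfg$warmup_duration_s
  t_exh <- t_ramp + ramp_s
  t_end <- t_exh + cfg$recovery_duration_s
  tt <- seq(0, t_end, by = cfg$dt_s)

  work <- ifelse(tt < t_ramp, wp,
          ifelse(tt <= t_exh, wp + ramp_rate * (tt - t_ramp) / 60,
                 cfg$recovery_power))
  ## noise-free VO2: first-order lag on the instantaneous demand, started
  ## at the warm-up steady state (warm-up assumed equilibrated)
  demand <- p$vo2_rest + p$efficiency * work
  if (cfg$tau_vo2 > 0) {
    a <- 1 - exp(-cfg$dt_s / cfg$tau_vo2)
    vo2_nf <- Reduce(function(prev, u) prev + a * (u - prev),
                     demand[-1], accumulate = TRUE, init = vo2_warm)
  } else vo2_nf <- demand

  get_vo2 <- p$get_frac * p$vo2max
  crossing <- which(vo2_nf >= get_vo2 & tt >= t_ramp)
  get_time <- if (length(crossing)) tt[crossing[1]] else NA_real_

  vco2_nf <- p$rq * vo2_nf + p$excess_slope * pmax(vo2_nf - get_vo2, 0)

  ## exponential VE-VO2 relation anchored at warm-up and peak
  ve_peak <- p$peak_ve_per_vo2 * p$vo2max
  beta <- log(ve_peak / p$ve_rest) / (p$vo2max - vo2_warm)
  alpha <- log(p$ve_rest) - beta * vo2_warm
  ve_nf <- exp(alpha + beta * vo2_nf)
  ## respiratory-compensation surge over the final window before exhaustion
  surge <- pmax(0, pmin(1, (tt - (t_exh - cfg$rcp_window_s)) /
                             cfg$rcp_window_s)) * (tt <= t_exh)
  ve_nf <- ve_nf * (1 + cfg$rcp_surge * surge)

  vo2 <- pmax(vo2_nf + rnorm(length(tt), 0, cfg$sd_vo2), 0)
  vco2 <- pmax(vco2_nf + rnorm(length(tt), 0, cfg$sd_vco2), 0)
  ve <- ve_nf * exp(rnorm(length(tt), 0, cfg$sdlog_ve))

  ## saturating tidal-volume recruitment toward the FVC ceiling;
  ## bf = ve/vt keeps the ventilation identity exact by construction
  vtmax <- p$maxvt_frac * p$fvc
  h <- p$ve_rest * (vtmax / p$vt_rest - 1)
  vt_of_ve <- function(v) vtmax * v / (v + h)
  vt <- vt_of_ve(ve)
  bf <- ve / vt

  markers <- c(warmup_start_s = 0, ramp_start_s = t_ramp,
               exhaustion_s = t_exh, recovery_end_s = t_end)
  tr <- cpet_trace(tt, work, vo2, vco2, ve, bf, vt, markers)

  ## noise-free reference slopes over the analysis window, recorded so
  ## zero-noise extraction can be checked against the generator
  win <- tt >= t_ramp & tt <= t_exh - cfg$rcp_window_s
  vt_nf <- vt_of_ve(ve_nf)
  bf_nf <- ve_nf / vt_nf
  sl <- function(y) unname(stats::coef(stats::lm.fit(
    cbind(1, vo2_nf[win]), y[win]))[2])
  truth <- list(true_get_vo2 = get_vo2, true_get_time_s = get_time,
                true_vo2max = p$vo2max, alpha = alpha, beta = beta,
                baseline_bf = p$ve_rest / p$vt_rest,
                baseline_vt = p$vt_rest,
                bf_slope = sl(bf_nf), vt_slope = sl(vt_nf),
                severity = p$severity,
                efficiency = p$efficiency, rq = p$rq,
                excess_slope = p$excess_slope, vd_frac = p$vd_frac,
                sd_vo2 = cfg$sd_vo2, sd_vco2 = cfg$sd_vco2,
                sdlog_ve = cfg$sdlog_ve, seed = sub_seed)

  cpet_patient(sprintf("P%02d", index), p$age, p$fvc, p$fev1, ramp_rate,
               tr, truth = truth)
}

#' Generate a synthetic cohort
#'
#' @param config a [cohort_config()].
#' @return A list of class `cpet_cohort`: `patients` (list of
#'   [cpet_patient()]) and `truth` (one row of ground-truth values per
#'   patient).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  patients <- lapply(seq_len(config$n_patients),
                     function(i) generate_patient(config, i))
  truth <- do.call(rbind, lapply(patients, function(p)
    data.frame(patient_id = p$patient_id, as.data.frame(p$truth))))
  structure(list(patients = patients, truth = truth, config = config),
            class = "cpet_cohort")
}

#' @export
print.cpet_cohort <- function(x, ...) {
  cat(sprintf("Synthetic CPET cohort: %d patients (seed %d)\n",
              length(x$patients), x$config$seed))
  cat(sprintf("  GET %.2f-%.2f L/min, VO2max %.2f-%.2f L/min\n",
              min(x$truth$true_get_vo2), max(x$truth$true_get_vo2),
              min(x$truth$true_vo2max), max(x$truth$true_vo2max)))
  invisible(x)
}

#' Write a cohort to disk
#'
#' One trace CSV per patient (`<patient_id>.csv`) plus `truth.csv`.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in cohort$patients)
    write_cpet_trace(p, file.path(dir, paste0(p$patient_id, ".csv")))
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}
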