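## Mechanistic ventilation modelling: the linear dead-space model
## VD(t) = VDB + a * W(t), the alveolar split VA = VE - VD, and a
## compartmental cardiorespiratory ODE core predicting ventilation from
## the work profile.

#' Dead-space parameters from rest and exercise measurements
#'
#' Constructs the linear dead-space ventilation model
#' `VD(t) = VDB + a * W(t)` from breathing frequency and dead-volume
#' measurements: `VDB = BF(rest) * VD(rest)` is the base dead-space
#' ventilation and `a = BF(exercise) * VD(exercise) / W(exercise)` scales
#' with disease severity (a more severe, tidal-volume-limited patient
#' breathes faster through the same dead volume).
#'
#' @param bf_rest,bf_ex breathing frequency at rest / peak exercise,
#'   1/min.
#' @param vd_rest,vd_ex dead volume at rest / peak exercise, L.
#' @param w_ex work rate at the exercise measurement, W (> 0).
#' @return An object of class `deadspace_params`: `vdb` (L/min) and `a`
#'   (L/min/W).
#' @export
deadspace_params <- function(bf_rest, vd_rest, bf_ex, vd_ex, w_ex) {
  vals <- c(bf_rest, vd_rest, bf_ex, vd_ex, w_ex)
  if (any(vals < 0)) stop_fmt("all measurements must be >= 0")
  if (w_ex <= 0) stop_fmt("exercise work rate must be > 0")
  structure(list(vdb = bf_rest * vd_rest, a = (bf_ex * vd_ex) / w_ex),
            class = "deadspace_params")
}

#' @export
print.deadspace_params <- function(x, ...) {
  cat(sprintf("Linear dead-space model: VD(t) = %.4g + %.4g * W(t)  [L/min]\n",
              x$vdb, x$a))
  invisible(x)
}

#' Dead-space ventilation under a work profile
#'
#' @param params a [deadspace_params()].
#' @param work work-rate series, W (vector).
#' @return `vdb + a * work`, elementwise (L/min).
#' @export
deadspace_rate <- function(params, work) {
  if (any(work < 0)) stop_fmt("work rate must be >= 0")
  params$vdb + params$a * work
}

#' Split total ventilation into dead-space and alveolar parts
#'
#' `VA = VE - VD` at every sample. Negative alveolar ventilation is
#' physically impossible and signals a mis-parameterised patient; such
#' samples are counted and flagged, never silently clipped.
#'
#' @param ve total ventilation series, L/min.
#' @param vd dead-space ventilation series on the same grid, L/min.
#' @return An object of class `ventilatory_split`: data frame `ve`, `vd`,
#'   `va` with attribute `n_negative_va`.
#' @export
split_ventilation <- function(ve, vd) {
  if (length(ve) != length(vd))
    stop_fmt("ve and vd must share a grid (lengths %d vs %d)",
             length(ve), length(vd))
  va <- ve - vd
  out <- data.frame(ve = ve, vd = vd, va = va)
  attr(out, "n_negative_va") <- sum(va < 0)
  class(out) <- c("ventilatory_split", "data.frame")
  if (any(va < 0))
    warning(sprintf("%d sample(s) with negative alveolar ventilation",
                    sum(va < 0)), call. = FALSE)
  out
}

#' Parameters of the cardiorespiratory ODE core
#'
#' Documented physiological defaults for a paediatric subject; these are
#' plausible textbook-scale values chosen by this package (the model's
#' testable content is its conservation structure, steady states and
#' solver behaviour, not a particular parameterisation). Units: pressures
#' mmHg, volumes L, flows L/min, time minutes inside the solver.
#'
#' @param pio2,pico2 inspired O2 / CO2 partial pressures, mmHg.
#' @param k1,k2 O2 dissociation constants:
#'   `CaO2 = k1 * (1 - exp(-k2 * PaO2))^2` (L O2 / L blood).
#' @param kco2,kco2_b linear CO2 dissociation
#'   `CaCO2 = kco2 * PaCO2 + kco2_b`.
#' @param vl_o2,vl_co2 effective lung storage volumes for O2 / CO2, L.
#' @param vt_o2,vt_co2 effective tissue storage volumes, L.
#' @param q_rest resting cardiac output, L/min.
#' @param cq cardiac-output gain, L blood per L/min of extra VO2.
#' @param mro2_rest resting metabolic O2 consumption, L/min.
#' @param rho metabolic O2 cost of external work, L/min per W
#'   (about 10 mL/min/W).
#' @param rq metabolic respiratory quotient.
#' @param gc,ic central chemoreflex gain (L/min/mmHg) and threshold
#'   (mmHg).
#' @param gp_gain,ip peripheral chemoreflex gain and threshold (O2-CO2
#'   interaction `gp_gain * exp(-0.05 PaO2) * (PaCO2 - ip)`).
#' @param tau_ve ventilation-drive time constant, min.
#' @param ve_min floor on the ventilation drive, L/min.
#' @param conv pressure-to-concentration conversion (863 mmHg, standard
#'   BTPS/STPD factor).
#' @return A named list of class `cardioresp_params`.
#' @export
cardioresp_params <- function(pio2 = 150, pico2 = 0,
                              k1 = 0.2, k2 = 0.046,
                              kco2 = 0.0065, kco2_b = 0.244,
                              vl_o2 = 2.5, vl_co2 = 3.2,
                              vt_o2 = 6, vt_co2 = 15,
                              q_rest = 4, cq = 6,
                              mro2_rest = 0.25, rho = 0.0105, rq = 0.85,
                              gc = 2.0, ic = 35,
                              gp_gain = 30, ip = 35,
                              tau_ve = 0.3, ve_min = 1,
                              conv = 863) {
  p <- as.list(environment())
  class(p) <- "cardioresp_params"
  p
}

.ca_o2 <- function(p, pa) p$k1 * (1 - exp(-p$k2 * pmax(pa, 0)))^2
.ca_co2 <- function(p, pa) p$kco2 * pa + p$kco2_b

## Metabolic and circulatory forcing at work rate w.
.forcing <- function(p, w) {
  mro2 <- p$mro2_rest + p$rho * w
  list(mro2 = mro2, mrco2 = p$rq * mro2,
       q = p$q_rest + p$cq * (mro2 - p$mro2_rest))
}

.vent_drive <- function(p, pao2, paco2) {
  d <- p$gp_gain * exp(-0.05 * pao2) * (paco2 - p$ip) +
    p$gc * (paco2 - p$ic)
  max(d, p$ve_min)
}

#' Steady state of the cardiorespiratory core
#'
#' Solves the algebraic steady state at a constant work rate: the
#' alveolar ventilation satisfying the chemoreflex drive balance is found
#' by root bracketing, and all other states follow from the gas mass
#' balances (so the Fick principle — tissue uptake equal to pulmonary
#' uptake — holds to solver precision at the returned state).
#'
#' @param pars a [cardioresp_params()].
#' @param w constant work rate, W.
#' @param deadspace a [deadspace_params()] or `NULL` for the zero
#'   dead-space model.
#' @return Named list: state vector (`pao2`, `paco2`, `cvo2`, `cvco2`,
#'   `ve`) plus `va`, `vd`, `q`, `mro2`, `mrco2`.
#' @export
steady_cardioresp <- function(pars, w = 0, deadspace = NULL) {
  fo <- .forcing(pars, w)
  vd <- if (is.null(deadspace)) 0 else deadspace_rate(deadspace, w)
  gap <- function(va) {
    paco2 <- pars$pico2 + pars$conv * fo$mrco2 / va
    pao2 <- pars$pio2 - pars$conv * fo$mro2 / va
    .vent_drive(pars, pao2, paco2) - (va + vd)
  }
  root <- stats::uniroot(gap, c(0.2, 400), tol = 1e-12)
  va <- root$root
  paco2 <- pars$pico2 + pars$conv * fo$mrco2 / va
  pao2 <- pars$pio2 - pars$conv * fo$mro2 / va
  cao2 <- .ca_o2(pars, pao2); caco2 <- .ca_co2(pars, paco2)
  list(pao2 = pao2, paco2 = paco2,
       cvo2 = cao2 - fo$mro2 / fo$q,
       cvco2 = caco2 + fo$mrco2 / fo$q,
       ve = va + vd, va = va, vd = vd, q = fo$q,
       mro2 = fo$mro2, mrco2 = fo$mrco2)
}

## ODE right-hand side; time in minutes, state (pao2, paco2, cvo2,
## cvco2, ve).
.cardioresp_rhs <- function(t, state, parms) {
  p <- parms$pars
  w <- parms$work_fn(t)
  fo <- .forcing(p, w)
  vd <- if (is.null(parms$deadspace)) 0
        else deadspace_rate(parms$deadspace, w)
  va <- state[5] - vd
  if (va <= 0)
    stop_fmt("alveolar ventilation non-positive (VE = %.3g, VD = %.3g) at t = %.3g min; dead-space model inconsistent with the ventilation drive",
             state[5], vd, t)
  cao2 <- .ca_o2(p, state[1]); caco2 <- .ca_co2(p, state[2])
  dpao2 <- (p$conv * fo$q * (state[3] - cao2) +
              va * (p$pio2 - state[1])) / p$vl_o2
  dpaco2 <- (p$conv * fo$q * (state[4] - caco2) +
               va * (p$pico2 - state[2])) / p$vl_co2
  dcvo2 <- (fo$q * (cao2 - state[3]) - fo$mro2) / p$vt_o2
  dcvco2 <- (fo$mrco2 - fo$q * (state[4] - caco2)) / p$vt_co2
  dve <- (.vent_drive(p, state[1], state[2]) - state[5]) / p$tau_ve
  list(c(dpao2, dpaco2, dcvo2, dcvco2, dve),
       c(work_W = w, vd = vd, va = va, q = fo$q,
         vo2 = fo$q * (cao2 - state[3]), vco2 = fo$q * (state[4] - caco2)))
}

#' Simulate the cardiorespiratory ODE core under a work profile
#'
#' Integrates the compartmental mass balances for O2 and CO2 in a lung
#' and a tissue compartment, with cardiac output and metabolic rate
#' driven algebraically by the work rate and a first-order chemoreflex
#' ventilation drive. Gas exchange is driven by alveolar ventilation
#' `VA = VE - VD`, where the dead space is either zero or the linear
#' model of [deadspace_params()]. Integration starts from the exact
#' steady state at the initial work rate unless `init` is given, and uses
#' a stiff-capable implicit solver (`deSolve::ode`, lsoda).
#'
#' @param work work profile: a `data.frame(t_s, work_W)` interpolated
#'   piecewise-linearly, a function of time in seconds, or a single
#'   constant (W).
#' @param duration_s simulation length, s (required when `work` is not a
#'   data frame).
#' @param pars a [cardioresp_params()].
#' @param deadspace a [deadspace_params()], or `NULL` for the zero
#'   dead-space model (in which case dead-space parameters have no
#'   influence on the output).
#' @param dt_out_s output grid spacing, s.
#' @param rtol,atol solver tolerances (defaults 1e-8, 1e-10).
#' @param init optional named initial state
#'   `(pao2, paco2, cvo2, cvco2, ve)`.
#' @return A data frame of class `cardioresp_sim`: `t_s`, `work_W`,
#'   states, `ve`, `vd`, `va`, `q`, and pulmonary `vo2`/`vco2` (L/min);
#'   attribute `pars` holds the parameter set.
#' @export
simulate_cardioresp <- function(work, duration_s = NULL,
                                pars = cardioresp_params(),
                                deadspace = NULL, dt_out_s = 1,
                                rtol = 1e-8, atol = 1e-10, init = NULL) {
  if (is.data.frame(work)) {
    stopifnot(all(c("t_s", "work_W") %in% names(work)))
    duration_s <- duration_s %||% max(work$t_s)
    wf_s <- stats::approxfun(work$t_s, work$work_W, rule = 2)
  } else if (is.function(work)) {
    if (is.null(duration_s)) stop_fmt("duration_s required with a work function")
    wf_s <- work
  } else {
    if (is.null(duration_s)) stop_fmt("duration_s required with constant work")
    w0 <- as.numeric(work)
    wf_s <- function(t) rep_len(w0, length(t))
  }
  work_fn <- function(t_min) wf_s(t_min * 60)  # solver runs in minutes
  if (any(wf_s(seq(0, duration_s, length.out = 101)) < 0))
    stop_fmt("work profile must be non-negative")

  if (is.null(init)) {
    ss <- steady_cardioresp(pars, wf_s(0), deadspace)
    init <- c(pao2 = ss$pao2, paco2 = ss$paco2, cvo2 = ss$cvo2,
              cvco2 = ss$cvco2, ve = ss$ve)
  }
  times <- seq(0, duration_s / 60, by = dt_out_s / 60)
  sol <- deSolve::ode(y = init, times = times, func = .cardioresp_rhs,
                      parms = list(pars = pars, work_fn = work_fn,
                                   deadspace = deadspace),
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop_fmt("ODE solver failed (istate = %d)", attr(sol, "istate")[1])
  out <- as.data.frame(sol)
  if (any(out$pao2 < 0 | out$paco2 < 0 | out$cvo2 < 0 | out$cvco2 < 0 |
          out$ve < 0))
    stop_fmt("negative state encountered; model mis-parameterised")
  res <- data.frame(t_s = out$time * 60, work_W = out$work_W,
                    pao2 = out$pao2, paco2 = out$paco2, cvo2 = out$cvo2,
                    cvco2 = out$cvco2, ve = out$ve, vd = out$vd,
                    va = out$va, q = out$q, vo2 = out$vo2,
                    vco2 = out$vco2)
  attr(res, "pars") <- pars
  attr(res, "deadspace") <- deadspace
  class(res) <- c("cardioresp_sim", "data.frame")
  res
}

#' @export
print.cardioresp_sim <- function(x, ...) {
  cat(sprintf("Cardiorespiratory simulation: %d samples over %g s\n",
              nrow(x), max(x$t_s)))
  cat(sprintf("  VE %.2f -> %.2f L/min, PaCO2 %.1f -> %.1f mmHg, VO2 %.2f -> %.2f L/min\n",
              x$ve[1], x$ve[nrow(x)], x$paco2[1], x$paco2[nrow(x)],
              x$vo2[1], x$vo2[nrow(x)]))
  invisible(x)
}

#' Rest/peak ventilatory summary for a cohort (dead-space model)
#'
#' For each patient, applies the linear dead-space model built from the
#' patient's own warm-up and peak-exercise breathing pattern to split the
#' measured ventilation into dead-space and alveolar parts at rest
#' (warm-up mean) and peak exercise (mean of the last 30 s before
#' exhaustion), and appends the group mean.
#'
#' @param cohort a [generate_cohort()] result or list of patients.
#' @param vd_frac_default dead-volume fraction of tidal volume used when
#'   a patient record carries no `vd_frac` ground truth.
#' @return A data frame with one row per patient plus a `"group_mean"`
#'   row: rest and peak `ve`, `vd`, `va` (L/min) and the per-patient
#'   dead-space parameters `vdb`, `a`.
#' @export
ventilatory_summary <- function(cohort, vd_frac_default = 0.3) {
  patients <- if (inherits(cohort, "cpet_cohort")) cohort$patients else cohort
  rows <- lapply(patients, function(p) {
    tr <- p$trace
    mk <- trace_markers(tr)
    rest <- tr$time >= mk[["warmup_start_s"]] & tr$time <= mk[["ramp_start_s"]]
    peak <- tr$time >= mk[["exhaustion_s"]] - 30 & tr$time <= mk[["exhaustion_s"]]
    vdf <- p$truth$vd_frac %||% vd_frac_default
    bf_rest <- mean(tr$bf[rest]); vt_rest <- mean(tr$vt[rest])
    bf_peak <- mean(tr$bf[peak]); vt_peak <- mean(tr$vt[peak])
    w_peak <- mean(tr$work_rate[peak])
    dsp <- deadspace_params(bf_rest, vdf * vt_rest, bf_peak,
                            vdf * vt_peak, w_peak)
    ve_rest <- mean(tr$ve[rest]); ve_peak <- mean(tr$ve[peak])
    vd_rest <- deadspace_rate(dsp, mean(tr$work_rate[rest]))
    vd_peak <- deadspace_rate(dsp, w_peak)
    data.frame(patient_id = p$patient_id,
               ve_rest = ve_rest, vd_rest = vd_rest,
               va_rest = ve_rest - vd_rest,
               ve_peak = ve_peak, vd_peak = vd_peak,
               va_peak = ve_peak - vd_peak,
               vdb = dsp$vdb, a = dsp$a)
  })
  tab <- do.call(rbind, rows)
  means <- colMeans(tab[-1])
  rbind(tab, data.frame(patient_id = "group_mean", t(means)))
}
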