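# Feature extraction: energy integral, log-linear ventilation fit,
# fixed-ventilation oxygen uptake, baselines, slopes, exclusion windows.

test_that("total energy matches closed-form work integrals", {
  mk60 <- c(warmup_start_s = 0, ramp_start_s = 0, exhaustion_s = 60,
            recovery_end_s = 60)
  tt <- 0:60
  const <- cpet_trace(tt, 100, 1, 0.9, 30, 30, 1, mk60)
  expect_equal(total_energy(const), 6.0, tolerance = 1e-12)

  zero <- cpet_trace(tt, 0, 1, 0.9, 30, 30, 1, mk60)
  expect_equal(total_energy(zero), 0, tolerance = 1e-12)

  mk600 <- c(warmup_start_s = 0, ramp_start_s = 0, exhaustion_s = 600,
             recovery_end_s = 600)
  tt <- seq(0, 600, by = 1)
  ramp <- cpet_trace(tt, 200 * tt / 600, 1, 0.9, 30, 30, 1, mk600)
  expect_equal(total_energy(ramp), 60.0, tolerance = 1e-12)
})

test_that("energy is additive over partitions and resampling-invariant", {
  tr <- make_trace()
  e_full <- total_energy(tr)
  ## split at an interior marker: integrate [0, 300] and [300, end]
  mk <- trace_markers(tr)
  left <- tr[tr$time <= 300, ]
  right <- tr[tr$time >= 300, ]
  e_left <- trapz(left$time, left$work_rate) / 1000
  e_right_to_exh <- {
    idx <- right$time <= mk[["exhaustion_s"]]
    trapz(right$time[idx], right$work_rate[idx]) / 1000
  }
  expect_equal(e_left + e_right_to_exh, e_full, tolerance = 1e-10)

  rs <- resample_uniform(tr, 0.5)   # work profile is piecewise linear
  expect_equal(total_energy(rs), e_full, tolerance = 1e-9)

  no_exh <- tr
  attr(no_exh, "markers")["exhaustion_s"] <- NA
  expect_error(total_energy(no_exh), "exhaustion marker")
})

test_that("log-linear fit recovers an exact exponential relation", {
  tr <- make_trace(ve = exp(2 + 0.5 * (0.3 + 0.01 * ifelse(
    seq(0, 900) < 180, 15,
    ifelse(seq(0, 900) <= 600, 15 + 15 * (seq(0, 900) - 180) / 60, 20)))))
  fit <- fit_ve_vo2(tr)
  expect_equal(fit$alpha, 2, tolerance = 1e-10)
  expect_equal(fit$beta, 0.5, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
})

test_that("samples outside the fit window have no influence", {
  cfg <- cohort_config(n_patients = 1, seed = 23)
  p <- generate_patient(cfg, 1)
  tr <- p$trace
  fit0 <- fit_ve_vo2(tr)
  sl0 <- ventilatory_slopes(tr)

  corrupted <- tr
  mk <- trace_markers(tr)
  outside <- tr$time < mk[["warmup_start_s"]] + 180 |
    tr$time > mk[["exhaustion_s"]] - 60
  corrupted$ve[outside] <- corrupted$ve[outside] * 10
  corrupted$bf[outside] <- corrupted$bf[outside] * 10  # keep identity
  fit1 <- fit_ve_vo2(corrupted)
  sl1 <- ventilatory_slopes(corrupted)
  expect_identical(fit1$alpha, fit0$alpha)
  expect_identical(fit1$beta, fit0$beta)
  expect_identical(sl1, sl0)
})

test_that("fit coefficients equal an explicit normal-equations solve", {
  p <- generate_patient(cohort_config(n_patients = 1, seed = 29), 1)
  tr <- p$trace
  fit <- fit_ve_vo2(tr)
  idx <- .window_idx(tr, fit$window)
  ab <- oracle_ols(tr$vo2[idx], log(tr$ve[idx]))
  expect_equal(fit$alpha, ab[1], tolerance = 1e-10)
  expect_equal(fit$beta, ab[2], tolerance = 1e-10)

  sl <- ventilatory_slopes(tr)
  expect_equal(unname(sl["bf_slope"]),
               oracle_ols(tr$vo2[idx], tr$bf[idx])[2], tolerance = 1e-10)
  expect_equal(unname(sl["vt_slope"]),
               oracle_ols(tr$vo2[idx], tr$vt[idx])[2], tolerance = 1e-10)
})

test_that("fit errors on short windows and nonpositive ventilation", {
  tr <- make_trace()
  short <- tr
  attr(short, "markers")["exhaustion_s"] <- 185
  expect_error(fit_ve_vo2(short), "samples")
  bad <- tr
  bad$ve[400] <- 0; bad$bf[400] <- 0
  expect_error(fit_ve_vo2(bad), "sample 400")
})

test_that("oxygen uptake at fixed ventilation inverts the fitted curve", {
  fit <- structure(list(alpha = log(49.32), beta = 0.5),
                   class = "ve_vo2_fit")
  expect_equal(vo2_at_ve(fit), 0, tolerance = 1e-12)

  fit2 <- structure(list(alpha = log(10), beta = 0.5),
                    class = "ve_vo2_fit")
  v <- vo2_at_ve(fit2)
  expect_equal(v, (log(49.32) - log(10)) / 0.5, tolerance = 1e-12)
  expect_equal(v, 3.191, tolerance = 1e-3)
  expect_equal(exp(fit2$alpha + fit2$beta * v), 49.32, tolerance = 1e-10)

  degenerate <- structure(list(alpha = 1, beta = 0), class = "ve_vo2_fit")
  expect_error(vo2_at_ve(degenerate), "degenerate")
})

test_that("baseline ventilation averages the warm-up window", {
  tt <- seq(0, 900)
  bf <- ifelse(tt <= 180, 20, 35)
  vt <- ifelse(tt <= 180, 0.8, 1.2)
  tr <- cpet_trace(tt, 15, 0.4, 0.34, bf * vt, bf, vt,
                   c(warmup_start_s = 0, ramp_start_s = 180,
                     exhaustion_s = 600, recovery_end_s = 900))
  b <- baseline_ventilation(tr)
  expect_equal(unname(b["baseline_bf"]), 20, tolerance = 1e-12)
  expect_equal(unname(b["baseline_vt"]), 0.8, tolerance = 1e-12)

  ## mean of a linear signal over a uniformly sampled window
  bf_lin <- ifelse(tt <= 180, 15 + 10 * tt / 180, 35)
  tr2 <- cpet_trace(tt, 15, 0.4, 0.34, bf_lin * vt, bf_lin, vt,
                    c(warmup_start_s = 0, ramp_start_s = 180,
                      exhaustion_s = 600, recovery_end_s = 900))
  expect_equal(unname(baseline_ventilation(tr2)["baseline_bf"]), 20,
               tolerance = 1e-12)
})

test_that("ventilatory slopes handle constant and linear channels", {
  tt <- seq(0, 900)
  work <- ifelse(tt < 180, 15, ifelse(tt <= 600, 15 + (tt - 180) / 10, 20))
  vo2 <- 0.3 + 0.01 * work
  bf <- 10 + 5 * vo2
  vt <- rep(1, length(tt))
  tr <- cpet_trace(tt, work, vo2, 0.85 * vo2, bf * vt, bf, vt,
                   c(warmup_start_s = 0, ramp_start_s = 180,
                     exhaustion_s = 600, recovery_end_s = 900))
  sl <- ventilatory_slopes(tr)
  expect_equal(unname(sl["bf_slope"]), 5, tolerance = 1e-10)
  expect_equal(unname(sl["vt_slope"]), 0, tolerance = 1e-10)

  const <- cpet_trace(tt, work, vo2, 0.85 * vo2, rep(24, length(tt)),
                      rep(20, length(tt)), rep(1.2, length(tt)),
                      trace_markers(tr))
  sl0 <- ventilatory_slopes(const)
  expect_equal(unname(sl0), c(0, 0), tolerance = 1e-10)

  ## time-based alternative has work/time units
  sl_t <- ventilatory_slopes(tr, against = "time")
  expect_equal(unname(sl_t["bf_slope"]), 5 * 0.01 / 10, tolerance = 1e-10)
})

test_that("VO2/VE ratio series is an elementwise division with invariance", {
  tr <- make_trace(ve = 25 * (0.3 + 0.01 * ifelse(
    seq(0, 900) < 180, 15,
    ifelse(seq(0, 900) <= 600, 15 + 15 * (seq(0, 900) - 180) / 60, 20))))
  rat <- vo2_ve_ratio(tr)
  expect_equal(rat$ratio, rep(1 / 25, nrow(tr)), tolerance = 1e-12)
  expect_equal(attr(rat, "exhaustion_s"), 600)

  ## dimensionless: common rescaling of both channels cancels
  tr2 <- tr
  tr2$vo2 <- tr2$vo2 / 60; tr2$ve <- tr2$ve / 60
  tr2$bf <- tr2$bf / 60   # keep identity consistent
  expect_equal(vo2_ve_ratio(tr2)$ratio, rat$ratio, tolerance = 1e-12)

  bad <- tr; bad$ve[5] <- 0; bad$bf[5] <- 0
  expect_error(vo2_ve_ratio(bad), "sample 5")

  p <- generate_patient(cohort_config(n_patients = 1, seed = 3), 1)
  expect_equal(vo2_ve_ratio(p$trace)$ratio, p$trace$vo2 / p$trace$ve,
               tolerance = 1e-12)
})

test_that("feature vector exposes exactly seven finite predictors", {
  p <- generate_patient(cohort_config(n_patients = 1, seed = 41), 1)
  fv <- extract_features(p)
  preds <- attr(fv, "predictors")
  expect_length(preds, 7)
  expect_true(all(is.finite(unlist(fv[preds]))))
  fv2 <- extract_features(p)
  expect_identical(as.data.frame(fv), as.data.frame(fv2))
})

test_that("zero-noise cohorts return generator parameters near-exactly", {
  cfg <- noiseless_config(n = 3, seed = 19)
  co <- generate_cohort(cfg)
  f <- cohort_features(co)
  tru <- co$truth
  rel <- function(a, b) abs(a - b) / pmax(abs(b), 1e-12)
  expect_true(all(rel(f$ve_fit_alpha, tru$alpha) <= 1e-8))
  expect_true(all(rel(f$ve_fit_beta, tru$beta) <= 1e-8))
  expect_true(all(rel(f$baseline_bf, tru$baseline_bf) <= 1e-8))
  expect_true(all(rel(f$baseline_vt, tru$baseline_vt) <= 1e-8))
  expect_true(all(rel(f$bf_slope, tru$bf_slope) <= 1e-8))
  expect_true(all(rel(f$vt_slope, tru$vt_slope) <= 1e-8))
  ## derived VO2 at the reference ventilation from the true curve
  v_true <- (log(49.32) - tru$alpha) / tru$beta
  expect_true(all(rel(f$vo2_at_fixed_ve, v_true) <= 1e-8))
})
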