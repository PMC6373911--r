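# Trace container, validation, file round-trip and resampling.

test_that("validation rejects structural defects and names the offender", {
  tr <- make_trace()
  expect_silent(validate_cpet_trace(tr))

  bad <- tr; bad$time[10] <- bad$time[12]
  expect_error(validate_cpet_trace(bad), "strictly increasing")

  bad <- tr; bad$vo2[7] <- -0.01
  expect_error(validate_cpet_trace(bad), "'vo2' negative at row 7")

  bad <- tr; bad$bf <- bad$bf * 1.5
  expect_error(validate_cpet_trace(bad), "ventilation identity")

  expect_error(
    cpet_trace(tr$time, tr$work_rate, tr$vo2, tr$vco2, tr$ve, tr$bf,
               tr$vt, c(warmup_start_s = 0, ramp_start_s = 700,
                        exhaustion_s = 600, recovery_end_s = 900)),
    "phase markers")
})

test_that("ventilation identity passes exactly when ve = bf * vt", {
  tr <- make_trace()
  expect_true(all(abs(tr$ve - tr$bf * tr$vt) < 1e-12))
  expect_silent(validate_cpet_trace(tr, tol = 1e-10))
})

test_that("patient record enforces spirometry and protocol invariants", {
  tr <- make_trace()
  expect_error(cpet_patient("X", 14, 2.5, 2.9, 15, tr), "fev1")
  expect_error(cpet_patient("X", 14, 3, 2.4, 35, tr), "ramp_rate")
  expect_s3_class(cpet_patient("X", 14, 3, 2.4, 35, tr,
                               allow_nonprotocol_ramp = TRUE),
                  "cpet_patient")
  expect_error(
    cpet_patient("X", 14, 3, 2.4, 15, tr,
                 truth = list(true_get_vo2 = 2, true_vo2max = 1.5)),
    "true_get_vo2")
})

test_that("reader reports all missing channels by canonical name", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# patient_id: X", "# age_y: 14", "# fvc_L: 3",
               "# fev1_L: 2.4", "# ramp_W_per_min: 15",
               "# warmup_start_s: 0", "# ramp_start_s: 180",
               "# exhaustion_s: 600", "# recovery_end_s: 900",
               "t_s,work_W,vo2_Lmin", "0,15,0.3", "1,15,0.31"), f)
  err <- tryCatch(read_cpet_trace(f), error = conditionMessage)
  expect_match(err, "vco2"); expect_match(err, "bf")
  expect_match(err, "vt"); expect_match(err, "ve")
})

test_that("write/read round-trip is lossless including ground truth", {
  rec <- generate_patient(cohort_config(n_patients = 2, seed = 3), 1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_cpet_trace(rec, f)
  back <- read_cpet_trace(f)
  expect_identical(back$patient_id, rec$patient_id)
  for (fld in c("age", "fvc", "fev1", "ramp_rate"))
    expect_equal(back[[fld]], rec[[fld]], tolerance = 1e-9)
  for (ch in names(rec$trace))
    expect_equal(back$trace[[ch]], rec$trace[[ch]], tolerance = 1e-9)
  expect_equal(trace_markers(back$trace), trace_markers(rec$trace),
               tolerance = 1e-9)
  expect_equal(back$truth$true_get_vo2, rec$truth$true_get_vo2,
               tolerance = 1e-9)
  expect_equal(back$truth$beta, rec$truth$beta, tolerance = 1e-9)
})

test_that("unit conversion normalises mL/min and L/s channels", {
  rec <- generate_patient(cohort_config(n_patients = 1, seed = 5), 1)
  f <- withr::local_tempfile(fileext = ".csv")
  mod <- rec
  mod$trace$vo2 <- mod$trace$vo2 * 1000     # mL/min in the file
  mod$trace$ve <- mod$trace$ve / 60         # L/s in the file
  write_cpet_trace(mod, f)
  back <- read_cpet_trace(f, dialect = list(units = c(vo2 = "mL/min",
                                                      ve = "L/s")))
  expect_equal(back$trace$vo2, rec$trace$vo2, tolerance = 1e-9)
  expect_equal(back$trace$ve, rec$trace$ve, tolerance = 1e-9)
})

test_that("resampling is idempotent on uniform grids and exact on linear signals", {
  tr <- make_trace(dt = 2)
  rs <- resample_uniform(tr, 2)
  shared <- intersect(tr$time, rs$time)
  expect_equal(rs$vo2[match(shared, rs$time)],
               tr$vo2[match(shared, tr$time)], tolerance = 1e-12)

  lin <- make_trace(vo2 = 2 * seq(0, 900, by = 1) / 900 + 0.3)
  rs <- resample_uniform(lin, 0.7)
  expect_equal(rs$vo2, 2 * rs$time / 900 + 0.3, tolerance = 1e-10)

  expect_error(resample_uniform(tr, 1e5), "exceeds")
  expect_error(resample_uniform(tr, 0), "dt must be")
})

test_that("interpolated values at original timestamps reproduce the originals", {
  set.seed(42)
  tt <- sort(runif(200, 0, 900))
  tt <- tt[c(TRUE, diff(tt) > 1e-3)]
  ve <- exp(2 + rnorm(length(tt), 0, 0.1))
  vt <- runif(length(tt), 0.5, 1.2)
  tr <- cpet_trace(tt, 50, abs(rnorm(length(tt), 1, 0.2)),
                   abs(rnorm(length(tt), 0.9, 0.2)), ve, ve / vt, vt,
                   c(warmup_start_s = min(tt), ramp_start_s = min(tt) + 180,
                     exhaustion_s = max(tt) - 10, recovery_end_s = max(tt)))
  rs <- resample_uniform(tr, 0.25)
  ## manual bracketing interpolation as the independent lookup oracle
  manual_interp <- function(x, y, xo) {
    vapply(xo, function(g) {
      i <- findInterval(g, x, all.inside = TRUE)
      y[i] + (y[i + 1] - y[i]) * (g - x[i]) / (x[i + 1] - x[i])
    }, 0)
  }
  for (ch in c("vo2", "vco2", "ve"))
    expect_equal(rs[[ch]], manual_interp(tt, tr[[ch]], rs$time),
                 tolerance = 1e-10)
  ## and grid points coinciding with original samples reproduce them
  on_grid <- tt[abs(tt / 0.25 - round(tt / 0.25)) < 1e-9]
  if (length(on_grid))
    expect_equal(rs$ve[match(round(on_grid, 10), round(rs$time, 10))],
                 tr$ve[match(on_grid, tt)], tolerance = 1e-10)
})

test_that("every synthetic trace passes validation at generator tolerance", {
  co <- generate_cohort(cohort_config(n_patients = 6, seed = 21))
  for (p in co$patients)
    expect_silent(validate_cpet_trace(p$trace, tol = 1e-9))
})
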