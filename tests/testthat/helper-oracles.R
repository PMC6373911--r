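# Independent oracles and small fixture builders used across the suite.
# Oracles deliberately re-derive results through a different code path
# (dense solve(), explicit normal equations, exhaustive search) than the
# implementation they check.

## Dense-matrix evaluation of the GP posterior mean/variance from a
## fitted emulator's stored parameters, using solve() throughout.
oracle_gp_predict <- function(gp, Z, mean_uncertainty = FALSE) {
  Z <- as.matrix(Z)
  Zs <- sweep(sweep(Z, 2, gp$x_center), 2, gp$x_scale, "/")
  n <- gp$n
  kf <- function(a, b) gp$sigma^2 * exp(-sum((a - b)^2 / (2 * gp$phi^2)))
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    K[i, j] <- kf(gp$Xs[i, ], gp$Xs[j, ])
  K <- K + diag(gp$nugget, n)
  Ki <- solve(K)
  H <- cbind(1, gp$Xs)
  out <- t(vapply(seq_len(nrow(Zs)), function(m) {
    z <- Zs[m, ]
    k <- vapply(seq_len(n), function(i) kf(gp$Xs[i, ], z), 0)
    hz <- c(1, z)
    mu <- sum(hz * gp$beta) + drop(t(k) %*% Ki %*% (gp$ys - H %*% gp$beta))
    s2 <- kf(z, z) - drop(t(k) %*% Ki %*% k)
    if (mean_uncertainty) {
      u <- hz - drop(t(H) %*% Ki %*% k)
      s2 <- s2 + drop(t(u) %*% solve(t(H) %*% Ki %*% H) %*% u)
    }
    c(mu, max(s2, 0))
  }, c(0, 0)))
  list(mean = gp$y_center + gp$y_scale * out[, 1],
       sd = gp$y_scale * sqrt(out[, 2]))
}

## OLS slope/intercept by explicit normal equations.
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  unname(drop(solve(t(X) %*% X, t(X) %*% y)))
}

## Exhaustive brute-force knot search for the continuous two-segment fit,
## computing each RSS through the normal equations.
oracle_knot_search <- function(v, cc, knots) {
  rss <- vapply(knots, function(k) {
    X <- cbind(1, v, pmax(v - k, 0))
    b <- solve(t(X) %*% X, t(X) %*% cc)
    sum((cc - X %*% b)^2)
  }, 0)
  list(knot = knots[which.min(rss)], rss = rss)
}

## Minimal well-formed trace from explicit channels on a uniform grid.
make_trace <- function(t_end = 900, dt = 1, warmup = 180, tail_rec = 300,
                       work = NULL, vo2 = NULL, vco2 = NULL, ve = NULL,
                       bf = NULL, vt = NULL) {
  tt <- seq(0, t_end, by = dt)
  t_exh <- t_end - tail_rec
  if (is.null(work))
    work <- ifelse(tt < warmup, 15,
            ifelse(tt <= t_exh, 15 + 15 * (tt - warmup) / 60, 20))
  if (is.null(vo2)) vo2 <- 0.3 + 0.01 * work
  if (is.null(vco2)) vco2 <- 0.85 * vo2
  if (is.null(ve)) ve <- exp(2 + 1.1 * vo2)
  if (is.null(vt)) vt <- pmin(0.5 + 0.02 * ve, 1.6)
  if (is.null(bf)) bf <- ve / vt
  cpet_trace(tt, work, vo2, vco2, ve, bf, vt,
             c(warmup_start_s = 0, ramp_start_s = warmup,
               exhaustion_s = t_exh, recovery_end_s = t_end))
}

## Noiseless piecewise V-slope trace with a known breakpoint.
make_vslope_trace <- function(get_vo2 = 1.5, slope_below = 1.0,
                              slope_above = 1.3, vo2_range = c(0.4, 2.4),
                              t_end = 1000) {
  tt <- seq(0, t_end, by = 1)
  t_exh <- t_end - 200
  ## VO2 rises linearly through the ramp so the window spans vo2_range
  vo2 <- approx(c(0, 180, t_exh, t_end),
                c(vo2_range[1], vo2_range[1], vo2_range[2] + 0.1,
                  vo2_range[1]), tt)$y
  vco2 <- 0.1 + slope_below * vo2 +
    (slope_above - slope_below) * pmax(vo2 - get_vo2, 0)
  ve <- exp(1.8 + 1.0 * vo2)
  vt <- pmin(0.5 + 0.02 * ve, 1.5)
  work <- ifelse(tt < 180, 15, ifelse(tt <= t_exh, 15 + (tt - 180) / 4, 20))
  cpet_trace(tt, work, vo2, vco2, ve, ve / vt, vt,
             c(warmup_start_s = 0, ramp_start_s = 180,
               exhaustion_s = t_exh, recovery_end_s = t_end))
}

## Zero-noise cohort configuration (exact analytic structure).
noiseless_config <- function(n = 5, seed = 11, tau = 0)
  cohort_config(n_patients = n, seed = seed, sd_vo2 = 0, sd_vco2 = 0,
                sdlog_ve = 0, tau_vo2 = tau)
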