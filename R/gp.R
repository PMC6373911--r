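#' Squared-exponential covariance between two points
#'
#' `k(x, x') = sigma^2 * prod_i exp(-|x_i - x'_i|^2 / (2 * phi_i^2))`.
#' `sigma` controls the vertical variability of sample functions and the
#' per-dimension lengthscales `phi_i > 0` their smoothness along input
#' dimension `i`.
#'
#' @param x,x2 input vectors of equal length `d`.
#' @param sigma signal standard deviation (> 0).
#' @param phi lengthscales, length `d` (or scalar, recycled), all > 0.
#' @return The covariance value.
#' @export
sqexp_kernel <- function(x, x2, sigma, phi) {
  x <- as.numeric(x); x2 <- as.numeric(x2)
  if (length(x) != length(x2))
    stop_fmt("dimension mismatch: length(x) = %d, length(x2) = %d",
             length(x), length(x2))
  phi <- rep_len(as.numeric(phi), length(x))
  if (sigma <= 0 || any(phi <= 0))
    stop_fmt("sigma and all lengthscales must be > 0")
  sigma^2 * exp(-sum((x - x2)^2 / (2 * phi^2)))
}

## Cross-covariance matrix between row sets X1 (n1 x d) and X2 (n2 x d).
.sqexp_cov <- function(X1, X2, sigma, phi) {
  d <- ncol(X1)
  phi <- rep_len(phi, d)
  S <- matrix(0, nrow(X1), nrow(X2))
  for (j in seq_len(d))
    S <- S + outer(X1[, j], X2[, j], "-")^2 / (2 * phi[j]^2)
  sigma^2 * exp(-S)
}

## Cholesky with escalating jitter; returns list(U, nugget_used) where
## U is the upper factor of K + nugget * I.
.chol_escalate <- function(K, nugget, nugget_max) {
  nug <- nugget
  repeat {
    U <- tryCatch(chol(K + diag(nug, nrow(K))), error = function(e) NULL)
    if (!is.null(U)) return(list(U = U, nugget = nug))
    if (nug >= nugget_max)
      stop_fmt("covariance matrix not positive definite even with nugget %.3g",
               nug)
    nug <- max(nug * 10, 1e-12)
  }
}

.solve_chol <- function(U, b) backsolve(U, backsolve(U, b, transpose = TRUE))

## Negative profile log marginal likelihood over theta = log(c(sigma, phi)).
## The first-order polynomial mean is profiled out by GLS at each theta.
.gp_negll <- function(theta, X, y, H, nugget_rel, nugget_max_rel) {
  sigma <- exp(theta[1]); phi <- exp(theta[-1])
  vy <- max(stats::var(y), 1e-12)
  K <- .sqexp_cov(X, X, sigma, phi)
  ch <- tryCatch(.chol_escalate(K, nugget_rel * vy, nugget_max_rel * vy),
                 error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  U <- ch$U
  KiH <- .solve_chol(U, H)
  A <- crossprod(H, KiH)
  beta <- tryCatch(solve(A, crossprod(KiH, y)), error = function(e) NULL)
  if (is.null(beta)) return(1e10)
  r <- y - H %*% beta
  quad <- sum(r * .solve_chol(U, r))
  ll <- -0.5 * quad - sum(log(diag(U))) - length(y) / 2 * log(2 * pi)
  if (!is.finite(ll)) return(1e10)
  -ll
}

.gp_fit_core <- function(X, y, hyper = NULL, restarts = 10,
                         nugget_rel = 1e-8, nugget_max_rel = 1e-2,
                         standardize = TRUE, opt_seed = 1) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X); d <- ncol(X)
  if (anyNA(X) || anyNA(y)) stop_fmt("NA in training inputs or outputs")
  if (length(y) != n) stop_fmt("length(y) must equal nrow(X)")
  if (n < d + 2) stop_fmt("need n >= d + 2 (%d) for an identifiable first-order mean, got n = %d",
                          d + 2, n)

  if (standardize) {
    x_center <- colMeans(X)
    x_scale <- apply(X, 2, stats::sd)
    x_scale[x_scale < 1e-12] <- 1
    y_center <- mean(y)
    y_scale <- stats::sd(y)
    if (!is.finite(y_scale) || y_scale < 1e-12) y_scale <- 1
  } else {
    x_center <- rep(0, d); x_scale <- rep(1, d)
    y_center <- 0; y_scale <- 1
  }
  Xs <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  ys <- (y - y_center) / y_scale
  H <- cbind(1, Xs)
  vy <- max(stats::var(ys), 1e-12)

  if (is.null(hyper)) {
    sx <- pmax(apply(Xs, 2, stats::sd), 1e-3)
    sy0 <- max(stats::sd(ys), 1e-3)
    starts <- with_seed(opt_seed, {
      s <- vector("list", max(1L, restarts))
      s[[1]] <- c(log(sy0), log(sx))
      for (i in seq_len(length(s) - 1L))
        s[[i + 1L]] <- c(log(sy0) + stats::runif(1, log(0.2), log(2)),
                         log(sx) + stats::runif(d, log(0.3), log(3)))
      s
    })
    lower <- c(log(1e-3 * sy0), log(0.05 * sx))
    upper <- c(log(1e3 * sy0), log(50 * sx))
    best <- NULL
    for (s in starts) {
      opt <- tryCatch(
        stats::optim(s, .gp_negll, method = "L-BFGS-B",
                     lower = lower, upper = upper,
                     control = list(maxit = 200),
                     X = Xs, y = ys, H = H, nugget_rel = nugget_rel,
                     nugget_max_rel = nugget_max_rel),
        error = function(e) NULL)
      ## derivative-free polish guards against line-search stalls of
      ## L-BFGS-B on the occasionally kinked profile likelihood
      polish_from <- if (!is.null(opt)) opt$par else s
      nm <- tryCatch(
        stats::optim(polish_from, .gp_negll, method = "Nelder-Mead",
                     control = list(maxit = 500),
                     X = Xs, y = ys, H = H, nugget_rel = nugget_rel,
                     nugget_max_rel = nugget_max_rel),
        error = function(e) NULL)
      if (!is.null(nm) && (is.null(opt) || nm$value < opt$value)) {
        nm$par <- pmin(pmax(nm$par, lower), upper)
        opt <- nm
      }
      if (!is.null(opt) && (is.null(best) || opt$value < best$value))
        best <- opt
    }
    if (is.null(best)) stop_fmt("hyperparameter optimisation failed from all starts")
    sigma <- exp(best$par[1]); phi <- exp(best$par[-1])
    negll <- best$value
  } else {
    sigma <- hyper$sigma
    phi <- rep_len(hyper$phi %||% hyper$lengthscales, d)
    if (sigma <= 0 || any(phi <= 0))
      stop_fmt("supplied hyperparameters must be positive")
    negll <- .gp_negll(log(c(sigma, phi)), Xs, ys, H, nugget_rel,
                       nugget_max_rel)
  }

  K <- .sqexp_cov(Xs, Xs, sigma, phi)
  ch <- .chol_escalate(K, nugget_rel * vy, nugget_max_rel * vy)
  U <- ch$U
  KiH <- .solve_chol(U, H)
  A <- crossprod(H, KiH)
  beta <- solve(A, crossprod(KiH, ys))
  r <- ys - H %*% beta
  alpha_vec <- .solve_chol(U, r)

  structure(list(
    sigma = sigma, phi = phi, nugget = ch$nugget,
    beta = drop(beta), U = U, alpha_vec = drop(alpha_vec),
    A_inv = solve(A),
    X = X, y = y, Xs = Xs, ys = ys, H = H,
    x_center = x_center, x_scale = x_scale,
    y_center = y_center, y_scale = y_scale,
    logLik = -negll, n = n, d = d,
    fit_args = list(restarts = restarts, nugget_rel = nugget_rel,
                    nugget_max_rel = nugget_max_rel,
                    standardize = standardize, opt_seed = opt_seed,
                    hyper = hyper)),
    class = "gp_emulator")
}

#' Gaussian-process emulator with squared-exponential kernel
#'
#' Fits a Gaussian-process regression model with a first-order polynomial
#' (linear) mean and a squared-exponential covariance. Hyperparameters
#' (signal SD and per-input lengthscales) are estimated by maximising the
#' log marginal likelihood in log-space with seeded multi-start L-BFGS-B;
#' the mean coefficients are obtained by generalised least squares under
#' the fitted covariance. Inputs are standardised to zero mean and unit SD
#' and the output is centred and scaled internally (so lengthscales are
#' comparable across heterogeneous units); predictions are returned on the
#' original scale.
#'
#' The intended use is emulating the gas-exchange threshold from the seven
#' CPET-derived inputs, but the implementation is generic in `d`.
#'
#' @param x for the default method, an `n x d` design matrix (or data
#'   frame); for the formula method, a model formula such as
#'   `get_vo2 ~ baseline_bf + ... `.
#' @param y numeric response of length `n` (default method).
#' @param data data frame holding the formula variables.
#' @param hyper optional list `list(sigma=, phi=)` of fixed
#'   hyperparameters *on the internal (standardised) scale*; when supplied
#'   the likelihood optimisation is skipped. Use `standardize = FALSE` to
#'   interpret them on the original scale.
#' @param restarts number of seeded multi-start optimisation restarts.
#' @param nugget_rel diagonal jitter as a fraction of `var(y)` (escalated
#'   by factors of 10 up to `nugget_max_rel` if the covariance fails to
#'   factorise).
#' @param nugget_max_rel escalation ceiling for the nugget.
#' @param standardize standardise inputs and centre/scale the output
#'   internally (default `TRUE`).
#' @param opt_seed seed for the multi-start draws (the global RNG state is
#'   left untouched).
#' @param ... passed between methods.
#' @return An object of class `gp_emulator` with components including
#'   `sigma`, `phi` (lengthscales), `nugget`, `beta` (mean coefficients on
#'   the internal scale), the training design and factorised covariance,
#'   and the standardisation constants.
#' @seealso [predict.gp_emulator()], [gp_loo()], [simulate.gp_emulator()]
#' @export
gp_emulator <- function(x, ...) UseMethod("gp_emulator")

#' @rdname gp_emulator
#' @export
gp_emulator.default <- function(x, y, hyper = NULL, restarts = 10,
                                nugget_rel = 1e-8, nugget_max_rel = 1e-2,
                                standardize = TRUE, opt_seed = 1, ...) {
  fit <- .gp_fit_core(x, y, hyper = hyper, restarts = restarts,
                      nugget_rel = nugget_rel,
                      nugget_max_rel = nugget_max_rel,
                      standardize = standardize, opt_seed = opt_seed)
  fit$call <- match.call()
  fit
}

#' @rdname gp_emulator
#' @export
gp_emulator.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data)
  y <- stats::model.response(mf)
  terms_x <- stats::delete.response(stats::terms(x, data = data))
  X <- stats::model.matrix(terms_x, mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  fit <- gp_emulator.default(X, y, ...)
  fit$terms <- terms_x
  fit$call <- match.call()
  fit
}

## Internal prediction on the original scale.
.gp_predict_core <- function(object, Z, mean_uncertainty = FALSE) {
  Z <- as.matrix(Z); storage.mode(Z) <- "double"
  if (ncol(Z) != object$d)
    stop_fmt("newdata has %d columns; model expects %d", ncol(Z), object$d)
  Zs <- sweep(sweep(Z, 2, object$x_center), 2, object$x_scale, "/")
  Ks <- .sqexp_cov(object$Xs, Zs, object$sigma, object$phi)  # n x m
  hz <- cbind(1, Zs)                                         # m x (d+1)
  m_s <- drop(hz %*% object$beta) + drop(crossprod(Ks, object$alpha_vec))
  V <- .solve_chol(object$U, Ks)                             # K^{ -1 } k
  s2 <- object$sigma^2 - colSums(Ks * V)
  if (mean_uncertainty) {
    Uu <- t(hz) - crossprod(object$H, V)                     # (d+1) x m
    s2 <- s2 + colSums(Uu * (object$A_inv %*% Uu))
  }
  s2 <- pmax(s2, 0)
  list(mean = object$y_center + object$y_scale * m_s,
       sd = object$y_scale * sqrt(s2))
}

#' Posterior prediction from a fitted GP emulator
#'
#' Returns the posterior predictive mean `m(z)` and variance `s^2(z)` of
#' the Gaussian process at new inputs, conditioning on the training data
#' (with the nugget on the diagonal of the training covariance), together
#' with 95% intervals `m +/- 1.96 s`. At a training input with a tiny
#' nugget the prediction interpolates the data and the variance vanishes;
#' far from all training points the mean reverts to the polynomial trend
#' and the variance to the prior signal variance.
#'
#' @param object a [gp_emulator()] fit.
#' @param newdata an `m x d` matrix/data frame of inputs (a data frame of
#'   the original variables for formula fits). Defaults to the training
#'   design.
#' @param mean_uncertainty add the generalised-least-squares term
#'   accounting for estimation of the mean coefficients (universal-kriging
#'   variance). Default `FALSE`: the plain posterior variance.
#' @param ... unused.
#' @return A data frame with columns `mean`, `sd`, `lwr95`, `upr95`.
#' @export
predict.gp_emulator <- function(object, newdata = NULL,
                                mean_uncertainty = FALSE, ...) {
  if (is.null(newdata)) {
    Z <- object$X
  } else if (!is.null(object$terms) && is.data.frame(newdata)) {
    mf <- stats::model.frame(object$terms, newdata)
    Z <- stats::model.matrix(object$terms, mf)
    Z <- Z[, colnames(Z) != "(Intercept)", drop = FALSE]
  } else {
    Z <- as.matrix(newdata)
    if (is.null(dim(newdata)) && length(newdata) == object$d)
      Z <- matrix(as.numeric(newdata), 1L)
  }
  pr <- .gp_predict_core(object, Z, mean_uncertainty = mean_uncertainty)
  data.frame(mean = pr$mean, sd = pr$sd,
             lwr95 = pr$mean - 1.96 * pr$sd,
             upr95 = pr$mean + 1.96 * pr$sd)
}

#' @export
fitted.gp_emulator <- function(object, ...) {
  .gp_predict_core(object, object$X)$mean
}

#' Residuals of a GP emulator
#'
#' `type = "training"` gives `y - m(x_i)` at the training points (near
#' zero for an interpolating fit); `type = "loo"` gives leave-one-out
#' residuals in fixed-hyperparameter mode (see [gp_loo()]).
#'
#' @param object a [gp_emulator()] fit.
#' @param type `"training"` or `"loo"`.
#' @param ... unused.
#' @export
residuals.gp_emulator <- function(object, type = c("training", "loo"),
                                  ...) {
  type <- match.arg(type)
  if (type == "training") return(object$y - fitted(object))
  rep_loo <- gp_loo(object, mode = "fixed")
  object$y - rep_loo$table$mean
}

#' @export
coef.gp_emulator <- function(object, ...) {
  stats::setNames(object$beta,
                  c("(Intercept)", colnames(object$X) %||%
                      paste0("x", seq_len(object$d))))
}

#' @export
print.gp_emulator <- function(x, ...) {
  cat("Gaussian-process emulator (squared-exponential kernel, linear mean)\n")
  cat(sprintf("  n = %d training points, d = %d inputs\n", x$n, x$d))
  cat(sprintf("  sigma = %.4g, nugget = %.3g, log marginal likelihood = %.4g\n",
              x$sigma, x$nugget, x$logLik))
  nm <- colnames(x$X) %||% paste0("x", seq_len(x$d))
  cat("  lengthscales (standardised inputs):\n")
  print(stats::setNames(round(x$phi, 4), nm))
  invisible(x)
}

#' @export
summary.gp_emulator <- function(object, ...) {
  res <- residuals(object, type = "training")
  structure(list(fit = object, training_rmse = sqrt(mean(res^2)),
                 coef = coef(object)), class = "summary.gp_emulator")
}

#' @export
print.summary.gp_emulator <- function(x, ...) {
  print(x$fit)
  cat("  mean-function coefficients (standardised scale):\n")
  print(round(x$coef, 4))
  cat(sprintf("  training RMSE: %.3g\n", x$training_rmse))
  invisible(x)
}

#' Sample functions from the emulator posterior
#'
#' Draws sample paths of the Gaussian process on a set of input points
#' from the posterior (or, with `prior = TRUE`, from the prior with the
#' fitted hyperparameters and mean). At a training input with a tiny
#' nugget all posterior samples pass through the observed value.
#'
#' @param object a [gp_emulator()] fit.
#' @param nsim number of sample paths.
#' @param seed RNG seed for the draws (global RNG state is preserved).
#' @param newdata `m x d` matrix of grid points (defaults to the training
#'   design).
#' @param prior draw from the prior instead of the posterior.
#' @param ... unused.
#' @return An `m x nsim` matrix, one column per sample path.
#' @export
simulate.gp_emulator <- function(object, nsim = 1, seed = NULL,
                                 newdata = NULL, prior = FALSE, ...) {
  Z <- if (is.null(newdata)) object$X else as.matrix(newdata)
  Zs <- sweep(sweep(Z, 2, object$x_center), 2, object$x_scale, "/")
  m <- nrow(Zs)
  if (prior) {
    mu <- drop(cbind(1, Zs) %*% object$beta)
    Sg <- .sqexp_cov(Zs, Zs, object$sigma, object$phi)
  } else {
    Ks <- .sqexp_cov(object$Xs, Zs, object$sigma, object$phi)
    V <- .solve_chol(object$U, Ks)
    mu <- drop(cbind(1, Zs) %*% object$beta) +
      drop(crossprod(Ks, object$alpha_vec))
    Sg <- .sqexp_cov(Zs, Zs, object$sigma, object$phi) - crossprod(Ks, V)
  }
  ch <- .chol_escalate((Sg + t(Sg)) / 2, 1e-10 * object$sigma^2,
                       1e-4 * object$sigma^2)
  draws <- with_seed(seed %||% 1L, matrix(stats::rnorm(m * nsim), m, nsim))
  paths <- mu + crossprod(ch$U, draws)
  object$y_center + object$y_scale * paths
}

#' Sample paths from a GP prior
#'
#' Convenience wrapper for illustrating the prior distribution over
#' functions: draws from a zero-mean (or constant-mean) GP with the
#' squared-exponential kernel on a grid.
#'
#' @param x grid points (vector for d = 1, or matrix).
#' @param sigma,phi kernel hyperparameters.
#' @param mean constant prior mean (default 0).
#' @param nsim number of paths.
#' @param seed RNG seed.
#' @return An `m x nsim` matrix of sample paths.
#' @export
gp_prior_sample <- function(x, sigma = 1, phi = 1, mean = 0, nsim = 5,
                            seed = 1) {
  X <- if (is.null(dim(x))) matrix(as.numeric(x)) else as.matrix(x)
  Sg <- .sqexp_cov(X, X, sigma, phi)
  ch <- .chol_escalate((Sg + t(Sg)) / 2, 1e-10 * sigma^2, 1e-4 * sigma^2)
  draws <- with_seed(seed, matrix(stats::rnorm(nrow(X) * nsim), nrow(X),
                                  nsim))
  mean + crossprod(ch$U, draws)
}

#' @export
plot.gp_emulator <- function(x, ...) {
  rep_loo <- gp_loo(x, mode = "fixed")
  plot(rep_loo, ...)
  invisible(x)
}

#' Leave-one-out cross-validation of a GP emulator
#'
#' For each training point `i`, predicts `m_{-i}(x^i)` and
#' `s^2_{-i}(x^i)` from a model trained on all data except point `i`, and
#' reports the leave-one-out mean squared error
#' `MSE_LOO = (1/n) * sum_i (m_{-i}(x^i) - y_i)^2`, its value relative to
#' the mean response (as a percentage), and how many of the
#' `m_{-i} +/- 1.96 s_{-i}` intervals cover the held-out value.
#'
#' Two modes: `"refit"` re-estimates the hyperparameters on each fold
#' (the literal reading of the leave-one-out definition; default) while
#' `"fixed"` keeps the full-data (or externally supplied) hyperparameters
#' and only re-estimates the mean coefficients per fold, which is much
#' faster and exactly calibrated when the hyperparameters are known.
#'
#' @param object a [gp_emulator()] fit, or an `n x d` design matrix.
#' @param y response vector (only when `object` is a matrix).
#' @param mode `"refit"` or `"fixed"`.
#' @param hyper optional fixed hyperparameters for `mode = "fixed"`
#'   (defaults to the fitted ones).
#' @param mean_uncertainty include the mean-estimation term in the
#'   predictive variance (default `TRUE`: fold intervals account for the
#'   per-fold GLS mean).
#' @param ... further arguments to [gp_emulator()] when refitting.
#' @return An object of class `gp_loo`: `table` (per-point `y`, `mean`,
#'   `sd`, `lwr95`, `upr95`, `covered`), `mse_loo`, `mse_rel_pct`
#'   (100 * mse_loo / mean(y)), `coverage` (count), `n`, `mode`.
#' @export
gp_loo <- function(object, y = NULL, mode = c("refit", "fixed"),
                   hyper = NULL, mean_uncertainty = TRUE, ...) {
  mode <- match.arg(mode)
  if (!inherits(object, "gp_emulator")) {
    object <- gp_emulator.default(object, y, ...)
  }
  X <- object$X; yy <- object$y
  n <- object$n
  if (n < object$d + 3)
    stop_fmt("leave-one-out needs n >= d + 3 (= %d), got n = %d",
             object$d + 3, n)
  fa <- object$fit_args
  if (mode == "fixed" && is.null(hyper))
    hyper <- list(sigma = object$sigma, phi = object$phi)
  pred <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    fit_i <- tryCatch(
      .gp_fit_core(X[-i, , drop = FALSE], yy[-i],
                   hyper = if (mode == "fixed") hyper else fa$hyper,
                   restarts = fa$restarts, nugget_rel = fa$nugget_rel,
                   nugget_max_rel = fa$nugget_max_rel,
                   standardize = fa$standardize, opt_seed = fa$opt_seed),
      error = function(e)
        stop_fmt("leave-one-out fold %d failed to fit: %s", i,
                 conditionMessage(e)))
    pr <- .gp_predict_core(fit_i, X[i, , drop = FALSE],
                           mean_uncertainty = mean_uncertainty)
    pred[i, ] <- c(pr$mean, pr$sd)
  }
  tab <- data.frame(patient = seq_len(n), y = yy, mean = pred[, 1],
                    sd = pred[, 2],
                    lwr95 = pred[, 1] - 1.96 * pred[, 2],
                    upr95 = pred[, 1] + 1.96 * pred[, 2])
  tab$covered <- tab$y >= tab$lwr95 & tab$y <= tab$upr95
  mse <- mean((tab$mean - tab$y)^2)
  structure(list(table = tab, mse_loo = mse,
                 mse_rel_pct = 100 * mse / mean(yy),
                 coverage = sum(tab$covered), n = n, mode = mode),
            class = "gp_loo")
}

#' @export
print.gp_loo <- function(x, ...) {
  cat(sprintf("Leave-one-out cross-validation (%s hyperparameters, n = %d)\n",
              x$mode, x$n))
  cat(sprintf("  MSE_LOO = %.4g (%.1f%% of the mean response)\n",
              x$mse_loo, x$mse_rel_pct))
  cat(sprintf("  95%% intervals cover %d / %d held-out values\n",
              x$coverage, x$n))
  invisible(x)
}

#' @export
plot.gp_loo <- function(x, ...) {
  tab <- x$table
  ylim <- range(tab$lwr95, tab$upr95, tab$y)
  graphics::plot(tab$patient, tab$mean, pch = 8, col = "red3",
                 ylim = ylim, xlab = "patient",
                 ylab = "GET (L/min)", ...)
  graphics::arrows(tab$patient, tab$lwr95, tab$patient, tab$upr95,
                   angle = 90, code = 3, length = 0.04, col = "red3")
  graphics::points(tab$patient, tab$y, pch = 16)
  graphics::legend("topleft", pch = c(16, 8), col = c("black", "red3"),
                   legend = c("exact", "LOO prediction"), bty = "n")
  invisible(x)
}
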