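#' PCA of the breathing-pattern / oxygen-uptake space
#'
#' Principal-component analysis of the three variables that jointly
#' characterise performance: baseline breathing frequency, baseline tidal
#' volume and oxygen uptake at a fixed ventilation. Cohort trajectories
#' evolve close to a planar manifold in this space, so the leading
#' component captures most of the structure. The loading of the first
#' component is expressed in spherical polar form through `theta`, its
#' angle to the breathing-frequency axis, and the fraction of
#' total-energy variance explained by a univariate regression on the
#' first-component scores operationalises "variation in performance
#' captured".
#'
#' @param features a [cohort_features()] table (or any data frame holding
#'   the columns in `vars` and `energy`).
#' @param vars the three variable columns (default baseline breathing
#'   frequency, baseline tidal volume, VO2 at fixed ventilation).
#' @param energy column holding the performance metric.
#' @param scale. standardise the variables before PCA (default `TRUE`;
#'   the three variables carry incommensurate units).
#' @return An object of class `cpet_pca`: `loadings` (3 x 3 orthonormal,
#'   first column signed so its breathing-frequency component is
#'   non-negative), `var_ratio` (explained-variance ratios, summing to 1),
#'   `scores`, `theta` (radians, in `[0, pi/2]` by the absolute-value
#'   convention), `performance_r2_pc1`.
#' @export
pca_performance <- function(features,
                            vars = c("baseline_bf", "baseline_vt",
                                     "vo2_at_fixed_ve"),
                            energy = "total_energy_kJ", scale. = TRUE) {
  missing_cols <- setdiff(c(vars, energy), names(features))
  if (length(missing_cols))
    stop_fmt("feature table missing column(s): %s",
             paste(missing_cols, collapse = ", "))
  X <- as.matrix(features[vars])
  if (nrow(X) < 4) stop_fmt("need at least 4 patients for PCA, got %d",
                            nrow(X))
  if (!all(is.finite(X))) stop_fmt("non-finite values in PCA variables")
  if (nrow(unique(X)) < 2) stop_fmt("rank-deficient input: fewer than 2 distinct rows")
  pc <- stats::prcomp(X, center = TRUE, scale. = scale.)
  L <- pc$rotation
  scores <- pc$x
  ## sign convention: first loading has non-negative bf component
  if (L[1, 1] < 0) { L[, 1] <- -L[, 1]; scores[, 1] <- -scores[, 1] }
  var_ratio <- pc$sdev^2 / sum(pc$sdev^2)
  theta <- acos(min(1, abs(L[1, 1])))
  en <- features[[energy]]
  r2 <- summary(stats::lm(en ~ scores[, 1]))$r.squared
  structure(list(loadings = L, var_ratio = var_ratio, scores = scores,
                 theta = theta, performance_r2_pc1 = r2,
                 center = pc$center, scale = pc$scale, vars = vars),
            class = "cpet_pca")
}

#' @export
print.cpet_pca <- function(x, ...) {
  cat("PCA of (baseline BF, baseline VT, VO2 at fixed VE)\n")
  cat(sprintf("  explained variance: %s\n",
              paste(sprintf("%.1f%%", 100 * x$var_ratio), collapse = ", ")))
  cat(sprintf("  theta (first loading vs BF axis) = %.3f rad\n", x$theta))
  cat(sprintf("  R2 of total energy on PC1 scores = %.3f\n",
              x$performance_r2_pc1))
  invisible(x)
}

#' @export
plot.cpet_pca <- function(x, features = NULL, ...) {
  graphics::plot(x$scores[, 1], x$scores[, 2],
                 xlab = sprintf("PC1 (%.0f%%)", 100 * x$var_ratio[1]),
                 ylab = sprintf("PC2 (%.0f%%)", 100 * x$var_ratio[2]),
                 pch = 16, ...)
  graphics::abline(h = 0, v = 0, lty = 3, col = "grey60")
  invisible(x)
}
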