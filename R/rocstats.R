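#' Silverman's rule-of-thumb bandwidth
#'
#' `0.9 * min(sd, IQR/1.34) * n^(-1/5)`, the classical plug-in bandwidth for
#' a Gaussian kernel. Falls back to the standard deviation when the IQR is
#' zero (heavily tied data with nonzero spread).
#'
#' @param x numeric vector, length >= 2, nonzero variance.
#' @return Positive bandwidth.
#' @export
silverman_bandwidth <- function(x) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  s <- stats::sd(x)
  iqr <- stats::IQR(x) / 1.34
  spread <- if (iqr > 0) min(s, iqr) else s
  if (!is.finite(spread) || spread <= 0) {
    stop("scores have zero variance; kernel density undefined ",
         "(use the empirical ROC instead)", call. = FALSE)
  }
  0.9 * spread * n^(-1 / 5)
}

#' Gaussian kernel density estimate on a uniform grid
#'
#' @param scores finite numeric vector, length >= 2.
#' @param bandwidth kernel bandwidth; defaults to [silverman_bandwidth()].
#' @param grid_size number of grid points (default 512).
#' @param from,to grid limits; default `min - 4h` to `max + 4h` so that
#'   essentially all kernel mass is on the grid.
#' @return Object of class `density_estimate` with `grid`, `density`,
#'   `bandwidth`, `n`.
#' @export
gaussian_kde <- function(scores, bandwidth = NULL, grid_size = 512L,
                         from = NULL, to = NULL) {
  if (length(scores) < 2L || anyNA(scores) || any(!is.finite(scores))) {
    stop("scores must be >= 2 finite values", call. = FALSE)
  }
  h <- if (is.null(bandwidth)) silverman_bandwidth(scores) else bandwidth
  if (h <= 0) stop("bandwidth must be positive", call. = FALSE)
  if (is.null(from)) from <- min(scores) - 4 * h
  if (is.null(to)) to <- max(scores) + 4 * h
  grid <- seq(from, to, length.out = grid_size)
  dens <- vapply(grid, function(g) mean(stats::dnorm((g - scores) / h)) / h,
                 numeric(1))
  structure(list(grid = grid, density = dens, bandwidth = h,
                 n = length(scores)),
            class = "density_estimate")
}

trapezoid <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

kernel_cdf <- function(grid, scores, h) {
  vapply(grid, function(g) mean(stats::pnorm((g - scores) / h)), numeric(1))
}

roc_curve_obj <- function(fpr, tpr, kind, auc, len, bandwidths = NULL) {
  structure(list(fpr = fpr, tpr = tpr, kind = kind, auc = auc,
                 length = len, bandwidths = bandwidths),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("%s ROC curve: %d points, AUC = %.4f, length = %.4f\n",
              x$kind, length(x$fpr), x$auc, x$length))
  invisible(x)
}

check_groups <- function(controls, cases) {
  if (length(controls) < 1L || length(cases) < 1L) {
    stop("need at least one control and one case", call. = FALSE)
  }
  if (anyNA(c(controls, cases)) || any(!is.finite(c(controls, cases)))) {
    stop("scores must be finite", call. = FALSE)
  }
}

#' Empirical ROC curve
#'
#' Step-function ROC over all distinct observed thresholds with the
#' convention "score >= threshold calls a case". The trapezoidal area equals
#' the Mann-Whitney statistic with ties counted 1/2.
#'
#' @param controls,cases numeric score vectors; higher scores are more
#'   case-like.
#' @return An object of class `roc_curve` with `kind = "empirical"`.
#' @export
empirical_roc <- function(controls, cases) {
  check_groups(controls, cases)
  thr <- sort(unique(c(controls, cases)), decreasing = TRUE)
  fpr <- vapply(thr, function(t) mean(controls >= t), numeric(1))
  tpr <- vapply(thr, function(t) mean(cases >= t), numeric(1))
  fpr <- c(0, fpr, 1)
  tpr <- c(0, tpr, 1)
  auc <- trapezoid(fpr, tpr)
  len <- sum(sqrt(diff(fpr)^2 + diff(tpr)^2))
  roc_curve_obj(fpr, tpr, "empirical", auc, len)
}

smooth_roc_grid <- function(controls, cases, grid_size, bandwidths) {
  if (length(controls) < 2L || length(cases) < 2L) {
    stop("smooth ROC needs >= 2 observations per group", call. = FALSE)
  }
  if (is.null(bandwidths)) {
    bandwidths <- c(silverman_bandwidth(controls), silverman_bandwidth(cases))
  }
  if (any(bandwidths <= 0)) stop("bandwidths must be positive", call. = FALSE)
  hmax <- max(bandwidths)
  grid <- seq(min(controls, cases) - 4 * hmax,
              max(controls, cases) + 4 * hmax, length.out = grid_size)
  list(grid = grid, h_control = bandwidths[1], h_case = bandwidths[2])
}

#' Kernel-smoothed ROC curve
#'
#' Smooths each group's score distribution with a Gaussian kernel (Silverman
#' bandwidth per group by default) and traces the ROC as
#' `(1 - F(c), 1 - G(c))` over a shared threshold grid `c`, where `F` and `G`
#' are the kernel-smoothed control and case CDFs. The AUC is the trapezoidal
#' area; `length` is the polyline arc length of the smooth curve.
#'
#' @param controls,cases numeric score vectors, each with >= 2 values and
#'   nonzero variance.
#' @param grid_size threshold-grid resolution (default 512).
#' @param bandwidths optional `c(h_control, h_case)` override.
#' @return An object of class `roc_curve` with `kind = "smooth"`.
#' @export
smooth_roc <- function(controls, cases, grid_size = 512L, bandwidths = NULL) {
  check_groups(controls, cases)
  g <- smooth_roc_grid(controls, cases, grid_size, bandwidths)
  fpr <- 1 - kernel_cdf(g$grid, controls, g$h_control)
  tpr <- 1 - kernel_cdf(g$grid, cases, g$h_case)
  ord <- order(fpr, tpr)
  fpr <- c(0, fpr[ord], 1)
  tpr <- c(0, tpr[ord], 1)
  fpr <- cummax(pmin(pmax(fpr, 0), 1))
  tpr <- cummax(pmin(pmax(tpr, 0), 1))
  auc <- trapezoid(fpr, tpr)
  len <- sum(sqrt(diff(fpr)^2 + diff(tpr)^2))
  roc_curve_obj(fpr, tpr, "smooth", auc, len,
                bandwidths = c(h_control = g$h_control, h_case = g$h_case))
}

#' ROC curve length statistic
#'
#' Arc length of the kernel-smoothed ROC curve, computed in its
#' threshold parametrization as `L = integral of sqrt(f(c)^2 + g(c)^2) dc`
#' with `f`, `g` the group kernel densities, by trapezoid over a shared grid.
#' The length is sqrt(2) for a useless marker (diagonal ROC) and approaches 2
#' for a perfectly separating one; unlike the AUC it also responds to
#' non-monotone markers whose case scores straddle the controls.
#'
#' @inheritParams smooth_roc
#' @return Arc length in `[sqrt(2), 2]` up to numerical tolerance.
#' @export
roc_length <- function(controls, cases, grid_size = 512L, bandwidths = NULL) {
  check_groups(controls, cases)
  g <- smooth_roc_grid(controls, cases, grid_size, bandwidths)
  f <- gaussian_kde(controls, g$h_control, grid_size,
                    from = g$grid[1], to = g$grid[grid_size])$density
  gg <- gaussian_kde(cases, g$h_case, grid_size,
                     from = g$grid[1], to = g$grid[grid_size])$density
  trapezoid(g$grid, sqrt(f^2 + gg^2))
}

#' Thresholds for monotone / non-monotone marker classification
#'
#' A marker is monotone when its smooth ROC length reaches 2 (up to the
#' finite-sample tolerance `len_tol`) with an extreme AUC (> `auc_hi` or
#' < `auc_lo`); non-monotone when the length exceeds `len_nonmono` while the
#' AUC sits in the mid-range `[auc_mid_lo, auc_mid_hi]`.
#'
#' @param len_mono ideal monotone length (2, attained only in the limit).
#' @param len_tol finite-sample tolerance below `len_mono` (default 0.05).
#' @param len_nonmono non-monotone length cutoff (default 1.6, exclusive).
#' @param auc_hi,auc_lo extreme-AUC cutoffs (0.8 / 0.2, exclusive).
#' @param auc_mid_lo,auc_mid_hi mid-range AUC band (0.35 / 0.65, inclusive).
#' @return Named list of thresholds.
#' @export
shape_thresholds <- function(len_mono = 2, len_tol = 0.05, len_nonmono = 1.6,
                             auc_hi = 0.8, auc_lo = 0.2,
                             auc_mid_lo = 0.35, auc_mid_hi = 0.65) {
  list(len_mono = len_mono, len_tol = len_tol, len_nonmono = len_nonmono,
       auc_hi = auc_hi, auc_lo = auc_lo,
       auc_mid_lo = auc_mid_lo, auc_mid_hi = auc_mid_hi)
}

#' Classify a marker as monotone, non-monotone or neither
#'
#' @param length smooth ROC curve length (see [roc_length()]).
#' @param auc smooth ROC AUC.
#' @param thresholds a [shape_thresholds()] list.
#' @return Object of class `marker_shape` with `label` in
#'   `{"monotone", "non_monotone", "neither"}`, plus the inputs.
#' @export
classify_marker_shape <- function(length, auc,
                                  thresholds = shape_thresholds()) {
  t <- thresholds
  label <- if (length >= t$len_mono - t$len_tol &&
               (auc > t$auc_hi || auc < t$auc_lo)) {
    "monotone"
  } else if (length > t$len_nonmono &&
             auc >= t$auc_mid_lo && auc <= t$auc_mid_hi) {
    "non_monotone"
  } else {
    "neither"
  }
  structure(list(label = label, length = length, auc = auc,
                 thresholds = t),
            class = "marker_shape")
}

#' Classify a marker from raw scores
#'
#' Convenience wrapper computing the smooth-ROC length and AUC, then applying
#' [classify_marker_shape()].
#'
#' @inheritParams smooth_roc
#' @param thresholds a [shape_thresholds()] list.
#' @return A `marker_shape`.
#' @export
classify_marker <- function(controls, cases, grid_size = 512L,
                            bandwidths = NULL,
                            thresholds = shape_thresholds()) {
  sr <- smooth_roc(controls, cases, grid_size, bandwidths)
  len <- roc_length(controls, cases, grid_size, bandwidths)
  classify_marker_shape(len, sr$auc, thresholds)
}

#' @export
print.marker_shape <- function(x, ...) {
  cat(sprintf("marker shape: %s (length = %.3f, AUC = %.3f)\n",
              x$label, x$length, x$auc))
  invisible(x)
}

delong_components <- function(controls, cases) {
  psi <- outer(cases, controls,
               function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' AUC with DeLong standard error, CI and one-tailed p-value
#'
#' Empirical (Mann-Whitney) AUC with a standard error from DeLong's
#' structural components, a normal-approximation confidence interval clipped
#' to `[0, 1]`, and a one-tailed p-value for the null AUC = 0.5 against
#' AUC > 0.5 using `z = (AUC - 0.5) / SE`. With perfectly separated groups
#' the component variance is zero; the p-value is then reported as the
#' exact permutation lower bound `1 / choose(m + n, n)` and flagged.
#'
#' @param controls,cases numeric score vectors.
#' @param ci_level confidence level (default 0.95).
#' @param method `"delong"` (default) or `"bootstrap"` (case/control
#'   resampling, for cross-checking).
#' @param n_boot bootstrap replicates when `method = "bootstrap"`.
#' @return Object of class `auc_inference` with `auc`, `se`, `ci_low`,
#'   `ci_high`, `p_one_tailed`, `ci_level`, `degenerate` flag.
#' @export
auc_inference <- function(controls, cases, ci_level = 0.95,
                          method = c("delong", "bootstrap"), n_boot = 2000L) {
  method <- match.arg(method)
  check_groups(controls, cases)
  comp <- delong_components(controls, cases)
  auc <- comp$auc
  se <- if (method == "delong") {
    v10 <- if (length(comp$v10) > 1L) stats::var(comp$v10) else 0
    v01 <- if (length(comp$v01) > 1L) stats::var(comp$v01) else 0
    sqrt(v10 / length(cases) + v01 / length(controls))
  } else {
    reps <- vapply(seq_len(n_boot), function(i) {
      delong_components(sample(controls, replace = TRUE),
                        sample(cases, replace = TRUE))$auc
    }, numeric(1))
    stats::sd(reps)
  }
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  degenerate <- se == 0
  if (degenerate) {
    ci <- c(auc, auc)
    p <- if (auc >= 1 || auc <= 0) {
      1 / choose(length(controls) + length(cases), length(cases))
    } else {
      1
    }
  } else {
    ci <- pmin(pmax(auc + c(-1, 1) * z * se, 0), 1)
    p <- stats::pnorm((auc - 0.5) / se, lower.tail = FALSE)
  }
  structure(list(auc = auc, se = se, ci_low = ci[1], ci_high = ci[2],
                 p_one_tailed = p, ci_level = ci_level,
                 degenerate = degenerate, method = method),
            class = "auc_inference")
}

#' @export
print.auc_inference <- function(x, ...) {
  cat(sprintf("AUC %.3f (SE %.3f, %d%% CI %.3f-%.3f, one-tailed p %.3g%s)\n",
              x$auc, x$se, round(100 * x$ci_level), x$ci_low, x$ci_high,
              x$p_one_tailed,
              if (x$degenerate) ", degenerate SE" else ""))
  invisible(x)
}

operating_grid <- function(controls, cases) {
  thr <- c(sort(unique(c(controls, cases))), Inf)
  data.frame(
    threshold = thr,
    sensitivity = vapply(thr, function(t) mean(cases >= t), numeric(1)),
    specificity = vapply(thr, function(t) mean(controls < t), numeric(1))
  )
}

operating_point <- function(row) {
  structure(list(threshold = row$threshold, sensitivity = row$sensitivity,
                 specificity = row$specificity,
                 youden_j = row$sensitivity + row$specificity - 1),
            class = "operating_point")
}

#' @export
print.operating_point <- function(x, ...) {
  cat(sprintf("threshold %.4g: sensitivity %.3f, specificity %.3f, J = %.3f\n",
              x$threshold, x$sensitivity, x$specificity, x$youden_j))
  invisible(x)
}

#' Sensitivity at a fixed specificity
#'
#' On the empirical ROC, the maximal sensitivity over thresholds whose
#' specificity is at least `target` (e.g. the 99.8% specificity bar of
#' multimodal ovarian-cancer screening). A sensitivity of 0 is a valid
#' answer for a weak marker at a stringent target.
#'
#' @param controls,cases numeric score vectors.
#' @param target required specificity in (0, 1\].
#' @return An `operating_point`.
#' @export
sensitivity_at_specificity <- function(controls, cases, target = 0.998) {
  check_groups(controls, cases)
  grid <- operating_grid(controls, cases)
  ok <- grid[grid$specificity >= target, , drop = FALSE]
  operating_point(ok[which.max(ok$sensitivity), ])
}

#' Specificity at a fixed sensitivity
#'
#' Mirror image of [sensitivity_at_specificity()]: the maximal specificity
#' over thresholds whose sensitivity is at least `target`.
#'
#' @param controls,cases numeric score vectors.
#' @param target required sensitivity in (0, 1\].
#' @return An `operating_point`.
#' @export
specificity_at_sensitivity <- function(controls, cases, target = 0.95) {
  check_groups(controls, cases)
  grid <- operating_grid(controls, cases)
  ok <- grid[grid$sensitivity >= target, , drop = FALSE]
  operating_point(ok[which.max(ok$specificity), ])
}

#' Youden-index optimal operating point
#'
#' Threshold maximizing `J = sensitivity + specificity - 1` over the
#' empirical thresholds; ties resolve to the higher-specificity threshold.
#'
#' @param controls,cases numeric score vectors.
#' @return An `operating_point`.
#' @export
youden <- function(controls, cases) {
  check_groups(controls, cases)
  grid <- operating_grid(controls, cases)
  j <- grid$sensitivity + grid$specificity - 1
  best <- which(j >= max(j) - 1e-12)
  pick <- best[which.max(grid$specificity[best])]
  operating_point(grid[pick, ])
}

#' Single-marker diagnostic report
#'
#' Bundles AUC inference, fixed-specificity and fixed-sensitivity operating
#' points, the Youden point and (optionally) the smooth-ROC shape
#' classification for one marker.
#'
#' @param controls,cases numeric score vectors.
#' @param spec_target specificity bar (default 0.998).
#' @param sens_target sensitivity bar (default 0.95).
#' @param ci_level confidence level for the AUC CI.
#' @param shape also run the smooth-ROC length classification (needs >= 2
#'   scores per group with nonzero variance).
#' @return List with `auc` (an `auc_inference`), `sens_at_spec`,
#'   `spec_at_sens`, `youden` and optionally `shape`.
#' @export
marker_report <- function(controls, cases, spec_target = 0.998,
                          sens_target = 0.95, ci_level = 0.95,
                          shape = FALSE) {
  out <- list(
    auc = auc_inference(controls, cases, ci_level),
    sens_at_spec = sensitivity_at_specificity(controls, cases, spec_target),
    spec_at_sens = specificity_at_sensitivity(controls, cases, sens_target),
    youden = youden(controls, cases)
  )
  if (shape) out$shape <- classify_marker(controls, cases)
  out
}
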