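## Linear calibration of analytical signal vs concentration, with the
## figures of merit used to compare data-treatment methods: sensitivity
## (slope), relative sensitivity error, limit of detection, and 95%
## confidence limits of the fitted mean response.

#' Fit a linear calibration curve
#'
#' Ordinary least squares of signal on concentration at replicate level.
#' Sensitivity is the slope; the relative sensitivity error is
#' `100 * SE(slope) / |slope|`. A method is flagged usable when the slope
#' differs significantly from zero (two-sided t test at `alpha`) — the
#' analogue of the em-dash cells a non-responsive channel earns in a method
#' comparison.
#'
#' @param concentration Numeric vector of concentrations (>= 3 distinct
#'   values required).
#' @param signal Numeric vector of analytical signals, same length.
#' @param alpha Significance level for the slope test (default 0.05).
#' @param lod_factor Multiplier in the detection-limit formula
#'   `LOD = factor * sigma / |slope|` (default 3.3; use 3 for the
#'   3-sigma variant).
#' @param blank_sd Standard deviation of blank signals, used as sigma in the
#'   LOD when at least `min_blank_replicates` blanks back it; otherwise the
#'   residual SD `s_yx` is used.
#' @param n_blank Number of blank replicates behind `blank_sd`.
#' @param min_blank_replicates Minimum blanks for `blank_sd` to be trusted
#'   (default 3).
#' @param method_id,label Optional identifiers carried into the result.
#' @return A `pad_calibration` object: list with `slope`, `slope_se`,
#'   `intercept`, `intercept_se`, `r2`, `s_yx`, `n`, `df`,
#'   `sensitivity_error_pct`, `lod`, `lod_sigma_source`, `slope_p`,
#'   `usable`, `alpha`, plus internals (`xbar`, `sxx`, `data`) needed by
#'   [predict_with_ci()].
#' @examples
#' fit <- fit_calibration(c(0, 1, 2, 3), c(1.1, 2.0, 2.9, 4.2))
#' fit$slope
#' @export
fit_calibration <- function(concentration, signal, alpha = 0.05,
                            lod_factor = 3.3, blank_sd = NULL, n_blank = 0,
                            min_blank_replicates = 3,
                            method_id = NA_integer_, label = NA_character_) {
  keep <- is.finite(concentration) & is.finite(signal)
  x <- as.numeric(concentration[keep]); y <- as.numeric(signal[keep])
  n <- length(x)
  if (n < 3) {
    pad_stop(sprintf("calibration needs at least 3 points; got %d finite ones",
                     n), "padquant_insufficient_data_error")
  }
  if (length(unique(x)) < 3) {
    pad_stop("calibration needs at least 3 distinct concentrations",
             if (length(unique(x)) == 1) "padquant_singular_design_error" else
               "padquant_insufficient_data_error")
  }
  fit <- stats::lm(y ~ x)
  ## noiseless synthetic data legitimately fits perfectly; keep that quiet
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  co <- sm$coefficients
  slope <- co["x", "Estimate"]; slope_se <- co["x", "Std. Error"]
  slope_p <- co["x", "Pr(>|t|)"]
  s_yx <- sm$sigma
  r2 <- sm$r.squared
  usable <- is.finite(slope_p) && slope_p < alpha
  sigma_src <- if (!is.null(blank_sd) && n_blank >= min_blank_replicates &&
                     is.finite(blank_sd)) "blank_sd" else "s_yx"
  sigma_lod <- if (sigma_src == "blank_sd") blank_sd else s_yx
  res <- structure(list(
    method_id = method_id, label = label,
    slope = slope, slope_se = slope_se,
    intercept = co["(Intercept)", "Estimate"],
    intercept_se = co["(Intercept)", "Std. Error"],
    r2 = r2, s_yx = s_yx, n = n, df = n - 2L,
    sensitivity_error_pct = sensitivity_error_pct(slope, slope_se),
    slope_p = slope_p, usable = usable, alpha = alpha,
    lod_factor = lod_factor, lod_sigma = sigma_lod,
    lod_sigma_source = sigma_src,
    xbar = mean(x), sxx = sum((x - mean(x))^2),
    data = data.frame(concentration = x, signal = y)
  ), class = "pad_calibration")
  res$lod <- if (usable && abs(slope) > 0) lod(res) else NA_real_
  res
}

#' Relative sensitivity error in percent
#'
#' `100 * SE(slope) / |slope|` — the "sensitivity error (%)" figure of
#' merit; also usable standalone on printed slope +/- SE pairs.
#'
#' @param slope Calibration slope (sensitivity).
#' @param slope_se Its standard error.
#' @return Percentage (numeric, >= 0); vectorized.
#' @examples
#' sensitivity_error_pct(-0.594, 0.018)   # 3.03
#' @export
sensitivity_error_pct <- function(slope, slope_se) {
  100 * slope_se / abs(slope)
}

#' Limit of detection from a fitted calibration
#'
#' `LOD = factor * sigma / |slope|` with `factor` 3.3 by default. `sigma`
#' is the blank-signal SD when the fit recorded one backed by enough blank
#' replicates, else the residual SD of the calibration.
#'
#' @param fit A `pad_calibration`.
#' @param blank_sd Optional override for sigma.
#' @param factor Optional override for the multiplier.
#' @return Detection limit in concentration units.
#' @export
lod <- function(fit, blank_sd = NULL, factor = NULL) {
  stopifnot(inherits(fit, "pad_calibration"))
  if (!isTRUE(fit$usable) || !is.finite(fit$slope) || fit$slope == 0) {
    pad_stop("LOD undefined: slope is zero or method is not usable",
             "padquant_undefined_lod_error")
  }
  sigma <- if (!is.null(blank_sd)) blank_sd else fit$lod_sigma
  f <- if (!is.null(factor)) factor else fit$lod_factor
  f * sigma / abs(fit$slope)
}

#' Fitted signal with its 95% confidence limit at a concentration
#'
#' Predicts the mean response `yhat = intercept + slope * x0` and the
#' half-width of its confidence limit,
#' `t(1 - (1-level)/2, df) * s_yx * sqrt(1/n + (x0 - xbar)^2 / Sxx)` —
#' the confidence limit of the fitted Y value (mean response), not a
#' prediction interval for a new observation.
#'
#' @param fit A `pad_calibration`.
#' @param x0 Concentration(s) at which to predict.
#' @param level Confidence level (default 0.95).
#' @return Data frame: `concentration`, `value`, `ci_half_width`, `df`.
#' @export
predict_with_ci <- function(fit, x0, level = 0.95) {
  stopifnot(inherits(fit, "pad_calibration"))
  if (fit$df < 1) {
    pad_stop("confidence limit undefined with 0 residual degrees of freedom",
             "padquant_undefined_ci_error")
  }
  x0 <- as.numeric(x0)
  yhat <- fit$intercept + fit$slope * x0
  tq <- stats::qt(1 - (1 - level) / 2, df = fit$df)
  hw <- tq * fit$s_yx * sqrt(1 / fit$n + (x0 - fit$xbar)^2 / fit$sxx)
  data.frame(concentration = x0, value = yhat, ci_half_width = hw,
             df = fit$df)
}

#' @export
print.pad_calibration <- function(x, ...) {
  cat(sprintf("<pad_calibration>%s n = %d points\n",
              if (!is.na(x$label)) sprintf(" method %s (%s),", x$method_id,
                                           x$label) else "", x$n))
  cat(sprintf("  sensitivity (slope): %.6g +/- %.3g  (%.2f%% rel. error)\n",
              x$slope, x$slope_se, x$sensitivity_error_pct))
  cat(sprintf("  intercept: %.6g   R^2 = %.4f   s(y.x) = %.4g\n",
              x$intercept, x$r2, x$s_yx))
  if (is.finite(x$lod %||% NA_real_)) {
    cat(sprintf("  LOD (%.1f*sigma/|slope|, sigma = %s): %.4g\n",
                x$lod_factor, x$lod_sigma_source, x$lod))
  }
  cat(sprintf("  slope p-value: %.3g -> %s\n", x$slope_p,
              if (x$usable) "usable" else "NOT usable (slope ~ 0)"))
  invisible(x)
}

#' Slope confidence interval of a calibration
#'
#' @param fit A `pad_calibration`.
#' @param level Confidence level (default 0.95).
#' @return Numeric length-2 vector (lower, upper).
#' @export
slope_ci <- function(fit, level = 0.95) {
  tq <- stats::qt(1 - (1 - level) / 2, df = fit$df)
  fit$slope + c(-1, 1) * tq * fit$slope_se
}
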