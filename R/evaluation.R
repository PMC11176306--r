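## Method comparison: the delta-signal-ratio discrimination statistic, the
## per-method comparison table, and the ranking that recommends a
## data-treatment method for the assay at hand.

#' A fitted signal with its confidence half-width
#'
#' Light constructor for feeding printed or externally fitted
#' `value +/- ci` pairs into [delta_signal_ratio()].
#'
#' @param value Fitted signal.
#' @param ci_half_width Half-width of its 95% confidence limit.
#' @return One-row data frame with `value` and `ci_half_width`.
#' @export
fitted_signal <- function(value, ci_half_width) {
  stopifnot(is_scalar_number(value), is_scalar_number(ci_half_width),
            ci_half_width >= 0)
  data.frame(value = value, ci_half_width = ci_half_width)
}

#' Delta-signal ratio: discrimination of two nearby concentrations
#'
#' The absolute difference of the fitted signals at two similar
#' concentrations divided by the average of their 95% confidence
#' half-widths. A ratio well above 1 means the two concentrations are
#' distinguishable by that data-treatment method; near or below 1 their
#' confidence bands overlap.
#'
#' @param low,high Fitted signals at the lower and higher concentration:
#'   outputs of [predict_with_ci()] or [fitted_signal()] (anything with
#'   `value` and `ci_half_width`).
#' @return One-row data frame: `s_low`, `u_low`, `s_high`, `u_high`,
#'   `delta_signal`, `ratio`, plus `ratio_2dp` rounded for display. Both
#'   uncertainties zero yields an infinite ratio with a warning.
#' @examples
#' delta_signal_ratio(fitted_signal(50.54, 1.09),
#'                    fitted_signal(54.24, 1.09))$ratio_2dp   # 3.39
#' @export
delta_signal_ratio <- function(low, high) {
  u_low <- as.numeric(low$ci_half_width); u_high <- as.numeric(high$ci_half_width)
  s_low <- as.numeric(low$value); s_high <- as.numeric(high$value)
  stopifnot(u_low >= 0, u_high >= 0)
  delta <- abs(s_high - s_low)
  denom <- (u_low + u_high) / 2
  ratio <- if (denom == 0) {
    if (delta == 0) 0 else {
      warning("both uncertainties are zero: delta-signal ratio is infinite")
      Inf
    }
  } else delta / denom
  data.frame(s_low = s_low, u_low = u_low, s_high = s_high, u_high = u_high,
             delta_signal = delta, ratio = ratio,
             ratio_2dp = round(ratio, 2))
}

#' Build the full method-comparison table
#'
#' For every method column of a signal table: fit the calibration, derive
#' the figures of merit, predict the fitted signals (with 95% confidence
#' half-widths) at the two concentrations of interest, and compute the
#' delta-signal ratio. Methods whose slope is indistinguishable from zero
#' are kept in the table with their discrimination metrics blanked — the
#' table analogue of an em-dash row.
#'
#' @param signals Signal table from [compute_all_signals()].
#' @param pair Numeric length-2: the two similar concentrations
#'   `(c_low, c_high)`, `c_low < c_high`, normally inside the calibrated
#'   range.
#' @param alpha Slope-test significance level (default 0.05).
#' @param lod_factor,blank_sd_from_blanks Passed to the LOD machinery;
#'   when `blank_sd_from_blanks` is `TRUE` (default) the SD of each
#'   method's blank-zone signals is used as sigma whenever >= 3 blanks
#'   exist.
#' @param level Confidence level for the fitted-signal limits (default
#'   0.95).
#' @return Data frame, one row per method: identifiers, calibration merit
#'   figures, fitted signals at the pair, `delta_signal`, `ratio`, `usable`
#'   and an `extrapolated` flag (pair outside the calibrated range).
#' @export
build_comparison <- function(signals, pair, alpha = 0.05, lod_factor = 3.3,
                             blank_sd_from_blanks = TRUE, level = 0.95) {
  stopifnot(length(pair) == 2, pair[1] < pair[2])
  reg <- signal_methods()
  codes <- intersect(reg$code, names(signals))
  if (!length(codes)) {
    pad_stop("signal table has no method columns (m01_R ... m19_logprod)",
             "padquant_schema_error")
  }
  conc <- signals$concentration
  is_blank <- !is.na(conc) & conc == 0
  xr <- range(conc, na.rm = TRUE)
  extrapolated <- pair[1] < xr[1] || pair[2] > xr[2]
  if (extrapolated) {
    warning(sprintf("concentration pair (%g, %g) lies outside the calibrated range [%g, %g]",
                    pair[1], pair[2], xr[1], xr[2]))
  }
  rows <- lapply(codes, function(code) {
    m <- reg[reg$code == code, ]
    y <- signals[[code]]
    base <- data.frame(method_id = m$method_id, label = m$label, code = code,
                       slope = NA_real_, slope_se = NA_real_,
                       sensitivity_error_pct = NA_real_, lod = NA_real_,
                       r2 = NA_real_, s_yx = NA_real_, n = sum(is.finite(y)),
                       slope_p = NA_real_, usable = FALSE,
                       s_low = NA_real_, u_low = NA_real_,
                       s_high = NA_real_, u_high = NA_real_,
                       delta_signal = NA_real_, ratio = NA_real_,
                       extrapolated = extrapolated,
                       stringsAsFactors = FALSE)
    bsd <- if (blank_sd_from_blanks && sum(is_blank & is.finite(y)) >= 1) {
      stats::sd(y[is_blank & is.finite(y)])
    } else NULL
    fit <- tryCatch(
      fit_calibration(conc, y, alpha = alpha, lod_factor = lod_factor,
                      blank_sd = bsd, n_blank = sum(is_blank & is.finite(y)),
                      method_id = m$method_id, label = m$label),
      padquant_error = function(e) NULL)
    if (is.null(fit)) return(base)
    base$slope <- fit$slope; base$slope_se <- fit$slope_se
    base$sensitivity_error_pct <- fit$sensitivity_error_pct
    base$r2 <- fit$r2; base$s_yx <- fit$s_yx; base$n <- fit$n
    base$slope_p <- fit$slope_p; base$usable <- fit$usable
    base$lod <- fit$lod %||% NA_real_
    if (fit$usable) {
      pr <- predict_with_ci(fit, pair, level = level)
      dsr <- delta_signal_ratio(pr[1, ], pr[2, ])
      base$s_low <- dsr$s_low; base$u_low <- dsr$u_low
      base$s_high <- dsr$s_high; base$u_high <- dsr$u_high
      base$delta_signal <- dsr$delta_signal; base$ratio <- dsr$ratio
    }
    base
  })
  out <- do.call(rbind, rows)
  attr(out, "pair") <- pair
  attr(out, "alpha") <- alpha
  out
}

#' Rank the usable methods
#'
#' Default policy: highest delta-signal ratio first (the discrimination of
#' similar concentrations is usually what the assay is for), ties broken by
#' lower detection limit, then lower relative sensitivity error. An
#' alternative weighted-score policy combines normalized ranks of the three
#' merit figures. Unusable methods receive no rank. Ranking is a
#' deterministic total order: any permutation of the input rows yields the
#' same ranked output (final tie-break on method_id).
#'
#' @param comparison Output of [build_comparison()].
#' @param policy `"ratio"` (default) or `"weighted"`.
#' @param weights For `"weighted"`: named numeric weights for `ratio`,
#'   `lod`, `sens_err` (default `c(ratio = 1, lod = 1, sens_err = 1)`);
#'   higher ratio and lower lod/sens_err score better.
#' @return `comparison` with a `rank` column, ordered best-first; unusable
#'   rows follow unranked (`rank = NA`).
#' @export
rank_methods <- function(comparison, policy = c("ratio", "weighted"),
                         weights = c(ratio = 1, lod = 1, sens_err = 1)) {
  policy <- match.arg(policy)
  usable <- comparison[isTRUE_vec(comparison$usable), , drop = FALSE]
  rest <- comparison[!isTRUE_vec(comparison$usable), , drop = FALSE]
  if (nrow(usable) == 0) {
    message("no usable methods: every slope is indistinguishable from zero")
    comparison$rank <- NA_integer_
    return(comparison)
  }
  ord <- if (policy == "ratio") {
    order(-usable$ratio, usable$lod, usable$sensitivity_error_pct,
          usable$method_id)
  } else {
    score <- weights["ratio"] * rank(-usable$ratio, ties.method = "average") +
      weights["lod"] * rank(usable$lod, ties.method = "average") +
      weights["sens_err"] * rank(usable$sensitivity_error_pct,
                                 ties.method = "average")
    order(score, usable$method_id)
  }
  usable <- usable[ord, , drop = FALSE]
  usable$rank <- seq_len(nrow(usable))
  rest$rank <- rep(NA_integer_, nrow(rest))
  out <- rbind(usable, rest)
  rownames(out) <- NULL
  attr(out, "pair") <- attr(comparison, "pair")
  out
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Write the comparison report
#'
#' Emits a full-precision CSV of the comparison table plus a human-readable
#' text report with merit-figure and discrimination sections (values at
#' 2 dp, unusable methods shown as em-dash cells) and a provenance header
#' stamping the analysis choices (log base, LOD formula, confidence-limit
#' type, concentration pair, seed).
#'
#' @param ranked Output of [rank_methods()] (or [build_comparison()]).
#' @param path_prefix Output paths are `<path_prefix>.csv` and
#'   `<path_prefix>.txt`.
#' @param metadata Named list echoed into the provenance header.
#' @return Character vector of the two paths, invisibly.
#' @export
render_report <- function(ranked, path_prefix, metadata = list()) {
  stopifnot(nrow(ranked) >= 1)
  csv_path <- paste0(path_prefix, ".csv")
  txt_path <- paste0(path_prefix, ".txt")
  utils::write.csv(ranked, csv_path, row.names = FALSE)

  dash <- "---"
  f2 <- function(x) ifelse(is.na(x), dash, sprintf("%.2f", x))
  fsig <- function(x) ifelse(is.na(x), dash, sprintf("%.4g", x))
  con <- file(txt_path, "w", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# padquant method comparison")
  w("# generated: deterministic given (inputs, config, seed)")
  meta <- c(list(`confidence limit` = "95% CI of the mean response",
                 `lod formula` = "factor * sigma / |slope|"), metadata)
  for (k in names(meta)) w("# %s: %s", k, paste(meta[[k]], collapse = " "))
  pair <- attr(ranked, "pair")
  if (!is.null(pair)) w("# concentration pair: %g / %g", pair[1], pair[2])
  w("")
  w("## Calibration figures of merit")
  w("%-3s %-18s %12s %12s %10s %10s %8s", "no", "method", "slope",
    "slope_se", "sens_err%", "LOD", "R2")
  for (i in seq_len(nrow(ranked))) {
    r <- ranked[i, ]
    w("%-3d %-18s %12s %12s %10s %10s %8s", r$method_id, r$label,
      fsig(r$slope), fsig(r$slope_se), f2(r$sensitivity_error_pct),
      fsig(r$lod), f2(r$r2))
  }
  w("")
  w("## Discrimination of the concentration pair")
  w("%-3s %-18s %16s %16s %8s %6s", "no", "method", "signal(low)",
    "signal(high)", "ratio", "rank")
  for (i in seq_len(nrow(ranked))) {
    r <- ranked[i, ]
    sl <- if (is.na(r$s_low)) dash else sprintf("%.2f +/- %.2f", r$s_low, r$u_low)
    sh <- if (is.na(r$s_high)) dash else sprintf("%.2f +/- %.2f", r$s_high, r$u_high)
    w("%-3d %-18s %16s %16s %8s %6s", r$method_id, r$label, sl, sh,
      f2(r$ratio), if (is.na(r$rank %||% NA)) dash else sprintf("%d", r$rank))
  }
  invisible(c(csv = csv_path, txt = txt_path))
}
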