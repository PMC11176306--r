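#' Published reference values for the BTB and Zn(II) model assays
#'
#' Two small tables of reference values from a published scanner-read uPAD
#' method comparison of the 19 signal transforms, for a bromothymol-blue
#' dye assay (BTB, mg/L) and a zinc(II)-xylenol orange assay (Zn, mmol/L):
#' \describe{
#'   \item{`"sensitivities"`}{per-method calibration slope, slope SE, the
#'     reported relative sensitivity error (%) and detection limit. Methods
#'     whose channels do not respond for Zn(II) are absent (they were
#'     reported as em-dashes).}
#'   \item{`"fitted_signals"`}{fitted signals +/- 95% confidence half-widths
#'     at two nearby concentrations (60/65 mg/L BTB, 0.30/0.35 mmol/L Zn)
#'     and the reported delta-signal ratio.}
#' }
#' Useful as worked examples for [sensitivity_error_pct()] and
#' [delta_signal_ratio()], and as a replay input for
#' `padquant analyze --from-fitted`.
#'
#' @param which `"sensitivities"` or `"fitted_signals"`.
#' @return Data frame.
#' @examples
#' head(reference_values("fitted_signals"))
#' @export
reference_values <- function(which = c("sensitivities", "fitted_signals")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("reported_", which, ".csv"),
                      package = "padquant", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
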