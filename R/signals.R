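## The panel of RGB analytical-signal transforms. Method numbering 1-19 is
## frozen so reports line up across runs:
##   1-3  single channels R, G, B
##   4    (R+G+B)/3
##   5-7  log10(I0/I) per channel (attenuance-style, blank-referenced)
##   8-10 I0 - I per channel
##   11   sum of the three channel differences
##   12-14 channel-sum ratios (R+G+B)/R, /G, /B
##   15-17 pairwise ratios R/G, G/B, R/B
##   18   Euclidean distance in RGB space from the blank ("RGB distance", ED)
##   19   -gamma * log10((R*G*B)/(R0*G0*B0))

#' Registry of the analytical-signal transforms
#'
#' @return Data frame with one row per method: `method_id` (1-19), `code`
#'   (column name used in signal tables, e.g. `"m18_ED"`), `label`
#'   (human-readable formula), and `requires_blank`.
#' @examples
#' signal_methods()
#' @export
signal_methods <- function() {
  data.frame(
    method_id = 1:19,
    code = c("m01_R", "m02_G", "m03_B", "m04_mean",
             "m05_logR", "m06_logG", "m07_logB",
             "m08_dR", "m09_dG", "m10_dB", "m11_dsum",
             "m12_sumoverR", "m13_sumoverG", "m14_sumoverB",
             "m15_RoverG", "m16_GoverB", "m17_RoverB",
             "m18_ED", "m19_logprod"),
    label = c("R", "G", "B", "(R+G+B)/3",
              "log(R0/R)", "log(G0/G)", "log(B0/B)",
              "R0-R", "G0-G", "B0-B", "dR+dG+dB",
              "(R+G+B)/R", "(R+G+B)/G", "(R+G+B)/B",
              "R/G", "G/B", "R/B",
              "ED", "-log(RGB/R0G0B0)"),
    requires_blank = 1:19 %in% c(5:11, 18, 19),
    stringsAsFactors = FALSE
  )
}

#' Blank (zero-concentration) reference intensities
#'
#' Aggregates the blank zones of a measurement table into per-channel mean
#' intensities I0 and their between-replicate standard deviations.
#'
#' @param zones Zone-measurement data frame, or `NULL` when `R0`,`G0`,`B0`
#'   are given directly.
#' @param blank_concentration Concentration treated as blank (default 0).
#' @param R0,G0,B0 Explicit channel means, bypassing `zones`.
#' @return A `pad_blank` list: `R0`, `G0`, `B0`, `sd_R0`, `sd_G0`, `sd_B0`,
#'   `n_blank`.
#' @export
blank_reference <- function(zones = NULL, blank_concentration = 0,
                            R0 = NULL, G0 = NULL, B0 = NULL) {
  if (!is.null(R0)) {
    stopifnot(is_scalar_number(R0), is_scalar_number(G0), is_scalar_number(B0))
    return(structure(list(R0 = R0, G0 = G0, B0 = B0,
                          sd_R0 = 0, sd_G0 = 0, sd_B0 = 0, n_blank = 1L),
                     class = "pad_blank"))
  }
  b <- zones[!is.na(zones$concentration) &
               zones$concentration == blank_concentration, , drop = FALSE]
  if (nrow(b) < 1) {
    pad_stop(sprintf("no blank zones at concentration %g in the data",
                     blank_concentration), "padquant_config_error")
  }
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  structure(list(
    R0 = mean(b$mean_R), G0 = mean(b$mean_G), B0 = mean(b$mean_B),
    sd_R0 = sd0(b$mean_R), sd_G0 = sd0(b$mean_G), sd_B0 = sd0(b$mean_B),
    n_blank = nrow(b)
  ), class = "pad_blank")
}

#' @export
print.pad_blank <- function(x, ...) {
  cat(sprintf("<pad_blank> I0 = (%.2f, %.2f, %.2f), n = %d replicates\n",
              x$R0, x$G0, x$B0, x$n_blank))
  invisible(x)
}

#' Compute one analytical signal for one zone
#'
#' Applies transform `method_id` (see [signal_methods()]) to a zone's mean
#' channel intensities, referenced to the blank where the method requires
#' one. Log and ratio methods guard their domains: a zero denominator or a
#' non-positive log argument raises a classed error rather than returning a
#' silently clamped value (set `clamp = TRUE` to clamp intensities to a
#' floor of 1 instead).
#'
#' @param method_id Integer 1-19.
#' @param zone One-row data frame or list with `mean_R`, `mean_G`, `mean_B`.
#' @param blank A [blank_reference()] object; required for methods
#'   5-11, 18, 19.
#' @param log_base Base of the logarithm in methods 5-7 and 19 (default 10).
#' @param gamma Correction factor for method 19 (default 1).
#' @param clamp If `TRUE`, channel intensities below 1 are clamped to 1 for
#'   log/ratio methods instead of erroring. Off by default: clamping biases
#'   calibrations silently.
#' @return The analytical-signal value (numeric scalar).
#' @examples
#' z <- list(mean_R = 100, mean_G = 150, mean_B = 200)
#' compute_signal(4, z)                         # (100+150+200)/3 = 150
#' b <- blank_reference(R0 = 200, G0 = 200, B0 = 200)
#' compute_signal(18, z, b)                     # Euclidean distance to blank
#' @export
compute_signal <- function(method_id, zone, blank = NULL, log_base = 10,
                           gamma = 1, clamp = FALSE) {
  stopifnot(length(method_id) == 1, method_id %in% 1:19)
  R <- as.numeric(zone$mean_R); G <- as.numeric(zone$mean_G)
  B <- as.numeric(zone$mean_B)
  if (!all(is.finite(c(R, G, B)))) {
    pad_stop("zone has non-finite channel means", "padquant_domain_error")
  }
  reg <- signal_methods()
  if (reg$requires_blank[method_id] && is.null(blank)) {
    pad_stop(sprintf("method %d (%s) requires a blank reference",
                     method_id, reg$label[method_id]),
             "padquant_config_error")
  }
  if (!is.null(blank)) {
    R0 <- blank$R0; G0 <- blank$G0; B0 <- blank$B0
  }
  lg <- function(x) log(x, base = log_base)
  guard_den <- function(x, name) {
    if (x == 0) pad_stop(sprintf("channel %s is 0: ratio method %d undefined",
                                 name, method_id), "padquant_division_error")
    x
  }
  guard_log <- function(x, name) {
    if (clamp) return(max(x, 1))
    if (x <= 0) pad_stop(
      sprintf("channel %s is %g (<= 0): log method %d undefined", name, x,
              method_id), "padquant_domain_error")
    x
  }
  switch(as.character(method_id),
    "1" = R, "2" = G, "3" = B,
    "4" = (R + G + B) / 3,
    "5" = lg(guard_log(R0, "R0") / guard_log(R, "R")),
    "6" = lg(guard_log(G0, "G0") / guard_log(G, "G")),
    "7" = lg(guard_log(B0, "B0") / guard_log(B, "B")),
    "8" = R0 - R,
    "9" = G0 - G,
    "10" = B0 - B,
    "11" = (R0 - R) + (G0 - G) + (B0 - B),
    "12" = (R + G + B) / guard_den(R, "R"),
    "13" = (R + G + B) / guard_den(G, "G"),
    "14" = (R + G + B) / guard_den(B, "B"),
    "15" = R / guard_den(G, "G"),
    "16" = G / guard_den(B, "B"),
    "17" = R / guard_den(B, "B"),
    "18" = sqrt((R0 - R)^2 + (G0 - G)^2 + (B0 - B)^2),
    "19" = -gamma * lg((guard_log(R, "R") * guard_log(G, "G") *
                          guard_log(B, "B")) /
                         (guard_log(R0, "R0") * guard_log(G0, "G0") *
                            guard_log(B0, "B0")))
  )
}

#' Compute the full zone-by-method signal table
#'
#' Applies every requested transform to every zone. A zone/method
#' combination whose guard trips (e.g. a zero denominator) is recorded as
#' `NA` with the reason collected in the `"failures"` attribute; it never
#' aborts the table.
#'
#' @param zones Zone-measurement data frame.
#' @param blank A [blank_reference()]; computed from the zero-concentration
#'   zones when `NULL` and any requested method needs one.
#' @param methods Integer vector of method ids (default all 19).
#' @param hsv If `TRUE`, append `hue_deg`, `sat_pct`, `val_pct` columns.
#' @inheritParams compute_signal
#' @return Data frame: `zone_id`, `concentration`, `replicate`, then one
#'   column per method named by its registry `code`. Attribute `"failures"`
#'   is a data frame of (zone_id, code, reason) for any `NA` cells.
#' @export
compute_all_signals <- function(zones, blank = NULL, methods = 1:19,
                                log_base = 10, gamma = 1, clamp = FALSE,
                                hsv = FALSE) {
  stopifnot(is.data.frame(zones), nrow(zones) >= 1)
  reg <- signal_methods()
  if (is.null(blank) && any(reg$requires_blank[methods])) {
    blank <- blank_reference(zones)
  }
  out <- zones[, c("zone_id", "concentration", "replicate"), drop = FALSE]
  failures <- list()
  for (m in methods) {
    code <- reg$code[m]
    vals <- vapply(seq_len(nrow(zones)), function(i) {
      tryCatch(
        compute_signal(m, zones[i, , drop = FALSE], blank,
                       log_base = log_base, gamma = gamma, clamp = clamp),
        padquant_error = function(e) {
          failures[[length(failures) + 1L]] <<-
            data.frame(zone_id = zones$zone_id[i], code = code,
                       reason = conditionMessage(e),
                       stringsAsFactors = FALSE)
          NA_real_
        })
    }, numeric(1))
    out[[code]] <- vals
  }
  if (hsv) {
    hsv_df <- rgb_to_hsv_zone(zones)
    out$hue_deg <- hsv_df$H; out$sat_pct <- hsv_df$S; out$val_pct <- hsv_df$V
  }
  attr(out, "failures") <- if (length(failures)) do.call(rbind, failures) else
    empty_failures()
  out
}

empty_failures <- function() {
  data.frame(zone_id = character(), code = character(), reason = character(),
             stringsAsFactors = FALSE)
}

#' Euclidean RGB distance pooled over several zone/blank pairs
#'
#' The RGB-distance signal extends naturally over indexed zones: the square
#' root of the sum of squared per-channel differences across all pairs. With
#' a single pair this is exactly method 18.
#'
#' @param zones Zone-measurement data frame (one row per zone).
#' @param blanks A single [blank_reference()] recycled to every zone, or a
#'   list of them paired positionally with `zones` rows.
#' @return Pooled distance (numeric scalar, non-negative).
#' @export
multi_zone_ed <- function(zones, blanks) {
  stopifnot(is.data.frame(zones), nrow(zones) >= 1)
  if (inherits(blanks, "pad_blank")) {
    blanks <- rep(list(blanks), nrow(zones))
  }
  if (length(blanks) != nrow(zones)) {
    pad_stop(sprintf("%d zones but %d blanks: pairs must match",
                     nrow(zones), length(blanks)), "padquant_pairing_error")
  }
  total <- 0
  for (i in seq_len(nrow(zones))) {
    b <- blanks[[i]]
    total <- total + (b$R0 - zones$mean_R[i])^2 +
      (b$G0 - zones$mean_G[i])^2 + (b$B0 - zones$mean_B[i])^2
  }
  sqrt(total)
}

#' Convert zone RGB means to HSV
#'
#' Standard hexcone conversion. Hue in degrees `[0, 360)` (0 when the zone
#' is achromatic), saturation and value in percent.
#'
#' @param zones Zone-measurement data frame, or a list with `mean_R`,
#'   `mean_G`, `mean_B`.
#' @return Data frame with columns `H`, `S`, `V`, one row per zone.
#' @export
rgb_to_hsv_zone <- function(zones) {
  R <- as.numeric(zones$mean_R); G <- as.numeric(zones$mean_G)
  B <- as.numeric(zones$mean_B)
  stopifnot(all(R >= 0 & R <= 255), all(G >= 0 & G <= 255),
            all(B >= 0 & B <= 255))
  hsv <- grDevices::rgb2hsv(rbind(R, G, B), maxColorValue = 255)
  data.frame(H = hsv["h", ] * 360, S = hsv["s", ] * 100, V = hsv["v", ] * 100,
             row.names = NULL)
}

#' Invert HSV back to RGB channel means (0-255)
#'
#' @param H Hue in degrees, `S`, `V` in percent.
#' @param S,V See `H`.
#' @return Data frame with `mean_R`, `mean_G`, `mean_B`.
#' @export
hsv_to_rgb_zone <- function(H, S, V) {
  h6 <- (H %% 360) / 60; s <- S / 100; v <- V / 100
  c_ <- v * s
  x_ <- c_ * (1 - abs(h6 %% 2 - 1))
  m_ <- v - c_
  sector <- floor(h6) %% 6
  r1 <- ifelse(sector == 0 | sector == 5, c_,
               ifelse(sector == 1 | sector == 4, x_, 0))
  g1 <- ifelse(sector == 1 | sector == 2, c_,
               ifelse(sector == 0 | sector == 3, x_, 0))
  b1 <- ifelse(sector == 3 | sector == 4, c_,
               ifelse(sector == 2 | sector == 5, x_, 0))
  data.frame(mean_R = (r1 + m_) * 255, mean_G = (g1 + m_) * 255,
             mean_B = (b1 + m_) * 255)
}

#' Write a signal table to CSV
#'
#' @param signals Output of [compute_all_signals()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_signal_table <- function(signals, path) {
  utils::write.csv(signals, path, row.names = FALSE)
  invisible(path)
}
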