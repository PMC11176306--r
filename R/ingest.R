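## Image ingestion: decode scans to a 3-channel 0-255 raster, average circular
## regions of interest, and read tabular RGB exports.

#' Load a scanned image as a 3-channel raster on the 0-255 scale
#'
#' Decodes a TIFF, PNG or JPEG file into a `pad_raster`: a
#' `height x width x 3` numeric array of channel intensities on the 8-bit
#' 0-255 scale, regardless of the source bit depth. 16-bit sources are
#' rescaled by 255/65535, greyscale images are replicated into three
#' identical channels, and an alpha channel (if present) is discarded.
#'
#' @param path Path to the image file.
#' @param format One of `"auto"` (default: decided by file extension),
#'   `"tiff"`, `"png"`, `"jpeg"`.
#' @return A `pad_raster`: numeric array `[row, col, channel]` with values in
#'   `[0, 255]`, with attributes `source_path` and `bit_depth_original`.
#' @examples
#' r <- render_scan(scan_layout(1, 3), concentrations = c(0, 50, 100),
#'                  replicates = 1, seed = 1)$raster
#' tf <- tempfile(fileext = ".tiff")
#' write_image(r, tf)
#' img <- load_image(tf)
#' dim(img)
#' @export
load_image <- function(path, format = c("auto", "tiff", "png", "jpeg")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    pad_stop(sprintf("cannot read image file '%s': no such file", path),
             "padquant_io_error")
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      tif = , tiff = "tiff",
      png = "png",
      jpg = , jpeg = "jpeg",
      pad_stop(sprintf("cannot infer image format from extension '%s' of '%s'",
                       ext, path), "padquant_format_error")
    )
  }
  bits <- 8L
  img <- switch(format,
    tiff = {
      x <- tryCatch(tiff::readTIFF(path, info = TRUE),
                    error = function(e) pad_stop(
                      sprintf("cannot decode '%s' as TIFF: %s", path,
                              conditionMessage(e)), "padquant_io_error"))
      b <- attr(x, "bits.per.sample")
      if (!is.null(b)) bits <- as.integer(b[1])
      x
    },
    png = {
      x <- tryCatch(png::readPNG(path),
                    error = function(e) pad_stop(
                      sprintf("cannot decode '%s' as PNG: %s", path,
                              conditionMessage(e)), "padquant_io_error"))
      bits <- png_bit_depth(path)
      x
    },
    jpeg = tryCatch(jpeg::readJPEG(path),
                    error = function(e) pad_stop(
                      sprintf("cannot decode '%s' as JPEG: %s", path,
                              conditionMessage(e)), "padquant_io_error"))
  )
  ## readTIFF/readPNG/readJPEG normalize to [0,1] by dividing by the source
  ## maximum (255 or 65535), so multiplying by 255 implements the 255/65535
  ## rescale for 16-bit input and the identity for 8-bit input.
  arr <- normalize_channels(img, path, format)
  structure(arr * 255,
            class = "pad_raster",
            source_path = path,
            bit_depth_original = bits)
}

## PNG bit depth lives at byte 25 of the file (IHDR); png::readPNG does not
## expose it.
png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", n = 26)
  if (length(hdr) >= 25) as.integer(hdr[25]) else 8L
}

normalize_channels <- function(img, path, format) {
  if (is.matrix(img)) {                      # greyscale -> replicate
    return(array(img, dim = c(dim(img), 3L)))
  }
  nc <- dim(img)[3]
  if (nc == 2L) {                            # grey + alpha
    return(array(img[, , 1], dim = c(dim(img)[1:2], 3L)))
  }
  if (nc == 3L) return(img)
  if (nc == 4L) {
    if (format == "jpeg") {
      pad_stop(sprintf("'%s' uses a 4-component (CMYK) colour model, not RGB",
                       path), "padquant_format_error")
    }
    return(img[, , 1:3, drop = FALSE])       # RGBA -> drop alpha
  }
  pad_stop(sprintf("'%s' has %d channels; expected greyscale or RGB(A)",
                   path, nc), "padquant_format_error")
}

#' Write a raster to disk (TIFF or PNG)
#'
#' Lossless output used by the synthetic-scan generator and round-trip tests.
#'
#' @param raster A `pad_raster` or plain `h x w x 3` array on the 0-255 scale.
#' @param path Output path; format from extension unless given.
#' @param format `"auto"`, `"tiff"` or `"png"`.
#' @return `path`, invisibly.
#' @export
write_image <- function(raster, path, format = c("auto", "tiff", "png")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     tif = , tiff = "tiff", png = "png",
                     pad_stop(sprintf("cannot infer output format for '%s'",
                                      path), "padquant_format_error"))
  }
  arr <- unclass(raster) / 255
  arr[arr < 0] <- 0
  arr[arr > 1] <- 1
  if (format == "tiff") tiff::writeTIFF(arr, path) else png::writePNG(arr, path)
  invisible(path)
}

#' @export
dim.pad_raster <- function(x) dim(unclass(x))

#' @export
print.pad_raster <- function(x, ...) {
  d <- dim(unclass(x))
  cat(sprintf("<pad_raster> %d x %d px, 3 channels (0-255), %d-bit source\n",
              d[2], d[1], attr(x, "bit_depth_original") %||% 8L))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean channel intensities over a circular detection zone
#'
#' Averages R, G and B over every pixel whose center lies within `radius`
#' (inclusive) of the zone center, the region of interest being the whole
#' circle inside the hydrophobic barrier. Coordinates are 0-based with
#' `x` = column, `y` = row, origin at the top-left pixel center.
#'
#' @param raster A `pad_raster` (or `h x w x 3` array, 0-255).
#' @param zone A list or one-row data frame with `zone_id`, `center_x`,
#'   `center_y`, `radius`, and optionally `concentration`, `replicate`.
#' @return One-row data frame: `zone_id`, `concentration`, `replicate`,
#'   `mean_R`, `mean_G`, `mean_B`, `n_pixels`.
#' @seealso [extract_zones()] for a whole layout.
#' @export
extract_zone_mean <- function(raster, zone) {
  arr <- unclass(raster)
  h <- dim(arr)[1]; w <- dim(arr)[2]
  cx <- as.numeric(zone$center_x); cy <- as.numeric(zone$center_y)
  r <- as.numeric(zone$radius)
  if (!is_scalar_number(r) || r <= 0) {
    pad_stop("zone radius must be a positive number", "padquant_zone_error")
  }
  if (cx - r < -0.5 || cx + r > w - 0.5 || cy - r < -0.5 || cy + r > h - 0.5) {
    pad_stop(sprintf("zone '%s' (center %.1f,%.1f r=%.1f) extends outside the %d x %d raster",
                     zone$zone_id %||% "?", cx, cy, r, w, h),
             "padquant_zone_error")
  }
  dx2 <- ((0:(w - 1)) - cx)^2
  dy2 <- ((0:(h - 1)) - cy)^2
  mask <- outer(dy2, dx2, `+`) <= r^2
  n <- sum(mask)
  if (n < 1L) {
    pad_stop(sprintf("zone '%s' selects zero pixels (radius %.2f px too small)",
                     zone$zone_id %||% "?", r), "padquant_zone_error")
  }
  data.frame(
    zone_id = as.character(zone$zone_id %||% NA_character_),
    concentration = as.numeric(zone$concentration %||% NA_real_),
    replicate = as.integer(zone$replicate %||% NA_integer_),
    mean_R = sum(arr[, , 1][mask]) / n,
    mean_G = sum(arr[, , 2][mask]) / n,
    mean_B = sum(arr[, , 3][mask]) / n,
    n_pixels = n,
    stringsAsFactors = FALSE
  )
}

#' Extract all zones of a layout from a raster
#'
#' @param raster A `pad_raster`.
#' @param layout Data frame with one row per zone (columns as in
#'   [extract_zone_mean()]); zone ids must be unique.
#' @return Data frame of zone measurements, one row per layout row, in
#'   layout order.
#' @export
extract_zones <- function(raster, layout) {
  stopifnot(is.data.frame(layout), nrow(layout) >= 1)
  if (anyDuplicated(layout$zone_id)) {
    pad_stop("zone_id values must be unique within a layout",
             "padquant_zone_error")
  }
  out <- lapply(seq_len(nrow(layout)),
                function(i) extract_zone_mean(raster, layout[i, , drop = FALSE]))
  do.call(rbind, out)
}

#' Detect a grid of circular detection zones from their dark barrier rings
#'
#' Thresholds the image (Otsu on the channel mean), labels dark connected
#' components, takes each sufficiently large component as one wax barrier
#' ring, and estimates the zone center (ring centroid) and interior radius
#' (minimum centroid-to-ring-pixel distance). Rings are returned row-major
#' (top-left first). Radii are shrunk by `margin_frac` so the returned zones
#' stay clear of the barrier.
#'
#' @param raster A `pad_raster`.
#' @param rows,cols Expected grid shape.
#' @param margin_frac Fraction by which to shrink each interior radius
#'   (default 0.1).
#' @param min_area Components smaller than this many pixels are ignored as
#'   speckle (default 50).
#' @return Data frame of zone specs: `zone_id` (`"z<row>_<col>"`),
#'   `center_x`, `center_y`, `radius` (0-based pixel coordinates).
#' @export
detect_zone_grid <- function(raster, rows, cols, margin_frac = 0.1,
                             min_area = 50) {
  arr <- unclass(raster)
  lum <- (arr[, , 1] + arr[, , 2] + arr[, , 3]) / 3
  rng <- range(lum)
  if (diff(rng) < 1) {
    pad_stop(sprintf("zone detection found 0 rings (expected %d): image has no dark features",
                     rows * cols), "padquant_detection_error", n_found = 0L)
  }
  thr <- EBImage::otsu(EBImage::Image(lum / 255), range = c(0, 1)) * 255
  mask <- lum < thr
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  labm <- EBImage::imageData(lab)
  ids <- sort(unique(as.vector(labm)))
  ids <- ids[ids > 0]
  comps <- list()
  for (id in ids) {
    idx <- which(labm == id, arr.ind = TRUE)
    if (nrow(idx) < min_area) next
    ## EBImage stores images [x, y]; our lum was [row, col] so the Image was
    ## transposed relative to screen axes: idx[,1] indexes rows, idx[,2] cols.
    y <- idx[, 1] - 1; x <- idx[, 2] - 1
    cx <- mean(x); cy <- mean(y)
    r_in <- sqrt(min((x - cx)^2 + (y - cy)^2))
    comps[[length(comps) + 1L]] <- c(cx = cx, cy = cy, r = r_in)
  }
  n_found <- length(comps)
  if (n_found != rows * cols) {
    pad_stop(sprintf("zone detection found %d rings where %d (%d x %d) were expected",
                     n_found, rows * cols, rows, cols),
             "padquant_detection_error", n_found = n_found)
  }
  m <- do.call(rbind, comps)
  ## row-major order: sort by y, chop into `rows` bands of `cols`, sort each by x
  m <- m[order(m[, "cy"]), , drop = FALSE]
  out <- vector("list", rows)
  for (i in seq_len(rows)) {
    band <- m[((i - 1) * cols + 1):(i * cols), , drop = FALSE]
    out[[i]] <- band[order(band[, "cx"]), , drop = FALSE]
  }
  m <- do.call(rbind, out)
  data.frame(
    zone_id = sprintf("z%d_%d", rep(seq_len(rows), each = cols),
                      rep(seq_len(cols), rows)),
    center_x = m[, "cx"],
    center_y = m[, "cy"],
    radius = m[, "r"] * (1 - margin_frac),
    stringsAsFactors = FALSE
  )
}

#' Read a tabular RGB export
#'
#' Two dialects are supported. `"native"`: a CSV with columns `zone_id`,
#' `concentration`, `replicate`, `R`, `G`, `B` (one row per zone).
#' `"imagej"`: an ImageJ Results-style export with `Label` and `Mean`
#' columns, three rows per zone; channel rows are matched by a
#' "(red)"/"(green)"/"(blue)" suffix in the label, or taken as consecutive
#' R, G, B triples when no suffix is present (channel-split stack order).
#'
#' @param path CSV file path.
#' @param dialect `"native"` or `"imagej"`.
#' @param layout Optional layout data frame with `zone_id`, `concentration`,
#'   `replicate`, joined onto ImageJ rows (which carry neither).
#' @return Data frame of zone measurements (`zone_id`, `concentration`,
#'   `replicate`, `mean_R`, `mean_G`, `mean_B`, `n_pixels`), preserving file
#'   row order. `n_pixels` is `NA` when the export does not report it.
#' @export
read_rgb_table <- function(path, dialect = c("native", "imagej"),
                           layout = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    pad_stop(sprintf("cannot read RGB table '%s': no such file", path),
             "padquant_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (dialect == "native") read_rgb_native(df, path) else
    read_rgb_imagej(df, path, layout)
}

read_rgb_native <- function(df, path) {
  need <- c("zone_id", "concentration", "replicate", "R", "G", "B")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    pad_stop(sprintf("RGB table '%s' is missing column(s): %s",
                     path, paste(missing, collapse = ", ")),
             "padquant_schema_error")
  }
  if (nrow(df) == 0) return(empty_measurements())
  for (col in c("concentration", "R", "G", "B")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "")
    if (length(bad)) {
      pad_stop(sprintf("non-numeric value '%s' in column '%s' of '%s' (data row %d)",
                       df[[col]][bad[1]], col, path, bad[1]),
               "padquant_parse_error")
    }
    df[[col]] <- v
  }
  data.frame(
    zone_id = as.character(df$zone_id),
    concentration = df$concentration,
    replicate = as.integer(df$replicate),
    mean_R = df$R, mean_G = df$G, mean_B = df$B,
    n_pixels = if ("n_pixels" %in% names(df)) as.integer(df$n_pixels) else
      NA_integer_,
    stringsAsFactors = FALSE
  )
}

read_rgb_imagej <- function(df, path, layout) {
  if (!"Mean" %in% names(df)) {
    pad_stop(sprintf("ImageJ table '%s' is missing the 'Mean' column", path),
             "padquant_schema_error")
  }
  if (nrow(df) == 0) return(empty_measurements())
  mean_v <- suppressWarnings(as.numeric(df$Mean))
  if (anyNA(mean_v)) {
    pad_stop(sprintf("non-numeric 'Mean' value in '%s' (data row %d)",
                     path, which(is.na(mean_v))[1]), "padquant_parse_error")
  }
  label <- as.character(df$Label %||% rep("", nrow(df)))
  chan <- rep(NA_character_, nrow(df))
  chan[grepl("\\(red\\)", label, ignore.case = TRUE)] <- "R"
  chan[grepl("\\(green\\)", label, ignore.case = TRUE)] <- "G"
  chan[grepl("\\(blue\\)", label, ignore.case = TRUE)] <- "B"
  if (all(is.na(chan))) {
    ## channel-split stack: consecutive triples in R, G, B order
    if (nrow(df) %% 3 != 0) {
      pad_stop(sprintf("ImageJ table '%s' has %d rows; expected a multiple of 3 (R, G, B per zone)",
                       path, nrow(df)), "padquant_schema_error")
    }
    zone <- rep(seq_len(nrow(df) / 3), each = 3)
    chan <- rep(c("R", "G", "B"), nrow(df) / 3)
    zid <- sub("\\s*\\((red|green|blue)\\)\\s*$", "",
               label[seq(1, nrow(df), by = 3)])
    zid <- ifelse(zid == "", sprintf("zone%d", unique(zone)), zid)
  } else {
    if (anyNA(chan)) {
      pad_stop(sprintf("ImageJ table '%s': row %d label '%s' has no (red)/(green)/(blue) suffix",
                       path, which(is.na(chan))[1], label[which(is.na(chan))[1]]),
               "padquant_schema_error")
    }
    zid_all <- trimws(sub("\\((red|green|blue)\\)\\s*$", "", label,
                          ignore.case = TRUE))
    zone <- match(zid_all, unique(zid_all))
    zid <- unique(zid_all)
  }
  out <- data.frame(zone_id = zid,
                    concentration = NA_real_, replicate = NA_integer_,
                    mean_R = NA_real_, mean_G = NA_real_, mean_B = NA_real_,
                    n_pixels = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_along(mean_v)) {
    out[[paste0("mean_", chan[i])]][zone[i]] <- mean_v[i]
  }
  if (!is.null(layout)) {
    j <- match(out$zone_id, layout$zone_id)
    out$concentration <- as.numeric(layout$concentration[j])
    out$replicate <- as.integer(layout$replicate[j])
  }
  out
}

empty_measurements <- function() {
  data.frame(zone_id = character(), concentration = numeric(),
             replicate = integer(), mean_R = numeric(), mean_G = numeric(),
             mean_B = numeric(), n_pixels = integer(),
             stringsAsFactors = FALSE)
}

#' Read a zone layout CSV
#'
#' Columns: `zone_id`, `center_x`, `center_y`, `radius`, and optionally
#' `concentration`, `replicate`.
#'
#' @param path CSV path.
#' @return Layout data frame.
#' @export
read_zone_layout <- function(path) {
  if (!file.exists(path)) {
    pad_stop(sprintf("cannot read layout '%s': no such file", path),
             "padquant_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("zone_id", "center_x", "center_y", "radius")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    pad_stop(sprintf("layout '%s' is missing column(s): %s", path,
                     paste(missing, collapse = ", ")),
             "padquant_schema_error")
  }
  df
}
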