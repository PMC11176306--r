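## Synthetic uPAD scans and RGB tables with known ground truth. The default
## response model reproduces the bromothymol-blue assay: near-white blank
## paper and per-channel darkening that is linear in dye concentration, with
## Gaussian between-replicate and within-zone (pixel) noise. Every random
## draw flows through an explicit seed.

#' Linear per-channel colour response model
#'
#' Zone mean intensity per channel is
#' `clip(blank + slope * concentration + N(0, replicate_sd), 0, 255)`;
#' rendered pixels add `N(0, pixel_sd)` within the zone. Defaults emulate a
#' bromothymol-blue dye assay: blank RGB (222, 229, 230) and sensitivities
#' (-0.594, -0.386, -0.212) intensity units per mg/L.
#'
#' @param blank_rgb Length-3 numeric, blank channel means (0-255).
#' @param channel_slopes Length-3 numeric, intensity change per
#'   concentration unit (typically negative: colour darkens).
#' @param replicate_sd Between-replicate SD of the zone mean, intensity
#'   units (default 1).
#' @param pixel_sd Within-zone per-pixel SD (default 2).
#' @return A `pad_response_model` list.
#' @export
response_model <- function(blank_rgb = c(222, 229, 230),
                           channel_slopes = c(-0.594, -0.386, -0.212),
                           replicate_sd = 1, pixel_sd = 2) {
  stopifnot(length(blank_rgb) == 3, all(blank_rgb >= 0 & blank_rgb <= 255),
            length(channel_slopes) == 3, replicate_sd >= 0, pixel_sd >= 0)
  structure(list(blank_rgb = as.numeric(blank_rgb),
                 channel_slopes = as.numeric(channel_slopes),
                 replicate_sd = replicate_sd, pixel_sd = pixel_sd),
            class = "pad_response_model")
}

#' Scan geometry for a grid of circular detection zones
#'
#' Default geometry scales the physical device (10 mm zone diameter, 1 mm
#' wax barrier) to 30 px interior radius and 3 px border.
#'
#' @param rows,cols Grid shape.
#' @param circle_radius_px Interior (inside-barrier) radius in pixels.
#' @param border_width_px Barrier ring width in pixels (>= 1).
#' @param spacing_px Gap between neighbouring barrier outer edges and the
#'   canvas margin.
#' @param background_rgb,border_rgb Canvas and barrier colours.
#' @return A `pad_scan_layout` list.
#' @export
scan_layout <- function(rows, cols, circle_radius_px = 30,
                        border_width_px = 3, spacing_px = 12,
                        background_rgb = c(245, 244, 240),
                        border_rgb = c(25, 22, 20)) {
  stopifnot(rows >= 1, cols >= 1, circle_radius_px > 0, border_width_px >= 1,
            spacing_px >= 0)
  structure(list(rows = rows, cols = cols,
                 circle_radius_px = circle_radius_px,
                 border_width_px = border_width_px, spacing_px = spacing_px,
                 background_rgb = as.numeric(background_rgb),
                 border_rgb = as.numeric(border_rgb)),
            class = "pad_scan_layout")
}

#' Generate a tabular RGB dataset with known ground truth
#'
#' @param model A [response_model()].
#' @param concentrations Numeric vector of standard concentrations; must
#'   include 0 (the blank).
#' @param replicates Zones per concentration (default 3, as on the physical
#'   device).
#' @param seed Integer seed; the dataset is a pure function of
#'   `(model, concentrations, replicates, seed)`.
#' @return List: `zones` (measurement data frame with `zone_id`,
#'   `concentration`, `replicate`, `mean_R/G/B`, `n_pixels = NA`) and
#'   `manifest` (true slopes, blanks, noise SDs, seed, clipped-zone count).
#'   A warning is raised when more than 20% of zone/channel means hit the
#'   0 or 255 clip bound.
#' @export
generate_rgb_dataset <- function(model, concentrations, replicates = 3,
                                 seed = 1) {
  stopifnot(inherits(model, "pad_response_model"), replicates >= 1)
  if (!0 %in% concentrations) {
    pad_stop("concentrations must include 0 (the blank)",
             "padquant_config_error")
  }
  grid <- expand.grid(replicate = seq_len(replicates),
                      concentration = sort(concentrations))
  grid <- grid[, c("concentration", "replicate")]
  nz <- nrow(grid)
  means <- withr::with_seed(seed, {
    vapply(1:3, function(ch) {
      model$blank_rgb[ch] + model$channel_slopes[ch] * grid$concentration +
        stats::rnorm(nz, 0, model$replicate_sd)
    }, numeric(nz))
  })
  means <- matrix(means, nrow = nz, ncol = 3)
  clipped <- sum(means < 0 | means > 255)
  means <- pmin(pmax(means, 0), 255)
  if (clipped / length(means) > 0.2) {
    warning(sprintf("saturation: %d of %d zone-channel means hit the [0, 255] bound",
                    clipped, length(means)))
  }
  zones <- data.frame(
    zone_id = sprintf("c%g_r%d", grid$concentration, grid$replicate),
    concentration = grid$concentration,
    replicate = grid$replicate,
    mean_R = means[, 1], mean_G = means[, 2], mean_B = means[, 3],
    n_pixels = NA_integer_, stringsAsFactors = FALSE
  )
  list(zones = zones,
       manifest = list(seed = seed, blank_rgb = model$blank_rgb,
                       channel_slopes = model$channel_slopes,
                       replicate_sd = model$replicate_sd,
                       pixel_sd = model$pixel_sd,
                       concentrations = sort(concentrations),
                       replicates = replicates, n_zones = nz,
                       n_clipped = clipped))
}

#' Render a synthetic scan of a zone grid
#'
#' Draws a light canvas with dark barrier rings; zone interiors are filled
#' with per-pixel draws from `N(zone mean, pixel_sd)` clipped to `[0, 255]`.
#' Zones are assigned row-major: each concentration occupies `replicates`
#' consecutive positions. The returned layout is ground truth (interior
#' circles, 0-based pixel coordinates).
#'
#' @param layout A [scan_layout()]; capacity `rows * cols` must cover
#'   `length(concentrations) * replicates`.
#' @param model A [response_model()].
#' @inheritParams generate_rgb_dataset
#' @return List: `raster` (`pad_raster`), `layout` (ground-truth zone specs
#'   with concentration and replicate), `zones` (true zone means drawn,
#'   i.e. after replicate noise but before pixel noise), `manifest`.
#' @export
render_scan <- function(layout, model = response_model(),
                        concentrations = c(0, 20, 40, 60, 80, 100),
                        replicates = 3, seed = 1) {
  stopifnot(inherits(layout, "pad_scan_layout"))
  nz <- length(concentrations) * replicates
  if (nz > layout$rows * layout$cols) {
    pad_stop(sprintf("layout capacity %d x %d = %d is below the %d zones requested",
                     layout$rows, layout$cols, layout$rows * layout$cols, nz),
             "padquant_layout_error")
  }
  ds <- generate_rgb_dataset(model, concentrations, replicates, seed = seed)
  zones <- ds$zones
  r_in <- layout$circle_radius_px
  bw <- layout$border_width_px
  sp <- layout$spacing_px
  pitch <- 2 * (r_in + bw) + sp
  w <- layout$cols * pitch + sp
  h <- layout$rows * pitch + sp
  arr <- array(rep(layout$background_rgb, each = h * w), dim = c(h, w, 3))
  specs <- zones[, c("zone_id", "concentration", "replicate")]
  specs$center_x <- NA_real_; specs$center_y <- NA_real_
  specs$radius <- r_in
  xs <- (0:(w - 1)); ys <- (0:(h - 1))
  withr::with_seed(seed + 1L, {
    for (k in seq_len(nz)) {
      i <- (k - 1) %/% layout$cols + 1
      j <- (k - 1) %% layout$cols + 1
      cx <- sp + (r_in + bw) + (j - 1) * pitch
      cy <- sp + (r_in + bw) + (i - 1) * pitch
      specs$center_x[k] <- cx; specs$center_y[k] <- cy
      d2 <- outer((ys - cy)^2, (xs - cx)^2, `+`)
      ring <- d2 > r_in^2 & d2 <= (r_in + bw)^2
      inside <- d2 <= r_in^2
      npx <- sum(inside)
      for (ch in 1:3) {
        plane <- arr[, , ch]
        plane[ring] <- layout$border_rgb[ch]
        px <- zones[[c("mean_R", "mean_G", "mean_B")[ch]]][k] +
          stats::rnorm(npx, 0, model$pixel_sd)
        plane[inside] <- pmin(pmax(px, 0), 255)
        arr[, , ch] <- plane
      }
    }
  })
  raster <- structure(arr, class = "pad_raster", source_path = NA_character_,
                      bit_depth_original = 8L)
  manifest <- ds$manifest
  manifest$layout <- list(rows = layout$rows, cols = layout$cols,
                          circle_radius_px = r_in, border_width_px = bw,
                          spacing_px = sp, width_px = w, height_px = h)
  list(raster = raster, layout = specs, zones = zones, manifest = manifest)
}

#' Write a ground-truth manifest as key-value text
#'
#' @param manifest Manifest list from [generate_rgb_dataset()] or
#'   [render_scan()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  flat <- unlist(manifest)
  writeLines(sprintf("%s = %s", names(flat),
                     vapply(flat, format, character(1), digits = 15)), path)
  invisible(path)
}
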