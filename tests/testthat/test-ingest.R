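test_that("load_image round-trips constant images losslessly for TIFF and PNG", {
  arr <- uniform_raster(10, 10, c(12, 34, 56))
  for (fmt in c("tiff", "png")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_image(arr, path)
    img <- load_image(path)
    expect_equal(dim(img), c(10, 10, 3))
    expect_true(all(unclass(img)[, , 1] == 12))
    expect_true(all(unclass(img)[, , 2] == 34))
    expect_true(all(unclass(img)[, , 3] == 56))
    expect_identical(attr(img, "bit_depth_original"), 8L)
  }
})

test_that("16-bit sources are rescaled to 255 and greyscale is replicated", {
  path16 <- withr::local_tempfile(fileext = ".tiff")
  tiff::writeTIFF(array(1, dim = c(4, 4, 3)), path16, bits.per.sample = 16L)
  img16 <- load_image(path16)
  expect_true(all(unclass(img16) == 255))
  expect_identical(attr(img16, "bit_depth_original"), 16L)

  pathg <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(100 / 255, 6, 5), pathg)
  imgg <- load_image(pathg)
  expect_equal(dim(imgg), c(6, 5, 3))
  expect_true(all(unclass(imgg) == 100))
})

test_that("load_image errors name the path for missing or malformed files", {
  expect_error(load_image("/nonexistent/scan.tiff"),
               "/nonexistent/scan.tiff", class = "padquant_io_error")
  bad <- withr::local_tempfile(fileext = ".png")
  writeLines("not a png", bad)
  expect_error(load_image(bad), class = "padquant_io_error")
})

test_that("extract_zone_mean handles uniform and symmetric fields", {
  r <- uniform_raster(40, 40, c(100, 150, 200))
  z <- extract_zone_mean(r, list(zone_id = "z", center_x = 20, center_y = 20,
                                 radius = 10))
  expect_equal(c(z$mean_R, z$mean_G, z$mean_B), c(100, 150, 200))

  # black left half, white right half, circle centered between the columns
  arr <- array(0, dim = c(20, 20, 3))
  arr[, 11:20, ] <- 255
  half <- structure(arr, class = "pad_raster")
  z2 <- extract_zone_mean(half, list(zone_id = "h", center_x = 9.5,
                                     center_y = 9.5, radius = 8))
  expect_equal(c(z2$mean_R, z2$mean_G, z2$mean_B), rep(127.5, 3))
})

test_that("zone means equal the brute-force pixel enumeration oracle", {
  withr::local_seed(421)
  for (i in 1:3) {
    r <- random_raster(64, 64)
    cx <- runif(1, 15, 48); cy <- runif(1, 15, 48); rad <- runif(1, 5, 12)
    got <- extract_zone_mean(r, list(zone_id = "z", center_x = cx,
                                     center_y = cy, radius = rad))
    want <- brute_force_zone_mean(unclass(r), cx, cy, rad)
    expect_identical(got$n_pixels, want$n)
    expect_equal(c(got$mean_R, got$mean_G, got$mean_B), want$mean,
                 tolerance = 1e-9)
  }
})

test_that("zone means are invariant under joint integer translation", {
  withr::local_seed(99)
  base <- array(runif(40 * 40 * 3, 0, 255), dim = c(40, 40, 3))
  big <- array(0, dim = c(100, 100, 3))
  big[1:40, 1:40, ] <- base
  big[61:100, 41:80, ] <- base        # same patch shifted by (+60 rows, +40 cols)
  z1 <- extract_zone_mean(structure(big, class = "pad_raster"),
                          list(zone_id = "a", center_x = 20, center_y = 20,
                               radius = 9))
  z2 <- extract_zone_mean(structure(big, class = "pad_raster"),
                          list(zone_id = "b", center_x = 60, center_y = 80,
                               radius = 9))
  expect_equal(c(z1$mean_R, z1$mean_G, z1$mean_B),
               c(z2$mean_R, z2$mean_G, z2$mean_B), tolerance = 1e-12)
})

test_that("degenerate and out-of-bounds zones raise zone errors", {
  r <- uniform_raster(30, 30, c(10, 10, 10))
  # center between pixel centers: radius 0.2 catches no pixel center
  expect_error(extract_zone_mean(r, list(zone_id = "z", center_x = 15.5,
                                         center_y = 15.5, radius = 0.2)),
               class = "padquant_zone_error")
  expect_error(extract_zone_mean(r, list(zone_id = "z", center_x = 2,
                                         center_y = 15, radius = 10)),
               class = "padquant_zone_error")
})

test_that("detect_zone_grid recovers a rendered grid and honours margin_frac", {
  sim <- render_scan(scan_layout(2, 3), concentrations = c(0, 25, 50),
                     replicates = 2, seed = 11)
  det <- detect_zone_grid(sim$raster, 2, 3, margin_frac = 0)
  expect_equal(nrow(det), 6)
  expect_true(all(abs(det$center_x - sim$layout$center_x) <= 2))
  expect_true(all(abs(det$center_y - sim$layout$center_y) <= 2))
  expect_true(all(abs(det$radius - sim$layout$radius) /
                    sim$layout$radius <= 0.05))

  det2 <- detect_zone_grid(sim$raster, 2, 3, margin_frac = 0.2)
  expect_equal(det2$center_x, det$center_x)
  expect_equal(det2$radius, det$radius * 0.8, tolerance = 1e-12)

  blank <- uniform_raster(50, 50, c(255, 255, 255))
  err <- tryCatch(detect_zone_grid(blank, 1, 1),
                  padquant_detection_error = function(e) e)
  expect_s3_class(err, "padquant_detection_error")
  expect_equal(err$n_found, 0L)
})

test_that("read_rgb_table parses the native dialect and flags bad schemas", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("zone_id,concentration,replicate,R,G,B",
               "z1,60,1,186.07,206.16,216.87"), path)
  z <- read_rgb_table(path)
  expect_equal(z$mean_R, 186.07)
  expect_equal(z$mean_G, 206.16)
  expect_equal(z$mean_B, 216.87)
  expect_equal(z$concentration, 60)

  writeLines("zone_id,concentration,replicate,R,G,B", path)
  expect_equal(nrow(read_rgb_table(path)), 0)

  writeLines(c("zone_id,concentration,replicate,G,B", "z1,60,1,2,3"), path)
  expect_error(read_rgb_table(path), "R", class = "padquant_schema_error")

  writeLines(c("zone_id,concentration,replicate,R,G,B",
               "z1,60,1,oops,206.16,216.87"), path)
  expect_error(read_rgb_table(path), "row 1", class = "padquant_parse_error")
})

test_that("read_rgb_table handles ImageJ channel-suffix and stack dialects", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(" ,Label,Mean",
               "1,z1 (red),186.07", "2,z1 (green),206.16",
               "3,z1 (blue),216.87",
               "4,z2 (red),150.00", "5,z2 (green),160.00",
               "6,z2 (blue),170.00"), path)
  layout <- data.frame(zone_id = c("z1", "z2"), concentration = c(60, 65),
                       replicate = c(1L, 1L))
  z <- read_rgb_table(path, dialect = "imagej", layout = layout)
  expect_equal(z$zone_id, c("z1", "z2"))
  expect_equal(z$mean_R, c(186.07, 150))
  expect_equal(z$mean_B, c(216.87, 170))
  expect_equal(z$concentration, c(60, 65))

  # no suffixes: consecutive R, G, B triples (channel-split stack order)
  writeLines(c(" ,Label,Mean",
               "1,,186.07", "2,,206.16", "3,,216.87"), path)
  z2 <- read_rgb_table(path, dialect = "imagej")
  expect_equal(c(z2$mean_R, z2$mean_G, z2$mean_B),
               c(186.07, 206.16, 216.87))
})
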