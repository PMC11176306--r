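blank200 <- blank_reference(R0 = 200, G0 = 200, B0 = 200)

test_that("compute_signal matches closed forms for representative methods", {
  z <- list(mean_R = 100, mean_G = 150, mean_B = 200)
  expect_equal(compute_signal(4, z), 150)
  expect_equal(compute_signal(12, list(mean_R = 90, mean_G = 120,
                                       mean_B = 90)), 300 / 90)
  expect_equal(compute_signal(6, list(mean_R = 1, mean_G = 100, mean_B = 1),
                              blank200), log10(2), tolerance = 1e-12)
  z0 <- list(mean_R = 200, mean_G = 200, mean_B = 200)
  expect_equal(compute_signal(18, z0, blank200), 0)
  expect_equal(compute_signal(19, list(mean_R = 100, mean_G = 100,
                                       mean_B = 100), blank200, gamma = 1),
               log10(8), tolerance = 1e-12)
})

test_that("log base and gamma are configurable", {
  z <- list(mean_R = 100, mean_G = 100, mean_B = 100)
  expect_equal(compute_signal(5, z, blank200, log_base = exp(1)), log(2),
               tolerance = 1e-12)
  expect_equal(compute_signal(19, z, blank200, gamma = 2.5),
               2.5 * log10(8), tolerance = 1e-12)
})

test_that("guards: missing blank, zero denominators, non-positive logs", {
  z <- list(mean_R = 100, mean_G = 100, mean_B = 0)
  expect_error(compute_signal(18, z), class = "padquant_config_error")
  expect_error(compute_signal(16, z), class = "padquant_division_error")
  expect_error(compute_signal(7, z, blank200),
               class = "padquant_domain_error")
  # clamp-to-1 turns the domain error into a defined value
  expect_equal(compute_signal(7, z, blank200, clamp = TRUE), log10(200),
               tolerance = 1e-12)
})

test_that("algebraic identities hold across random zone/blank pairs", {
  withr::local_seed(7)
  for (i in 1:200) {
    p <- random_zone_pair()
    v <- vapply(1:19, compute_signal, numeric(1), zone = p$zone,
                blank = p$blank)
    expect_equal(v[4], mean(v[1:3]))                        # A
    expect_equal(v[11], v[8] + v[9] + v[10])                # B
    expect_equal(v[19], v[5] + v[6] + v[7], tolerance = 1e-12)  # C
    expect_equal(v[18]^2, v[8]^2 + v[9]^2 + v[10]^2,
                 tolerance = 1e-9)                          # D
    expect_gte(v[18], 0)
  }
})

test_that("Euclidean distance is zero exactly when zone equals blank", {
  b <- blank_reference(R0 = 120, G0 = 130, B0 = 140)
  expect_equal(compute_signal(18, list(mean_R = 120, mean_G = 130,
                                       mean_B = 140), b), 0)
  expect_gt(compute_signal(18, list(mean_R = 120.01, mean_G = 130,
                                    mean_B = 140), b), 0)
})

test_that("compute_all_signals builds a complete table consistent with single calls", {
  withr::local_seed(31)
  zones <- do.call(rbind, lapply(1:3, function(i) {
    p <- random_zone_pair()
    data.frame(zone_id = paste0("z", i), concentration = i * 10,
               replicate = 1L, mean_R = p$zone$mean_R,
               mean_G = p$zone$mean_G, mean_B = p$zone$mean_B,
               n_pixels = 100L)
  }))
  b <- blank_reference(R0 = 220, G0 = 225, B0 = 230)
  tab <- compute_all_signals(zones, b)
  codes <- signal_methods()$code
  expect_true(all(codes %in% names(tab)))
  expect_equal(sum(is.finite(as.matrix(tab[codes]))), 57)
  for (m in c(1, 5, 11, 18, 19)) {
    for (i in 1:3) {
      expect_equal(tab[[codes[m]]][i],
                   compute_signal(m, zones[i, ], b), tolerance = 1e-14)
    }
  }
})

test_that("a zero channel yields NA for its ratio methods, not a crash", {
  zones <- data.frame(zone_id = c("ok", "b0"), concentration = c(0, 10),
                      replicate = 1L, mean_R = c(100, 100),
                      mean_G = c(110, 110), mean_B = c(120, 0),
                      n_pixels = 10L)
  b <- blank_reference(R0 = 100, G0 = 110, B0 = 120)
  tab <- compute_all_signals(zones, b)
  expect_true(is.na(tab$m14_sumoverB[2]))
  expect_true(is.na(tab$m16_GoverB[2]))
  expect_true(is.na(tab$m07_logB[2]))     # log of 0 also guarded
  expect_true(is.finite(tab$m12_sumoverR[2]))
  expect_true(is.finite(tab$m18_ED[2]))
  fails <- attr(tab, "failures")
  expect_true(all(fails$zone_id == "b0"))
  expect_true("m16_GoverB" %in% fails$code)
})

test_that("multi_zone_ed pools pairs and reduces to method 18 for one pair", {
  z1 <- data.frame(zone_id = "a", concentration = 1, replicate = 1L,
                   mean_R = 10, mean_G = 20, mean_B = 30, n_pixels = 1L)
  b1 <- blank_reference(R0 = 13, G0 = 24, B0 = 30)
  expect_equal(multi_zone_ed(z1, b1), 5)                     # 3-4-5
  expect_equal(multi_zone_ed(z1, b1), compute_signal(18, z1, b1))
  z2 <- rbind(z1, z1)
  expect_equal(multi_zone_ed(z2, b1), sqrt(50), tolerance = 1e-12)
  expect_equal(multi_zone_ed(z1, blank_reference(R0 = 10, G0 = 20, B0 = 30)),
               0)
  expect_error(multi_zone_ed(z2, list(b1)),
               class = "padquant_pairing_error")
})

test_that("rgb_to_hsv_zone matches endpoints and the textbook oracle", {
  red <- rgb_to_hsv_zone(list(mean_R = 255, mean_G = 0, mean_B = 0))
  expect_equal(unlist(red), c(H = 0, S = 100, V = 100))
  grey <- rgb_to_hsv_zone(list(mean_R = 128, mean_G = 128, mean_B = 128))
  expect_equal(grey$S, 0)
  expect_equal(grey$H, 0)             # hue defined as 0 on the grey axis
  expect_equal(grey$V, 100 * 128 / 255, tolerance = 1e-9)

  withr::local_seed(55)
  for (i in 1:50) {
    rgb <- runif(3, 0, 255)
    got <- rgb_to_hsv_zone(list(mean_R = rgb[1], mean_G = rgb[2],
                                mean_B = rgb[3]))
    want <- hsv_textbook(rgb[1], rgb[2], rgb[3])
    expect_equal(c(got$H, got$S, got$V), unname(want), tolerance = 1e-6)
  }
})

test_that("HSV then inverse conversion recovers RGB within half an intensity unit", {
  withr::local_seed(56)
  for (i in 1:50) {
    rgb <- runif(3, 0, 255)
    hsv <- rgb_to_hsv_zone(list(mean_R = rgb[1], mean_G = rgb[2],
                                mean_B = rgb[3]))
    back <- hsv_to_rgb_zone(hsv$H, hsv$S, hsv$V)
    expect_equal(unlist(back), c(mean_R = rgb[1], mean_G = rgb[2],
                                 mean_B = rgb[3]), tolerance = 0.5)
  }
})
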