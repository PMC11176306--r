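# Independent oracles, deliberately written by routes different from the
# package implementation, plus small fixture builders.

# ROI mean by explicit per-pixel loop (0-based coords, center-in-circle rule)
brute_force_zone_mean <- function(arr, cx, cy, r) {
  h <- dim(arr)[1]; w <- dim(arr)[2]
  tot <- c(0, 0, 0); n <- 0L
  for (i in 0:(h - 1)) {
    for (j in 0:(w - 1)) {
      if ((j - cx)^2 + (i - cy)^2 <= r^2) {
        n <- n + 1L
        for (ch in 1:3) tot[ch] <- tot[ch] + arr[i + 1, j + 1, ch]
      }
    }
  }
  list(mean = tot / n, n = n)
}

# OLS by the normal equations (solve, not QR as lm uses)
ols_normal_equations <- function(x, y) {
  X <- cbind(1, x)
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  resid <- y - X %*% beta
  s2 <- sum(resid^2) / (length(y) - 2)
  covb <- s2 * solve(XtX)
  list(intercept = beta[1], slope = beta[2],
       intercept_se = sqrt(covb[1, 1]), slope_se = sqrt(covb[2, 2]),
       s_yx = sqrt(s2),
       r2 = 1 - sum(resid^2) / sum((y - mean(y))^2))
}

# Mean-response CI half-width by the hat-matrix leverage form
ci_leverage_form <- function(x, y, x0, level = 0.95) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  resid <- y - X %*% beta
  s <- sqrt(sum(resid^2) / (length(y) - 2))
  x0v <- c(1, x0)
  lev <- drop(t(x0v) %*% solve(t(X) %*% X) %*% x0v)
  qt(1 - (1 - level) / 2, length(y) - 2) * s * sqrt(lev)
}

# Textbook hexcone RGB(0-255) -> HSV (deg, pct, pct)
hsv_textbook <- function(R, G, B) {
  r <- R / 255; g <- G / 255; b <- B / 255
  mx <- max(r, g, b); mn <- min(r, g, b); d <- mx - mn
  H <- if (d == 0) 0
  else if (mx == r) 60 * (((g - b) / d) %% 6)
  else if (mx == g) 60 * (((b - r) / d) + 2)
  else 60 * (((r - g) / d) + 4)
  S <- if (mx == 0) 0 else d / mx * 100
  c(H = H, S = S, V = mx * 100)
}

# Random zone/blank pair away from the channel floor so every transform is
# defined
random_zone_pair <- function() {
  z <- list(mean_R = runif(1, 20, 250), mean_G = runif(1, 20, 250),
            mean_B = runif(1, 20, 250))
  b <- blank_reference(R0 = runif(1, 20, 250), G0 = runif(1, 20, 250),
                       B0 = runif(1, 20, 250))
  list(zone = z, blank = b)
}

# Uniform-colour raster builder
uniform_raster <- function(h, w, rgb) {
  structure(array(rep(rgb, each = h * w), dim = c(h, w, 3)),
            class = "pad_raster", source_path = NA_character_,
            bit_depth_original = 8L)
}

random_raster <- function(h, w) {
  structure(array(runif(h * w * 3, 0, 255), dim = c(h, w, 3)),
            class = "pad_raster", source_path = NA_character_,
            bit_depth_original = 8L)
}
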