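# Color space conversions and whole-image difference metrics.

test_that("sRGB decoding hits the D65 white and black, and round-trips 8-bit grays", {
  expect_equal(unname(srgb_to_xyz(c(255, 255, 255))), c(95.047, 100, 108.883),
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(unname(srgb_to_xyz(c(0, 0, 0))), c(0, 0, 0),
               ignore_attr = TRUE)
  grays <- matrix(rep(0:255, 3), ncol = 3)
  expect_identical(round(xyz_to_srgb(srgb_to_xyz(grays))), grays * 1.0)
})

test_that("sRGB -> XYZ/Lab agrees with an independent converter (farver)", {
  skip_if_not_installed("farver")
  set.seed(11)
  rgb <- matrix(sample(0:255, 60, replace = TRUE), ncol = 3)
  rgb <- rbind(rgb, c(128, 64, 200))
  expect_equal(srgb_to_xyz(rgb) / 100,
               farver::convert_colour(rgb, "rgb", "xyz") / 100,
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(srgb_to_lab(rgb), farver::convert_colour(rgb, "rgb", "lab"),
               tolerance = 2e-2, ignore_attr = TRUE)
})

test_that("CIELAB transfer: whitepoint maps to (100, 0, 0), origin to 0, mid gray to formula", {
  wp <- matrix(c(95.047, 100, 108.883), 1)
  expect_equal(unname(drop(xyz_to_lab(wp, whitepoint = drop(wp)))), c(100, 0, 0),
               tolerance = 1e-9)
  expect_equal(unname(xyz_to_lab(c(0, 0, 0), whitepoint = drop(wp))), c(0, 0, 0))
  # L* of a neutral Y = 18.4 surface, from the cube-root branch evaluated here
  L_expect <- 116 * (18.4 / 100)^(1 / 3) - 16
  got <- xyz_to_lab(drop(wp) * 0.184, whitepoint = drop(wp))
  expect_equal(unname(got[1]), L_expect, tolerance = 1e-9)
  expect_error(xyz_to_lab(wp, whitepoint = c(-1, 0, 0)),
               class = "relcol_config_error")
})

test_that("CIECAM02 reproduces the published worked example and maps white near the origin", {
  cond <- cam02_conditions(whitepoint = c(95.05, 100, 108.88), L_A = 318.31,
                           Y_b = 20, surround = "average")
  u <- xyz_to_cam02ucs(matrix(c(19.01, 20, 21.78), 1), cond)
  Jp <- u[1]
  J <- Jp / (1.7 - 0.007 * Jp)
  Mp <- sqrt(u[2]^2 + u[3]^2)
  M <- (exp(0.0228 * Mp) - 1) / 0.0228
  h <- atan2(u[3], u[2]) %% (2 * pi) * 180 / pi
  expect_equal(J, 41.73, tolerance = 1e-3)
  expect_equal(M, 0.1088, tolerance = 1e-2)
  expect_equal(h, 219.05, tolerance = 1e-3)
  w <- xyz_to_cam02ucs(matrix(c(95.05, 100, 108.88), 1), cond)
  expect_equal(w[1], 100, tolerance = 1e-6)
  expect_lt(max(abs(w[2:3])), 0.5)
  expect_error(cam02_conditions(L_A = -5), class = "relcol_config_error")
})

test_that("Delta-E summaries are non-negative, symmetric, and zero iff identical", {
  scene <- exact_recovery_scene(seed = 3, h = 12, w = 12)
  a <- scene$image
  b <- a; b[, , 1] <- pmin(b[, , 1] + 14, 255)
  expect_equal(mean_delta_e_ucs(a, a)$mean_delta_e, 0)
  expect_equal(mean_delta_e_scielab(a, a)$mean_delta_e, 0)
  d_ab <- mean_delta_e_ucs(a, b)$mean_delta_e
  expect_gt(d_ab, 0)
  expect_equal(d_ab, mean_delta_e_ucs(b, a)$mean_delta_e)
  s_ab <- mean_delta_e_scielab(a, b)$mean_delta_e
  expect_gt(s_ab, 0)
  expect_equal(s_ab, mean_delta_e_scielab(b, a)$mean_delta_e)
  expect_error(mean_delta_e_ucs(a, a[1:6, , , drop = FALSE]),
               class = "relcol_dimension_error")
  expect_error(mean_delta_e_scielab(a, b, samples_per_degree = 0),
               class = "relcol_config_error")
})

test_that("constant-image UCS difference equals the single-pair distance", {
  mk <- function(rgb) array(rep(rgb, each = 64), c(8, 8, 3))
  a <- mk(c(100, 150, 30)); b <- mk(c(120, 140, 60))
  pair <- sqrt(sum((srgb_to_cam02ucs(c(100, 150, 30)) -
                    srgb_to_cam02ucs(c(120, 140, 60)))^2))
  expect_equal(mean_delta_e_ucs(a, b)$mean_delta_e, pair, tolerance = 1e-9)
})

test_that("S-CIELAB of uniform image pairs equals plain CIELAB Delta-E", {
  mk <- function(rgb) array(rep(rgb, each = 100), c(10, 10, 3))
  a <- mk(c(100, 150, 30)); b <- mk(c(120, 140, 60))
  plain <- sqrt(sum((srgb_to_lab(c(100, 150, 30)) -
                     srgb_to_lab(c(120, 140, 60)))^2))
  expect_equal(mean_delta_e_scielab(a, b)$mean_delta_e, plain,
               tolerance = 1e-6)
})

test_that("the separable spatial filter matches a direct 2-D convolution", {
  # independent path: brute-force 2-D convolution with reflective padding
  direct_conv <- function(mat, k) {
    half <- (length(k) - 1) / 2
    n <- nrow(mat); m <- ncol(mat)
    ref <- function(i, n) { i <- ifelse(i < 1, 1 - i, i); ifelse(i > n, 2 * n + 1 - i, i) }
    out <- matrix(0, n, m)
    for (i in seq_len(n)) for (j in seq_len(m)) {
      acc <- 0
      for (di in -half:half) for (dj in -half:half) {
        acc <- acc + k[di + half + 1] * k[dj + half + 1] *
          mat[ref(i + di, n), ref(j + dj, m)]
      }
      out[i, j] <- acc
    }
    out
  }
  set.seed(5)
  mat <- matrix(runif(12 * 10), 12, 10)
  k <- relcol:::gauss_kernel_1d(1.8, 12)
  expect_equal(relcol:::conv_sep_reflect(mat, k), direct_conv(mat, k),
               tolerance = 1e-10)
})

test_that("mean Delta-E is non-increasing in n for nested palettes", {
  scene <- exact_recovery_scene(seed = 9, h = 24, w = 24)
  img <- scene$image
  pal4 <- separated_palette()
  palettes <- list(                      # each palette contains the previous
    pal4[1, , drop = FALSE],
    pal4[c(1, 3), , drop = FALSE],
    pal4)
  de <- vapply(palettes, function(p) {
    labels <- relcol:::nearest_label(relcol:::pixel_matrix(img), p)
    q <- relcol:::new_quantization(p, labels, dim(img)[1:2], nrow(p), "manual")
    c(mean_delta_e_ucs(img, apply_palette(img, q))$mean_delta_e,
      mean_delta_e_scielab(img, apply_palette(img, q))$mean_delta_e)
  }, numeric(2))
  expect_true(all(diff(de[1, ]) <= 1e-9))
  expect_true(all(diff(de[2, ]) <= 1e-9))
})
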