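# Color space conversions: sRGB <-> CIE XYZ <-> CIELAB, the CIECAM02 forward
# model with the CAM02-UCS coordinates, and whole-image color-difference
# summaries (mean Euclidean Delta-E in CAM02-UCS, and the spatially filtered
# S-CIELAB measure).  All conversions run in double precision on matrices of
# triplets; image arrays are reshaped transparently.

# D65 whitepoint, 2-degree observer, Y normalized to 100.
D65_WHITE <- c(X = 95.047, Y = 100, Z = 108.883)

# IEC 61966-2-1 sRGB primaries -> XYZ (D65), scaled so white Y = 100.
SRGB_TO_XYZ_M <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE) * 100

XYZ_TO_SRGB_M <- solve(SRGB_TO_XYZ_M)

# Accepts h x w x 3 array or N x 3 matrix; returns list(values = N x 3 matrix,
# restore = function putting a result matrix back into the input's shape).
as_triplets <- function(x, arg = "image") {
  if (is.array(x) && length(dim(x)) == 3L) {
    assert_rgb_image(x, arg)
    d <- dim(x)
    list(values = matrix(x, ncol = 3L),
         restore = function(m) array(m, dim = d))
  } else if (is.matrix(x) && ncol(x) == 3L) {
    list(values = x, restore = identity)
  } else if (is.numeric(x) && length(x) == 3L) {
    list(values = matrix(x, 1L, 3L), restore = function(m) drop(m))
  } else {
    abort(sprintf("`%s` must be an RGB array, an N x 3 matrix or a triplet.", arg),
          class = "relcol_dimension_error")
  }
}

#' Convert 8-bit sRGB to CIE 1931 XYZ
#'
#' Standard sRGB decoding: gamma expansion followed by the 3x3 primary
#' matrix, D65 whitepoint, 2-degree observer, Y scaled so that reference
#' white has Y = 100.
#'
#' @param image RGB array (`h x w x 3`), `N x 3` matrix, or length-3 triplet,
#'   with channel values in `[0, 255]`.
#' @return XYZ values in the same shape as the input, with
#'   `attr(, "whitepoint")` set to the D65 white.
#' @export
srgb_to_xyz <- function(image) {
  t3 <- as_triplets(image)
  v <- t3$values / 255
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  out <- t3$restore(lin %*% t(SRGB_TO_XYZ_M))
  attr(out, "whitepoint") <- D65_WHITE
  out
}

#' Convert CIE XYZ back to 8-bit-scale sRGB
#'
#' Inverse of [srgb_to_xyz()]; output on the 0--255 scale, clamped to gamut
#' but not rounded (8-bit quantization happens only at file output).
#'
#' @param xyz XYZ values (array, matrix or triplet), white Y = 100.
#' @return sRGB values in `[0, 255]`, same shape as input.
#' @export
xyz_to_srgb <- function(xyz) {
  t3 <- as_triplets(xyz, "xyz")
  lin <- t3$values %*% t(XYZ_TO_SRGB_M)
  lin <- clamp(lin, 0, 1)
  v <- ifelse(lin <= 0.0031308, 12.92 * lin, 1.055 * lin^(1 / 2.4) - 0.055)
  t3$restore(v * 255)
}

#' Convert CIE XYZ to CIELAB
#'
#' CIE 1976 L*a*b* with the standard cube-root / linear-segment transfer,
#' relative to the supplied whitepoint.
#'
#' @param xyz XYZ values (array, matrix or triplet).
#' @param whitepoint XYZ of the adopted white (Y = 100); defaults to the
#'   whitepoint attribute of `xyz`, else D65.
#' @return (L*, a*, b*) values, same shape as input.
#' @export
xyz_to_lab <- function(xyz, whitepoint = NULL) {
  whitepoint <- whitepoint %||% attr(xyz, "whitepoint") %||% D65_WHITE
  if (length(whitepoint) != 3L || any(whitepoint <= 0)) {
    abort("`whitepoint` must be a positive XYZ triplet.",
          class = "relcol_config_error")
  }
  t3 <- as_triplets(xyz, "xyz")
  r <- sweep(t3$values, 2L, whitepoint, "/")
  eps <- (6 / 29)^3
  f <- ifelse(r > eps, r^(1 / 3), r / (3 * (6 / 29)^2) + 4 / 29)
  lab <- cbind(116 * f[, 2] - 16,
               500 * (f[, 1] - f[, 2]),
               200 * (f[, 2] - f[, 3]))
  t3$restore(lab)
}

#' Convert CIELAB to CIE XYZ
#'
#' @param lab (L*, a*, b*) values (array, matrix or triplet).
#' @param whitepoint XYZ of the adopted white (Y = 100).
#' @return XYZ values, same shape as input.
#' @export
lab_to_xyz <- function(lab, whitepoint = D65_WHITE) {
  t3 <- as_triplets(lab, "lab")
  v <- t3$values
  fy <- (v[, 1] + 16) / 116
  fx <- fy + v[, 2] / 500
  fz <- fy - v[, 3] / 200
  finv <- function(f) ifelse(f > 6 / 29, f^3, 3 * (6 / 29)^2 * (f - 4 / 29))
  xyz <- cbind(finv(fx) * whitepoint[1],
               finv(fy) * whitepoint[2],
               finv(fz) * whitepoint[3])
  out <- t3$restore(xyz)
  attr(out, "whitepoint") <- whitepoint
  out
}

#' sRGB to CIELAB in one step
#' @inheritParams srgb_to_xyz
#' @return (L*, a*, b*) values, same shape as input (D65 white).
#' @export
srgb_to_lab <- function(image) xyz_to_lab(srgb_to_xyz(image), D65_WHITE)

#' CIELAB to sRGB in one step
#' @inheritParams lab_to_xyz
#' @return sRGB values in `[0, 255]`.
#' @export
lab_to_srgb <- function(lab, whitepoint = D65_WHITE) {
  xyz_to_srgb(lab_to_xyz(lab, whitepoint))
}

#' CIECAM02 viewing conditions
#'
#' The appearance model needs the adopted white, the adapting luminance
#' `L_A` (cd/m^2), the relative background luminance factor `Y_b` (percent of
#' white), and a surround category.  Defaults: D65 white (the 6500 K
#' illuminant), `L_A` = 64 cd/m^2, `Y_b` = 20, "average" surround.
#'
#' @param whitepoint XYZ of the adopted white, Y = 100.
#' @param L_A Adapting field luminance in cd/m^2 (> 0).
#' @param Y_b Background relative luminance (0--100).
#' @param surround One of "average", "dim", "dark".
#' @return A list of viewing-condition parameters with derived constants.
#' @export
cam02_conditions <- function(whitepoint = D65_WHITE, L_A = 64, Y_b = 20,
                             surround = c("average", "dim", "dark")) {
  surround <- match.arg(surround)
  if (!is.numeric(L_A) || length(L_A) != 1L || !is.finite(L_A) || L_A <= 0) {
    abort("`L_A` must be a positive adapting luminance in cd/m^2.",
          class = "relcol_config_error")
  }
  if (Y_b <= 0 || Y_b > 100) {
    abort("`Y_b` must lie in (0, 100].", class = "relcol_config_error")
  }
  sp <- switch(surround,
    average = list(F = 1.0, c = 0.69, N_c = 1.0),
    dim     = list(F = 0.9, c = 0.59, N_c = 0.9),
    dark    = list(F = 0.8, c = 0.525, N_c = 0.8))
  k <- 1 / (5 * L_A + 1)
  F_L <- 0.2 * k^4 * (5 * L_A) + 0.1 * (1 - k^4)^2 * (5 * L_A)^(1 / 3)
  n <- Y_b / whitepoint[2]
  structure(list(
    whitepoint = unname(whitepoint), L_A = L_A, Y_b = Y_b, surround = surround,
    F = sp$F, c = sp$c, N_c = sp$N_c, F_L = F_L, n = unname(n),
    z = 1.48 + sqrt(n), N_bb = 0.725 * (1 / n)^0.2, N_cb = 0.725 * (1 / n)^0.2),
    class = "relcol_cam02_conditions")
}

CAT02_M <- matrix(c(
   0.7328, 0.4296, -0.1624,
  -0.7036, 1.6975,  0.0061,
   0.0030, 0.0136,  0.9834), 3, 3, byrow = TRUE)

HPE_M <- matrix(c(
   0.38971, 0.68898, -0.07868,
  -0.22981, 1.18340,  0.04641,
   0.00000, 0.00000,  1.00000), 3, 3, byrow = TRUE)

# Post-adaptation nonlinear compression; x may be negative (sign-preserving).
cam02_compress <- function(x, F_L) {
  t <- (F_L * abs(x) / 100)^0.42
  sign(x) * 400 * t / (27.13 + t) + 0.1
}

#' Convert CIE XYZ to CIECAM02-UCS
#'
#' Runs the CIECAM02 forward model (chromatic adaptation with the CAT02
#' transform and degree of adaptation D, Hunt-Pointer-Estevez cone space,
#' luminance-dependent compression, lightness J and colorfulness M) and maps
#' the correlates into the uniform CAM02-UCS coordinates
#' \eqn{(J', a', b')}.
#'
#' @param xyz XYZ values (array, matrix or triplet), white Y = 100.
#' @param conditions Viewing conditions from [cam02_conditions()].
#' @return (J', a', b') values in the shape of the input, with the viewing
#'   conditions attached as an attribute.
#' @export
xyz_to_cam02ucs <- function(xyz, conditions = cam02_conditions()) {
  if (!inherits(conditions, "relcol_cam02_conditions")) {
    abort("`conditions` must come from cam02_conditions().",
          class = "relcol_config_error")
  }
  t3 <- as_triplets(xyz, "xyz")
  wp <- conditions$whitepoint
  D <- clamp(conditions$F * (1 - (1 / 3.6) * exp(-(conditions$L_A + 42) / 92)), 0, 1)

  rgb_w <- as.vector(CAT02_M %*% wp)
  d_scale <- wp[2] * D / rgb_w + 1 - D
  M_cat <- HPE_M %*% solve(CAT02_M)

  compress_row <- function(xyz_m) {
    rgb <- xyz_m %*% t(CAT02_M)
    rgb_c <- sweep(rgb, 2L, d_scale, "*")
    rgb_p <- rgb_c %*% t(M_cat)
    cam02_compress(rgb_p, conditions$F_L)
  }

  a_w <- {
    rw <- compress_row(matrix(wp, 1L, 3L))
    (2 * rw[1] + rw[2] + rw[3] / 20 - 0.305) * conditions$N_bb
  }

  ra <- compress_row(t3$values)
  a <- ra[, 1] - 12 * ra[, 2] / 11 + ra[, 3] / 11
  b <- (ra[, 1] + ra[, 2] - 2 * ra[, 3]) / 9
  h <- atan2(b, a) %% (2 * pi)
  e_t <- (cos(h + 2) + 3.8) / 4
  A <- (2 * ra[, 1] + ra[, 2] + ra[, 3] / 20 - 0.305) * conditions$N_bb
  A <- pmax(A, 0)
  J <- 100 * (A / a_w)^(conditions$c * conditions$z)
  t_num <- (50000 / 13) * conditions$N_c * conditions$N_cb * e_t * sqrt(a^2 + b^2)
  t_den <- ra[, 1] + ra[, 2] + 21 * ra[, 3] / 20
  tt <- ifelse(t_den > 0, t_num / t_den, 0)
  C <- tt^0.9 * sqrt(J / 100) * (1.64 - 0.29^conditions$n)^0.73
  M <- C * conditions$F_L^0.25

  Jp <- 1.7 * J / (1 + 0.007 * J)
  Mp <- log(1 + 0.0228 * M) / 0.0228
  out <- t3$restore(cbind(Jp, Mp * cos(h), Mp * sin(h)))
  attr(out, "conditions") <- conditions
  out
}

#' sRGB to CIECAM02-UCS in one step
#' @inheritParams srgb_to_xyz
#' @inheritParams xyz_to_cam02ucs
#' @return (J', a', b') values.
#' @export
srgb_to_cam02ucs <- function(image, conditions = cam02_conditions()) {
  xyz_to_cam02ucs(srgb_to_xyz(image), conditions)
}

new_delta_e_summary <- function(mean_delta_e, space_tag) {
  tibble(space = space_tag, mean_delta_e = mean_delta_e)
}

#' Mean CIECAM02-UCS color difference between two images
#'
#' Per-pixel Euclidean distance in (J', a', b'), averaged over the whole
#' image.  Symmetric in its two image arguments and zero iff the images
#' agree in that space.
#'
#' @param original,quantized RGB arrays of identical dimensions (0--255).
#' @param conditions Viewing conditions from [cam02_conditions()].
#' @return One-row tibble with columns `space` ("cam02ucs") and
#'   `mean_delta_e`.
#' @export
mean_delta_e_ucs <- function(original, quantized,
                             conditions = cam02_conditions()) {
  assert_rgb_image(original, "original")
  assert_rgb_image(quantized, "quantized")
  assert_same_shape(original, quantized)
  u1 <- matrix(srgb_to_cam02ucs(original, conditions), ncol = 3L)
  u2 <- matrix(srgb_to_cam02ucs(quantized, conditions), ncol = 3L)
  new_delta_e_summary(mean(sqrt(rowSums((u1 - u2)^2))), "cam02ucs")
}

# ---- S-CIELAB ---------------------------------------------------------------

# Zhang-Wandell opponent transform (XYZ -> AC1C2) and its inverse.
OPP_M <- matrix(c(
   0.279, 0.72, -0.107,
  -0.449, 0.29, -0.077,
   0.086, -0.59, 0.501), 3, 3, byrow = TRUE)
OPP_M_INV <- solve(OPP_M)

# Per-channel mixture-of-Gaussians spatial filters: weights and half-widths
# at half height, in degrees of visual angle (Zhang-Wandell parameterization).
SCIELAB_FILTERS <- list(
  list(w = c(0.921, 0.105, -0.108), hw = c(0.0283, 0.133, 4.336)),  # luminance
  list(w = c(0.531, 0.330),         hw = c(0.0392, 0.494)),         # red-green
  list(w = c(0.488, 0.371),         hw = c(0.0536, 0.386)))         # blue-yellow

# Unit-sum 1-D Gaussian kernel with half-width-at-half-height hw (in samples),
# truncated at a support that covers the tails, capped at the image extent.
gauss_kernel_1d <- function(hw, max_len) {
  alpha <- 4 * log(2) / max(hw, 1e-6)^2
  half <- min(max(ceiling(2.5 * hw), 1L), max_len)
  x <- (-half):half
  k <- exp(-alpha * x^2)
  k / sum(k)
}

# Separable 2-D convolution with symmetric (reflective) padding.
conv_sep_reflect <- function(mat, k) {
  half <- (length(k) - 1L) / 2L
  reflect_idx <- function(n) {
    idx <- c(rev(seq_len(min(half, n))), seq_len(n), n + 1 - seq_len(min(half, n)))
    if (half > n) { # degenerate tiny images: recycle reflection
      idx <- rep(idx, length.out = n + 2L * half)
    }
    idx
  }
  conv_cols <- function(m) {
    n <- nrow(m)
    mp <- m[reflect_idx(n), , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * mp[(j - 1L) + seq_len(n), , drop = FALSE]
    out
  }
  t(conv_cols(t(conv_cols(mat))))
}

# Filter one opponent plane by its Gaussian mixture; kernels normalized so the
# combined filter has unit DC gain (constants are eigenfunctions).
scielab_filter_plane <- function(plane, filt, samples_per_degree) {
  total <- sum(filt$w)
  out <- matrix(0, nrow(plane), ncol(plane))
  for (i in seq_along(filt$w)) {
    k <- gauss_kernel_1d(filt$hw[i] * samples_per_degree,
                         max_len = max(dim(plane)))
    out <- out + (filt$w[i] / total) * conv_sep_reflect(plane, k)
  }
  out
}

# XYZ image array -> spatially filtered XYZ image array.
scielab_filter_xyz <- function(xyz, samples_per_degree) {
  d <- dim(xyz)
  m <- matrix(xyz, ncol = 3L)
  opp <- m %*% t(OPP_M)
  planes <- lapply(1:3, function(ch) {
    scielab_filter_plane(matrix(opp[, ch], d[1], d[2]),
                         SCIELAB_FILTERS[[ch]], samples_per_degree)
  })
  opp_f <- cbind(as.vector(planes[[1]]), as.vector(planes[[2]]),
                 as.vector(planes[[3]]))
  array(opp_f %*% t(OPP_M_INV), dim = d)
}

#' Mean S-CIELAB color difference between two images
#'
#' Spatial extension of CIELAB Delta-E: both images are converted to XYZ,
#' transformed to opponent channels, filtered by the eye's channel-specific
#' spatial-frequency sensitivities (mixture-of-Gaussians kernels, reflective
#' edge padding), converted back to CIELAB, and differenced per pixel; the
#' mean over the image is reported.  Spatially uniform images are untouched
#' by the unit-gain filters, so the measure then reduces to plain CIELAB
#' Delta-E.
#'
#' @param original,quantized RGB arrays of identical dimensions (0--255).
#' @param samples_per_degree Image resolution in samples per degree of
#'   visual angle (> 0); default 72.
#' @param whitepoint XYZ of the adopted white for the CIELAB step.
#' @return One-row tibble with columns `space` ("scielab") and `mean_delta_e`.
#' @export
mean_delta_e_scielab <- function(original, quantized, samples_per_degree = 72,
                                 whitepoint = D65_WHITE) {
  assert_rgb_image(original, "original")
  assert_rgb_image(quantized, "quantized")
  assert_same_shape(original, quantized)
  if (!is.numeric(samples_per_degree) || samples_per_degree <= 0) {
    abort("`samples_per_degree` must be positive.",
          class = "relcol_config_error")
  }
  lab1 <- xyz_to_lab(scielab_filter_xyz(srgb_to_xyz(original), samples_per_degree),
                     whitepoint)
  lab2 <- xyz_to_lab(scielab_filter_xyz(srgb_to_xyz(quantized), samples_per_degree),
                     whitepoint)
  d <- matrix(lab1 - lab2, ncol = 3L)
  new_delta_e_summary(mean(sqrt(rowSums(d^2))), "scielab")
}
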