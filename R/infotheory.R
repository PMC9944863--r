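# Entropy and mutual information between an image and its quantized
# representation.  The color variable is discretized by cubic binning of RGB
# space; entropies come from the plug-in (naive) estimator or the Grassberger
# bias-corrected estimator, and MI from the three-term identity
# I(A1; A2) = H(A1) + H(A2) - H(A1, A2), all in bits.

#' Bin the colors of an image
#'
#' Assigns every pixel to the cubic bin `floor(channel / bin_side)` per
#' channel and tabulates occupied bins.
#'
#' @param image RGB array (`h x w x 3`), values in `[0, 255]`.
#' @param bin_side Bin side length in 8-bit channel units (>= 1);
#'   `bin_side = 1` makes bins the exact 8-bit colors.
#' @return A tibble of occupied bins with columns `bin_r`, `bin_g`, `bin_b`,
#'   `count`, carrying attributes `bin_side` and `total` (class
#'   `relcol_hist`).
#' @export
bin_colors <- function(image, bin_side = 8) {
  if (!is.numeric(bin_side) || length(bin_side) != 1L || bin_side < 1) {
    abort("`bin_side` must be a single value >= 1.",
          class = "relcol_config_error")
  }
  px <- pixel_matrix(image)
  keys <- bin_keys(px, bin_side)
  tab <- tabulate_keys(keys)
  b <- decode_bin_key(tab$key)
  out <- tibble(bin_r = b[, 1], bin_g = b[, 2], bin_b = b[, 3],
                count = tab$count)
  structure(out, bin_side = bin_side, total = sum(tab$count),
            class = c("relcol_hist", class(out)))
}

# Integer bin key for a pixel matrix; base 256 is always enough since
# floor(255 / bin_side) < 256.
bin_keys <- function(px, bin_side) {
  b <- floor(px / bin_side)
  (b[, 1] * 256 + b[, 2]) * 256 + b[, 3]
}

decode_bin_key <- function(key) {
  b3 <- key %% 256
  key <- (key - b3) / 256
  b2 <- key %% 256
  b1 <- (key - b2) / 256
  cbind(b1, b2, b3)
}

# Fast count of identical keys (numeric vector) -> list(key, count).
tabulate_keys <- function(keys) {
  u <- sort(unique(keys))
  list(key = u, count = tabulate(match(keys, u), nbins = length(u)))
}

hist_counts <- function(hist) {
  if (inherits(hist, "relcol_hist")) hist$count
  else if (is.numeric(hist)) as.vector(hist)
  else if (is.data.frame(hist) && "count" %in% names(hist)) hist$count
  else abort("expected a histogram or a vector of counts.",
             class = "relcol_domain_error")
}

check_counts <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0L) {
    abort("empty histogram: no occupied bins.", class = "relcol_domain_error")
  }
  counts
}

#' Naive (plug-in) entropy of a histogram, in bits
#'
#' \eqn{\hat H = -\sum_i (c_i/N) \log_2 (c_i/N)} over occupied bins, with
#' \eqn{0 \log 0 = 0}.
#'
#' @param hist A histogram from [bin_colors()], or a vector of counts.
#' @return Entropy in bits.
#' @export
naive_entropy <- function(hist) {
  counts <- check_counts(hist_counts(hist))
  n <- sum(counts)
  p <- counts / n
  -sum(p * log2(p))
}

#' Grassberger bias-corrected entropy of a histogram, in bits
#'
#' The plug-in estimator is negatively biased when many bins hold few
#' samples.  The Grassberger (2003) estimator replaces the per-bin
#' \eqn{\log} with a digamma-based correction:
#' \deqn{\hat H_G = \ln N - \frac{1}{N}\sum_i n_i G(n_i), \quad
#'   G(n) = \psi(n) + \tfrac12 (-1)^n \left[\psi\!\left(\tfrac{n+1}{2}\right)
#'   - \psi\!\left(\tfrac{n}{2}\right)\right]}
#' (result converted from nats to bits).  The correction vanishes as all
#' counts grow.
#'
#' @inheritParams naive_entropy
#' @return Entropy estimate in bits (may exceed `log2(#bins)` slightly).
#' @export
grassberger_entropy <- function(hist) {
  counts <- check_counts(hist_counts(hist))
  n_tot <- sum(counts)
  g <- digamma(counts) +
    0.5 * (-1)^counts * (digamma((counts + 1) / 2) - digamma(counts / 2))
  (log(n_tot) - sum(counts * g) / n_tot) / log(2)
}

entropy_fun <- function(estimator = c("naive", "grassberger")) {
  estimator <- match.arg(estimator)
  if (estimator == "naive") naive_entropy else grassberger_entropy
}

#' Build a joint histogram of binned color and quantization label
#'
#' @param image RGB array.
#' @param labels Integer label per pixel (vector or matrix matching the
#'   pixel grid, column-major order).
#' @param bin_side Color bin side for the original image; see [bin_colors()].
#' @return Tibble with columns `bin`, `label`, `count` (class
#'   `relcol_joint`); row and column sums reproduce the marginal histograms.
#' @export
joint_histogram <- function(image, labels, bin_side = 8) {
  px <- pixel_matrix(image)
  labels <- as.integer(labels)
  if (length(labels) != nrow(px)) {
    abort("`labels` must cover every pixel.", class = "relcol_dimension_error")
  }
  keys <- bin_keys(px, bin_side)
  pair <- keys * 4096 + labels  # labels are bounded well below 4096
  tab <- tabulate_keys(pair)
  out <- tibble(bin = (tab$key - tab$key %% 4096) / 4096,
                label = as.integer(tab$key %% 4096),
                count = tab$count)
  structure(out, bin_side = bin_side, total = sum(tab$count),
            class = c("relcol_joint", class(out)))
}

joint_counts <- function(joint) {
  if (inherits(joint, "relcol_joint") ||
      (is.data.frame(joint) && all(c("bin", "label", "count") %in% names(joint)))) {
    list(cell = joint$count,
         a = tapply(joint$count, joint$bin, sum),
         q = tapply(joint$count, joint$label, sum))
  } else if (is.matrix(joint)) {
    list(cell = as.vector(joint), a = rowSums(joint), q = colSums(joint))
  } else {
    abort("`joint` must be a relcol_joint tibble or a count matrix.",
          class = "relcol_domain_error")
  }
}

#' Mutual information from a joint histogram
#'
#' Applies the chosen entropy estimator to both marginals and to the joint
#' distribution and combines them by
#' \eqn{I = H(A_1) + H(A_2) - H(A_1, A_2)}.
#'
#' @param joint A joint histogram from [joint_histogram()] or a count matrix
#'   (rows = first variable, columns = second).
#' @param estimator `"naive"` or `"grassberger"`.  Bias-corrected MI can be
#'   slightly negative; values are reported as-is, never clipped.
#' @return One-row tibble (class `relcol_info`) with `H_original`,
#'   `H_quantized`, `H_joint`, `I` (all bits) and `estimator`.
#' @export
mutual_information <- function(joint, estimator = c("naive", "grassberger")) {
  estimator <- match.arg(estimator)
  cnt <- joint_counts(joint)
  if (sum(cnt$cell) == 0) {
    abort("empty joint histogram.", class = "relcol_domain_error")
  }
  h <- entropy_fun(estimator)
  h_a <- h(cnt$a)
  h_q <- h(cnt$q)
  h_j <- h(cnt$cell)
  out <- tibble(H_original = h_a, H_quantized = h_q, H_joint = h_j,
                I = h_a + h_q - h_j, estimator = estimator)
  class(out) <- c("relcol_info", class(out))
  out
}

#' Mutual information between an image and its quantization
#'
#' Forms the joint histogram of (binned original color, cluster label) over
#' all pixels and estimates MI.  The quantized variable is the cluster
#' label, not a re-binned palette color.
#'
#' @param image RGB array.
#' @param quantization A quantization (see [kmeans_quantize()] and friends),
#'   or an integer label vector/matrix over the pixel grid.
#' @param bin_side Color bin side for the original image.
#' @param estimator `"naive"` or `"grassberger"`.
#' @return One-row `relcol_info` tibble; see [mutual_information()].
#' @export
image_quantization_mi <- function(image, quantization, bin_side = 8,
                                  estimator = c("naive", "grassberger")) {
  labels <- if (inherits(quantization, "relcol_quantization")) {
    quantization$labels
  } else {
    quantization
  }
  mutual_information(joint_histogram(image, labels, bin_side),
                     match.arg(estimator))
}

#' Information efficiency of a method relative to a reference
#'
#' \eqn{\eta = I / I_{ref}}: the ratio of a method's estimated mutual
#' information to the reference method's on the same image at the same
#' number of relevant colors.  Dimensionless; multiply by 100 to report
#' percent.
#'
#' @param I Estimated MI of the method under test, bits (vectorized).
#' @param I_ref Reference MI, bits; must be positive.
#' @param image_id,n,method Optional metadata recorded in the output.
#' @return Tibble with columns `image_id`, `method`, `n`, `I`, `I_ref`,
#'   `eta`.
#' @export
efficiency <- function(I, I_ref, image_id = NA_character_, n = NA_integer_,
                       method = NA_character_) {
  if (any(!is.finite(I_ref)) || any(I_ref <= 0)) {
    abort("`I_ref` must be positive.", class = "relcol_domain_error")
  }
  tibble(image_id = image_id, method = method, n = as.integer(n),
         I = I, I_ref = I_ref, eta = I / I_ref)
}

#' @export
tidy.relcol_info <- function(x, ...) {
  tibble(quantity = c("H_original", "H_quantized", "H_joint", "I"),
         bits = c(x$H_original, x$H_quantized, x$H_joint, x$I),
         estimator = x$estimator)
}
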