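# Shared internal helpers: RNG discipline, pixel-matrix plumbing, validation.

# All randomness in the package flows through with_rng(): Mersenne-Twister with
# an explicit integer seed, global .Random.seed saved and restored so package
# calls never perturb (or depend on) the caller's RNG state.
with_rng <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite integer.", class = "relcol_config_error")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max, kind = "Mersenne-Twister")
  force(code)
}

# Derive a reproducible child seed from a parent seed and a stream label,
# keeping the result within 32-bit integer range (double arithmetic: exact
# for the magnitudes involved).
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 1009 + as.numeric(stream) * 9176) %% 2147480009
}

assert_rgb_image <- function(image, arg = "image") {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L) {
    abort(sprintf("`%s` must be a height x width x 3 RGB array.", arg),
          class = "relcol_dimension_error")
  }
  invisible(image)
}

assert_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    abort("images must have identical dimensions.",
          class = "relcol_dimension_error")
  }
  invisible(NULL)
}

# h x w x 3 array (0..255) -> N x 3 matrix, rows in column-major pixel order.
pixel_matrix <- function(image) {
  assert_rgb_image(image)
  d <- dim(image)
  matrix(image, nrow = d[1] * d[2], ncol = 3L,
         dimnames = list(NULL, c("R", "G", "B")))
}

# N x 3 matrix -> h x w x 3 array.
matrix_to_image <- function(px, height, width) {
  array(px, dim = c(height, width, 3L))
}

# Squared Euclidean distances between rows of x (N x d) and rows of centers
# (k x d); returns N x k matrix.  Clamped at zero against float cancellation.
dist2_to_centers <- function(x, centers) {
  d2 <- outer(rowSums(x^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(x)), rowSums(centers^2)) -
    2 * tcrossprod(x, centers)
  d2[d2 < 0] <- 0
  d2
}

# Nearest-center labels with deterministic ties (lowest index wins).
nearest_label <- function(x, centers) {
  max.col(-dist2_to_centers(x, centers), ties.method = "first")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a
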