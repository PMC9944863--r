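# Synthetic painting-like images with known ground truth.  An image is a
# spatial patchwork of n_true color modes with stated mixing proportions,
# within-mode Gaussian chromatic noise, and one of three region layouts.
# Mode pixel counts are realized exactly (largest-remainder apportionment
# over a spatial region ordering), so the analytic entropy of the mixing
# proportions is attainable by an ideal quantizer at zero noise.

#' Specify a synthetic image
#'
#' @param n_true Number of ground-truth color modes.
#' @param palette_true `n_true x 3` matrix of mode colors (integer RGB), or
#'   `NULL` to draw a well-separated default palette (jittered lattice,
#'   pairwise RGB distance >= 48, channels in `[24, 232]`).
#' @param proportions Mixing weights (sum to 1), or `NULL` for a seeded
#'   Dirichlet(4) draw (moderately uneven, painting-like dominance).
#' @param noise_sigma Per-channel Gaussian jitter, RGB units.
#' @param layout Spatial arrangement: `"voronoi"` (irregular patches,
#'   default), `"stripes"`, or `"blobs"` (fewer, larger patches).
#' @param width,height Image size in pixels.
#' @param seed Integer seed governing palette, proportions, layout and noise.
#' @return A spec list (class `relcol_synthetic_spec`).
#' @export
synthetic_spec <- function(n_true = 8, palette_true = NULL, proportions = NULL,
                           noise_sigma = 6, layout = c("voronoi", "stripes", "blobs"),
                           width = 256, height = 256, seed = 1) {
  layout <- match.arg(layout)
  if (is.null(palette_true)) {
    palette_true <- default_palette(n_true, child_seed(seed, 101L))
  }
  palette_true <- as.matrix(palette_true)
  if (nrow(palette_true) != n_true) {
    abort("`palette_true` must have n_true rows.", class = "relcol_config_error")
  }
  if (anyDuplicated(palette_true)) {
    abort("palette colors must be pairwise distinct.",
          class = "relcol_config_error")
  }
  if (is.null(proportions)) {
    proportions <- with_rng(child_seed(seed, 102L), {
      g <- stats::rgamma(n_true, shape = 4)
      g / sum(g)
    })
  }
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-12) {
    abort("`proportions` must be non-negative and sum to 1.",
          class = "relcol_config_error")
  }
  flags <- character(0)
  if (n_true > 1L && noise_sigma > 0) {
    dmin <- min(stats::dist(palette_true))
    if (dmin < 4 * noise_sigma) {
      flags <- "modes_not_separable"
      warn("palette colors closer than 4 * noise_sigma; modes may overlap.")
    }
  }
  structure(list(n_true = as.integer(n_true), palette_true = palette_true,
                 proportions = proportions, noise_sigma = noise_sigma,
                 layout = layout, width = as.integer(width),
                 height = as.integer(height), seed = as.integer(seed),
                 flags = flags),
            class = "relcol_synthetic_spec")
}

# Well-separated integer palette: seeded sample (without replacement) of a
# 4 x 4 x 4 RGB lattice with spacing 64, jittered by +/- 8.
default_palette <- function(n, seed) {
  if (n > 64) {
    abort("default palette supports at most 64 modes.",
          class = "relcol_config_error")
  }
  lattice <- as.matrix(expand.grid(c(32, 96, 160, 224), c(32, 96, 160, 224),
                                   c(32, 96, 160, 224)))
  with_rng(seed, {
    pick <- sample.int(64, n)
    jitter <- matrix(sample(-8:8, n * 3, replace = TRUE), n, 3)
    unname(lattice[pick, , drop = FALSE] + jitter)
  })
}

# Largest-remainder apportionment of N pixels over weights w.
apportion <- function(N, w) {
  exact <- N * w
  base <- floor(exact)
  rem <- N - sum(base)
  if (rem > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# Spatial region id per pixel (column-major), per layout.  Regions are the
# granularity at which modes tile the image.
layout_regions <- function(layout, height, width, n_true, seed) {
  N <- height * width
  if (layout == "stripes") {
    rep(seq_len(width), each = height)
  } else {
    n_sites <- if (layout == "voronoi") max(8L * n_true, 40L) else
      max(2L * n_true, 8L)
    sites <- with_rng(seed, cbind(runif(n_sites, 1, height),
                                  runif(n_sites, 1, width)))
    rows <- rep(seq_len(height), times = width)
    cols <- rep(seq_len(width), each = height)
    d2 <- outer(rows, sites[, 1], "-")^2 + outer(cols, sites[, 2], "-")^2
    max.col(-d2, ties.method = "first")
  }
}

#' Generate a synthetic image with ground-truth labels
#'
#' Pixels are ordered by spatial region; consecutive slices of that ordering
#' (largest-remainder target counts) take the mode colors, so realized mode
#' frequencies match the proportions to within one pixel while regions stay
#' spatially coherent.  Gaussian noise is added per channel, clipped to
#' `[0, 255]` and rounded to 8-bit integers.  Fully reproducible from the
#' spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @return List (class `relcol_synthetic`) with `image` (RGB array),
#'   `labels` (ground-truth mode index matrix) and `spec`.
#' @export
generate_image <- function(spec) {
  if (!inherits(spec, "relcol_synthetic_spec")) {
    abort("`spec` must come from synthetic_spec().",
          class = "relcol_config_error")
  }
  h <- spec$height; w <- spec$width; N <- h * w
  region <- layout_regions(spec$layout, h, w, spec$n_true,
                           child_seed(spec$seed, 103L))
  ord <- order(region, seq_len(N))
  counts <- apportion(N, spec$proportions)
  labels <- integer(N)
  labels[ord] <- rep.int(seq_len(spec$n_true), counts)

  img <- spec$palette_true[labels, , drop = FALSE]
  if (spec$noise_sigma > 0) {
    img <- img + with_rng(child_seed(spec$seed, 104L),
                          matrix(rnorm(N * 3, 0, spec$noise_sigma), N, 3))
  }
  img <- round(clamp(img, 0, 255))
  structure(list(image = matrix_to_image(img, h, w),
                 labels = matrix(labels, h, w), spec = spec),
            class = "relcol_synthetic")
}

#' Analytic information content of a synthetic spec
#'
#' The entropy of the mode-label distribution, \eqn{-\sum_k w_k \log_2 w_k}.
#' At zero noise and `bin_side = 1` this equals the mutual information
#' attained by the ideal `n_true`-color quantization, provided the
#' proportions are exactly realizable at the image size (the generator uses
#' largest-remainder apportionment).
#'
#' @param spec A [synthetic_spec()].
#' @return Bits.
#' @export
true_information <- function(spec) {
  w <- spec$proportions[spec$proportions > 0]
  -sum(w * log2(w))
}

#' Simulate an observer's relevant-color picks
#'
#' Emulates a participant clicking representative image locations: one pick
#' per mode in decreasing area order (cycling when `n_picked > n_true`),
#' placed at an interior pixel of the mode, jittered by `pick_noise` pixels,
#' clamped to the image.  Each relevant color is the mean of the 5 x 5 patch
#' of pixels around the pick (patches clipped at borders are flagged).  The
#' induced quantization assigns every pixel to the nearest picked color.
#'
#' @param synthetic A `relcol_synthetic` from [generate_image()].
#' @param n_picked Number of relevant colors chosen (>= 1); default
#'   `n_true`.
#' @param pick_noise Standard deviation of the Gaussian location jitter, in
#'   pixels.
#' @param seed Integer seed.
#' @return List (class `relcol_observer_sim`) with `picks` (tibble: mode,
#'   row, col, patch-mean RGB), `quantization` (a `relcol_quantization`,
#'   `method = "observer"`), `n_picked` and `pick_noise`.
#' @export
simulate_observer <- function(synthetic, n_picked = NULL, pick_noise = 0,
                              seed = 1) {
  if (!inherits(synthetic, "relcol_synthetic")) {
    abort("`synthetic` must come from generate_image().",
          class = "relcol_config_error")
  }
  spec <- synthetic$spec
  n_picked <- as.integer(n_picked %||% spec$n_true)
  if (n_picked < 1L) {
    abort("`n_picked` must be >= 1.", class = "relcol_config_error")
  }
  img <- synthetic$image
  lab <- synthetic$labels
  h <- nrow(lab); w <- ncol(lab)
  areas <- tabulate(lab, spec$n_true)
  mode_order <- order(areas, decreasing = TRUE)
  chosen <- rep_len(mode_order[areas[mode_order] > 0], n_picked)

  flags <- character(0)
  picks <- with_rng(seed, {
    lapply(chosen, function(mode) {
      loc <- interior_pixel(lab, mode)
      if (pick_noise > 0) loc <- loc + round(rnorm(2, 0, pick_noise))
      loc <- c(clamp(loc[1], 1, h), clamp(loc[2], 1, w))
      loc
    })
  })
  colors <- t(vapply(picks, function(loc) {
    rows <- (loc[1] - 2):(loc[1] + 2)
    cols <- (loc[2] - 2):(loc[2] + 2)
    if (any(rows < 1 | rows > h | cols < 1 | cols > w)) {
      flags <<- union(flags, "patch_clamped")
      rows <- clamp(rows, 1, h); cols <- clamp(cols, 1, w)
    }
    patch <- img[unique(rows), unique(cols), , drop = FALSE]
    apply(patch, 3L, mean)
  }, numeric(3)))

  labels <- nearest_label(pixel_matrix(img), colors)
  colnames(colors) <- c("R", "G", "B")
  q <- new_quantization(colors, labels, c(h, w), n_picked, "observer",
                        seed = seed, flags = flags,
                        meta = list(pick_noise = pick_noise))
  structure(list(
    picks = tibble(mode = chosen,
                   row = vapply(picks, `[`, numeric(1), 1),
                   col = vapply(picks, `[`, numeric(1), 2),
                   R = colors[, 1], G = colors[, 2], B = colors[, 3]),
    quantization = q, n_picked = n_picked, pick_noise = pick_noise),
    class = "relcol_observer_sim")
}

# A pixel of the given mode whose 5x5 neighborhood lies within the mode, as
# close to the mode's centroid as possible; falls back to the mode pixel
# nearest the centroid.
interior_pixel <- function(lab, mode) {
  sel <- which(lab == mode)
  h <- nrow(lab)
  rows <- ((sel - 1) %% h) + 1
  cols <- ((sel - 1) %/% h) + 1
  cr <- mean(rows); cc <- mean(cols)
  is_mode <- lab == mode
  interior <- vapply(seq_along(sel), function(i) {
    r <- rows[i]; co <- cols[i]
    if (r < 3 || r > h - 2 || co < 3 || co > ncol(lab) - 2) return(FALSE)
    all(is_mode[(r - 2):(r + 2), (co - 2):(co + 2)])
  }, logical(1))
  cand <- if (any(interior)) which(interior) else seq_along(sel)
  best <- cand[which.min((rows[cand] - cr)^2 + (cols[cand] - cc)^2)]
  c(rows[best], cols[best])
}

#' Generate a synthetic study corpus
#'
#' A set of synthetic images mimicking a multi-image study design: `n_images`
#' images with `n_true` drawn from `n_true_range`, Dirichlet proportions,
#' fixed noise, each with its own derived seed.
#'
#' @param n_images Number of images.
#' @param n_true_range Inclusive range to draw each image's `n_true` from.
#' @param noise_sigma,layout,width,height Passed to [synthetic_spec()].
#' @param seed Corpus seed.
#' @return List of `relcol_synthetic` objects; the manifest of specs is
#'   attached as attribute `"manifest"` (a tibble).
#' @export
synthetic_corpus <- function(n_images = 20, n_true_range = c(5, 25),
                             noise_sigma = 6, layout = "voronoi",
                             width = 256, height = 256, seed = 1) {
  n_trues <- with_rng(child_seed(seed, 105L),
                      sample(n_true_range[1]:n_true_range[2], n_images,
                             replace = TRUE))
  images <- lapply(seq_len(n_images), function(i) {
    generate_image(synthetic_spec(
      n_true = n_trues[i], noise_sigma = noise_sigma, layout = layout,
      width = width, height = height, seed = child_seed(seed, 200L + i)))
  })
  manifest <- tibble(
    image_id = sprintf("synth%02d", seq_len(n_images)),
    n_true = n_trues,
    noise_sigma = noise_sigma, layout = layout,
    width = width, height = height,
    seed = vapply(images, function(s) s$spec$seed, integer(1)))
  attr(images, "manifest") <- manifest
  images
}

#' Write a corpus to disk (PNG images + JSON manifest)
#'
#' @param corpus From [synthetic_corpus()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- attr(corpus, "manifest")
  for (i in seq_along(corpus)) {
    write_image(corpus[[i]]$image,
                file.path(dir, paste0(manifest$image_id[i], ".png")))
  }
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
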