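# The colorimetric quantizer: partition CIELAB into cubic cells on a fixed
# grid, designate cells as "relevant" by occupancy, lightness and chroma
# criteria, and map every pixel to a relevant-cell average.  The number of
# relevant colors n is a property of the image, not an input.

#' Configuration for the colorimetric quantizer
#'
#' Thresholds are conventions (the criteria ranges are not fully published):
#' cells of side `cell_side` CIELAB units on a fixed origin at
#' (L*, a*, b*) = (0, -128, -128); a cell is relevant iff it holds at least
#' `min_fraction` of the pixels, its mean L* lies within
#' `[lightness_min, lightness_max]`, and its mean chroma is at least
#' `min_chroma` -- except that near-neutral cells (chroma below
#' `min_chroma`) still qualify when they hold at least
#' `neutral_exemption_factor * min_fraction` of the pixels.
#'
#' @param cell_side Cell side in CIELAB units (> 0).
#' @param min_fraction Minimum occupancy fraction for relevance.
#' @param lightness_min,lightness_max Allowed mean L* range.
#' @param min_chroma Minimum mean chroma (C*ab).
#' @param neutral_exemption_factor Occupancy multiplier exempting
#'   near-neutral cells from the chroma criterion.
#' @return A config list (class `relcol_colorimetric_config`).
#' @export
colorimetric_config <- function(cell_side = 10, min_fraction = 0.001,
                                lightness_min = 5, lightness_max = 95,
                                min_chroma = 5,
                                neutral_exemption_factor = 5) {
  if (cell_side <= 0) {
    abort("`cell_side` must be positive.", class = "relcol_config_error")
  }
  structure(list(cell_side = cell_side, min_fraction = min_fraction,
                 lightness_min = lightness_min, lightness_max = lightness_max,
                 min_chroma = min_chroma,
                 neutral_exemption_factor = neutral_exemption_factor),
            class = "relcol_colorimetric_config")
}

# Cell key on the fixed (0, -128, -128) origin.
lab_cell_keys <- function(lab, cell_side) {
  i1 <- floor(lab[, 1] / cell_side)
  i2 <- floor((lab[, 2] + 128) / cell_side)
  i3 <- floor((lab[, 3] + 128) / cell_side)
  (i1 * 4096 + i2) * 4096 + i3
}

#' Build the CIELAB cell grid of an image
#'
#' @param lab_image CIELAB values: `h x w x 3` array or `N x 3` matrix (from
#'   [srgb_to_lab()]).
#' @param cell_side Cell side in CIELAB units (> 0).
#' @return Tibble of occupied cells (class `relcol_cell_grid`): cell index
#'   columns, `count`, mean `L`, `a`, `b`, mean `chroma` and a `relevant`
#'   flag (all `FALSE` until [designate_relevant()]).
#' @export
build_cell_grid <- function(lab_image, cell_side = 10) {
  if (cell_side <= 0) {
    abort("`cell_side` must be positive.", class = "relcol_config_error")
  }
  lab <- if (is.array(lab_image) && length(dim(lab_image)) == 3L) {
    matrix(lab_image, ncol = 3L)
  } else {
    as.matrix(lab_image)
  }
  keys <- lab_cell_keys(lab, cell_side)
  u <- sort(unique(keys))
  cell <- match(keys, u)
  count <- tabulate(cell, length(u))
  mean_by <- function(v) as.vector(tapply(v, cell, sum)) / count
  chroma <- sqrt(lab[, 2]^2 + lab[, 3]^2)
  out <- tibble(cell_key = u, count = count,
                L = mean_by(lab[, 1]), a = mean_by(lab[, 2]),
                b = mean_by(lab[, 3]), chroma = mean_by(chroma),
                relevant = FALSE)
  structure(out, cell_side = cell_side, total = sum(count),
            class = c("relcol_cell_grid", class(out)))
}

#' Designate relevant cells
#'
#' Applies the occupancy, lightness and chroma criteria from
#' [colorimetric_config()].  If no cell qualifies, the single most occupied
#' cell is made relevant and the result is flagged.
#'
#' @param grid A cell grid from [build_cell_grid()].
#' @param config A [colorimetric_config()].
#' @return The grid with its `relevant` column filled in; attribute
#'   `"flags"` records a forced relaxation.
#' @export
designate_relevant <- function(grid, config = colorimetric_config()) {
  total <- attr(grid, "total")
  frac <- grid$count / total
  chroma_ok <- grid$chroma >= config$min_chroma |
    frac >= config$neutral_exemption_factor * config$min_fraction
  rel <- frac >= config$min_fraction &
    grid$L >= config$lightness_min & grid$L <= config$lightness_max &
    chroma_ok
  flags <- character(0)
  if (!any(rel)) {
    rel[which.max(grid$count)] <- TRUE
    flags <- "relaxed_to_modal_cell"
  }
  grid$relevant <- rel
  attr(grid, "flags") <- flags
  grid
}

#' Colorimetric relevant-color quantization
#'
#' Converts the image to CIELAB, builds the cell grid, designates relevant
#' cells, and maps every pixel to a relevant-cell average: pixels inside a
#' relevant cell take that cell's average color; pixels elsewhere take the
#' nearest relevant-cell average (Euclidean distance in CIELAB, ties broken
#' toward the lowest cell index).  `n` is the number of relevant cells,
#' determined automatically.
#'
#' Cell averages used for output are the mean RGB of the member pixels (the
#' same statistic as the mean CIELAB color, but exact in the image's native
#' space); distances are measured in CIELAB.
#'
#' @param image RGB array.
#' @param config A [colorimetric_config()].
#' @return A `relcol_quantization` with `method = "colorimetric"`; `n` is
#'   automatic.
#' @export
colorimetric_quantize <- function(image, config = colorimetric_config()) {
  assert_rgb_image(image)
  px <- pixel_matrix(image)
  lab <- srgb_to_lab(px)
  grid <- designate_relevant(build_cell_grid(lab, config$cell_side), config)
  rel_idx <- which(grid$relevant)
  n <- length(rel_idx)

  keys <- lab_cell_keys(lab, config$cell_side)
  cell_of_pixel <- match(keys, grid$cell_key)
  label <- match(cell_of_pixel, rel_idx)  # NA for pixels in non-relevant cells

  rel_lab <- as.matrix(grid[rel_idx, c("L", "a", "b")])
  outside <- which(is.na(label))
  if (length(outside)) {
    label[outside] <- nearest_label(lab[outside, , drop = FALSE], rel_lab)
  }

  palette <- t(vapply(seq_len(n), function(k) {
    sel <- cell_of_pixel %in% rel_idx[k]
    colMeans(px[sel, , drop = FALSE])
  }, numeric(3)))
  colnames(palette) <- c("R", "G", "B")
  new_quantization(palette, label, dim(image)[1:2], n, "colorimetric",
                   seed = NA_integer_, flags = attr(grid, "flags"),
                   meta = list(config = unclass(config)))
}
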