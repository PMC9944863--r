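# Fixtures are built in code: small mode-structured images with known ground
# truth, and count-defined toy images for histogram-level oracles.

# Image whose pixels cycle through `palette` rows according to `labels`
# (vector, column-major); h x w inferred from length.
image_from_labels <- function(palette, labels, h, w) {
  px <- palette[labels, , drop = FALSE]
  array(px, dim = c(h, w, 3))
}

# 1 x N image realizing exact per-color counts (distinct, well-spread colors)
# -- used for histogram/partition oracles where geometry is irrelevant.
image_from_counts <- function(counts) {
  B <- length(counts)
  cols <- cbind((seq_len(B) * 30) %% 256, (seq_len(B) * 97) %% 256,
                (seq_len(B) * 53) %% 256)
  px <- cols[rep(seq_len(B), counts), , drop = FALSE]
  array(px, dim = c(nrow(px), 1, 3))
}

# Palette of modes that are far apart in RGB *and* CIELAB (>= 3 cells of 10
# units), with mid lightness -- suited to exact-recovery constructions.
separated_palette <- function() {
  pal <- rbind(c(200, 40, 40), c(40, 170, 40), c(60, 60, 220), c(220, 210, 60))
  lab <- relcol::srgb_to_lab(pal)
  stopifnot(min(dist(lab)) > 30, all(lab[, 1] > 5), all(lab[, 1] < 95))
  pal
}

# Noise-free synthetic scene with exactly realizable dyadic proportions.
exact_recovery_scene <- function(seed = 1, h = 64, w = 64) {
  pal <- separated_palette()
  spec <- relcol::synthetic_spec(
    n_true = 4, palette_true = pal, proportions = c(0.5, 0.25, 0.125, 0.125),
    noise_sigma = 0, layout = "voronoi", width = w, height = h, seed = seed)
  relcol::generate_image(spec)
}

# Brute-force naive MI from an explicit (color, label) contingency table.
brute_force_mi <- function(image, labels, bin_side = 1) {
  px <- matrix(image, ncol = 3)
  key <- paste(floor(px[, 1] / bin_side), floor(px[, 2] / bin_side),
               floor(px[, 3] / bin_side))
  tab <- table(key, as.vector(labels))
  p <- tab / sum(tab)
  h <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  h(rowSums(p)) + h(colSums(p)) - h(as.vector(p))
}
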