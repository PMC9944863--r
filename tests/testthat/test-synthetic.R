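# The synthetic-image generator and the simulated observer.

test_that("zero-noise images realize the palette and proportions exactly", {
  spec <- synthetic_spec(n_true = 4, proportions = c(0.5, 0.25, 0.125, 0.125),
                         noise_sigma = 0, width = 64, height = 64, seed = 7)
  s <- generate_image(spec)
  expect_equal(n_unique_colors(s$image), 4L)
  expect_equal(tabulate(s$labels, 4) / 4096, spec$proportions)
  expect_identical(generate_image(spec), s)  # bit-identical regeneration
})

test_that("realized mode frequencies track arbitrary proportions across layouts", {
  for (layout in c("voronoi", "stripes", "blobs")) {
    spec <- synthetic_spec(n_true = 5, proportions = c(.31, .24, .2, .15, .1),
                           noise_sigma = 3, layout = layout,
                           width = 100, height = 100, seed = 21)
    s <- generate_image(spec)
    freq <- tabulate(s$labels, 5) / 1e4
    se <- sqrt(spec$proportions * (1 - spec$proportions) / 1e4)
    expect_true(all(abs(freq - spec$proportions) <= pmax(3 * se, 2e-4)),
                info = layout)
  }
})

test_that("overlapping modes are flagged at generation time", {
  pal <- rbind(c(100, 100, 100), c(104, 100, 100))
  expect_warning(
    synthetic_spec(n_true = 2, palette_true = pal, proportions = c(.5, .5),
                   noise_sigma = 6, width = 16, height = 16, seed = 1),
    "modes may overlap")
  expect_error(
    synthetic_spec(n_true = 2, palette_true = pal[c(1, 1), ],
                   proportions = c(.5, .5), noise_sigma = 0, seed = 1),
    class = "relcol_config_error")
})

test_that("true_information is the entropy of the mixing weights", {
  expect_equal(true_information(synthetic_spec(4, proportions = rep(.25, 4),
                                               noise_sigma = 0, seed = 1,
                                               width = 16, height = 16)), 2)
  expect_equal(true_information(synthetic_spec(
    3, proportions = c(.5, .25, .25), noise_sigma = 0, seed = 1,
    width = 16, height = 16)), 1.5)
  one <- synthetic_spec(1, palette_true = matrix(c(10, 20, 30), 1),
                        proportions = 1, noise_sigma = 0, seed = 1,
                        width = 8, height = 8)
  expect_equal(true_information(one), 0)
})

test_that("noise-free observer picks recover the full information", {
  scene <- exact_recovery_scene(seed = 11)
  ob <- simulate_observer(scene, n_picked = 4, pick_noise = 0, seed = 2)
  got <- image_quantization_mi(scene$image, ob$quantization, 1, "naive")$I
  expect_equal(got, true_information(scene$spec), tolerance = 1e-12)
  # a single pick carries no information
  ob1 <- simulate_observer(scene, n_picked = 1, seed = 2)
  expect_equal(image_quantization_mi(scene$image, ob1$quantization, 1,
                                     "naive")$I, 0)
  expect_error(simulate_observer(scene, n_picked = 0),
               class = "relcol_config_error")
})

test_that("picking fewer colors than modes merges them as the induced partition", {
  pal <- separated_palette()[1:3, ]
  spec <- synthetic_spec(n_true = 3, palette_true = pal,
                         proportions = c(0.5, 0.25, 0.25), noise_sigma = 0,
                         width = 32, height = 32, seed = 13)
  scene <- generate_image(spec)
  ob <- simulate_observer(scene, n_picked = 2, pick_noise = 0, seed = 4)
  got <- image_quantization_mi(scene$image, ob$quantization, 1, "naive")$I
  # explicit joint table of (true color, induced 2-way merge)
  expect_equal(got, brute_force_mi(scene$image, ob$quantization$labels, 1),
               tolerance = 1e-12)
  expect_lt(got, true_information(spec))
})

test_that("every pick stays inside the image and respects patch clamping", {
  scene <- generate_image(synthetic_spec(n_true = 6, noise_sigma = 6,
                                         width = 24, height = 24, seed = 17))
  ob <- simulate_observer(scene, n_picked = 8, pick_noise = 10, seed = 5)
  expect_true(all(ob$picks$row >= 1 & ob$picks$row <= 24))
  expect_true(all(ob$picks$col >= 1 & ob$picks$col <= 24))
  expect_equal(ob$quantization$n, 8L)
})

test_that("the corpus manifest describes its images and reproduces them", {
  corpus <- synthetic_corpus(n_images = 3, n_true_range = c(4, 6),
                             width = 24, height = 24, seed = 5)
  man <- attr(corpus, "manifest")
  expect_equal(nrow(man), 3L)
  expect_equal(man$n_true,
               vapply(corpus, function(s) s$spec$n_true, integer(1)))
  corpus2 <- synthetic_corpus(n_images = 3, n_true_range = c(4, 6),
                              width = 24, height = 24, seed = 5)
  expect_identical(corpus, corpus2)
})

test_that("PNG round-trip preserves generated images exactly", {
  scene <- generate_image(synthetic_spec(n_true = 3, noise_sigma = 4,
                                         width = 12, height = 12, seed = 23))
  path <- tempfile(fileext = ".png")
  write_image(scene$image, path)
  back <- read_image(path)
  expect_equal(back, scene$image, ignore_attr = TRUE)
})
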