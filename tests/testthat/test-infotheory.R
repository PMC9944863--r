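# Entropy/MI estimation: frozen oracle values, estimator properties, and
# brute-force cross-checks.

test_that("naive entropy matches direct evaluation", {
  expect_equal(naive_entropy(c(1, 1, 1, 1)), 2)
  expect_equal(naive_entropy(c(8)), 0)
  expect_equal(naive_entropy(c(3, 1)), 0.811278, tolerance = 1e-6)
  expect_error(naive_entropy(integer(0)), class = "relcol_domain_error")
  expect_error(naive_entropy(c(0, 0)), class = "relcol_domain_error")
})

test_that("Grassberger estimator follows the digamma identities and converges", {
  # G(1) = -gamma - ln 2, so four singletons give (ln 4 + gamma + ln 2)/ln 2
  gamma_e <- -digamma(1)
  expect_equal(grassberger_entropy(c(1, 1, 1, 1)),
               (log(4) + gamma_e + log(2)) / log(2), tolerance = 1e-9)
  # large balanced counts: correction vanishes, estimate -> log2 k
  expect_equal(grassberger_entropy(rep(1e4, 8)), 3, tolerance = 1e-3)
  expect_equal(grassberger_entropy(rep(1e4, 8)) - naive_entropy(rep(1e4, 8)),
               0, tolerance = 1e-3)
})

test_that("Grassberger bias is smaller than naive bias at small samples", {
  p <- c(0.4, 0.3, 0.2, 0.1)
  H_true <- -sum(p * log2(p))
  set.seed(202)
  est <- vapply(1:300, function(i) {
    counts <- as.vector(rmultinom(1, 50, p))
    counts <- counts[counts > 0]
    c(naive_entropy(counts), grassberger_entropy(counts))
  }, numeric(2))
  expect_lt(abs(mean(est[2, ]) - H_true), abs(mean(est[1, ]) - H_true))
})

test_that("bin_colors tabulates pixels into cubes correctly", {
  const <- array(rep(c(10, 20, 30), each = 35), c(5, 7, 3))
  h <- bin_colors(const, 16)
  expect_equal(nrow(h), 1L)
  expect_equal(h$count, 35L)
  # 4-color toy at bin_side 64, against an explicit per-pixel loop
  pal <- rbind(c(10, 10, 10), c(70, 10, 10), c(10, 140, 10), c(200, 200, 200))
  labs <- rep(1:4, times = c(7, 5, 2, 6))
  img <- image_from_labels(pal, labs, 4, 5)
  h <- bin_colors(img, 64)
  manual <- table(apply(floor(matrix(img, ncol = 3) / 64), 1, paste,
                        collapse = ","))
  expect_setequal(h$count, as.integer(manual))
  expect_equal(attr(h, "total"), 20L)
  # bin_side 1 resolves exact unique colors
  expect_equal(nrow(bin_colors(img, 1)), 4L)
  expect_error(bin_colors(img, 0), class = "relcol_config_error")
})

test_that("joint histogram reproduces both marginals exactly", {
  scene <- exact_recovery_scene(seed = 2, h = 16, w = 16)
  j <- joint_histogram(scene$image, scene$labels, bin_side = 8)
  marg_a <- tapply(j$count, j$bin, sum)
  h <- bin_colors(scene$image, 8)
  expect_equal(sort(as.integer(marg_a)), sort(h$count))
  marg_q <- tapply(j$count, j$label, sum)
  expect_equal(sort(as.integer(marg_q)),
               sort(tabulate(scene$labels, scene$spec$n_true)))
})

test_that("MI identities hold on canonical joints", {
  expect_equal(mutual_information(matrix(25, 2, 2), "naive")$I, 0)
  expect_equal(mutual_information(diag(4) * 10, "naive")$I, 2)
  r <- mutual_information(matrix(c(3, 1, 1, 3), 2), "naive")
  expect_equal(r$I, 0.188722, tolerance = 1e-6)
  expect_equal(r$I, r$H_original + r$H_quantized - r$H_joint)
  expect_error(mutual_information(matrix(0, 2, 2)),
               class = "relcol_domain_error")
})

test_that("naive MI is non-negative, bounded, symmetric, and label-permutation invariant", {
  set.seed(31)
  for (rep in 1:20) {
    j <- matrix(rpois(12, 4), 3, 4)
    j[1, 1] <- j[1, 1] + 1  # never all-zero
    r <- mutual_information(j, "naive")
    expect_gte(r$I, -1e-12)
    expect_lte(r$I, min(r$H_original, r$H_quantized) + 1e-12)
    expect_equal(mutual_information(t(j), "naive")$I, r$I)
    perm <- sample(4)
    expect_equal(mutual_information(j[, perm], "naive")$I, r$I)
    # data processing: merging two columns never increases naive MI
    merged <- cbind(j[, 1] + j[, 2], j[, 3:4])
    expect_lte(mutual_information(merged, "naive")$I, r$I + 1e-12)
  }
})

test_that("image-quantization MI matches a brute-force joint table", {
  scene <- exact_recovery_scene(seed = 6, h = 20, w = 20)
  img <- scene$image
  q <- kmeans_quantize(img, 3, seed = 4)
  got <- image_quantization_mi(img, q, bin_side = 1, estimator = "naive")$I
  expect_equal(got, brute_force_mi(img, q$labels, 1), tolerance = 1e-12)
  # one cluster carries no information
  one <- kmeans_quantize(img, 1, seed = 1)
  expect_equal(image_quantization_mi(img, one, 8, "naive")$I, 0)
  # lossless quantization at bin_side 1 attains H(original)
  ideal <- relcol:::new_quantization(scene$spec$palette_true, scene$labels,
                                     dim(img)[1:2], 4, "truth")
  r <- image_quantization_mi(img, ideal, 1, "naive")
  expect_equal(r$I, r$H_original, tolerance = 1e-12)
})

test_that("efficiency is the plain ratio and rejects non-positive references", {
  expect_equal(efficiency(1.8, 2.0)$eta, 0.9)
  expect_equal(efficiency(2.0, 2.0)$eta, 1)
  expect_error(efficiency(1, 0), class = "relcol_domain_error")
  expect_error(efficiency(1, -2), class = "relcol_domain_error")
})
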