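# Clustering quantizers: seeding law, exhaustive oracles, convergence
# guarantees, and the exactly-n contract.

test_that("k-means++ seeding degenerates correctly and follows the D-squared law", {
  x <- matrix(c(0, 0, 0, 10, 0, 0, 0, 10, 0, 5, 5, 5), 4, 3, byrow = TRUE)
  expect_equal(nrow(kmeanspp_init(x, 1, seed = 3)), 1L)
  all4 <- kmeanspp_init(x, 4, seed = 3)
  expect_setequal(apply(all4, 1, paste, collapse = ","),
                  apply(x, 1, paste, collapse = ","))
  expect_error(kmeanspp_init(x[c(1, 1, 2), ], 3, seed = 1),
               class = "relcol_domain_error")
  # empirical distribution of the (first, second) center pair vs the D^2 law:
  # P(first = i) = 1/3, P(second = j | i) = d2_ij / sum_k d2_ik
  x2 <- matrix(c(0, 0, 0, 3, 0, 0, 0, 4, 0), 3, 3, byrow = TRUE)
  row_id <- function(ctr) match(ctr[1] + ctr[2], c(0, 3, 4))  # x + y is unique
  d2 <- as.matrix(dist(x2))^2
  expected <- outer(1:3, 1:3, Vectorize(function(i, j) {
    if (i == j) 0 else (1 / 3) * d2[i, j] / sum(d2[i, -i])
  }))
  emp_mat <- matrix(0, 3, 3)
  for (s in 1:3000) {
    ctr <- kmeanspp_init(x2, 2, seed = s)
    i <- row_id(ctr[1, ]); j <- row_id(ctr[2, ])
    emp_mat[i, j] <- emp_mat[i, j] + 1
  }
  emp_mat <- emp_mat / 3000
  expect_lt(max(abs(emp_mat - expected)), 0.03)
})

test_that("k-means recovers exact palettes and the global optimum on tiny instances", {
  scene <- exact_recovery_scene(seed = 5, h = 16, w = 16)
  q <- kmeans_quantize(scene$image, 4, seed = 2)
  expect_equal(sort(q$palette[, 1]), sort(separated_palette()[, 1]))
  expect_equal(n_unique_colors(apply_palette(scene$image, q)), 4L)
  # n = 1 gives the global mean color
  q1 <- kmeans_quantize(scene$image, 1, seed = 2)
  expect_equal(drop(q1$palette),
               colMeans(relcol:::pixel_matrix(scene$image)),
               ignore_attr = TRUE)
  # 8 points, n = 2: objective equals the best over all 2-partitions
  set.seed(77)
  pts <- matrix(runif(24, 0, 255), 8, 3)
  img <- array(t(pts), c(3, 8, 1)) |> aperm(c(2, 3, 1))
  q2 <- kmeans_quantize(img, 2, seed = 9)
  wss <- function(lab) sum(vapply(unique(lab), function(k) {
    sum(sweep(pts[lab == k, , drop = FALSE], 2,
              colMeans(pts[lab == k, , drop = FALSE]))^2)
  }, numeric(1)))
  best <- min(vapply(1:126, function(m) {
    lab <- as.integer(intToBits(m))[1:8]
    if (length(unique(lab)) < 2) return(Inf)
    wss(lab)
  }, numeric(1)))
  got <- wss(as.vector(q2$labels))
  expect_equal(got, best, tolerance = 1e-9)
})

test_that("MEC objective is non-increasing and collapses to k-means as T -> 0", {
  scene <- exact_recovery_scene(seed = 12, h = 24, w = 24)
  noisy <- scene$image + array(rnorm(length(scene$image), 0, 4),
                               dim(scene$image))
  noisy <- round(pmin(pmax(noisy, 0), 255))
  q <- mec_quantize(noisy, 4, seed = 3)
  expect_true(all(diff(q$objective_trace) <= 1e-8 * abs(q$objective_trace[-length(q$objective_trace)]) + 1e-8))
  # annealing limit: tiny T reproduces k-means labels up to relabeling
  qc <- mec_quantize(noisy, 4, seed = 3, temperature = 1e-6)
  qk <- kmeans_quantize(noisy, 4, seed = 3)
  tab <- table(qc$labels, qk$labels)
  expect_equal(sum(apply(tab, 1, max)), length(qc$labels))
  expect_error(mec_quantize(noisy, 4, temperature = -1),
               class = "relcol_config_error")
})

test_that("MEC converged memberships satisfy the fixed-point equations", {
  pts <- matrix(c(0, 0, 0, 2, 0, 0, 0, 3, 0, 60, 60, 60, 62, 60, 60, 60, 63, 60),
                6, 3, byrow = TRUE)
  img <- array(t(pts), c(3, 6, 1)) |> aperm(c(2, 3, 1))
  temperature <- 25
  q <- mec_quantize(img, 2, seed = 8, temperature = temperature, tol = 1e-12)
  # recompute memberships and centers from scratch at the solution
  centers <- t(vapply(1:2, function(k)
    colMeans(pts[as.vector(q$labels) == k, , drop = FALSE]), numeric(3)))
  d2 <- relcol:::dist2_to_centers(pts, centers)
  u <- exp(-d2 / temperature); u <- u / rowSums(u)
  centers_next <- crossprod(u, pts) / colSums(u)
  expect_equal(unname(centers_next), unname(centers), tolerance = 1e-3)
})

test_that("GMM EM recovers separated Gaussians and increases the likelihood", {
  set.seed(55)
  mu_true <- rbind(c(40, 40, 40), c(150, 60, 200), c(220, 220, 100))
  pts <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(400 * 3, 0, 7), 400, 3), 2, mu_true[k, ], "+")))
  img <- array(t(pts), c(3, 1200, 1)) |> aperm(c(2, 3, 1))
  q <- gmm_quantize(img, 3, seed = 6)
  expect_true(all(diff(q$objective_trace) >= -1e-6))
  se <- 7 / sqrt(400)
  reorder <- apply(relcol:::dist2_to_centers(mu_true, q$palette), 1, which.min)
  expect_lt(max(abs(q$palette[reorder, ] - mu_true)), 3 * se * 3)
  # independent cross-check: mclust on the same sample finds the same means
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))  # Mclust resolves helpers unqualified
  fit <- Mclust(pts, G = 3, modelNames = "VVV", verbose = FALSE)
  mcl <- t(fit$parameters$mean)
  reorder2 <- apply(relcol:::dist2_to_centers(mcl, q$palette), 1, which.min)
  expect_lt(max(abs(q$palette[reorder2, ] - mcl)), 2)
})

test_that("GMM with one component returns the sample moments", {
  set.seed(9)
  pts <- matrix(rnorm(300, 120, 15), 100, 3)
  img <- array(t(pts), c(3, 100, 1)) |> aperm(c(2, 3, 1))
  q <- gmm_quantize(img, 1, seed = 2)
  expect_equal(drop(q$palette), colMeans(pts), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("graph-cut energy is non-increasing and exact on an enumerable instance", {
  scene <- exact_recovery_scene(seed = 21, h = 4, w = 4)
  img <- scene$image[, , , drop = FALSE]
  q <- graphcut_quantize(img, 2, seed = 5, smoothness_weight = 0.2)
  expect_true(all(diff(q$objective_trace) <= 1e-9))
  # rebuild the same energy and enumerate all 2^16 labelings
  x <- relcol:::pixel_matrix(img)
  best_fit <- NULL
  for (r in 1:2) {
    fit <- relcol:::lloyd(x, kmeanspp_init(x, 2, relcol:::child_seed(5, 60 + r)),
                          max_iter = 50)
    if (is.null(best_fit) || fit$trace[length(fit$trace)] <
          best_fit$trace[length(best_fit$trace)]) best_fit <- fit
  }
  d2 <- relcol:::dist2_to_centers(x, best_fit$centers)
  scale <- mean(d2[cbind(1:16, max.col(-d2))]) + 1e-9
  unary <- d2 / scale
  edges <- relcol:::grid_edges(4, 4)
  diff2 <- rowSums((x[edges[, 1], ] - x[edges[, 2], ])^2)
  ew <- 0.2 * exp(-diff2 / (2 * (mean(diff2) + 1e-9)))
  energies <- vapply(0:(2^16 - 1), function(m) {
    lab <- as.integer(intToBits(m))[1:16] + 1L
    relcol:::potts_energy(lab, unary, edges, ew)
  }, numeric(1))
  got <- relcol:::potts_energy(as.vector(q$labels), unary, edges, ew)
  expect_equal(got, min(energies), tolerance = 1e-9)
})

test_that("graph-cut with zero smoothness is exactly nearest-center labeling", {
  scene <- exact_recovery_scene(seed = 31, h = 12, w = 12)
  noisy <- round(pmin(pmax(scene$image +
    array(rnorm(length(scene$image), 0, 5), dim(scene$image)), 0), 255))
  q <- graphcut_quantize(noisy, 3, seed = 7, smoothness_weight = 0)
  px <- relcol:::pixel_matrix(noisy)
  expect_equal(as.vector(q$labels), relcol:::nearest_label(px, q$palette))
})

test_that("apply_palette enforces label integrity and the unique-color bound", {
  scene <- exact_recovery_scene(seed = 41, h = 10, w = 10)
  q <- kmeans_quantize(scene$image, 2, seed = 1)
  out <- apply_palette(scene$image, q)
  expect_lte(n_unique_colors(out), 2L)
  q_bad <- q; q_bad$labels[1] <- 99L
  expect_error(apply_palette(scene$image, q_bad),
               class = "relcol_integrity_error")
})

test_that("every quantizer returns exactly n clusters and is seed-deterministic", {
  scene <- exact_recovery_scene(seed = 51, h = 24, w = 24)
  noisy <- round(pmin(pmax(scene$image +
    array(rnorm(length(scene$image), 0, 6), dim(scene$image)), 0), 255))
  makers <- list(
    kmeans = function(s) kmeans_quantize(noisy, 5, seed = s),
    mec = function(s) mec_quantize(noisy, 5, seed = s),
    gmm = function(s) gmm_quantize(noisy, 5, seed = s),
    mincentropy = function(s) mincentropy_quantize(noisy, 5, seed = s),
    graphcut = function(s) graphcut_quantize(noisy, 5, seed = s))
  for (nm in names(makers)) {
    q <- makers[[nm]](7)
    expect_equal(q$n, 5L, info = nm)
    expect_setequal(unique(as.vector(q$labels)), 1:5)
    expect_lte(n_unique_colors(apply_palette(noisy, q)), 5L)
    expect_identical(q, makers[[nm]](7), info = nm)
  }
})
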