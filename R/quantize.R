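# The clustering quantizers.  Each returns a `relcol_quantization`: a palette
# of n representative RGB colors, a per-pixel label map, the per-iteration
# objective trace, and the seed, so runs are bit-reproducible.
#
# Megapixel images are clustered on a seeded uniform pixel subsample; label
# assignment and palette estimation always use every pixel.

#' Draw a seeded pixel sample for clustering
#'
#' @param image RGB array.
#' @param max_pixels Largest sample size; if the image has fewer pixels, all
#'   are used.
#' @param seed Integer seed for the subsample.
#' @param space Clustering space: `"rgb"` (default, clusters raw pixel
#'   values) or `"lab"` (CIELAB).
#' @return `N x 3` matrix of colors in the clustering space, with attributes
#'   `seed`, `space` and `idx` (pixel indices drawn).
#' @export
pixel_sample <- function(image, max_pixels = 1e5, seed = 1, space = "rgb") {
  px <- pixel_matrix(image)
  n_px <- nrow(px)
  idx <- if (n_px > max_pixels) {
    with_rng(seed, sample.int(n_px, max_pixels))
  } else {
    seq_len(n_px)
  }
  x <- px[idx, , drop = FALSE]
  if (space == "lab") x <- srgb_to_lab(x)
  structure(x, seed = seed, space = space, idx = idx)
}

#' k-means++ seeding
#'
#' D-squared seeding: the first center is drawn uniformly (or by weight),
#' each subsequent center with probability proportional to the squared
#' distance to the nearest center already chosen.
#'
#' @param x `N x d` matrix of points.
#' @param n Number of centers (>= 1); must not exceed the number of
#'   distinct rows.
#' @param seed Integer seed.
#' @param weights Optional non-negative multiplicity per row.
#' @return `n x d` matrix of initial centers.
#' @export
kmeanspp_init <- function(x, n, seed = 1, weights = NULL) {
  x <- as.matrix(x)
  if (n < 1) abort("`n` must be >= 1.", class = "relcol_config_error")
  if (nrow(unique(x)) < n) {
    abort("fewer distinct points than requested centers.",
          class = "relcol_domain_error")
  }
  w <- weights %||% rep(1, nrow(x))
  with_rng(seed, {
    centers <- matrix(0, n, ncol(x))
    first <- sample.int(nrow(x), 1L, prob = w)
    centers[1L, ] <- x[first, ]
    if (n > 1L) {
      d2 <- rowSums(sweep(x, 2L, centers[1L, ])^2)
      for (k in 2:n) {
        p <- w * d2
        nxt <- if (sum(p) > 0) {
          sample.int(nrow(x), 1L, prob = p)
        } else {
          # all remaining mass sits on already-chosen colors; take any
          # point distinct from the current centers
          which(!duplicated(rbind(centers[seq_len(k - 1L), , drop = FALSE], x))[
            -seq_len(k - 1L)])[1L]
        }
        centers[k, ] <- x[nxt, ]
        d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[k, ])^2))
      }
    }
    centers
  })
}

# Lloyd iterations with weighted points.  Empty clusters are re-seeded from
# the point farthest from its current center, preserving exactly n clusters.
lloyd <- function(x, centers, weights = NULL, max_iter = 300, tol = 1e-6) {
  w <- weights %||% rep(1, nrow(x))
  labels <- rep(0L, nrow(x))
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    d2 <- dist2_to_centers(x, centers)
    new_labels <- max.col(-d2, ties.method = "first")
    # re-seed empty clusters from the farthest point; the point is assigned
    # outright so duplicate centers or distance ties cannot cycle
    repeat {
      empty <- setdiff(seq_len(nrow(centers)), unique(new_labels))
      if (length(empty) == 0L) break
      dmin <- d2[cbind(seq_len(nrow(x)), new_labels)]
      far <- which.max(dmin)
      centers[empty[1L], ] <- x[far, ]
      d2[, empty[1L]] <- rowSums(sweep(x, 2L, centers[empty[1L], ])^2)
      new_labels <- max.col(-d2, ties.method = "first")
      new_labels[far] <- empty[1L]
    }
    obj <- sum(w * d2[cbind(seq_len(nrow(x)), new_labels)])
    trace <- c(trace, obj)
    converged <- identical(new_labels, labels) ||
      (it > 1L && abs(trace[it - 1L] - obj) <= tol * max(trace[it - 1L], 1e-12))
    labels <- new_labels
    for (k in seq_len(nrow(centers))) {
      sel <- labels == k
      centers[k, ] <- colSums(x[sel, , drop = FALSE] * w[sel]) / sum(w[sel])
    }
    if (converged) break
  }
  list(centers = centers, labels = labels, trace = trace)
}

new_quantization <- function(palette, labels, dim_hw, n, method, trace = NULL,
                             seed = NA_integer_, flags = character(0),
                             meta = list()) {
  structure(list(
    palette = palette, labels = matrix(as.integer(labels), dim_hw[1], dim_hw[2]),
    n = as.integer(n), method = method, objective_trace = trace,
    seed = seed, flags = flags, meta = meta),
    class = "relcol_quantization")
}

#' @export
print.relcol_quantization <- function(x, ...) {
  cat(sprintf("<relcol_quantization> method=%s n=%d pixels=%d%s\n",
              x$method, x$n, length(x$labels),
              if (length(x$flags)) paste0(" flags=", paste(x$flags, collapse = ","))
              else ""))
  invisible(x)
}

#' @export
tidy.relcol_quantization <- function(x, ...) {
  counts <- tabulate(x$labels, nbins = x$n)
  tibble(label = seq_len(x$n), R = x$palette[, 1], G = x$palette[, 2],
         B = x$palette[, 3], pixels = counts,
         fraction = counts / length(x$labels))
}

#' @export
glance.relcol_quantization <- function(x, ...) {
  tibble(method = x$method, n = x$n,
         objective = if (length(x$objective_trace))
           x$objective_trace[length(x$objective_trace)] else NA_real_,
         iterations = length(x$objective_trace),
         flags = paste(x$flags, collapse = ";"))
}

# Assign every pixel of the full image to its nearest center (in the
# clustering space), repair empty clusters, and set the palette to the
# per-cluster mean RGB of the pixels actually assigned.
finalize_quantization <- function(image, centers, method, trace, seed,
                                  space = "rgb", flags = character(0),
                                  meta = list()) {
  px <- pixel_matrix(image)
  xs <- if (space == "lab") srgb_to_lab(px) else px
  d2 <- dist2_to_centers(xs, centers)
  labels <- max.col(-d2, ties.method = "first")
  repeat {
    empty <- setdiff(seq_len(nrow(centers)), unique(labels))
    if (length(empty) == 0L) break
    flags <- union(flags, "reseeded_empty_cluster")
    dmin <- d2[cbind(seq_len(nrow(px)), labels)]
    far <- which.max(dmin)
    labels[far] <- empty[1L]
    d2[far, ] <- Inf; d2[far, empty[1L]] <- 0
  }
  palette <- t(vapply(seq_len(nrow(centers)), function(k) {
    colMeans(px[labels == k, , drop = FALSE])
  }, numeric(3)))
  colnames(palette) <- c("R", "G", "B")
  new_quantization(palette, labels, dim(image)[1:2], nrow(centers), method,
                   trace, seed, flags, meta)
}

#' Quantize an image by k-means++
#'
#' Lloyd iterations from a k-means++ seeding, restarted `restarts` times
#' with derived seeds; the run with the lowest within-cluster sum of squares
#' wins.
#'
#' @param image RGB array.
#' @param n Number of relevant colors (clusters).
#' @param seed Integer seed; fixed seed implies a bit-identical result.
#' @param restarts Independent k-means++ starts (default 5).
#' @param max_pixels Clustering subsample size (see [pixel_sample()]).
#' @param space `"rgb"` or `"lab"`.
#' @param max_iter,tol Lloyd iteration controls.
#' @return A `relcol_quantization`.
#' @export
kmeans_quantize <- function(image, n, seed = 1, restarts = 5,
                            max_pixels = 1e5, space = "rgb",
                            max_iter = 300, tol = 1e-6) {
  x <- pixel_sample(image, max_pixels, child_seed(seed, 1L), space)
  best <- NULL
  for (r in seq_len(restarts)) {
    init <- kmeanspp_init(x, n, child_seed(seed, 10L + r))
    fit <- lloyd(x, init, max_iter = max_iter, tol = tol)
    if (is.null(best) || fit$trace[length(fit$trace)] <
          best$trace[length(best$trace)]) best <- fit
  }
  finalize_quantization(image, best$centers, "kmeans", best$trace, seed, space)
}

#' Quantize an image by maximum-entropy clustering
#'
#' Soft memberships of Gibbs form: alternating minimization of
#' \eqn{\sum_{ik} u_{ik} d_{ik} + T \sum_{ik} u_{ik} \ln u_{ik}} where
#' `d_ik` is squared distance to center k.  The membership update is the
#' softmax \eqn{u_{ik} \propto e^{-d_{ik}/T}}; the temperature T controls the
#' entropy penalty, and as T drops to zero the labels coincide with k-means.
#' Final hard labels are by maximum membership.
#'
#' @inheritParams kmeans_quantize
#' @param temperature Temperature T (> 0).  Default: the mean within-cluster
#'   variance of the k-means++ initialization.
#' @return A `relcol_quantization`; `objective_trace` is non-increasing.  A
#'   `"not_converged"` flag marks hitting `max_iter`.
#' @export
mec_quantize <- function(image, n, seed = 1, temperature = NULL,
                         max_pixels = 1e5, space = "rgb",
                         max_iter = 300, tol = 1e-6) {
  if (!is.null(temperature) && temperature <= 0) {
    abort("`temperature` must be positive.", class = "relcol_config_error")
  }
  x <- pixel_sample(image, max_pixels, child_seed(seed, 1L), space)
  centers <- kmeanspp_init(x, n, child_seed(seed, 2L))
  d2 <- dist2_to_centers(x, centers)
  if (is.null(temperature)) {
    temperature <- max(mean(d2[cbind(seq_len(nrow(x)),
                                     max.col(-d2, ties.method = "first"))]),
                       1e-8)
  }
  trace <- numeric(0)
  flags <- character(0)
  for (it in seq_len(max_iter)) {
    # membership update: row-wise softmax of -d2/T (stable in log space)
    z <- -d2 / temperature
    z <- z - apply(z, 1L, max)
    u <- exp(z); u <- u / rowSums(u)
    ent <- sum(u[u > 0] * log(u[u > 0]))
    obj <- sum(u * d2) + temperature * ent
    trace <- c(trace, obj)
    if (it > 1L && abs(trace[it - 1L] - obj) <=
          tol * max(abs(trace[it - 1L]), 1e-12)) break
    mass <- colSums(u)
    mass[mass < 1e-12] <- 1e-12
    centers <- crossprod(u, x) / mass
    d2 <- dist2_to_centers(x, centers)
    if (it == max_iter) flags <- c(flags, "not_converged")
  }
  finalize_quantization(image, centers, "mec", trace, seed, space, flags,
                        meta = list(temperature = temperature))
}

# Eigendecompose a covariance with an eigenvalue floor; reused across the
# E-step so each component is decomposed once per iteration.
gauss_decomp <- function(sigma, floor_eig) {
  es <- eigen(sigma, symmetric = TRUE)
  floored <- any(es$values < floor_eig)
  list(vectors = es$vectors, values = pmax(es$values, floor_eig),
       floored = floored)
}

# Log density of rows of x under N(mu, Sigma) given its decomposition.
gauss_logdens <- function(x, mu, dec) {
  xc <- sweep(x, 2L, mu)
  proj <- xc %*% dec$vectors
  maha <- proj^2 %*% (1 / dec$values)
  -0.5 * (ncol(x) * log(2 * pi) + sum(log(dec$values)) + maha)
}

#' Quantize an image by a Gaussian mixture model (EM)
#'
#' Expectation-maximization on a mixture of `n` Gaussians (full or diagonal
#' covariance), initialized from the hard k-means++ partition (means,
#' covariances and membership weights).  Covariances are regularized with an
#' eigenvalue floor, flagged when it binds.  Hard labels by maximum
#' responsibility; the palette holds the responsibility-weighted component
#' means.
#'
#' @inheritParams kmeans_quantize
#' @param cov_type `"full"` or `"diag"` covariance.
#' @param floor_frac Eigenvalue floor as a fraction of the total data
#'   variance.
#' @return A `relcol_quantization`; `objective_trace` is the log-likelihood
#'   per iteration (non-decreasing while the floor is inactive).
#' @export
gmm_quantize <- function(image, n, seed = 1, max_pixels = 1e5, space = "rgb",
                         cov_type = c("full", "diag"), max_iter = 300,
                         tol = 1e-6, floor_frac = 1e-6) {
  cov_type <- match.arg(cov_type)
  x <- pixel_sample(image, max_pixels, child_seed(seed, 1L), space)
  init <- lloyd(x, kmeanspp_init(x, n, child_seed(seed, 2L)), max_iter = 20)
  floor_eig <- max(floor_frac * sum(apply(x, 2L, var)), 1e-10)
  flags <- character(0)

  mu <- init$centers
  sig <- lapply(seq_len(n), function(k) {
    sel <- init$labels == k
    s <- if (sum(sel) > 1L) stats::cov(x[sel, , drop = FALSE]) else
      diag(ncol(x))
    if (cov_type == "diag") s <- diag(diag(s), ncol(x))
    s
  })
  wts <- tabulate(init$labels, n) / nrow(x)

  ll_trace <- numeric(0)
  dec <- lapply(sig, gauss_decomp, floor_eig = floor_eig)
  for (it in seq_len(max_iter)) {
    ld <- vapply(seq_len(n), function(k) {
      as.vector(gauss_logdens(x, mu[k, ], dec[[k]])) + log(wts[k])
    }, numeric(nrow(x)))
    m <- apply(ld, 1L, max)
    lse <- m + log(rowSums(exp(ld - m)))
    ll <- sum(lse)
    ll_trace <- c(ll_trace, ll)
    resp <- exp(ld - lse)
    if (it > 1L && abs(ll - ll_trace[it - 1L]) <=
          tol * max(abs(ll_trace[it - 1L]), 1)) break
    nk <- colSums(resp)
    nk[nk < 1e-10] <- 1e-10
    wts <- nk / nrow(x)
    mu <- crossprod(resp, x) / nk
    for (k in seq_len(n)) {
      xc <- sweep(x, 2L, mu[k, ])
      s <- crossprod(xc * resp[, k], xc) / nk[k]
      if (cov_type == "diag") s <- diag(diag(s), ncol(x))
      sig[[k]] <- s
      dec[[k]] <- gauss_decomp(s, floor_eig)
      if (dec[[k]]$floored) flags <- union(flags, "covariance_floored")
    }
  }

  # full-image responsibilities for the hard labels
  px <- pixel_matrix(image)
  xs <- if (space == "lab") srgb_to_lab(px) else px
  ld_full <- vapply(seq_len(n), function(k) {
    as.vector(gauss_logdens(xs, mu[k, ], dec[[k]])) + log(wts[k])
  }, numeric(nrow(xs)))
  labels <- max.col(ld_full, ties.method = "first")
  empty <- setdiff(seq_len(n), unique(labels))
  if (length(empty)) {
    return(finalize_quantization(image, mu, "gmm", ll_trace, seed, space,
                                 union(flags, "reseeded_empty_cluster")))
  }
  palette <- if (space == "lab") lab_to_srgb(mu) else mu
  colnames(palette) <- c("R", "G", "B")
  new_quantization(palette, labels, dim(image)[1:2], n, "gmm", ll_trace,
                   seed, flags)
}

#' Apply a quantization's palette to an image
#'
#' Replaces every pixel by its cluster's palette color.  The output has at
#' most `n` unique colors.
#'
#' @param image RGB array the quantization was fitted to (used for its
#'   dimensions).
#' @param quantization A `relcol_quantization` whose labels cover the pixel
#'   grid.
#' @return RGB array of the same dimensions.
#' @export
apply_palette <- function(image, quantization) {
  assert_rgb_image(image)
  labels <- as.vector(quantization$labels)
  if (length(labels) != prod(dim(image)[1:2])) {
    abort("labels do not cover the pixel grid.",
          class = "relcol_dimension_error")
  }
  if (any(labels < 1L | labels > quantization$n)) {
    abort("label out of range.", class = "relcol_integrity_error")
  }
  matrix_to_image(quantization$palette[labels, , drop = FALSE],
                  dim(image)[1], dim(image)[2])
}
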