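# Objective estimation of the number of relevant colors: scan internal
# cluster-validity indices over a range of n, or grow clusters adaptively
# without a predetermined n.  Index formulas are computed directly (closed
# forms); the k-means fits at each n reuse the package's k-means++/Lloyd
# machinery with a per-n derived seed so curves are reproducible pointwise.

# Variance-ratio criterion (between/within dispersion ratio).
calinski_harabasz_index <- function(x, labels, centers) {
  N <- nrow(x); n <- nrow(centers)
  gm <- colMeans(x)
  sizes <- tabulate(labels, n)
  ssb <- sum(sizes * rowSums(sweep(centers, 2L, gm)^2))
  ssw <- sum((x - centers[labels, , drop = FALSE])^2)
  (ssb / (n - 1)) / (ssw / (N - n))
}

# Mean over clusters of the worst (within_i + within_j) / between_ij ratio.
davies_bouldin_index <- function(x, labels, centers) {
  n <- nrow(centers)
  s <- vapply(seq_len(n), function(k) {
    sel <- labels == k
    mean(sqrt(rowSums(sweep(x[sel, , drop = FALSE], 2L, centers[k, ])^2)))
  }, numeric(1))
  m <- as.matrix(stats::dist(centers))
  r <- vapply(seq_len(n), function(i) {
    max(((s[i] + s[-i]) / m[i, -i]))
  }, numeric(1))
  mean(r)
}

new_nscan <- function(method, curve, n_opt, n_range, seed, flags = character(0)) {
  structure(list(method = method, curve = curve, n_opt = n_opt,
                 n_range = n_range, seed = seed, flags = flags),
            class = "relcol_nscan")
}

#' @export
print.relcol_nscan <- function(x, ...) {
  cat(sprintf("<relcol_nscan> %s: n_opt = %d (scanned %d..%d)%s\n", x$method,
              x$n_opt, x$n_range[1], x$n_range[2],
              if (length(x$flags)) paste0(" flags=", paste(x$flags, collapse = ","))
              else ""))
  invisible(x)
}

#' @export
tidy.relcol_nscan <- function(x, ...) x$curve

#' @export
glance.relcol_nscan <- function(x, ...) {
  tibble(method = x$method, n_opt = x$n_opt,
         n_min = x$n_range[1], n_max = x$n_range[2], seed = x$seed)
}

index_scan <- function(x, n_min, n_max, seed, index_fn, pick, method) {
  if (n_min < 2 || n_min > n_max) {
    abort("need 2 <= n_min <= n_max.", class = "relcol_config_error")
  }
  x <- as.matrix(x)
  flags <- character(0)
  n_distinct <- nrow(unique(x))
  if (n_max >= n_distinct) {
    n_max <- n_distinct - 1L
    flags <- "n_max_clamped"
    if (n_max < n_min) {
      abort("too few distinct colors to scan.", class = "relcol_domain_error")
    }
  }
  vals <- vapply(n_min:n_max, function(n) {
    init <- kmeanspp_init(x, n, child_seed(seed, n))
    fit <- lloyd(x, init, max_iter = 100)
    index_fn(x, fit$labels, fit$centers)
  }, numeric(1))
  curve <- tibble(n = n_min:n_max, index = vals, method = method)
  n_opt <- curve$n[pick(vals)]
  new_nscan(method, curve, n_opt, c(n_min, n_max), seed, flags)
}

#' Select the number of clusters by the Calinski-Harabasz criterion
#'
#' k-means at every candidate n; the variance-ratio criterion
#' `(SSB / (n - 1)) / (SSW / (N - n))` is evaluated and the n with the
#' highest value selected.
#'
#' @param sample `N x 3` matrix of colors (e.g. from [pixel_sample()]).
#' @param n_min,n_max Scan bounds (`n_min >= 2`); `n_max` is clamped (and
#'   flagged) if it reaches the number of distinct colors.
#' @param seed Integer seed; each n uses a seed derived from `seed + n`.
#' @return A `relcol_nscan` with the selected `n_opt` and the full index
#'   curve.
#' @export
calinski_harabasz_scan <- function(sample, n_min = 2, n_max = 40, seed = 1) {
  index_scan(sample, n_min, n_max, seed, calinski_harabasz_index,
             which.max, "calinski_harabasz")
}

#' Select the number of clusters by the Davies-Bouldin index
#'
#' As [calinski_harabasz_scan()] but minimizing the Davies-Bouldin
#' within-to-between distance ratio.
#'
#' @inheritParams calinski_harabasz_scan
#' @return A `relcol_nscan`.
#' @export
davies_bouldin_scan <- function(sample, n_min = 2, n_max = 80, seed = 1) {
  index_scan(sample, n_min, n_max, seed, davies_bouldin_index,
             which.min, "davies_bouldin")
}

#' Adaptive k-means without a predetermined number of clusters
#'
#' Starts from a single center at the per-channel image mean; any pixel
#' farther than `distance_threshold` (RGB units, Euclidean) from every
#' center spawns a new center at the most distant such pixel; centers are
#' then updated as cluster means until assignments stabilize, clusters that
#' attract no pixels are dropped, and centers closer together than the
#' spawn threshold merge into their weighted mean -- so final clusters are
#' mutually separated by at least the threshold and jointly cover every
#' pixel within it.  Deterministic: no randomness is involved.
#'
#' @param image RGB array.
#' @param distance_threshold Spawn distance in RGB units (> 0).
#' @param max_pixels Subsample cap (deterministic thinning).
#' @param max_n Hard cap on the number of clusters; exceeding it aborts.
#' @return List with `scan` (a `relcol_nscan` whose `n_opt` is the final
#'   cluster count) and `quantization` (a `relcol_quantization`).
#' @export
adaptive_kmeans <- function(image, distance_threshold = 32, max_pixels = 1e5,
                            max_n = 1024) {
  assert_rgb_image(image)
  if (distance_threshold <= 0) {
    abort("`distance_threshold` must be positive.",
          class = "relcol_config_error")
  }
  px <- pixel_matrix(image)
  x <- if (nrow(px) > max_pixels) {
    px[round(seq(1, nrow(px), length.out = max_pixels)), , drop = FALSE]
  } else px
  thr2 <- distance_threshold^2

  centers <- matrix(colMeans(x), 1L)
  trace <- numeric(0)
  for (outer in seq_len(200)) {
    repeat {  # spawn phase: farthest uncovered pixel becomes a center
      dmin <- dist2_to_centers(x, centers)
      dmin <- dmin[cbind(seq_len(nrow(x)), max.col(-dmin, ties.method = "first"))]
      if (max(dmin) <= thr2) break
      if (nrow(centers) >= max_n) {
        abort("adaptive k-means exceeded the cluster cap; increase the threshold.",
              class = "relcol_domain_error")
      }
      centers <- rbind(centers, x[which.max(dmin), ])
    }
    # mean updates; clusters that attract no pixels are dropped, since the
    # grower has no fixed n to preserve
    moved <- FALSE
    for (it in seq_len(100)) {
      d2 <- dist2_to_centers(x, centers)
      labels <- max.col(-d2, ties.method = "first")
      keep <- sort(unique(labels))
      if (length(keep) < nrow(centers)) {
        centers <- centers[keep, , drop = FALSE]
        labels <- match(labels, keep)
      }
      new_centers <- t(vapply(seq_len(nrow(centers)), function(k)
        colMeans(x[labels == k, , drop = FALSE]), numeric(ncol(x))))
      trace <- c(trace, sum((x - new_centers[labels, , drop = FALSE])^2))
      delta <- max(abs(new_centers - centers))
      centers <- new_centers
      if (delta < 1e-9) break
    }
    # merge phase: centers closer than the spawn threshold collapse to their
    # weighted mean, so clusters stay mutually separated by the threshold
    repeat {
      if (nrow(centers) < 2L) break
      cd <- as.matrix(stats::dist(centers))
      diag(cd) <- Inf
      if (min(cd) >= distance_threshold) break
      pair <- which(cd == min(cd), arr.ind = TRUE)[1L, ]
      sizes <- tabulate(max.col(-dist2_to_centers(x, centers),
                                ties.method = "first"), nrow(centers))
      w <- sizes[pair] / max(sum(sizes[pair]), 1L)
      centers[pair[1L], ] <- w[1L] * centers[pair[1L], ] +
        w[2L] * centers[pair[2L], ]
      centers <- centers[-pair[2L], , drop = FALSE]
    }
    dmin <- dist2_to_centers(x, centers)
    dmin <- dmin[cbind(seq_len(nrow(x)), max.col(-dmin, ties.method = "first"))]
    if (max(dmin) <= thr2) break  # stable and fully covered
  }
  n <- nrow(centers)
  q <- finalize_quantization(image, centers, "adaptive_kmeans", trace,
                             NA_integer_,
                             meta = list(distance_threshold = distance_threshold))
  scan <- new_nscan("adaptive_kmeans",
                    tibble(n = n, index = NA_real_, method = "adaptive_kmeans"),
                    n, c(1L, max_n), NA_integer_)
  list(scan = scan, quantization = q)
}
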