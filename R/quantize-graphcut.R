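# Graph-cut quantizer: Potts energy over the pixel grid,
#   E(f) = sum_p U(p, f_p) + lambda * sum_{(p,q)} w_pq [f_p != f_q],
# with data terms U from squared color distance to the k-means palette and
# edge affinities w_pq from local color similarity.  Minimized by iterated
# alpha-expansion; each expansion move is a binary submodular energy solved
# exactly as an s-t min cut (igraph max-flow).

# One alpha-expansion move.  labels: current labeling; returns new labeling.
# unary: G x n matrix; edges: 2-column index matrix; ew: lambda * w per edge.
expand_label <- function(labels, alpha, unary, edges, ew) {
  G <- nrow(unary)
  theta0 <- unary[cbind(seq_len(G), labels)]  # keep own label
  theta1 <- unary[, alpha]                    # take alpha
  fixed <- labels == alpha
  theta0[fixed] <- theta1[fixed]

  cap_pair <- numeric(0)
  pair_from <- integer(0); pair_to <- integer(0)
  if (nrow(edges) > 0 && any(ew > 0)) {
    fp <- labels[edges[, 1]]; fq <- labels[edges[, 2]]
    A <- ew * (fp != fq)        # (keep, keep)
    B <- ew * (fp != alpha)     # (keep, alpha)
    C <- ew * (alpha != fq)     # (alpha, keep)
    # D = 0; decomposition: theta_p(1) += C - A ; theta_q(1) += -C ;
    # pairwise penalty B + C - A on (x_p = 0, x_q = 1), an s-t edge q -> p.
    inc1 <- tapply(C - A, edges[, 1], sum)
    theta1[as.integer(names(inc1))] <- theta1[as.integer(names(inc1))] + inc1
    inc2 <- tapply(-C, edges[, 2], sum)
    theta1[as.integer(names(inc2))] <- theta1[as.integer(names(inc2))] + inc2
    cap <- B + C - A
    keep <- cap > 1e-14
    pair_from <- edges[keep, 2]; pair_to <- edges[keep, 1]
    cap_pair <- cap[keep]
  }

  shift <- pmin(theta0, theta1)
  c0 <- theta0 - shift  # capacity s -> p (paid when x_p = 0)
  c1 <- theta1 - shift  # capacity p -> t (paid when x_p = 1)

  s <- G + 1L; t <- G + 2L
  from <- c(rep(s, G), seq_len(G), pair_from)
  to <- c(seq_len(G), rep(t, G), pair_to)
  cap_all <- c(c0, c1, cap_pair)
  pos <- cap_all > 0
  g <- igraph::make_empty_graph(n = G + 2L, directed = TRUE)
  g <- igraph::add_edges(g, rbind(from[pos], to[pos]))
  igraph::E(g)$capacity <- cap_all[pos]
  fl <- igraph::max_flow(g, source = s, target = t)
  take <- rep(FALSE, G)
  part <- setdiff(as.integer(fl$partition1), s)
  take[part] <- TRUE
  new_labels <- labels
  new_labels[take] <- alpha
  new_labels
}

potts_energy <- function(labels, unary, edges, ew) {
  e <- sum(unary[cbind(seq_along(labels), labels)])
  if (nrow(edges)) {
    e <- e + sum(ew * (labels[edges[, 1]] != labels[edges[, 2]]))
  }
  e
}

# 4-connected neighbor index pairs of an h x w grid (column-major indices).
grid_edges <- function(h, w) {
  idx <- matrix(seq_len(h * w), h, w)
  rbind(cbind(as.vector(idx[-h, , drop = FALSE]),
              as.vector(idx[-1, , drop = FALSE])),
        cbind(as.vector(idx[, -w, drop = FALSE]),
              as.vector(idx[, -1, drop = FALSE])))
}

#' Quantize an image by graph-cut energy minimization
#'
#' Potts smoothness over the 4-connected pixel grid with color-similarity
#' edge weights, data terms from a k-means palette, minimized by iterated
#' alpha-expansion (exact s-t min-cut subproblems).  With
#' `smoothness_weight = 0` the labeling is exactly the nearest-palette
#' assignment.  Large images are cut on a spatially subsampled grid
#' (`<= grid_max` per side); off-grid pixels take the nearest palette color.
#'
#' @inheritParams kmeans_quantize
#' @param smoothness_weight Potts weight lambda (>= 0).
#' @param grid_max Largest grid side used for the cut.
#' @param max_sweeps Expansion sweeps over all labels.
#' @return A `relcol_quantization`; `objective_trace` holds the energy after
#'   each accepted expansion and is non-increasing.
#' @export
graphcut_quantize <- function(image, n, seed = 1, smoothness_weight = 1,
                              grid_max = 256, max_sweeps = 5, restarts = 2) {
  assert_rgb_image(image)
  if (smoothness_weight < 0) {
    abort("`smoothness_weight` must be >= 0.", class = "relcol_config_error")
  }
  d <- dim(image)
  ri <- unique(round(seq(1, d[1], length.out = min(d[1], grid_max))))
  ci <- unique(round(seq(1, d[2], length.out = min(d[2], grid_max))))
  sub <- image[ri, ci, , drop = FALSE]
  x <- pixel_matrix(sub)
  G <- nrow(x)

  # k-means initialization on the grid pixels
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- lloyd(x, kmeanspp_init(x, n, child_seed(seed, 60L + r)),
                 max_iter = 50)
    if (is.null(best) || fit$trace[length(fit$trace)] <
          best$trace[length(best$trace)]) best <- fit
  }
  centers <- best$centers
  labels <- best$labels

  d2 <- dist2_to_centers(x, centers)
  scale <- mean(d2[cbind(seq_len(G), max.col(-d2, ties.method = "first"))]) + 1e-9
  unary <- d2 / scale

  edges <- grid_edges(length(ri), length(ci))
  diff2 <- rowSums((x[edges[, 1], , drop = FALSE] -
                    x[edges[, 2], , drop = FALSE])^2)
  sigma2 <- mean(diff2) + 1e-9
  ew <- smoothness_weight * exp(-diff2 / (2 * sigma2))

  energy <- potts_energy(labels, unary, edges, ew)
  trace <- energy
  flags <- character(0)
  if (n > 1L) {
    for (sweep in seq_len(max_sweeps)) {
      improved <- FALSE
      for (alpha in seq_len(n)) {
        cand <- tryCatch(expand_label(labels, alpha, unary, edges, ew),
                         error = function(e) NULL)
        if (is.null(cand)) { flags <- union(flags, "maxflow_failed"); next }
        e_new <- potts_energy(cand, unary, edges, ew)
        if (e_new < energy - 1e-12) {
          labels <- cand; energy <- e_new; improved <- TRUE
          trace <- c(trace, energy)
        }
      }
      if (!improved) break
    }
  }
  if ("maxflow_failed" %in% flags) {
    labels <- max.col(-unary, ties.method = "first")  # unary-only fallback
  }

  # repair empty labels to honor the exactly-n contract
  repeat {
    empty <- setdiff(seq_len(n), unique(labels))
    if (!length(empty)) break
    flags <- union(flags, "reseeded_empty_cluster")
    dmin <- d2[cbind(seq_len(G), labels)]
    labels[which.max(dmin)] <- empty[1L]
  }

  palette <- t(vapply(seq_len(n), function(k) {
    colMeans(x[labels == k, , drop = FALSE])
  }, numeric(3)))
  colnames(palette) <- c("R", "G", "B")

  full_labels <- if (length(ri) == d[1] && length(ci) == d[2]) {
    lab_grid <- matrix(labels, length(ri), length(ci))
    as.vector(lab_grid)
  } else {
    nearest_label(pixel_matrix(image), palette)
  }
  new_quantization(palette, full_labels, d[1:2], n, "graphcut", trace, seed,
                   flags, meta = list(lambda = smoothness_weight,
                                      grid = c(length(ri), length(ci))))
}
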