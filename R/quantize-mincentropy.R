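# The reference quantizer: choose cluster labels over the occupied color bins
# to maximize the mutual information I(binned color; cluster label).  Because
# each bin maps to exactly one label, the joint distribution is deterministic
# given the labeling and (with the plug-in estimator) the objective reduces to
# the entropy of the cluster mass distribution; the generic MI identity is
# still what is reported downstream, and tests assert the equality.
#
# Optimization is stochastic local search: hill climbing over single-bin
# reassignments (first-improvement, seeded random scan order) plus, on small
# histograms, pairwise label swaps -- single-bin moves alone provably stall
# on balanced-partition local optima.  Several seeded restarts are taken
# (k-means++ color clustering, a mass-balancing greedy, and random labelings)
# and the best final objective wins, so the result never falls below its
# k-means++ initialization.

# Shannon entropy (bits) of a vector of masses.
mass_entropy <- function(m, total) {
  p <- m[m > 0] / total
  -sum(p * log2(p))
}

#' Quantize an image by mutual-information-maximizing clustering
#'
#' @inheritParams kmeans_quantize
#' @param bin_side Color bin side defining the histogram the optimizer works
#'   on; use the same value as the downstream MI estimate so the objective
#'   and the report coincide.
#' @param restarts Number of optimization starts (>= 1); the first is always
#'   the k-means++ start, the second a mass-balancing greedy start.
#' @param max_sweeps Upper bound on improvement sweeps per start.
#' @param swap_max_bins Pairwise swap moves are tried only when the
#'   histogram has at most this many occupied bins (they are quadratic).
#' @return A `relcol_quantization`; `objective_trace` holds the objective
#'   (bits) after each sweep and is non-decreasing.
#' @export
mincentropy_quantize <- function(image, n, seed = 1, bin_side = 8,
                                 restarts = 3, max_sweeps = 100,
                                 swap_max_bins = 400) {
  hist <- bin_colors(image, bin_side)
  B <- nrow(hist)
  if (B < n) {
    abort("`n` exceeds the number of occupied color bins.",
          class = "relcol_domain_error")
  }
  px <- pixel_matrix(image)
  keys <- bin_keys(px, bin_side)
  ukeys <- sort(unique(keys))
  bin_of_pixel <- match(keys, ukeys)
  m <- hist$count
  total <- sum(m)
  # per-bin mean colors (for the k-means++ start and the palette)
  bin_rgb <- vapply(1:3, function(ch) {
    as.vector(tapply(px[, ch], bin_of_pixel, sum)) / m
  }, numeric(B))

  # Start set: color-coherent labelings (the objective is blind to bin
  # colors, so among its many near-maximizers we steer toward ones whose
  # clusters are also contiguous in color space and therefore renderable --
  # matching how the cited similarity-based method behaves).  The two-way
  # case additionally gets the exact mass-balance search and mass-only
  # heuristics: at n = 2 exact maximization is the method's defining
  # property and rendering is coarse regardless.
  starts <- list()
  starts[[1]] <- local({  # k-means++ & Lloyd on bin colors, mass-weighted
    init <- kmeanspp_init(bin_rgb, n, child_seed(seed, 21L), weights = m)
    lloyd(bin_rgb, init, weights = m, max_iter = 50)$labels
  })
  if (restarts >= 2) starts[[2]] <- pc_slice_labels(bin_rgb, m, n)
  if (n == 2L) {
    starts[[length(starts) + 1L]] <- if (B <= 30L) {
      ckk_partition_labels(m)  # exact two-way balance at small size
    } else {
      kk_partition_labels(m)
    }
    starts[[length(starts) + 1L]] <- balance_greedy_labels(m, n)
    if (restarts >= 3) {
      for (r in 3:restarts) {
        starts[[length(starts) + 1L]] <- with_rng(child_seed(seed, 30L + r), {
          l <- sample.int(n, B, replace = TRUE)
          l[sample.int(B, n)] <- seq_len(n)  # ensure every label occupied
          l
        })
      }
    }
  }

  best <- NULL
  for (r in seq_along(starts)) {
    res <- climb_partition_entropy(m, starts[[r]], n, total,
                                   child_seed(seed, 50L + r), max_sweeps,
                                   B <= swap_max_bins)
    if (is.null(best) || res$obj > best$obj) best <- res
  }

  labels_px <- best$labels[bin_of_pixel]
  palette <- t(vapply(seq_len(n), function(k) {
    sel <- best$labels == k
    colSums(bin_rgb[sel, , drop = FALSE] * m[sel]) / sum(m[sel])
  }, numeric(3)))
  colnames(palette) <- c("R", "G", "B")
  new_quantization(palette, labels_px, dim(image)[1:2], n, "mincentropy",
                   best$trace, seed,
                   meta = list(bin_side = bin_side, objective_bits = best$obj))
}

# Karmarkar-Karp largest-differencing start for the two-cluster case:
# repeatedly commit the two largest masses to opposite sides, re-inserting
# their difference; near-optimal for balanced 2-partitions, where single-bin
# hill climbing alone has many local optima.
kk_partition_labels <- function(m) {
  nodes <- lapply(seq_along(m), function(i) list(v = m[i], a = i, b = integer(0)))
  while (length(nodes) > 1L) {
    vs <- vapply(nodes, `[[`, numeric(1), "v")
    i <- which.max(vs); x <- nodes[[i]]; nodes[[i]] <- NULL
    vs <- vapply(nodes, `[[`, numeric(1), "v")
    j <- which.max(vs); y <- nodes[[j]]; nodes[[j]] <- NULL
    nodes[[length(nodes) + 1L]] <- list(v = x$v - y$v, a = c(x$a, y$b),
                                        b = c(x$b, y$a))
  }
  labels <- integer(length(m))
  labels[nodes[[1]]$a] <- 1L
  labels[nodes[[1]]$b] <- 2L
  labels
}

# Color-coherent balanced start: order bins along the first (mass-weighted)
# principal axis of their colors and slice the ordering into n groups of
# near-equal mass -- balanced like the entropy maximizer wants, contiguous
# in color like a renderable palette needs.
pc_slice_labels <- function(bin_rgb, m, n) {
  mu <- colSums(bin_rgb * m) / sum(m)
  xc <- sweep(bin_rgb, 2L, mu)
  v <- eigen(crossprod(xc * m, xc), symmetric = TRUE)$vectors[, 1L]
  ord <- order(as.vector(bin_rgb %*% v), seq_len(nrow(bin_rgb)))
  target <- sum(m) / n
  labels <- integer(length(m))
  grp <- 1L; acc <- 0
  remaining_bins <- length(m)
  for (i in seq_along(ord)) {
    b <- ord[i]
    labels[b] <- grp
    acc <- acc + m[b]
    remaining_bins <- remaining_bins - 1L
    # close the group when its mass target is met, but keep one bin per
    # remaining group
    if (grp < n && (acc >= grp * target || remaining_bins <= n - grp)) {
      grp <- grp + 1L
    }
  }
  labels
}

# Complete Karmarkar-Karp (Korf): branch on "difference" vs "sum" of the two
# largest masses, pruning when the largest dominates the rest.  Returns the
# optimal two-way balance; entropy of a 2-partition is monotone in balance,
# so this is the exact n = 2 maximizer.  Exponential worst case -- only used
# for small histograms.
ckk_partition_labels <- function(m) {
  best <- NULL
  rec <- function(nodes) {
    if (!is.null(best) && best$v <= m[which.min(m)] * 0) return()  # perfect
    if (length(nodes) == 1L) {
      node <- nodes[[1L]]
      node$v <- abs(node$v)
      if (is.null(best) || node$v < best$v) best <<- node
      return()
    }
    vs <- vapply(nodes, `[[`, numeric(1), "v")
    ord <- order(vs, decreasing = TRUE)
    x <- nodes[[ord[1L]]]; y <- nodes[[ord[2L]]]
    rest <- nodes[ord[-(1:2)]]
    if (x$v >= y$v + sum(vs[ord[-1L]]) - y$v) {
      # largest dominates: put everything else on the other side
      node <- x
      for (z in c(list(y), rest)) {
        node <- list(v = node$v - z$v, a = c(node$a, z$b), b = c(node$b, z$a))
      }
      rec(list(node))
      return()
    }
    rec(c(list(list(v = x$v - y$v, a = c(x$a, y$b), b = c(x$b, y$a))), rest))
    if (!is.null(best) && best$v == 0) return()
    rec(c(list(list(v = x$v + y$v, a = c(x$a, y$a), b = c(x$b, y$b))), rest))
  }
  rec(lapply(seq_along(m), function(i) list(v = m[i], a = i, b = integer(0))))
  labels <- integer(length(m))
  labels[best$a] <- 1L
  labels[best$b] <- 2L
  labels
}

# Greedy balancing start: bins in decreasing mass order, each to the
# currently lightest cluster.
balance_greedy_labels <- function(m, n) {
  ord <- order(m, decreasing = TRUE)
  mass <- numeric(n)
  labels <- integer(length(m))
  for (b in ord) {
    k <- which.min(mass)
    labels[b] <- k
    mass[k] <- mass[k] + m[b]
  }
  labels
}

# Hill climbing on H(cluster masses) with single-bin moves and optional
# pairwise swaps; first improvement; clusters must stay non-empty.
climb_partition_entropy <- function(m, labels, n, total, seed, max_sweeps,
                                    use_swaps) {
  B <- length(m)
  mass <- vapply(seq_len(n), function(k) sum(m[labels == k]), numeric(1))
  size <- tabulate(labels, n)
  hterm <- function(x) ifelse(x > 0, -(x / total) * log2(x / total), 0)
  obj <- sum(hterm(mass))
  trace <- obj
  scan_order <- with_rng(seed, replicate(max_sweeps, sample.int(B),
                                         simplify = FALSE))
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    for (b in scan_order[[sweep]]) {
      l <- labels[b]
      if (size[l] == 1L) next
      base <- hterm(mass[l]) ; base_new <- hterm(mass[l] - m[b])
      for (l2 in seq_len(n)) {
        if (l2 == l) next
        delta <- (base_new + hterm(mass[l2] + m[b])) -
          (base + hterm(mass[l2]))
        if (delta > 1e-12) {
          labels[b] <- l2
          mass[l] <- mass[l] - m[b]; mass[l2] <- mass[l2] + m[b]
          size[l] <- size[l] - 1L; size[l2] <- size[l2] + 1L
          obj <- obj + delta
          improved <- TRUE
          break
        }
      }
    }
    if (use_swaps) {
      for (b1 in seq_len(B - 1L)) for (b2 in (b1 + 1L):B) {
        l1 <- labels[b1]; l2 <- labels[b2]
        if (l1 == l2 || m[b1] == m[b2]) next
        d <- m[b2] - m[b1]
        delta <- (hterm(mass[l1] + d) + hterm(mass[l2] - d)) -
          (hterm(mass[l1]) + hterm(mass[l2]))
        if (delta > 1e-12) {
          labels[b1] <- l2; labels[b2] <- l1
          mass[l1] <- mass[l1] + d; mass[l2] <- mass[l2] - d
          obj <- obj + delta
          improved <- TRUE
        }
      }
    }
    trace <- c(trace, obj)
    if (!improved) break
  }
  list(labels = labels, obj = obj, trace = trace)
}
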