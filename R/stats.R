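# Statistical machinery for summaries: BCa bootstrap intervals, the
# regression of mutual information on log2 n, and the Kruskal-Wallis rank
# test wrapper.

#' BCa bootstrap confidence interval
#'
#' Bias-corrected and accelerated interval for a statistic of a sample: the
#' bias correction comes from the fraction of the bootstrap distribution
#' below the point estimate, the acceleration from jackknife skewness
#' (computed by [boot::boot.ci()]).  Degenerate bootstrap distributions fall
#' back to a percentile interval and are flagged; constant data gives a
#' zero-width interval at the constant.
#'
#' @param values Numeric vector, or data frame resampled by rows.
#' @param statistic Function of a vector (or data frame) returning a single
#'   number.
#' @param replicates Bootstrap replications (>= 100).
#' @param conf Confidence level.
#' @param seed Integer seed.
#' @return One-row tibble: `estimate`, `lower`, `upper`, `conf`, `method`
#'   (`"bca"` or `"percentile"`).
#' @export
bca_bootstrap <- function(values, statistic = mean, replicates = 1000,
                          conf = 0.95, seed = 1) {
  n_obs <- if (is.data.frame(values)) nrow(values) else length(values)
  if (n_obs < 2L) {
    abort("need at least two observations.", class = "relcol_domain_error")
  }
  if (replicates < 100) {
    abort("`replicates` must be >= 100.", class = "relcol_config_error")
  }
  pick <- if (is.data.frame(values)) {
    function(d, i) statistic(d[i, , drop = FALSE])
  } else {
    function(d, i) statistic(d[i])
  }
  est <- pick(values, seq_len(n_obs))
  done <- function(lower, upper, method) {
    tibble(estimate = unname(est), lower = unname(lower),
           upper = unname(upper), conf = conf, method = method)
  }
  bo <- with_rng(seed, boot::boot(values, pick, R = replicates))
  tvals <- bo$t[, 1]
  ok <- is.finite(tvals)  # degenerate resamples (e.g. a collapsed design)
  if (sum(ok) < 2 || sd(tvals[ok]) < .Machine$double.eps^0.5) {
    return(done(est, est, "degenerate"))
  }
  # acceleration from the exact jackknife influence values (the regression
  # estimate boot.ci defaults to is noisier)
  jack <- vapply(seq_len(n_obs), function(i) {
    pick(values, seq_len(n_obs)[-i])
  }, numeric(1))
  L <- (n_obs - 1) * (mean(jack) - jack)
  ci <- if (all(ok) && all(is.finite(L))) {
    # boot.ci warns when adjusted endpoints hit extreme order statistics;
    # that is expected at modest R and the percentile fallback covers it
    tryCatch(suppressWarnings(boot::boot.ci(bo, conf = conf, type = "bca",
                                            L = L)),
             error = function(e) NULL)
  }
  if (!is.null(ci) && !is.null(ci$bca)) {
    done(ci$bca[1, 4], ci$bca[1, 5], "bca")
  } else {
    q <- quantile(tvals[ok], c((1 - conf) / 2, 1 - (1 - conf) / 2),
                  names = FALSE)
    done(q[1], q[2], "percentile")
  }
}

#' Regress mutual information on log2 of the number of relevant colors
#'
#' Ordinary least squares of `I` on `log2(n)` over per-(image, n) rows,
#' with a BCa bootstrap confidence interval for the slope (resampling
#' rows).
#'
#' @param rows Data frame with columns `I` (bits) and `n`; typically a
#'   filtered [run_experiment()] summary.
#' @param replicates,conf,seed Bootstrap controls.
#' @return An object of class `relcol_regression` with `slope`,
#'   `intercept`, `slope_lower`, `slope_upper`, the fitted `model`, and the
#'   data.
#' @export
regression_mi_vs_logn <- function(rows, replicates = 1000, conf = 0.95,
                                  seed = 1) {
  rows <- rows[stats::complete.cases(rows[, c("I", "n")]), , drop = FALSE]
  if (length(unique(rows$n)) < 3L) {
    abort("need at least 3 distinct values of n.",
          class = "relcol_domain_error")
  }
  d <- tibble(I = rows$I, log2n = log2(rows$n))
  fit <- lm(I ~ log2n, data = d)
  ci <- bca_bootstrap(d, function(dd) coef(lm(I ~ log2n, data = dd))[[2]],
                      replicates = replicates, conf = conf, seed = seed)
  structure(list(slope = coef(fit)[[2]], intercept = coef(fit)[[1]],
                 slope_lower = ci$lower, slope_upper = ci$upper,
                 conf = conf, model = fit, data = d),
            class = "relcol_regression")
}

#' @export
print.relcol_regression <- function(x, ...) {
  cat(sprintf("<relcol_regression> I = %.4f + %.4f * log2(n); slope %g%% CI (%.4f, %.4f)\n",
              x$intercept, x$slope, 100 * x$conf, x$slope_lower, x$slope_upper))
  invisible(x)
}

#' @export
tidy.relcol_regression <- function(x, ...) {
  tibble(term = c("(Intercept)", "log2n"),
         estimate = c(x$intercept, x$slope),
         conf.low = c(NA_real_, x$slope_lower),
         conf.high = c(NA_real_, x$slope_upper))
}

#' @export
glance.relcol_regression <- function(x, ...) {
  s <- summary(x$model)
  tibble(r.squared = s$r.squared, sigma = s$sigma,
         nobs = nrow(x$data), slope = x$slope,
         slope_lower = x$slope_lower, slope_upper = x$slope_upper)
}

#' Kruskal-Wallis rank test
#'
#' Rank-based H statistic with tie correction and a chi-squared p value,
#' for comparing groups of efficiencies or of chosen n.  If every value is
#' identical the test is degenerate; by convention H = 0, p = 1, flagged.
#'
#' @param values Numeric vector, or a list of numeric group vectors (then
#'   `groups` is ignored).
#' @param groups Group membership vector parallel to `values`.
#' @return One-row tibble: `statistic` (H), `df`, `p.value`, `flags`.
#' @export
kruskal_wallis <- function(values, groups = NULL) {
  if (is.list(values) && !is.data.frame(values)) {
    groups <- rep(seq_along(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  if (is.null(groups) || length(groups) != length(values)) {
    abort("`groups` must parallel `values`.", class = "relcol_config_error")
  }
  if (length(unique(groups)) < 2L || any(!table(groups))) {
    abort("need >= 2 non-empty groups.", class = "relcol_domain_error")
  }
  if (length(unique(values)) == 1L) {
    return(tibble(statistic = 0, df = length(unique(groups)) - 1,
                  p.value = 1, flags = "degenerate"))
  }
  kt <- kruskal.test(values, factor(groups))
  tibble(statistic = unname(kt$statistic), df = unname(kt$parameter),
         p.value = kt$p.value, flags = "")
}

#' Compare an image with its codec-compressed version
#'
#' Encodes the image as baseline JPEG at the given quality, decodes it,
#' counts unique decoded colors, and scores the decoded image as a
#' quantization: each decoded unique color is a label, MI is estimated
#' against the binned original, and the two mean color differences are
#' computed.  The codec floor quality is 1.
#'
#' @param image RGB array.
#' @param quality JPEG quality, clamped to `[1, 100]`.
#' @param bin_side,estimator MI estimation controls.
#' @param delta_e Compute mean color differences too.
#' @return One-row tibble: `n_colors`, `H_original`, `H_quantized`, `I`,
#'   `delta_e_ucs`, `delta_e_scielab`, `quality`.
#' @export
codec_comparison <- function(image, quality = 1, bin_side = 8,
                             estimator = "grassberger", delta_e = TRUE) {
  assert_rgb_image(image)
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    abort("codec stage requires the 'EBImage' package.",
          class = "relcol_config_error")
  }
  quality <- clamp(round(quality), 1, 100)
  path <- tempfile(fileext = ".jpg")
  on.exit(unlink(path), add = TRUE)
  # libjpeg warns about coarse quantization tables at the lowest qualities
  suppressWarnings(write_image(image, path, quality = quality))
  decoded <- suppressWarnings(read_image(path))

  px <- round(pixel_matrix(decoded))
  key <- (px[, 1] * 256 + px[, 2]) * 256 + px[, 3]
  tab <- tabulate_keys(key)
  labels <- match(key, tab$key)
  info <- image_quantization_mi(image, labels, bin_side, estimator)
  de_ucs <- NA_real_; de_sc <- NA_real_
  if (isTRUE(delta_e)) {
    de_ucs <- mean_delta_e_ucs(image, decoded)$mean_delta_e
    de_sc <- mean_delta_e_scielab(image, decoded)$mean_delta_e
  }
  tibble(n_colors = length(tab$key), H_original = info$H_original,
         H_quantized = info$H_quantized, I = info$I,
         delta_e_ucs = de_ucs, delta_e_scielab = de_sc, quality = quality)
}
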