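# Orchestration: run every quantizer over a corpus at matched numbers of
# relevant colors, estimate MI and efficiency against the reference
# (MI-maximizing) method, summarize with BCa bootstrap limits, regression of
# I on log2 n, rank tests, color-rendering error, and the codec stage.

#' Configure an experiment
#'
#' @param images List of `relcol_synthetic` objects (from
#'   [synthetic_corpus()] / [generate_image()]) or paths to image files.
#' @param methods Clustering quantizers to run; any of `"kmeans"`, `"mec"`,
#'   `"gmm"`, `"mincentropy"`, `"graphcut"`.
#' @param reference Reference method for efficiencies (default
#'   `"mincentropy"`, the MI maximizer).
#' @param n_source Where the numbers of relevant colors come from:
#'   `"observer"` (simulated observers, several n per image),
#'   `"colorimetric"` (one automatic n per image), or `"fixed"`.
#' @param n_fixed Integer vector of n values when `n_source = "fixed"`.
#' @param n_observers Number of simulated observers per image.
#' @param pick_noise Observer location jitter, pixels.
#' @param estimator MI estimator: `"grassberger"` (default) or `"naive"`.
#' @param bin_side Color bin side for MI estimation.
#' @param max_pixels Clustering subsample size.
#' @param delta_e Also compute mean CIECAM02-UCS and S-CIELAB differences
#'   for reference, colorimetric, observer and codec representations (the
#'   color-rendering comparison).
#' @param include_colorimetric,include_codec Run those stages.
#' @param codec_quality JPEG quality for the codec stage (codec floor is 1).
#' @param seed Experiment seed; all stage seeds derive from it.
#' @return An `relcol_experiment_config`.
#' @export
experiment_config <- function(images,
                              methods = c("kmeans", "mec", "gmm",
                                          "mincentropy", "graphcut"),
                              reference = "mincentropy",
                              n_source = c("observer", "colorimetric", "fixed"),
                              n_fixed = NULL,
                              n_observers = 6,
                              pick_noise = 2,
                              estimator = c("grassberger", "naive"),
                              bin_side = 8,
                              max_pixels = 1e5,
                              delta_e = TRUE,
                              include_colorimetric = TRUE,
                              include_codec = FALSE,
                              codec_quality = 1,
                              seed = 1) {
  n_source <- match.arg(n_source)
  estimator <- match.arg(estimator)
  if (length(images) < 1L || length(methods) < 1L) {
    abort("need at least one image and one method.",
          class = "relcol_config_error")
  }
  if (n_source == "fixed" && length(n_fixed) < 1L) {
    abort("`n_fixed` required when n_source = 'fixed'.",
          class = "relcol_config_error")
  }
  if (!reference %in% methods) methods <- c(reference, methods)
  structure(list(images = images, methods = methods, reference = reference,
                 n_source = n_source, n_fixed = n_fixed,
                 n_observers = n_observers, pick_noise = pick_noise,
                 estimator = estimator, bin_side = bin_side,
                 max_pixels = max_pixels, delta_e = delta_e,
                 include_colorimetric = include_colorimetric,
                 include_codec = include_codec,
                 codec_quality = codec_quality, seed = seed),
            class = "relcol_experiment_config")
}

quantize_with <- function(method, image, n, seed, config) {
  switch(method,
    kmeans = kmeans_quantize(image, n, seed, max_pixels = config$max_pixels),
    mec = mec_quantize(image, n, seed, max_pixels = config$max_pixels),
    gmm = gmm_quantize(image, n, seed, max_pixels = config$max_pixels),
    mincentropy = mincentropy_quantize(image, n, seed,
                                       bin_side = config$bin_side),
    graphcut = graphcut_quantize(image, n, seed),
    abort(sprintf("unknown method '%s'.", method),
          class = "relcol_config_error"))
}

load_experiment_image <- function(x) {
  if (inherits(x, "relcol_synthetic")) x$image
  else if (is.character(x)) read_image(x)
  else if (is.array(x)) x
  else abort("images must be synthetic objects, arrays or paths.",
             class = "relcol_config_error")
}

# One scored row.  delta_e columns are NA unless computed.
score_row <- function(image, q, image_id, method, config) {
  info <- image_quantization_mi(image, q, config$bin_side, config$estimator)
  de_ucs <- NA_real_; de_sc <- NA_real_
  if (isTRUE(config$delta_e)) {
    rec <- apply_palette(image, q)
    de_ucs <- mean_delta_e_ucs(image, rec)$mean_delta_e
    de_sc <- mean_delta_e_scielab(image, rec)$mean_delta_e
  }
  tibble(image_id = image_id, method = method, n = q$n,
         H_original = info$H_original, H_quantized = info$H_quantized,
         I = info$I, estimator = config$estimator,
         delta_e_ucs = de_ucs, delta_e_scielab = de_sc,
         n_pairing = "matched", flags = paste(q$flags, collapse = ";"))
}

#' Run the full experiment
#'
#' For every image: determine the numbers of relevant colors n (simulated
#' observers, colorimetric-auto, or a fixed grid), run every clustering
#' method at each n, the reference at each n, the colorimetric and codec
#' stages at the colorimetric n (the pairing used when a method cannot be
#' matched on n), estimate MI and the efficiency \eqn{\eta = I/I_{ref}},
#' and optionally the two mean color differences.  Every row carries its
#' seeds; identical configs give byte-identical summaries.
#'
#' @param config From [experiment_config()].
#' @return Tibble (class `relcol_summary`) of per-(image, method, n) rows;
#'   failures are flagged, not fatal.
#' @export
run_experiment <- function(config) {
  if (!inherits(config, "relcol_experiment_config")) {
    abort("`config` must come from experiment_config().",
          class = "relcol_config_error")
  }
  rows <- list()
  for (i in seq_along(config$images)) {
    synth <- config$images[[i]]
    image <- load_experiment_image(synth)
    image_id <- if (inherits(synth, "relcol_synthetic")) {
      sprintf("synth%02d", i)
    } else sprintf("image%02d", i)
    iseed <- child_seed(config$seed, i)

    # --- numbers of relevant colors, and observer rows where applicable
    observer_qs <- list()
    n_colorimetric <- NULL
    col_q <- NULL
    if (config$include_colorimetric || config$n_source == "colorimetric" ||
        config$include_codec) {
      col_q <- tryCatch(colorimetric_quantize(image), error = function(e) NULL)
      n_colorimetric <- if (!is.null(col_q)) col_q$n
    }
    n_values <- switch(config$n_source,
      fixed = sort(unique(as.integer(config$n_fixed))),
      colorimetric = n_colorimetric,
      observer = {
        if (!inherits(synth, "relcol_synthetic")) {
          abort("observer n source needs synthetic images (ground truth).",
                class = "relcol_config_error")
        }
        n_true <- synth$spec$n_true
        picks <- with_rng(child_seed(iseed, 300L),
                          sample(pmax(2L, n_true + (-2:4)),
                                 config$n_observers, replace = TRUE))
        observer_qs <- lapply(seq_along(picks), function(o) {
          simulate_observer(synth, n_picked = picks[o],
                            pick_noise = config$pick_noise,
                            seed = child_seed(iseed, 400L + o))$quantization
        })
        sort(unique(picks))
      })
    if (is.null(n_values)) next

    # --- clustering methods at every matched n
    for (n in n_values) {
      for (m in config$methods) {
        q <- tryCatch(
          quantize_with(m, image, n, child_seed(iseed, 500L + n), config),
          error = function(e) NULL)
        rows[[length(rows) + 1L]] <- if (is.null(q)) {
          tibble(image_id = image_id, method = m, n = n, H_original = NA_real_,
                 H_quantized = NA_real_, I = NA_real_,
                 estimator = config$estimator, delta_e_ucs = NA_real_,
                 delta_e_scielab = NA_real_, n_pairing = "matched",
                 flags = "stage_failed")
        } else {
          cfg <- config
          # rendering error is reported for the reference representation only
          cfg$delta_e <- isTRUE(config$delta_e) && m == config$reference
          score_row(image, q, image_id, m, cfg)
        }
      }
    }

    # --- observer rows at each observer's own n
    for (q in observer_qs) {
      rows[[length(rows) + 1L]] <- score_row(image, q, image_id, "observer",
                                             config)
    }

    # --- colorimetric stage at its own n, reference re-run at that n
    if (config$include_colorimetric && !is.null(col_q)) {
      rows[[length(rows) + 1L]] <-
        score_row(image, col_q, image_id, "colorimetric", config) |>
        dplyr::mutate(n_pairing = "colorimetric_n")
      if (!n_colorimetric %in% n_values) {
        ref_q <- tryCatch(
          quantize_with(config$reference, image, n_colorimetric,
                        child_seed(iseed, 500L + n_colorimetric), config),
          error = function(e) NULL)
        if (!is.null(ref_q)) {
          rows[[length(rows) + 1L]] <-
            score_row(image, ref_q, image_id, config$reference, config) |>
            dplyr::mutate(n_pairing = "colorimetric_n")
        }
      }
    }

    # --- codec stage (unique decoded colors as the quantized variable)
    if (config$include_codec) {
      cr <- tryCatch(
        codec_comparison(image, quality = config$codec_quality,
                         bin_side = config$bin_side,
                         estimator = config$estimator,
                         delta_e = config$delta_e),
        error = function(e) NULL)
      rows[[length(rows) + 1L]] <- if (is.null(cr)) {
        tibble(image_id = image_id, method = "jpeg", n = NA_integer_,
               H_original = NA_real_, H_quantized = NA_real_, I = NA_real_,
               estimator = config$estimator, delta_e_ucs = NA_real_,
               delta_e_scielab = NA_real_, n_pairing = "colorimetric_n",
               flags = "codec_failed")
      } else {
        tibble(image_id = image_id, method = "jpeg", n = cr$n_colors,
               H_original = cr$H_original, H_quantized = cr$H_quantized,
               I = cr$I, estimator = config$estimator,
               delta_e_ucs = cr$delta_e_ucs,
               delta_e_scielab = cr$delta_e_scielab,
               n_pairing = "colorimetric_n", flags = "")
      }
    }
  }

  out <- dplyr::bind_rows(rows)
  out <- add_efficiency(out, config$reference)
  structure(out, config = config,
            class = c("relcol_summary", class(out)))
}

# Efficiency eta = I / I_ref joined at the same (image, n) for matched rows;
# colorimetric-n rows (colorimetric, jpeg) pair at the colorimetric n.
add_efficiency <- function(rows, reference) {
  ref <- rows |>
    dplyr::filter(.data$method == reference) |>
    dplyr::select("image_id", "n", I_ref = "I") |>
    dplyr::distinct(.data$image_id, .data$n, .keep_all = TRUE)
  matched <- rows |>
    dplyr::filter(.data$method != "jpeg") |>
    dplyr::left_join(ref, by = c("image_id", "n"))
  # jpeg cannot be matched on n; pair with the reference at the
  # colorimetric n (the row the reference holds with colorimetric pairing)
  ref_col <- rows |>
    dplyr::filter(.data$method == reference) |>
    dplyr::semi_join(
      rows |> dplyr::filter(.data$method == "colorimetric"),
      by = c("image_id", "n")) |>
    dplyr::select("image_id", I_ref = "I")
  jpeg <- rows |>
    dplyr::filter(.data$method == "jpeg") |>
    dplyr::left_join(ref_col, by = "image_id")
  dplyr::bind_rows(matched, jpeg) |>
    dplyr::mutate(eta = .data$I / .data$I_ref)
}

#' Aggregate an experiment summary by method
#'
#' Mean efficiency (and mean MI, mean color differences where present) per
#' method, with BCa bootstrap confidence limits on the mean efficiency.
#'
#' @param summary A `relcol_summary` from [run_experiment()].
#' @param replicates Bootstrap replications.
#' @param conf Confidence level.
#' @param seed Bootstrap seed.
#' @return Tibble: method, rows, mean_eta, eta_lower, eta_upper, mean_I,
#'   mean_delta_e_ucs, mean_delta_e_scielab.
#' @export
summarize_experiment <- function(summary, replicates = 1000, conf = 0.95,
                                 seed = 1) {
  summary |>
    dplyr::filter(!is.na(.data$eta)) |>
    dplyr::group_by(.data$method) |>
    dplyr::group_modify(function(d, key) {
      ci <- bca_bootstrap(d$eta, mean, replicates = replicates, conf = conf,
                          seed = child_seed(seed, nrow(d)))
      tibble(rows = nrow(d), mean_eta = mean(d$eta),
             eta_lower = ci$lower, eta_upper = ci$upper,
             mean_I = mean(d$I),
             mean_delta_e_ucs = mean(d$delta_e_ucs, na.rm = TRUE),
             mean_delta_e_scielab = mean(d$delta_e_scielab, na.rm = TRUE))
    }) |>
    dplyr::ungroup()
}

#' Write an experiment summary deterministically
#'
#' Plain CSV with a fixed column order and no timestamps: identical configs
#' produce byte-identical files.
#'
#' @param summary A `relcol_summary`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  df <- as.data.frame(summary)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 12))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "NA",
                   fileEncoding = "UTF-8")
  invisible(path)
}
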