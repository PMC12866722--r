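# The four-step spectral preprocessing chain: cosmic-ray removal, baseline
# correction, Gaussian smoothing and per-spectrum min-max normalization.
# Each step is an individually testable operation on a numeric vector, a
# raman_spectrum or a whole cohort; the pipeline applies them in a
# configurable order (default: despike first so spikes cannot distort the
# baseline fit).

#' Preprocessing configuration
#'
#' @param despike_window odd window (channels, >= 3) for the rolling robust
#'   statistics of the despiker
#' @param despike_z modified z-score threshold above which a channel is
#'   treated as a cosmic-ray artifact
#' @param baseline_lambda smoothness weight of the asymmetric-least-squares
#'   baseline (larger = stiffer baseline)
#' @param baseline_p asymmetry weight in (0, 0.5); points above the baseline
#'   get weight `p`, points below get `1 - p`
#' @param baseline_iters reweighting iterations
#' @param smooth_sigma Gaussian smoothing SD in channels (> 0)
#' @param steps step order; any permutation of
#'   `c("despike", "baseline", "smooth", "normalize")`, possibly omitting
#'   steps (e.g. drop `"normalize"` ahead of peak-ratio analysis)
#' @return an object of class `preprocess_config`
#' @export
preprocess_config <- function(despike_window = 21L, despike_z = 8,
                              baseline_lambda = 1e5, baseline_p = 0.01,
                              baseline_iters = 10L, smooth_sigma = 2,
                              steps = c("despike", "baseline", "smooth",
                                        "normalize")) {
  assert_scalar_num(despike_window, "despike_window", lower = 3)
  if (despike_window %% 2 == 0) stop("despike_window must be odd")
  assert_scalar_num(despike_z, "despike_z", lower = 0)
  assert_scalar_num(baseline_lambda, "baseline_lambda", lower = 0)
  assert_scalar_num(baseline_p, "baseline_p", lower = 1e-12, upper = 0.5)
  assert_scalar_num(baseline_iters, "baseline_iters", lower = 1)
  assert_scalar_num(smooth_sigma, "smooth_sigma", lower = 1e-12)
  known <- c("despike", "baseline", "smooth", "normalize")
  if (!all(steps %in% known) || anyDuplicated(steps))
    stop("steps must be distinct elements of: ", paste(known, collapse = ", "))
  structure(list(despike_window = as.integer(despike_window),
                 despike_z = despike_z, baseline_lambda = baseline_lambda,
                 baseline_p = baseline_p,
                 baseline_iters = as.integer(baseline_iters),
                 smooth_sigma = smooth_sigma, steps = steps),
            class = "preprocess_config")
}

#' Remove cosmic-ray spikes
#'
#' Channels whose modified z-score of the spectrum's second difference
#' (against a rolling window) exceeds `cfg$despike_z` are flagged one at a
#' time, worst first, and replaced by linear interpolation between the
#' nearest unflagged neighbours; all other channels are returned
#' bit-identical. The flagged channel indices are recorded (in `meta` for a
#' [raman_spectrum()], in attribute `"despike_flags"` for a cohort).
#'
#' @param x numeric vector, [raman_spectrum()] or [sers_cohort()]
#' @param cfg a [preprocess_config()]
#' @return same type as `x`
#' @export
remove_cosmic_rays <- function(x, cfg = preprocess_config()) {
  UseMethod("remove_cosmic_rays")
}

#' @export
remove_cosmic_rays.numeric <- function(x, cfg = preprocess_config()) {
  r <- despike_cpp(x, cfg$despike_window, cfg$despike_z)
  structure(r$intensity, flagged = r$flagged)
}

#' @export
remove_cosmic_rays.raman_spectrum <- function(x, cfg = preprocess_config()) {
  r <- despike_cpp(x$intensity, cfg$despike_window, cfg$despike_z)
  x$intensity <- r$intensity
  x$meta$despiked_channels <- r$flagged
  x
}

#' @export
remove_cosmic_rays.sers_cohort <- function(x, cfg = preprocess_config()) {
  r <- tryCatch(
    despike_mat_cpp(x$intensities, cfg$despike_window, cfg$despike_z),
    error = function(e) {
      # locate the offending spectrum for a useful message
      for (i in seq_len(n_spectra(x))) {
        ok <- tryCatch({
          despike_cpp(x$intensities[i, ], cfg$despike_window, cfg$despike_z)
          TRUE
        }, error = function(e2) FALSE)
        if (!ok) stop("despike failed for spectrum '",
                      x$info$spectrum_id[i], "': ", conditionMessage(e),
                      call. = FALSE)
      }
      stop(e)
    })
  out <- x
  out$intensities <- r$intensity
  rownames(out$intensities) <- x$info$spectrum_id
  attr(out, "despike_flags") <- r$flagged
  out$preprocessed <- c(x$preprocessed, "despike")
  out
}

#' Subtract an asymmetric-least-squares baseline
#'
#' Estimates a smooth baseline by iteratively reweighted penalized least
#' squares (second-difference penalty `lambda`, asymmetry `p`) and returns
#' the baseline-subtracted intensities. Negative residuals are retained, not
#' clipped. For a single spectrum the estimated baseline is stored in
#' `meta$baseline`.
#'
#' @inheritParams remove_cosmic_rays
#' @return same type as `x`
#' @export
correct_baseline <- function(x, cfg = preprocess_config()) {
  UseMethod("correct_baseline")
}

#' @export
correct_baseline.numeric <- function(x, cfg = preprocess_config()) {
  b <- als_baseline_cpp(x, cfg$baseline_lambda, cfg$baseline_p,
                        cfg$baseline_iters)
  structure(x - b, baseline = b)
}

#' @export
correct_baseline.raman_spectrum <- function(x, cfg = preprocess_config()) {
  b <- als_baseline_cpp(x$intensity, cfg$baseline_lambda, cfg$baseline_p,
                        cfg$baseline_iters)
  x$intensity <- x$intensity - b
  x$meta$baseline <- b
  x
}

#' @export
correct_baseline.sers_cohort <- function(x, cfg = preprocess_config()) {
  bad <- which(!apply(is.finite(x$intensities), 1L, all))
  if (length(bad))
    stop("non-finite intensities in spectrum '",
         x$info$spectrum_id[bad[1]], "'")
  b <- als_baseline_mat_cpp(x$intensities, cfg$baseline_lambda,
                            cfg$baseline_p, cfg$baseline_iters)
  out <- x
  out$intensities <- x$intensities - b
  rownames(out$intensities) <- x$info$spectrum_id
  out$preprocessed <- c(x$preprocessed, "baseline")
  out
}

#' Gaussian smoothing
#'
#' Discrete convolution with a Gaussian kernel of SD `smooth_sigma`
#' channels, truncated at 4 sigma and renormalized to unit sum, with
#' reflect boundary handling.
#'
#' @inheritParams remove_cosmic_rays
#' @return same type as `x`
#' @export
smooth_gaussian <- function(x, cfg = preprocess_config()) {
  UseMethod("smooth_gaussian")
}

#' @export
smooth_gaussian.numeric <- function(x, cfg = preprocess_config()) {
  as.numeric(gauss_smooth_cpp(x, cfg$smooth_sigma))
}

#' @export
smooth_gaussian.raman_spectrum <- function(x, cfg = preprocess_config()) {
  x$intensity <- as.numeric(gauss_smooth_cpp(x$intensity, cfg$smooth_sigma))
  x
}

#' @export
smooth_gaussian.sers_cohort <- function(x, cfg = preprocess_config()) {
  out <- x
  out$intensities <- gauss_smooth_mat_cpp(x$intensities, cfg$smooth_sigma)
  rownames(out$intensities) <- x$info$spectrum_id
  out$preprocessed <- c(x$preprocessed, "smooth")
  out
}

#' Min-max normalization to the 0-1 range
#'
#' `(x - min x) / (max x - min x)` per spectrum. A constant spectrum is a
#' declared degenerate case: it maps to all zeros with a warning.
#'
#' @inheritParams remove_cosmic_rays
#' @return same type as `x`
#' @export
normalize_minmax <- function(x, ...) UseMethod("normalize_minmax")

#' @export
normalize_minmax.numeric <- function(x, ...) {
  rng <- range(x)
  if (rng[2] - rng[1] <= 0) {
    warning("constant spectrum: min-max normalization returns zeros")
    return(numeric(length(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' @export
normalize_minmax.raman_spectrum <- function(x, ...) {
  x$intensity <- normalize_minmax(x$intensity)
  x
}

#' @export
normalize_minmax.sers_cohort <- function(x, ...) {
  lo <- apply(x$intensities, 1L, min)
  hi <- apply(x$intensities, 1L, max)
  span <- hi - lo
  flat <- span <= 0
  if (any(flat)) {
    warning(sum(flat), " constant spectrum(s) normalized to zeros")
    span[flat] <- 1
  }
  out <- x
  out$intensities <- (x$intensities - lo) / span
  out$intensities[flat, ] <- 0
  rownames(out$intensities) <- x$info$spectrum_id
  out$preprocessed <- c(x$preprocessed, "normalize")
  out
}

#' Run the preprocessing chain on a cohort
#'
#' Applies the configured steps in order (default despike -> baseline ->
#' smooth -> normalize) to every spectrum, preserving ids and labels, and
#' logs a one-line summary per step.
#'
#' @param ds a [sers_cohort()]
#' @param cfg a [preprocess_config()]
#' @param steps override of `cfg$steps`
#' @param verbose emit per-step messages
#' @return the preprocessed [sers_cohort()]; despiked channel lists are in
#'   attribute `"despike_flags"`
#' @export
preprocess_pipeline <- function(ds, cfg = preprocess_config(), steps = NULL,
                                verbose = FALSE) {
  stopifnot(inherits(ds, "sers_cohort"))
  steps <- steps %||% cfg$steps
  if (n_spectra(ds) == 0L) return(ds)
  flags <- NULL
  for (st in steps) {
    ds <- switch(st,
      despike = {
        d <- remove_cosmic_rays(ds, cfg)
        flags <- attr(d, "despike_flags")
        if (verbose)
          message("despike: ", sum(lengths(flags)), " channel(s) repaired")
        d
      },
      baseline = {
        d <- correct_baseline(ds, cfg)
        if (verbose) message("baseline: asymmetric least squares subtracted")
        d
      },
      smooth = {
        d <- smooth_gaussian(ds, cfg)
        if (verbose)
          message("smooth: Gaussian sigma ", cfg$smooth_sigma, " channels")
        d
      },
      normalize = {
        d <- normalize_minmax(ds)
        if (verbose) message("normalize: per-spectrum min-max to [0, 1]")
        d
      },
      stop("unknown preprocessing step: ", st))
  }
  if (!is.null(flags)) attr(ds, "despike_flags") <- flags
  ds
}
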