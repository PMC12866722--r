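# Interpretability layer: per-channel feature importance (input-gradient
# saliency by default, first-layer weight-energy projection as the literal
# weight-based alternative), per-class differential spectra against the
# non-cancer mean, and internal-reference peak-ratio statistics with Welch
# t-tests.

#' Per-channel feature importance of a trained CNN
#'
#' Default method `"saliency"`: mean absolute gradient of the top logit with
#' respect to the input, over a representative spectra set. Alternative
#' method `"weights"`: the first-layer weight-energy projection - squared
#' dense-layer weights are propagated back through the pooling map onto the
#' convolution positions and combined with the squared convolution kernel
#' weights per input channel. Both are normalized so channel contributions
#' sum to 100 percent.
#'
#' @param model a trained [train_cnn()] fit
#' @param spectra matrix of preprocessed spectra (required for
#'   `"saliency"`; ignored by `"weights"`)
#' @param method `"saliency"` or `"weights"`
#' @param grid optional [wavenumber_grid()] labelling the channels
#' @return an object of class `sers_importance`: data.frame with
#'   `wavenumber` (or channel index) and `percent`
#' @export
feature_importance <- function(model, spectra = NULL,
                               method = c("saliency", "weights"),
                               grid = NULL) {
  method <- match.arg(method)
  if (!inherits(model, "sers_cnn")) stop("model must be a trained sers_cnn")
  P <- model$input_length
  if (method == "saliency") {
    if (is.null(spectra)) stop("saliency needs a spectra matrix")
    stopifnot(is.matrix(spectra), ncol(spectra) == P)
    raw <- as.numeric(nn_saliency_cpp(
      model$weights, spectra, use_conv = TRUE,
      n_classes = model$cfg$n_classes, filters = model$cfg$conv_filters,
      kernel = model$cfg$conv_kernel, fc_sizes = model$cfg$fc_sizes,
      leaky = model$cfg$leaky, batch = model$cfg$batch_size))
  } else {
    raw <- weight_energy_projection(model)
  }
  tot <- sum(raw)
  if (tot <= 0) stop("degenerate importance profile (all-zero gradients)")
  wn <- if (!is.null(grid)) grid$values else seq_len(P)
  structure(data.frame(wavenumber = wn, percent = 100 * raw / tot),
            class = c("sers_importance", "data.frame"), method = method)
}

# squared-weight energy of dense layer 1 propagated through flatten
# (feature j = filter f, pooled position l), split equally over the two
# convolution positions of each pool, then spread over input channels by
# the squared convolution kernel.
weight_energy_projection <- function(model) {
  cfg <- model$cfg
  P <- model$input_length
  K <- cfg$conv_kernel
  nf <- cfg$conv_filters
  L <- P - K + 1L
  Lp <- L %/% 2L
  W1 <- model$weights$W[[1]] # (F*Lp) x h1
  Wc <- model$weights$Wc     # K x F
  efeat <- rowSums(W1^2)     # energy per flatten feature, j = (f-1)*Lp + l
  chan <- numeric(P)
  for (f in seq_len(nf)) {
    pe <- efeat[((f - 1L) * Lp + 1L):(f * Lp)]
    conv_e <- numeric(L)
    conv_e[seq(1L, 2L * Lp, by = 2L)] <- pe / 2
    conv_e[seq(2L, 2L * Lp, by = 2L)] <- pe / 2
    for (k in seq_len(K))
      chan[(k - 1L) + seq_len(L)] <- chan[(k - 1L) + seq_len(L)] +
        Wc[k, f]^2 * conv_e
  }
  chan
}

#' Aggregate channel importance into named bands
#'
#' Sums channel percents within `center +/- window` cm^-1 for each named
#' band center.
#'
#' @param importance a [feature_importance()] profile
#' @param centers band centers (cm^-1), default the two diagnostic bands
#' @param window half-width of each band window (cm^-1)
#' @return named numeric vector of band percents
#' @export
band_importance <- function(importance, centers = c(1080, 1380),
                            window = 10) {
  stopifnot(inherits(importance, "sers_importance"))
  out <- vapply(centers, function(ctr)
    sum(importance$percent[abs(importance$wavenumber - ctr) <= window]),
    numeric(1))
  names(out) <- as.character(centers)
  out
}

#' Score non-overlapping fixed-width bands
#'
#' Tiles the axis into consecutive non-overlapping windows of `width`
#' channels (remainder dropped) and sums channel percents per window; used
#' to rank bands by model attention.
#'
#' @param importance a [feature_importance()] profile
#' @param width band width in channels
#' @return data.frame with `band`, `start_wavenumber`, `center_wavenumber`,
#'   `percent`, sorted by descending percent
#' @export
band_scores <- function(importance, width = 21L) {
  stopifnot(inherits(importance, "sers_importance"), width >= 1L)
  p <- nrow(importance)
  nb <- p %/% width
  idx <- rep(seq_len(nb), each = width)
  pct <- tapply(importance$percent[seq_len(nb * width)], idx, sum)
  start <- importance$wavenumber[(seq_len(nb) - 1L) * width + 1L]
  ctr <- importance$wavenumber[(seq_len(nb) - 1L) * width +
                                 (width + 1L) %/% 2L]
  out <- data.frame(band = seq_len(nb), start_wavenumber = start,
                    center_wavenumber = ctr, percent = as.numeric(pct))
  out[order(-out$percent), ]
}

#' Differential spectrum of a class against a reference group
#'
#' Channelwise mean intensity of the class minus the reference-group mean
#' (default `non_cancer`), on whatever intensity scale the cohort currently
#' carries (typically post-preprocessing).
#'
#' @param ds a [sers_cohort()]
#' @param class_label class whose spectra form the first group
#' @param reference class(es) forming the reference group
#' @return an object of class `sers_diffspec`: list with `class_label`,
#'   `reference`, `wavenumber`, `delta`
#' @export
differential_spectrum <- function(ds, class_label,
                                  reference = "non_cancer") {
  stopifnot(inherits(ds, "sers_cohort"))
  a <- ds$info$class %in% class_label
  b <- ds$info$class %in% reference
  if (!any(a)) stop("no spectra for class '",
                    paste(class_label, collapse = ","), "'")
  if (!any(b)) stop("no spectra for reference '",
                    paste(reference, collapse = ","), "'")
  delta <- colMeans(ds$intensities[a, , drop = FALSE]) -
    colMeans(ds$intensities[b, , drop = FALSE])
  structure(list(class_label = paste(class_label, collapse = "+"),
                 reference = paste(reference, collapse = "+"),
                 wavenumber = ds$grid$values, delta = as.numeric(delta)),
            class = "sers_diffspec")
}

#' @export
print.sers_diffspec <- function(x, ...) {
  cat(sprintf("<sers_diffspec> %s - %s (%d channels)\n", x$class_label,
              x$reference, length(x$delta)))
  invisible(x)
}

#' Differential-spectrum matrix over all cancer classes
#'
#' One row per non-reference class: mean class spectrum minus the
#' reference mean (the heatmap analogue of per-class differential spectra).
#'
#' @param ds a [sers_cohort()]
#' @param reference reference class label
#' @param classes classes to include; default all except the reference
#' @return matrix (classes x channels), wavenumbers as column names
#' @export
differential_matrix <- function(ds, reference = "non_cancer",
                                classes = NULL) {
  classes <- classes %||% setdiff(sort(unique(ds$info$class)), reference)
  m <- t(vapply(classes, function(cl)
    differential_spectrum(ds, cl, reference)$delta,
    numeric(length(ds$grid$values))))
  rownames(m) <- classes
  colnames(m) <- as.character(ds$grid$values)
  m
}

#' Internal-reference peak-ratio statistic
#'
#' Per-spectrum intensity ratio at the channel nearest `numerator` over the
#' channel nearest `reference` (default 1080 or 1380 over the stable
#' 643 cm^-1 band), compared between two groups with a Welch two-sample
#' t-test. Spectra with nonpositive reference intensity are excluded with a
#' message; if 5 percent or more are nonpositive the reference band is
#' considered absent and the test errors. Ratios should be computed on
#' preprocessed but un-normalized intensities (min-max scaling would
#' distort them).
#'
#' @param ds a [sers_cohort()]
#' @param numerator numerator band center (cm^-1)
#' @param reference reference band center (cm^-1)
#' @param groups named list of two class-label vectors defining the groups;
#'   default `non_cancer` versus everything else
#' @return an object of class `sers_ratio`: per-group ratio vectors, means,
#'   SDs, the Welch t statistic, p-value and star code
#' @export
peak_ratio_test <- function(ds, numerator = 1080, reference = 643,
                            groups = NULL) {
  stopifnot(inherits(ds, "sers_cohort"))
  if (numerator < ds$grid$start || numerator > ds$grid$stop ||
      reference < ds$grid$start || reference > ds$grid$stop)
    stop("band centers must lie on the wavenumber grid")
  all_classes <- sort(unique(ds$info$class))
  groups <- groups %||% list(non_cancer = "non_cancer",
                             cancer = setdiff(all_classes, "non_cancer"))
  stopifnot(is.list(groups), length(groups) == 2L)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- c("group1", "group2")
  i_num <- nearest_channel(ds$grid, numerator)
  i_ref <- nearest_channel(ds$grid, reference)

  ratio_of <- function(labels) {
    rows <- which(ds$info$class %in% labels)
    if (!length(rows)) stop("no spectra for group: ",
                            paste(labels, collapse = ","))
    num <- ds$intensities[rows, i_num]
    ref <- ds$intensities[rows, i_ref]
    bad <- ref <= 0
    if (mean(bad) >= 0.05)
      stop(sprintf(
        "reference band absent: %.1f%% of spectra have nonpositive %g cm^-1 intensity",
        100 * mean(bad), reference))
    if (any(bad))
      message(sum(bad), " spectrum(s) excluded (nonpositive reference ",
              "intensity)")
    num[!bad] / ref[!bad]
  }
  ratios <- lapply(groups, ratio_of)
  tt <- t.test(ratios[[1]], ratios[[2]], var.equal = FALSE)
  structure(list(numerator = numerator, reference = reference,
                 groups = names(groups), ratios = ratios,
                 means = vapply(ratios, mean, numeric(1)),
                 sds = vapply(ratios, sd, numeric(1)),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, stars = p_stars(tt$p.value)),
            class = "sers_ratio")
}

#' @export
print.sers_ratio <- function(x, ...) {
  cat(sprintf("<sers_ratio> I(%g)/I(%g): %s %.3f +/- %.3f vs %s %.3f +/- %.3f\n",
              x$numerator, x$reference, x$groups[1], x$means[1], x$sds[1],
              x$groups[2], x$means[2], x$sds[2]))
  cat(sprintf("  Welch t = %.3f, df = %.1f, p = %.3g %s\n", x$t, x$df,
              x$p, x$stars))
  invisible(x)
}
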