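# Synthetic SERS cohort generator. The simulator plants the pan-cancer
# band-level effects (1080 cm^-1 up, 1380 cm^-1 down, 643 cm^-1 stable)
# on a shared serum-exosome-like band set, then layers acquisition
# artifacts: polynomial baseline drift, additive noise, cosmic-ray spikes
# and per-spectrum amplitude jitter. Ground truth (spike channels, jitter,
# planted deltas) is recorded so preprocessing and interpretability stages
# can be tested against it.

#' Default serum-exosome-like base bands
#'
#' A fixed set of Gaussian bands shared by all classes, spanning typical
#' biomolecular Raman features (phenylalanine ring breathing near
#' 1004 cm^-1, CH2 deformation near 1450 cm^-1, amide I near 1655 cm^-1, the
#' stable 643 cm^-1 reference, and the diagnostic 1080 / 1380 cm^-1 bands).
#' The maximum band amplitude is 1 a.u., so planted deltas are directly
#' interpretable as fractions of the strongest band.
#'
#' @return list of [peak_spec()]
#' @export
default_base_peaks <- function() {
  tab <- list(
    c(643, 10, 0.60), c(730, 12, 0.35), c(850, 14, 0.30),
    c(1004, 8, 0.80), c(1080, 12, 0.55), c(1260, 16, 0.40),
    c(1380, 12, 0.50), c(1450, 14, 0.70), c(1580, 14, 0.45),
    c(1655, 18, 1.00))
  lapply(tab, function(v) peak_spec(v[1], v[2], v[3]))
}

#' The ten cancer class labels
#' @return character vector of the ten cancer types plus nothing else
#' @export
cancer_types <- function() {
  c("breast", "thyroid", "esophageal", "kidney", "pancreatic",
    "duodenal", "lung", "colorectal", "ovarian", "gastric")
}

# distinct minor bands per cancer type (center1, center2), amplitudes
# 0.20 / 0.15, FWHM 12; centers avoid the three anchor bands
cancer_extra_centers <- function() {
  list(breast = c(500, 1620), thyroid = c(525, 1700),
       esophageal = c(550, 1525), kidney = c(575, 1745),
       pancreatic = c(600, 900), duodenal = c(690, 935),
       lung = c(760, 1175), colorectal = c(805, 1220),
       ovarian = c(880, 1300), gastric = c(960, 1560))
}

#' Build a cancer class signature with default planted effects
#'
#' @param label cancer class label
#' @param delta_1080 amplitude offset on the 1080 cm^-1 band (default +0.15,
#'   i.e. +15 percent of the maximum band amplitude)
#' @param delta_1380 amplitude offset on the 1380 cm^-1 band (default -0.10)
#' @param extra_peaks list of class-specific [peak_spec()]
#' @param base_peaks shared base bands
#' @return a [class_signature()]
#' @export
cancer_signature <- function(label, delta_1080 = 0.15, delta_1380 = -0.10,
                             extra_peaks = list(),
                             base_peaks = default_base_peaks()) {
  class_signature(label, base_peaks = base_peaks, delta_1080 = delta_1080,
                  delta_1380 = delta_1380, extra_peaks = extra_peaks)
}

#' Default binary (cancer presence) cohort plan
#'
#' Two classes (`non_cancer` and a pooled pan-cancer class carrying only the
#' shared 1080/1380 effects), at the package's default effect sizes and
#' noise level.
#'
#' @param samples_per_class samples per class
#' @param spectra_per_sample spectra per sample
#' @param seed master seed
#' @param noise a [noise_model()]
#' @param grid a [wavenumber_grid()]
#' @return a [cohort_plan()]
#' @export
binary_cohort_plan <- function(samples_per_class = 40,
                               spectra_per_sample = 50, seed = 1L,
                               noise = noise_model(),
                               grid = wavenumber_grid()) {
  cohort_plan(
    classes = list(class_signature("non_cancer"),
                   cancer_signature("cancer")),
    samples_per_class = samples_per_class,
    spectra_per_sample = spectra_per_sample,
    grid = grid, noise = noise, seed = seed)
}

#' Default 11-class cohort plan
#'
#' The control class plus the ten cancer types, each cancer carrying the
#' shared 1080/1380 effects and two distinct class-specific minor bands.
#'
#' @inheritParams binary_cohort_plan
#' @return a [cohort_plan()]
#' @export
multiclass_cohort_plan <- function(samples_per_class = 15,
                                   spectra_per_sample = 30, seed = 1L,
                                   noise = noise_model(),
                                   grid = wavenumber_grid()) {
  extras <- cancer_extra_centers()
  classes <- c(
    list(class_signature("non_cancer")),
    lapply(cancer_types(), function(lb) {
      ctr <- extras[[lb]]
      cancer_signature(lb, extra_peaks = list(
        peak_spec(ctr[1], 12, 0.20), peak_spec(ctr[2], 12, 0.15)))
    }))
  cohort_plan(classes = classes, samples_per_class = samples_per_class,
              spectra_per_sample = spectra_per_sample, grid = grid,
              noise = noise, seed = seed)
}

#' Cohort plan with a deliberately confusable cancer pair
#'
#' Control plus two cancer classes whose signatures differ only by a small
#' amplitude contrast on one shared minor band, so the spectrum-level CNN
#' systematically confuses them and the stacked refiner has structure to
#' exploit.
#'
#' @inheritParams binary_cohort_plan
#' @param contrast amplitude difference between the pair's shared band
#' @return a [cohort_plan()]
#' @export
confusable_pair_plan <- function(samples_per_class = 15,
                                 spectra_per_sample = 20, seed = 1L,
                                 contrast = 0.06,
                                 noise = noise_model(),
                                 grid = wavenumber_grid()) {
  cohort_plan(
    classes = list(
      class_signature("non_cancer"),
      cancer_signature("cancer_A", extra_peaks = list(
        peak_spec(900, 12, 0.20), peak_spec(1550, 12, 0.15))),
      cancer_signature("cancer_B", extra_peaks = list(
        peak_spec(900, 12, 0.20 + contrast), peak_spec(1550, 12, 0.15)))),
    samples_per_class = samples_per_class,
    spectra_per_sample = spectra_per_sample,
    grid = grid, noise = noise, seed = seed)
}

# draw all stochastic terms for one spectrum from the current RNG state;
# the draw order (jitter, baseline, noise, spikes) is part of the contract
simulate_spectrum_impl <- function(signature, grid, noise, base = NULL) {
  p <- length(grid$values)
  base <- base %||% signature_profile(signature, grid)

  jitter <- 1
  cv <- noise$amplitude_jitter_cv
  if (cv > 0) {
    sdl <- sqrt(log(1 + cv^2))
    jitter <- exp(rnorm(1, -sdl^2 / 2, sdl))
  }
  r <- noise$baseline_coef_ranges
  cf <- vapply(r, function(rg) runif(1, rg[1], rg[2]), numeric(1))
  t01 <- seq(0, 1, length.out = p)
  baseline <- cf[1] + if (length(cf) > 1)
    Reduce(`+`, lapply(seq_along(cf)[-1],
                       function(i) cf[i] * t01^(i - 1)), 0) else 0
  y <- jitter * base + baseline
  if (noise$additive_sd > 0) y <- y + rnorm(p, 0, noise$additive_sd)

  spike_channels <- integer(0)
  if (noise$spike_rate > 0) {
    nsp <- rpois(1, noise$spike_rate)
    if (nsp > 0) {
      nsp <- min(nsp, p - 2L)
      spike_channels <- sort(sample(2:(p - 1L), nsp))
      amps <- runif(nsp, noise$spike_amplitude[1], noise$spike_amplitude[2])
      y[spike_channels] <- y[spike_channels] + amps
    }
  }
  y <- pmax(y, 0)
  list(intensity = y, spike_channels = spike_channels, jitter = jitter)
}

#' Simulate a single SERS spectrum
#'
#' Sum of the class band profiles plus random polynomial baseline, additive
#' Gaussian noise and Poisson-count one-channel cosmic-ray spikes, clipped
#' at zero. Ground-truth spike channel indices and the amplitude jitter are
#' returned in `meta`.
#'
#' @param signature a [class_signature()]
#' @param grid a [wavenumber_grid()]; must cover every peak center
#' @param noise a [noise_model()]
#' @param seed optional integer; when given, the spectrum is reproducible in
#'   isolation. Otherwise draws come from the current RNG state.
#' @return an object of class `raman_spectrum`: list with `grid`,
#'   `intensity`, `spectrum_id`, `sample_id`, `meta`
#' @export
simulate_spectrum <- function(signature, grid = wavenumber_grid(),
                              noise = noise_model(), seed = NULL) {
  stopifnot(inherits(signature, "class_signature"),
            inherits(grid, "wavenumber_grid"),
            inherits(noise, "noise_model"))
  if (!is.null(seed)) set.seed(seed)
  sim <- simulate_spectrum_impl(signature, grid, noise)
  raman_spectrum(grid, sim$intensity,
                 spectrum_id = NA_character_, sample_id = NA_character_,
                 meta = list(class = signature$label,
                             spike_channels = sim$spike_channels,
                             jitter = sim$jitter))
}

#' Raman spectrum container
#'
#' @param grid a [wavenumber_grid()]
#' @param intensity numeric vector, one finite value per channel
#' @param spectrum_id,sample_id identifiers
#' @param meta list of annotations (ground-truth spike channels, estimated
#'   baseline, ...)
#' @return an object of class `raman_spectrum`
#' @export
raman_spectrum <- function(grid, intensity, spectrum_id = NA_character_,
                           sample_id = NA_character_, meta = list()) {
  stopifnot(inherits(grid, "wavenumber_grid"))
  if (length(intensity) != length(grid$values))
    stop("intensity length must equal grid length")
  if (!all(is.finite(intensity))) stop("intensity must be finite")
  structure(list(grid = grid, intensity = as.numeric(intensity),
                 spectrum_id = spectrum_id, sample_id = sample_id,
                 meta = meta),
            class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> %s (%s), %d channels\n",
              x$spectrum_id, x$sample_id, length(x$intensity)))
  invisible(x)
}

# TNM-style stage assignment; ovarian uses FIGO staging. Early-stage cases
# are T1N0M0 / T2N0M0 (FIGO I for ovarian); overall early fraction 0.5.
draw_stage <- function(label, n) {
  if (label == "non_cancer") return(rep(NA_character_, n))
  if (label == "ovarian")
    sample(c("FIGO_I", "FIGO_II", "FIGO_III"), n, replace = TRUE,
           prob = c(0.5, 0.25, 0.25))
  else
    sample(c("T1N0M0", "T2N0M0", "T3N1M0", "T4N2M1"), n, replace = TRUE,
           prob = c(0.25, 0.25, 0.3, 0.2))
}

#' Simulate a labeled cohort of per-sample spectrum bundles
#'
#' Generates `samples_per_class` samples for every class in the plan, each
#' with `spectra_per_sample` spectra, emulating the acquisition regime where
#' hundreds of spectra are randomly collected per serum sample. All
#' randomness flows from `plan$seed`. Cancer samples receive a TNM-style
#' stage annotation (FIGO for ovarian) so early-stage filtering can be
#' exercised.
#'
#' @param plan a [cohort_plan()]
#' @return an object of class `sers_cohort`; see [sers_cohort()]
#' @export
simulate_cohort <- function(plan) {
  stopifnot(inherits(plan, "cohort_plan"))
  set.seed(plan$seed)
  grid <- plan$grid
  p <- length(grid$values)
  labels <- vapply(plan$classes, `[[`, character(1), "label")
  n_total <- length(labels) * plan$samples_per_class * plan$spectra_per_sample

  intens <- matrix(0, nrow = n_total, ncol = p)
  spectrum_id <- sample_id <- cls <- stage <- character(n_total)
  spikes <- vector("list", n_total)
  jitters <- numeric(n_total)

  row <- 0L
  for (ci in seq_along(plan$classes)) {
    sig <- plan$classes[[ci]]
    base <- signature_profile(sig, grid)
    stages <- draw_stage(sig$label, plan$samples_per_class)
    for (si in seq_len(plan$samples_per_class)) {
      sid <- sprintf("%s_s%03d", sig$label, si)
      for (ri in seq_len(plan$spectra_per_sample)) {
        row <- row + 1L
        sim <- simulate_spectrum_impl(sig, grid, plan$noise, base = base)
        intens[row, ] <- sim$intensity
        spectrum_id[row] <- sprintf("%s_r%04d", sid, ri)
        sample_id[row] <- sid
        cls[row] <- sig$label
        stage[row] <- stages[si]
        spikes[[row]] <- sim$spike_channels
        jitters[row] <- sim$jitter
      }
    }
  }
  info <- data.frame(spectrum_id = spectrum_id, sample_id = sample_id,
                     class = cls, stage = stage, stringsAsFactors = FALSE)
  truth <- list(
    deltas = data.frame(
      class = labels,
      delta_1080 = vapply(plan$classes, `[[`, numeric(1), "delta_1080"),
      delta_1380 = vapply(plan$classes, `[[`, numeric(1), "delta_1380")),
    jitter = jitters, seed = plan$seed)
  sers_cohort(grid, intens, info, spike_truth = spikes, truth = truth)
}
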