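# Domain types for the synthetic SERS cohort generator: the wavenumber axis,
# spectral bands, class signatures, the acquisition noise model and the
# cohort plan. All constructors validate and return light S3 lists.

#' Wavenumber grid
#'
#' The shared Raman-shift axis of a spectra set: a strictly increasing,
#' uniformly spaced vector of channel positions in cm^-1. By default the
#' axis must cover the three anchor bands used throughout the package
#' (643, 1080 and 1380 cm^-1: the internal-reference band and the two
#' disease-informative bands); pass `anchors = NULL` to lift that
#' requirement, e.g. for cropped instrument exports.
#'
#' @param start first channel (cm^-1)
#' @param stop last channel (cm^-1)
#' @param step channel spacing (cm^-1)
#' @param anchors wavenumbers that must fall inside `[start, stop]`,
#'   or `NULL`
#' @return an object of class `wavenumber_grid`
#' @examples
#' g <- wavenumber_grid()          # 400-1800 cm^-1 at 1 cm^-1, 1401 channels
#' length(g$values)
#' @export
wavenumber_grid <- function(start = 400, stop = 1800, step = 1,
                            anchors = c(643, 1080, 1380)) {
  assert_scalar_num(start, "start")
  assert_scalar_num(stop, "stop")
  assert_scalar_num(step, "step", lower = 1e-9)
  if (stop <= start) stop("`stop` must exceed `start`")
  values <- seq(start, stop, by = step)
  if (!is.null(anchors) && (any(anchors < start) || any(anchors > stop)))
    stop("grid must cover the anchor bands (", paste(anchors, collapse = ", "),
         " cm^-1)")
  structure(list(start = start, stop = tail_value(values), step = step,
                 values = values),
            class = "wavenumber_grid")
}

tail_value <- function(x) x[length(x)]

#' Reconstruct a wavenumber grid from channel positions
#'
#' Used by the spectra reader: validates that header wavenumbers are strictly
#' increasing and uniformly spaced (to within a 1e-6 relative tolerance).
#'
#' @param values numeric vector of channel positions (cm^-1)
#' @return a `wavenumber_grid`
#' @export
grid_from_values <- function(values) {
  if (length(values) < 2L || anyNA(values))
    stop("need at least two finite wavenumber values")
  d <- diff(values)
  if (any(d <= 0)) stop("wavenumbers must be strictly increasing")
  if (max(d) - min(d) > 1e-6 * mean(d))
    stop("wavenumbers must be uniformly spaced")
  structure(list(start = values[1L], stop = tail_value(values),
                 step = mean(d), values = values),
            class = "wavenumber_grid")
}

#' @export
print.wavenumber_grid <- function(x, ...) {
  cat(sprintf("<wavenumber_grid> %g-%g cm^-1, step %g (%d channels)\n",
              x$start, x$stop, x$step, length(x$values)))
  invisible(x)
}

#' Spectral band specification
#'
#' One Raman band: a Gaussian or Lorentzian profile with peak value
#' `amplitude` at `center` and full width at half maximum `fwhm`.
#'
#' @param center band center (cm^-1)
#' @param fwhm full width at half maximum (cm^-1), > 0
#' @param amplitude peak intensity (a.u.), >= 0
#' @param shape `"gaussian"` or `"lorentzian"`
#' @return an object of class `peak_spec`
#' @export
peak_spec <- function(center, fwhm, amplitude, shape = c("gaussian",
                                                         "lorentzian")) {
  shape <- match.arg(shape)
  assert_scalar_num(center, "center")
  assert_scalar_num(fwhm, "fwhm", lower = 1e-9)
  assert_scalar_num(amplitude, "amplitude", lower = 0)
  structure(list(center = center, fwhm = fwhm, amplitude = amplitude,
                 shape = shape),
            class = "peak_spec")
}

# evaluate a list of peaks on a grid (sum of band profiles)
peak_profile <- function(peaks, grid) {
  x <- grid$values
  y <- numeric(length(x))
  for (pk in peaks) {
    if (pk$center < grid$start || pk$center > grid$stop)
      stop(sprintf("peak center %g cm^-1 outside grid [%g, %g]",
                   pk$center, grid$start, grid$stop))
    if (pk$shape == "gaussian") {
      y <- y + pk$amplitude * exp(-4 * log(2) * (x - pk$center)^2 / pk$fwhm^2)
    } else {
      hw <- pk$fwhm / 2
      y <- y + pk$amplitude * hw^2 / ((x - pk$center)^2 + hw^2)
    }
  }
  y
}

#' Class spectral signature
#'
#' The deterministic spectral content of one diagnostic class: shared base
#' bands, signed amplitude offsets planted on the 1080 cm^-1 (dATP) and
#' 1380 cm^-1 (phosphatidylserine) bands, and optional class-specific minor
#' bands. Every cancer class must carry the pan-cancer effect direction:
#' `delta_1080 > 0` and `delta_1380 < 0`; the non-cancer class must have
#' both zero.
#'
#' @param label class label; `"non_cancer"` marks the control class
#' @param base_peaks list of [peak_spec()] shared across classes
#' @param delta_1080 signed amplitude offset (a.u.) on the 1080 cm^-1 band
#' @param delta_1380 signed amplitude offset (a.u.) on the 1380 cm^-1 band
#' @param extra_peaks list of [peak_spec()] specific to this class
#' @return an object of class `class_signature`
#' @export
class_signature <- function(label, base_peaks = default_base_peaks(),
                            delta_1080 = 0, delta_1380 = 0,
                            extra_peaks = list()) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  assert_scalar_num(delta_1080, "delta_1080")
  assert_scalar_num(delta_1380, "delta_1380")
  if (identical(label, "non_cancer")) {
    if (delta_1080 != 0 || delta_1380 != 0)
      stop("non_cancer signature must have zero band deltas")
  } else {
    if (delta_1080 <= 0 || delta_1380 >= 0)
      stop("cancer signatures require delta_1080 > 0 and delta_1380 < 0 ",
           "(the pan-cancer effect direction)")
  }
  centers <- vapply(base_peaks, function(p) p$center, numeric(1))
  if ((delta_1080 != 0 && !any(centers == 1080)) ||
      (delta_1380 != 0 && !any(centers == 1380)))
    stop("base_peaks must contain 1080 and 1380 cm^-1 bands to plant deltas")
  structure(list(label = label, base_peaks = base_peaks,
                 delta_1080 = delta_1080, delta_1380 = delta_1380,
                 extra_peaks = extra_peaks),
            class = "class_signature")
}

# deterministic band sum of a signature (deltas applied, no noise)
signature_profile <- function(signature, grid) {
  peaks <- signature$base_peaks
  for (i in seq_along(peaks)) {
    if (peaks[[i]]$center == 1080)
      peaks[[i]]$amplitude <- peaks[[i]]$amplitude + signature$delta_1080
    if (peaks[[i]]$center == 1380)
      peaks[[i]]$amplitude <- peaks[[i]]$amplitude + signature$delta_1380
  }
  peak_profile(c(peaks, signature$extra_peaks), grid)
}

#' Acquisition noise model
#'
#' Stochastic artifacts layered on the deterministic band sum: additive
#' Gaussian noise, a random low-order polynomial baseline (fluorescence /
#' substrate background), one-channel cosmic-ray spikes with a Poisson count
#' per spectrum, and a lognormal per-spectrum global amplitude jitter
#' modelling exosome-sampling heterogeneity. When spikes are enabled their
#' minimum amplitude must exceed 10x the additive noise SD so that ground
#' truth is unambiguous.
#'
#' @param additive_sd SD of additive Gaussian noise (a.u.)
#' @param baseline_coef_ranges list of length-2 ranges for polynomial
#'   coefficients `c0 + c1*t + c2*t^2` evaluated on t in `[0, 1]`; the
#'   default ranges keep the baseline nonnegative across the axis so that
#'   clipping the final spectrum at zero cannot create flat runs
#' @param spike_rate expected cosmic-ray spikes per spectrum
#' @param spike_amplitude length-2 range of spike heights (a.u.)
#' @param amplitude_jitter_cv coefficient of variation of the lognormal
#'   per-spectrum scale factor (mean 1)
#' @return an object of class `noise_model`
#' @export
noise_model <- function(additive_sd = 0.03,
                        baseline_coef_ranges = list(c0 = c(0.1, 0.4),
                                                    c1 = c(-0.05, 0.3),
                                                    c2 = c(-0.05, 0.3)),
                        spike_rate = 0.1,
                        spike_amplitude = c(2, 5),
                        amplitude_jitter_cv = 0.1) {
  assert_scalar_num(additive_sd, "additive_sd", lower = 0)
  assert_scalar_num(spike_rate, "spike_rate", lower = 0)
  assert_scalar_num(amplitude_jitter_cv, "amplitude_jitter_cv", lower = 0)
  stopifnot(is.list(baseline_coef_ranges),
            all(vapply(baseline_coef_ranges, length, 1L) == 2L))
  stopifnot(length(spike_amplitude) == 2L, spike_amplitude[1] > 0,
            spike_amplitude[2] >= spike_amplitude[1])
  if (spike_rate > 0 && spike_amplitude[1] <= 10 * additive_sd)
    stop("minimum spike amplitude must exceed 10x additive_sd")
  structure(list(additive_sd = additive_sd,
                 baseline_coef_ranges = baseline_coef_ranges,
                 spike_rate = spike_rate,
                 spike_amplitude = spike_amplitude,
                 amplitude_jitter_cv = amplitude_jitter_cv),
            class = "noise_model")
}

#' Noise-free acquisition model
#'
#' All stochastic terms off: useful for closed-form oracle checks.
#' @return a `noise_model` with every rate and SD zero
#' @export
zero_noise <- function() {
  noise_model(additive_sd = 0,
              baseline_coef_ranges = list(c0 = c(0, 0), c1 = c(0, 0),
                                          c2 = c(0, 0)),
              spike_rate = 0, spike_amplitude = c(1, 1),
              amplitude_jitter_cv = 0)
}

#' Cohort simulation plan
#'
#' A full specification of a synthetic cohort: the class signatures, the
#' number of serum samples per class, the number of spectra acquired per
#' sample, the wavenumber grid, the noise model and the master seed.
#'
#' @param classes list of [class_signature()]
#' @param samples_per_class samples per class (>= 2)
#' @param spectra_per_sample spectra per sample (>= 1)
#' @param grid a [wavenumber_grid()]
#' @param noise a [noise_model()]
#' @param seed master integer seed; all randomness flows from it
#' @return an object of class `cohort_plan`
#' @export
cohort_plan <- function(classes, samples_per_class, spectra_per_sample,
                        grid = wavenumber_grid(), noise = noise_model(),
                        seed = 1L) {
  stopifnot(is.list(classes), length(classes) >= 1L,
            all(vapply(classes, inherits, TRUE, "class_signature")))
  assert_scalar_num(samples_per_class, "samples_per_class", lower = 2)
  assert_scalar_num(spectra_per_sample, "spectra_per_sample", lower = 1)
  stopifnot(inherits(grid, "wavenumber_grid"), inherits(noise, "noise_model"))
  labels <- vapply(classes, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("duplicate class labels in plan")
  # the internal-reference band must be planted identically in every class
  ref_amp <- vapply(classes, function(sig) {
    hit <- vapply(sig$base_peaks, function(p) p$center == 643, TRUE)
    if (!any(hit)) return(NA_real_)
    sig$base_peaks[[which(hit)[1]]]$amplitude
  }, numeric(1))
  if (anyNA(ref_amp) || length(unique(ref_amp)) != 1L)
    stop("every class signature needs an identical 643 cm^-1 reference band")
  structure(list(classes = classes, samples_per_class = samples_per_class,
                 spectra_per_sample = as.integer(spectra_per_sample),
                 grid = grid, noise = noise, seed = as.integer(seed)),
            class = "cohort_plan")
}
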