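# Synthetic cohort generator: closed-form noiseless spectra, planted
# effects, ground-truth bookkeeping, determinism.

test_that("noiseless single-peak spectrum matches the closed-form Gaussian", {
  g <- wavenumber_grid()
  base <- list(peak_spec(643, 10, 0.5), peak_spec(1080, 10, 1),
               peak_spec(1380, 10, 0.5))
  sig <- class_signature("non_cancer", base_peaks = base)
  s <- simulate_spectrum(sig, g, zero_noise(), seed = 1)
  expected <- 0.5 * exp(-4 * log(2) * (g$values - 643)^2 / 100) +
    1.0 * exp(-4 * log(2) * (g$values - 1080)^2 / 100) +
    0.5 * exp(-4 * log(2) * (g$values - 1380)^2 / 100)
  expect_equal(s$intensity, expected, tolerance = 1e-12)
  expect_equal(s$intensity[g$values == 1080], 1.0, tolerance = 1e-9)
  expect_length(s$meta$spike_channels, 0) # spike_rate 0 -> empty truth
})

test_that("peak centers outside the grid are rejected", {
  g <- wavenumber_grid(600, 1500)
  sig <- class_signature("non_cancer",
                         base_peaks = c(default_base_peaks(),
                                        list(peak_spec(1700, 10, 0.2))))
  expect_error(simulate_spectrum(sig, g, zero_noise()), "outside grid")
})

test_that("simulate_spectrum is deterministic under a fixed seed", {
  g <- coarse_grid()
  sig <- cancer_signature("cancer")
  s1 <- simulate_spectrum(sig, g, noise_model(), seed = 42)
  s2 <- simulate_spectrum(sig, g, noise_model(), seed = 42)
  expect_identical(s1$intensity, s2$intensity)
  expect_identical(s1$meta$spike_channels, s2$meta$spike_channels)
})

test_that("cohort dimensions follow the plan (conservation)", {
  for (nc in c(2L, 3L)) {
    classes <- c(list(class_signature("non_cancer")),
                 lapply(seq_len(nc - 1L),
                        function(i) cancer_signature(paste0("c", i))))
    plan <- cohort_plan(classes, samples_per_class = 3,
                        spectra_per_sample = 5, grid = coarse_grid(),
                        noise = zero_noise(), seed = 2)
    ds <- simulate_cohort(plan)
    expect_equal(n_spectra(ds), nc * 3L * 5L)
    expect_equal(n_samples(ds), nc * 3L)
    expect_false(anyDuplicated(ds$info$spectrum_id) > 0)
  }
})

test_that("noiseless planted deltas appear exactly at the anchor channels", {
  plan <- binary_cohort_plan(samples_per_class = 2, spectra_per_sample = 2,
                             seed = 3, noise = zero_noise(),
                             grid = coarse_grid())
  # override deltas to the documented example value
  plan$classes[[2]] <- cancer_signature("cancer", delta_1080 = 0.2,
                                        delta_1380 = -0.1)
  ds <- simulate_cohort(plan)
  i1080 <- which(ds$grid$values == 1080)
  i1380 <- which(ds$grid$values == 1380)
  cancer <- ds$info$class == "cancer"
  expect_equal(mean(ds$intensities[cancer, i1080]) -
                 mean(ds$intensities[!cancer, i1080]), 0.2,
               tolerance = 1e-12)
  expect_equal(mean(ds$intensities[cancer, i1380]) -
                 mean(ds$intensities[!cancer, i1380]), -0.1,
               tolerance = 1e-12)
})

test_that("noisy planted effect is recovered within 3 SE; 643 is stable", {
  plan <- binary_cohort_plan(samples_per_class = 10,
                             spectra_per_sample = 25, seed = 5)
  ds <- simulate_cohort(plan)
  g <- ds$grid
  cancer <- ds$info$class == "cancer"
  for (ch in c(1080, 1380, 643)) {
    i <- which(g$values == ch)
    a <- ds$intensities[cancer, i]
    b <- ds$intensities[!cancer, i]
    diff <- mean(a) - mean(b)
    se <- sqrt(var(a) / length(a) + var(b) / length(b))
    planted <- switch(as.character(ch), "1080" = 0.15, "1380" = -0.10, 0)
    expect_lt(abs(diff - planted), 3 * se)
  }
})

test_that("spike truth is recorded and matches the planted count regime", {
  plan <- tiny_binary_plan(samples = 3, spectra = 20, seed = 7,
                           noise = noise_model(spike_rate = 1))
  ds <- simulate_cohort(plan)
  counts <- lengths(ds$spike_truth)
  expect_equal(length(counts), n_spectra(ds))
  # Poisson(1) over 120 spectra: mean within 3 SE of 1
  expect_lt(abs(mean(counts) - 1), 3 * sqrt(1 / length(counts)))
  # spikes land on interior channels only
  p <- length(ds$grid$values)
  expect_true(all(unlist(ds$spike_truth) %in% 2:(p - 1)))
})

test_that("cancer signatures enforce the pan-cancer effect direction", {
  expect_error(cancer_signature("breast", delta_1080 = -0.1),
               "delta_1080 > 0")
  expect_error(class_signature("non_cancer", delta_1080 = 0.1),
               "zero band deltas")
  # reference band amplitude must be equal across classes
  base2 <- default_base_peaks()
  base2[[1]] <- peak_spec(643, 10, 0.99)
  expect_error(
    cohort_plan(list(class_signature("non_cancer"),
                     cancer_signature("cancer", base_peaks = base2)),
                samples_per_class = 2, spectra_per_sample = 2,
                grid = coarse_grid(), seed = 1),
    "identical 643")
})
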