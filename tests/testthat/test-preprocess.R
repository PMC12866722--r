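# Preprocessing chain: despiking vs ground truth, ALS baseline limiting
# cases, smoothing vs a direct-summation oracle, min-max postconditions.

test_that("despiking is a bit-identical no-op on spike-free spectra", {
  g <- wavenumber_grid()
  s <- simulate_spectrum(class_signature("non_cancer"), g,
                         noise_model(spike_rate = 0), seed = 13)
  out <- remove_cosmic_rays(s$intensity)
  expect_identical(as.numeric(out), s$intensity)
  expect_length(attr(out, "flagged"), 0)
})

test_that("a large spike on a noiseless spectrum is exactly repaired", {
  g <- wavenumber_grid()
  s <- simulate_spectrum(class_signature("non_cancer"), g, zero_noise(),
                         seed = 1)
  k <- which(g$values == 760) # flat region between bands
  y <- s$intensity
  y[k] <- y[k] + 50
  out <- remove_cosmic_rays(y)
  expect_equal(attr(out, "flagged"), k)
  # repaired channel = linear interpolation of its clean neighbours
  expect_equal(as.numeric(out)[k], (y[k - 1] + y[k + 1]) / 2,
               tolerance = 1e-12)
  dev <- abs(as.numeric(out) - s$intensity)
  expect_lt(dev[k], 1e-6)
  expect_equal(max(dev[-k]), 0)
})

test_that("two adjacent spiked channels are both flagged and repaired", {
  g <- wavenumber_grid()
  s <- simulate_spectrum(class_signature("non_cancer"), g, zero_noise(),
                         seed = 1)
  k <- which(g$values == 900)
  y <- s$intensity
  y[k] <- y[k] + 30
  y[k + 1] <- y[k + 1] + 45
  out <- remove_cosmic_rays(y)
  expect_setequal(attr(out, "flagged"), c(k, k + 1))
  # both interpolated across the flanking clean channels
  t1 <- 1 / 3
  t2 <- 2 / 3
  expect_equal(as.numeric(out)[k],
               y[k - 1] + t1 * (y[k + 2] - y[k - 1]), tolerance = 1e-12)
  expect_equal(as.numeric(out)[k + 1],
               y[k - 1] + t2 * (y[k + 2] - y[k - 1]), tolerance = 1e-12)
})

test_that("despiking recall/precision against planted spikes is high", {
  plan <- binary_cohort_plan(samples_per_class = 8,
                             spectra_per_sample = 25, seed = 17,
                             noise = noise_model(spike_rate = 2))
  ds <- simulate_cohort(plan)
  expect_gte(sum(lengths(ds$spike_truth)), 500)
  d <- remove_cosmic_rays(ds)
  fl <- attr(d, "despike_flags")
  tp <- sum(mapply(function(f, t) length(intersect(f, t)), fl,
                   ds$spike_truth))
  expect_gte(tp / sum(lengths(ds$spike_truth)), 0.99)
  expect_gte(tp / sum(lengths(fl)), 0.95)
})

test_that("ALS leaves zero-baseline noiseless peaks nearly intact", {
  g <- wavenumber_grid()
  s <- simulate_spectrum(class_signature("non_cancer"), g, zero_noise(),
                         seed = 1)
  out <- correct_baseline(s$intensity)
  # tolerance: ALS bias under isolated peaks, 2% of max band amplitude
  expect_lt(max(abs(as.numeric(out) - s$intensity)), 0.02 * 1.0)
})

test_that("ALS removes a pure linear ramp and a constant offset", {
  p <- 1401
  ramp <- seq(0, 2, length.out = p)
  out <- as.numeric(correct_baseline(ramp))
  interior <- 50:(p - 50)
  expect_lt(max(abs(out[interior])), 0.01 * 2)
  cst <- rep(5, p)
  out2 <- as.numeric(correct_baseline(cst))
  expect_lt(max(abs(out2)), 0.01 * 5)
})

test_that("baseline estimate is exposed for inspection", {
  g <- coarse_grid()
  s <- simulate_spectrum(class_signature("non_cancer"), g, noise_model(),
                         seed = 3)
  out <- correct_baseline(s)
  expect_length(out$meta$baseline, length(g$values))
  expect_equal(out$intensity + out$meta$baseline, s$intensity,
               tolerance = 1e-12)
})

test_that("Gaussian smoothing matches the direct-summation oracle", {
  set.seed(19)
  y <- rnorm(301)
  for (sigma in c(1, 2, 3.5)) {
    got <- smooth_gaussian(y, preprocess_config(smooth_sigma = sigma))
    expect_equal(got, smooth_oracle(y, sigma), tolerance = 1e-10)
  }
})

test_that("smoothing preserves constants and unit-impulse kernel shape", {
  cfg <- preprocess_config(smooth_sigma = 2)
  expect_equal(smooth_gaussian(rep(3.7, 100), cfg), rep(3.7, 100),
               tolerance = 1e-12)
  imp <- numeric(101)
  imp[51] <- 1
  out <- smooth_gaussian(imp, cfg)
  r <- ceiling(4 * 2)
  k <- exp(-0.5 * (-r:r)^2 / 4)
  k <- k / sum(k)
  expect_equal(out[(51 - r):(51 + r)], k, tolerance = 1e-12)
  expect_equal(sum(out), 1, tolerance = 1e-12)
  # max abs never increases for nonnegative input
  set.seed(5)
  z <- abs(rnorm(200))
  expect_lte(max(smooth_gaussian(z, cfg)), max(z))
})

test_that("min-max normalization attains exactly 0 and 1, with a defined
           degenerate case", {
  expect_equal(normalize_minmax(c(2, 4, 6)), c(0, 0.5, 1))
  v <- c(0, 0.25, 1, 0.5)
  expect_identical(normalize_minmax(v), v)
  expect_warning(out <- normalize_minmax(rep(2, 10)), "constant")
  expect_equal(out, numeric(10))
})

test_that("pipeline preserves ids, order, and the planted group ranking", {
  plan <- binary_cohort_plan(samples_per_class = 4, spectra_per_sample = 10,
                             seed = 23, noise = zero_noise())
  ds <- simulate_cohort(plan)
  pp <- quiet_pp(ds)
  expect_identical(pp$info, ds$info)
  expect_true(all(pp$intensities >= 0 & pp$intensities <= 1))
  i1080 <- which(ds$grid$values == 1080)
  cancer <- ds$info$class == "cancer"
  expect_gt(mean(pp$intensities[cancer, i1080]),
            mean(pp$intensities[!cancer, i1080]))
})

test_that("step order is configurable and unknown steps are rejected", {
  plan <- tiny_binary_plan(samples = 2, spectra = 2, seed = 29)
  ds <- simulate_cohort(plan)
  pp <- quiet_pp(ds, steps = c("baseline", "despike", "smooth", "normalize"))
  expect_equal(pp$preprocessed,
               c("baseline", "despike", "smooth", "normalize"))
  pp2 <- quiet_pp(ds, steps = c("despike", "baseline", "smooth"))
  expect_false("normalize" %in% pp2$preprocessed)
  expect_error(quiet_pp(ds, steps = "rescale"), "unknown preprocessing step")
})
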