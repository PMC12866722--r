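# Interpretability layer: importance normalization, differential spectra
# arithmetic, peak-ratio statistics and their invariances.

train_toy_model <- function(seed = 51, p = 150, n = 160, epochs = 25) {
  set.seed(seed)
  y <- rep(c("a", "b"), each = n / 2)
  x <- matrix(rnorm(n * p, sd = 0.05), n, p)
  x[y == "b", 70:80] <- x[y == "b", 70:80] + 0.8
  list(fit = train_cnn(x, y, model_config(2, epochs = epochs, seed = seed)),
       x = x, y = y)
}

test_that("importance profiles are percent-normalized for both methods", {
  toy <- train_toy_model()
  for (m in c("saliency", "weights")) {
    imp <- feature_importance(toy$fit, toy$x, method = m)
    expect_equal(sum(imp$percent), 100, tolerance = 0.01)
    expect_true(all(imp$percent >= 0))
    expect_equal(nrow(imp), ncol(toy$x))
  }
})

test_that("band aggregation is plain window arithmetic", {
  toy <- train_toy_model()
  imp <- feature_importance(toy$fit, toy$x)
  # synthetic uniform profile: every band holds width/total of the mass
  uni <- imp
  uni$percent <- rep(100 / nrow(uni), nrow(uni))
  bs <- band_scores(uni, width = 21)
  expect_equal(unique(round(bs$percent, 10)),
               round(21 * 100 / nrow(uni), 10))
  bi <- band_importance(uni, centers = uni$wavenumber[75], window = 10)
  expect_equal(unname(bi), 21 * 100 / nrow(uni), tolerance = 1e-9)
})

test_that("saliency concentrates on the discriminative region", {
  toy <- train_toy_model()
  imp <- feature_importance(toy$fit, toy$x)
  bs <- band_scores(imp, width = 21)
  # the top band overlaps channels 70..80
  top <- bs[1, ]
  expect_true(top$start_wavenumber <= 80 &&
                top$start_wavenumber + 20 >= 70)
})

test_that("differential spectra: zero for identical groups, antisymmetric,
           exact for noiseless planted deltas", {
  plan <- binary_cohort_plan(samples_per_class = 2, spectra_per_sample = 3,
                             seed = 53, noise = zero_noise())
  plan$classes[[2]] <- cancer_signature("cancer", delta_1080 = 0.2,
                                        delta_1380 = -0.1)
  ds <- simulate_cohort(plan)
  i1080 <- which(ds$grid$values == 1080)
  dsp <- differential_spectrum(ds, "cancer", "non_cancer")
  expect_equal(dsp$delta[i1080], 0.2, tolerance = 1e-12)
  # off-band channel far from every peak
  i500 <- which(ds$grid$values == 500)
  expect_equal(dsp$delta[i500], 0, tolerance = 1e-9)
  # antisymmetry under group swap, exactly
  rev <- differential_spectrum(ds, "non_cancer", "cancer")
  expect_identical(dsp$delta, -rev$delta)
  # identical groups give the zero vector
  same <- differential_spectrum(ds, "cancer", "cancer")
  expect_identical(same$delta, numeric(length(ds$grid$values)))
  expect_error(differential_spectrum(ds, "missing"), "no spectra")
})

test_that("peak ratios are nearest-channel quotients, scale-invariant, and
           Welch-tested", {
  plan <- binary_cohort_plan(samples_per_class = 3, spectra_per_sample = 10,
                             seed = 57)
  ds <- simulate_cohort(plan)
  pp <- quiet_pp(ds, steps = c("despike", "baseline", "smooth"))
  rt <- peak_ratio_test(pp, 1080, 643)
  # single-spectrum hand check: first control spectrum
  i_n <- which(ds$grid$values == 1080)
  i_r <- which(ds$grid$values == 643)
  first_nc <- which(pp$info$class == "non_cancer")[1]
  expect_equal(rt$ratios$non_cancer[1],
               pp$intensities[first_nc, i_n] /
                 pp$intensities[first_nc, i_r],
               tolerance = 1e-12)
  # invariance to per-spectrum positive rescaling
  sc <- pp
  set.seed(1)
  fac <- runif(n_spectra(pp), 0.5, 3)
  sc$intensities <- sc$intensities * fac
  rt_sc <- peak_ratio_test(sc, 1080, 643)
  expect_equal(rt_sc$ratios, rt$ratios, tolerance = 1e-12)
  # statistic agrees with stats::t.test on the same ratios
  tt <- t.test(rt$ratios[[1]], rt$ratios[[2]])
  expect_equal(rt$t, unname(tt$statistic))
  expect_equal(rt$p, tt$p.value)
  expect_true(rt$stars %in% c("ns", "*", "**", "***", "****"))
})

test_that("star codes follow the declared p-value mapping", {
  expect_equal(p_stars(0.2), "ns")
  expect_equal(p_stars(0.04), "*")
  expect_equal(p_stars(0.004), "**")
  expect_equal(p_stars(4e-4), "***")
  expect_equal(p_stars(4e-5), "****")
})

test_that("an absent reference band aborts the ratio test", {
  plan <- tiny_binary_plan(samples = 2, spectra = 5, seed = 59)
  ds <- simulate_cohort(plan)
  broken <- ds
  i_r <- which.min(abs(ds$grid$values - 643))
  broken$intensities[, i_r] <- -1
  expect_error(peak_ratio_test(broken, 1080, 643), "reference band absent")
  expect_error(peak_ratio_test(ds, 1080, 200), "on the wavenumber grid")
})
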