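# Shared fixtures and independent oracles. Oracles are deliberately naive
# (direct summation, pairwise counting) so they cannot share bugs with the
# implementation paths they check.

# coarse grid covering the three anchor bands: fast unit-test cohorts
coarse_grid <- function(step = 10) wavenumber_grid(400, 1800, step)

# small binary plan on the coarse grid
tiny_binary_plan <- function(samples = 4, spectra = 5, seed = 1,
                             noise = noise_model(), grid = coarse_grid()) {
  binary_cohort_plan(samples_per_class = samples, spectra_per_sample = spectra,
                     seed = seed, noise = noise, grid = grid)
}

# direct O(n k) Gaussian convolution with reflect boundary: the oracle for
# the smoothing kernel (same kernel definition, independent summation)
smooth_oracle <- function(y, sigma) {
  p <- length(y)
  r <- max(1, ceiling(4 * sigma))
  k <- exp(-0.5 * (-r:r)^2 / sigma^2)
  k <- k / sum(k)
  reflect <- function(t) {
    while (t < 1 || t > p) {
      if (t < 1) t <- 1 - t
      if (t > p) t <- 2 * p + 1 - t
    }
    t
  }
  vapply(seq_len(p), function(i)
    sum(k * vapply(-r:r, function(j) y[reflect(i + j)], numeric(1))),
    numeric(1))
}

# pairwise-concordance AUC oracle: P(score_pos > score_neg) + 0.5 ties
auc_concordance <- function(scores, is_positive) {
  pos <- scores[is_positive]
  neg <- scores[!is_positive]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (sp in pos) for (sn in neg)
    tot <- tot + (sp > sn) + 0.5 * (sp == sn)
  tot / (length(pos) * length(neg))
}

# fast quiet preprocessing for tests
quiet_pp <- function(ds, ...) suppressMessages(preprocess_pipeline(ds, ...))

# implementation path under test: threshold-sweep ROC + trapezoid
roc_curve_auc <- function(scores, is_positive) {
  sersdx:::roc_curve(scores, is_positive)$auc
}
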