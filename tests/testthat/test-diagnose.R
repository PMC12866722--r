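# Sample-level aggregation, evaluation report, ROC/AUC oracle equivalence,
# probability heatmap invariants.

# build a predictions data.frame by hand
fake_pred <- function(sample_ids, classes, probs, truth, fold = 1L) {
  df <- data.frame(spectrum_id = paste0("sp", seq_along(sample_ids)),
                   sample_id = sample_ids, class = truth, fold = fold,
                   stringsAsFactors = FALSE)
  df[paste0("cnn_p_", classes)] <- probs
  df[paste0("ref_p_", classes)] <- probs
  df
}

test_that("per-sample mean probability matches the arithmetic mean", {
  classes <- c("cancer", "non_cancer")
  probs <- cbind(c(0.9, 0.7, 0.8, 0.2), c(0.1, 0.3, 0.2, 0.8))
  pred <- fake_pred(c("s1", "s1", "s1", "s2"), classes, probs,
                    c("cancer", "cancer", "cancer", "non_cancer"))
  d <- aggregate_samples(pred)
  expect_equal(d$mean_p_cancer[d$sample_id == "s1"], 0.8)
  expect_equal(d$n_spectra, c(3L, 1L))
  # single spectrum: diagnosis equals that spectrum's vector
  expect_equal(d$mean_p_cancer[d$sample_id == "s2"], 0.2)
  # independent summation oracle to 1e-12
  oracle <- sum(probs[1:3, 1]) / 3
  expect_equal(d$mean_p_cancer[1], oracle, tolerance = 1e-12)
  # aggregate_sample picks the right row
  expect_equal(aggregate_sample(pred, "s2")$sample_id, "s2")
  expect_error(aggregate_sample(pred, "nope"), "no predictions")
})

test_that("uniform probabilities break ties toward the first class", {
  classes <- c("alpha", "beta", "gamma")
  probs <- matrix(1 / 3, 4, 3)
  pred <- fake_pred(rep("s1", 4), classes, probs, rep("beta", 4))
  d <- aggregate_samples(pred)
  expect_equal(d$call, "alpha")
})

test_that("binary threshold calls use the positive-class probability", {
  classes <- c("cancer", "non_cancer")
  probs <- cbind(c(0.55, 0.45), c(0.45, 0.55))
  pred <- fake_pred(c("s1", "s2"), classes, probs,
                    c("cancer", "non_cancer"))
  d <- aggregate_samples(pred, threshold = 0.5)
  expect_equal(d$call, c("cancer", "non_cancer"))
  d2 <- aggregate_samples(pred, threshold = 0.6)
  expect_equal(d2$call, c("non_cancer", "non_cancer"))
})

test_that("evaluation report reproduces textbook contingency numbers", {
  classes <- c("cancer", "non_cancer")
  # 9 TP, 1 FN, 10 TN, 0 FP at the 0.5 threshold
  p_cancer <- c(seq(0.6, 0.95, length.out = 9), 0.4,
                seq(0.05, 0.45, length.out = 10))
  truth <- c(rep("cancer", 10), rep("non_cancer", 10))
  pred <- fake_pred(paste0("s", 1:20), classes,
                    cbind(p_cancer, 1 - p_cancer), truth)
  d <- aggregate_samples(pred, threshold = 0.5)
  ev <- evaluate_diagnoses(d)
  pc <- ev$per_class
  expect_equal(pc$sensitivity[pc$class == "cancer"], 0.9)
  expect_equal(pc$specificity[pc$class == "cancer"], 1.0)
  expect_equal(ev$accuracy, 19 / 20)
  expect_equal(sum(ev$confusion), 20)
  expect_equal(unname(rowSums(ev$confusion)), c(10, 10))
})

test_that("perfect calls give an identity confusion matrix and AUC 1", {
  classes <- c("a", "b", "c")
  probs <- diag(3)[rep(1:3, each = 2), ]
  pred <- fake_pred(paste0("s", 1:6), classes, probs,
                    rep(c("a", "b", "c"), each = 2))
  ev <- evaluate_diagnoses(aggregate_samples(pred))
  expect_true(all(diag(ev$confusion) == 2))
  expect_equal(ev$accuracy, 1.0)
  expect_equal(unname(ev$auc), rep(1, 3))
})

test_that("threshold-sweep AUC equals the pairwise-concordance oracle and
           is invariant to monotone rescaling", {
  set.seed(43)
  for (rep in 1:5) {
    n <- 16
    scores <- round(runif(n), 2) # ties likely
    pos <- runif(n) < 0.5
    if (!any(pos) || all(pos)) next
    got <- roc_curve_auc(scores, pos)
    expect_equal(got, auc_concordance(scores, pos), tolerance = 1e-12)
    # monotone transform leaves the AUC unchanged
    expect_equal(roc_curve_auc(exp(3 * scores), pos), got,
                 tolerance = 1e-12)
  }
})

test_that("probability heatmap rows are normalized and dimensioned", {
  plan <- tiny_binary_plan(samples = 3, spectra = 4, seed = 47)
  ds <- simulate_cohort(plan)
  pp <- quiet_pp(ds)
  cv <- cross_validate(pp, model_config(2, epochs = 4, seed = 3), k = 3)
  dir <- withr::local_tempdir()
  m <- probability_heatmap(cv, csv = file.path(dir, "hm.csv"))
  expect_equal(dim(m), c(n_spectra(ds), 2L))
  expect_true(all(abs(rowSums(m) - 1) < 1e-6))
  expect_true(file.exists(file.path(dir, "hm.csv")))
  m2 <- probability_heatmap(cv, subsample = 2)
  expect_equal(nrow(m2), 2L * n_samples(ds))
})
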