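# Model module: architecture shape arithmetic, grouped stratified folds,
# trainer convergence/determinism, refiner contracts, cross-validation
# partition properties.

test_that("layer shape report matches the printed architecture", {
  spec <- build_cnn(model_config(2), 1401)
  expect_equal(attr(spec, "conv_length"), 1399L)
  expect_equal(attr(spec, "pool_length"), 699L)
  expect_equal(attr(spec, "flatten_size"), 64L * 699L) # 44736
  spec2 <- build_cnn(model_config(2), 4)
  expect_equal(attr(spec2, "conv_length"), 2L)
  expect_equal(attr(spec2, "pool_length"), 1L)
  expect_equal(attr(spec2, "flatten_size"), 64L)
  expect_error(build_cnn(model_config(2), 3), "exceed")
})

test_that("architecture knobs outside the supported geometry error early", {
  expect_error(model_config(2, conv_stride = 2), "stride")
  expect_error(model_config(2, pool_size = 3), "pool_size")
  expect_error(model_config(2, dropout_rate = 1), "dropout_rate")
})

test_that("folds are stratified, grouped, and deterministic", {
  plan <- tiny_binary_plan(samples = 10, spectra = 3, seed = 31)
  ds <- simulate_cohort(plan)
  f1 <- make_folds(ds, k = 5, seed = 9)
  f2 <- make_folds(ds, k = 5, seed = 9)
  expect_identical(f1, f2)
  # 10 samples/class over 5 folds -> exactly 2 per class per fold
  tab <- table(f1$class, f1$fold)
  expect_true(all(tab == 2))
  # every sample in exactly one fold; all spectra inherit it
  expect_equal(sort(unique(f1$sample_id)), sort(unique(ds$info$sample_id)))
  sp <- f1$fold[match(ds$info$sample_id, f1$sample_id)]
  expect_false(anyNA(sp))
  by_sample <- tapply(sp, ds$info$sample_id, function(v) length(unique(v)))
  expect_true(all(by_sample == 1))
  expect_error(make_folds(ds, k = 11), "fewer samples")
})

test_that("the CNN fits a separable problem and is seed-deterministic", {
  set.seed(33)
  n <- 120
  p <- 120
  y <- rep(c("a", "b"), each = n / 2)
  x <- matrix(rnorm(n * p, sd = 0.05), n, p)
  x[y == "b", 50:60] <- x[y == "b", 50:60] + 1
  cfg <- model_config(2, epochs = 30, seed = 7)
  fit <- train_cnn(x, y, cfg)
  h <- fit$history
  expect_equal(h$train_acc[30], 1.0)
  expect_lt(h$train_loss[30], h$train_loss[1])
  pr <- predict(fit, x)
  expect_true(all(abs(rowSums(pr) - 1) < 1e-6))
  expect_true(all(pr >= 0))
  fit2 <- train_cnn(x, y, cfg)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$weights, fit2$weights)
  expect_error(train_cnn(x, rep("a", n), cfg), "single class")
})

test_that("the scheduler reduces the learning rate on a plateau", {
  set.seed(35)
  # pure-noise labels: loss plateaus quickly
  x <- matrix(rnorm(80 * 60), 80, 60)
  y <- rep(c("a", "b"), 40)
  cfg <- model_config(2, epochs = 40, seed = 11, scheduler_patience = 3)
  fit <- train_cnn(x, y, cfg)
  expect_lt(min(fit$history$lr), cfg$lr)
  expect_equal(max(fit$history$lr), cfg$lr)
})

test_that("refiner refuses in-fold probabilities and preserves one-hot
           argmax", {
  set.seed(37)
  n <- 300
  classes <- c("a", "b")
  y <- sample(classes, n, replace = TRUE)
  onehot <- matrix(0, n, 2, dimnames = list(NULL, classes))
  onehot[cbind(seq_len(n), match(y, classes))] <- 1
  cfg <- model_config(2, epochs = 60, seed = 13)
  expect_error(train_refiner(onehot, y, cfg), "leakage")
  ref <- train_refiner(oof_probs(onehot), y, cfg)
  out <- predict(ref, onehot)
  expect_true(all(abs(rowSums(out) - 1) < 1e-6))
  expect_equal(max.col(out), max.col(onehot)) # nothing to correct
  # random inputs still sum to 1
  rnd <- matrix(runif(20), 10, 2, dimnames = list(NULL, classes))
  rnd <- rnd / rowSums(rnd)
  expect_true(all(abs(rowSums(predict(ref, rnd)) - 1) < 1e-6))
})

test_that("refiner can exclude the fold it will refine", {
  set.seed(39)
  n <- 200
  classes <- c("a", "b")
  y <- sample(classes, n, replace = TRUE)
  pr <- matrix(runif(2 * n), n, 2, dimnames = list(NULL, classes))
  pr <- pr / rowSums(pr)
  fold <- rep(1:4, each = 50)
  cfg <- model_config(2, epochs = 5, seed = 1)
  expect_silent(train_refiner(oof_probs(pr, fold), y, cfg,
                              exclude_fold = 2))
  expect_error(train_refiner(oof_probs(pr), y, cfg, exclude_fold = 2),
               "fold attribute")
})

test_that("cross-validation partitions predictions and never leaks
           samples", {
  plan <- tiny_binary_plan(samples = 6, spectra = 4, seed = 41)
  ds <- simulate_cohort(plan)
  pp <- quiet_pp(ds)
  cfg <- model_config(2, epochs = 6, seed = 15)
  cv <- cross_validate(pp, cfg, k = 3)
  pred <- cv$predictions
  # every spectrum exactly once
  expect_setequal(pred$spectrum_id, ds$info$spectrum_id)
  expect_false(anyNA(pred[paste0("cnn_p_", cv$classes)]))
  expect_false(anyNA(pred[paste0("ref_p_", cv$classes)]))
  # fold of a spectrum equals the fold of its sample
  expect_true(all(tapply(pred$fold, pred$sample_id,
                         function(v) length(unique(v))) == 1))
  # probability normalization for both stages
  expect_true(all(abs(rowSums(cv_probs(cv, "cnn")) - 1) < 1e-6))
  expect_true(all(abs(rowSums(cv_probs(cv, "refined")) - 1) < 1e-6))
  # determinism end to end
  cv2 <- cross_validate(pp, cfg, k = 3)
  expect_identical(cv$predictions, cv2$predictions)
})
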