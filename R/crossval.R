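# Grouped k-fold cross-validation of the CNN + stacked-refiner pipeline.
# Every spectrum receives exactly one out-of-fold CNN prediction; the
# stacked refiner is trained on those out-of-fold probabilities, so every
# refiner input was produced by a CNN that never saw the sample.

#' Cross-validate the hybrid CNN + refiner classifier
#'
#' For each fold: a CNN is trained on the training samples' spectra (the
#' fold's own spectra serve as the monitored validation split), then
#' predicts the fold's spectra out-of-fold. After all folds, one stacked
#' MLP refiner is trained on the pooled out-of-fold probabilities (every
#' input row comes from a CNN that never saw that sample) and applied to
#' them. Fold membership is at the sample level; a leakage check asserts
#' that train and validation sample ids never intersect.
#'
#' @param ds a preprocessed [sers_cohort()]
#' @param cfg a [model_config()]
#' @param k number of folds
#' @param verbose per-fold progress messages
#' @return an object of class `sers_cv`: `predictions` (data.frame with
#'   `spectrum_id`, `sample_id`, `class`, `fold`, `cnn_p_*`, `ref_p_*`),
#'   `folds`, `histories`, `models`, `classes`, `cfg`
#' @export
cross_validate <- function(ds, cfg, k = 5L, verbose = FALSE) {
  stopifnot(inherits(ds, "sers_cohort"), inherits(cfg, "model_config"))
  classes <- sort(unique(ds$info$class))
  if (length(classes) != cfg$n_classes)
    stop("cfg$n_classes does not match the cohort's class count")
  folds <- make_folds(ds, k, seed = cfg$seed)
  sp_fold <- fold_of_spectra(folds, ds)
  n <- n_spectra(ds)
  X <- ds$intensities
  y <- ds$info$class

  cnn_probs <- matrix(NA_real_, n, length(classes),
                      dimnames = list(NULL, classes))
  models <- vector("list", k)
  histories <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- which(sp_fold != f)
    va <- which(sp_fold == f)
    if (length(intersect(ds$info$sample_id[tr], ds$info$sample_id[va])))
      stop("grouped-CV leakage: train and validation folds share samples ",
           "(fold ", f, ")")
    cfg_f <- cfg
    cfg_f$seed <- derive_seed(cfg$seed, f)
    fit <- tryCatch(
      train_cnn(X[tr, , drop = FALSE], y[tr], cfg_f,
                x_val = X[va, , drop = FALSE], y_val = y[va],
                classes = classes),
      error = function(e) stop("fold ", f, ": ", conditionMessage(e),
                               call. = FALSE))
    cnn_probs[va, ] <- predict(fit, X[va, , drop = FALSE])
    models[[f]] <- fit
    histories[[f]] <- fit$history
    if (verbose)
      message(sprintf("fold %d/%d: val acc %.3f", f, k,
                      fit$history$val_acc[cfg$epochs]))
  }
  stopifnot(!anyNA(cnn_probs)) # partition property: one prediction each

  # one stacked refiner over all out-of-fold CNN probabilities: every row
  # was predicted by a CNN that never saw that sample, which is the
  # leakage guarantee the stacking needs
  oof <- oof_probs(cnn_probs, fold = sp_fold)
  refiner <- train_refiner(oof, y, cfg)
  ref_probs <- predict(refiner, cnn_probs)

  pred <- data.frame(ds$info[c("spectrum_id", "sample_id", "class")],
                     fold = sp_fold, stringsAsFactors = FALSE)
  cn <- paste0("cnn_p_", classes)
  rn <- paste0("ref_p_", classes)
  pred[cn] <- as.data.frame(cnn_probs)
  pred[rn] <- as.data.frame(ref_probs)
  structure(list(predictions = pred, folds = folds, histories = histories,
                 models = list(cnn = models, refiner = refiner),
                 classes = classes, cfg = cfg, k = k),
            class = "sers_cv")
}

#' @export
print.sers_cv <- function(x, ...) {
  cat(sprintf("<sers_cv> %d folds, %d spectra, %d classes\n", x$k,
              nrow(x$predictions), length(x$classes)))
  invisible(x)
}

#' Extract spectrum-level probability matrices from a cross-validation
#'
#' @param cv a [cross_validate()] result
#' @param use `"refined"` or `"cnn"`
#' @return matrix of out-of-fold class probabilities
#' @export
cv_probs <- function(cv, use = c("refined", "cnn")) {
  use <- match.arg(use)
  pre <- if (use == "refined") "ref_p_" else "cnn_p_"
  m <- as.matrix(cv$predictions[paste0(pre, cv$classes)])
  colnames(m) <- cv$classes
  m
}
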