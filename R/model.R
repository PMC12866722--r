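# The hybrid classifier: a 1D CNN over preprocessed spectra whose class
# probabilities are refined by a stacked MLP trained on out-of-fold
# predictions. Training is grouped (sample-level) five-fold
# cross-validation so no sample's spectra straddle a fold boundary.

#' Model configuration
#'
#' Architecture and training schedule of the spectrum-level CNN and the MLP
#' probability refiner. The convolution/pooling geometry (64 filters,
#' kernel 3, stride 1; max-pool size 2, stride 2), the two 64-neuron refiner
#' hidden layers, the 50-epoch / batch-64 schedule and the plateau patience
#' of 5 are the reference architecture; the dense stack width, dropout rate
#' and optimizer settings are package defaults (see the methods vignette).
#'
#' @param n_classes number of classes (2 for presence/early-stage, 11 for
#'   typing)
#' @param conv_filters,conv_kernel,conv_stride convolution geometry (valid
#'   padding; only stride 1 is supported)
#' @param pool_size,pool_stride max-pooling geometry (only 2/2 supported)
#' @param dropout_rate dropout on the convolution activations, in `[0, 1)`
#' @param leaky slope of the leaky-ReLU used by the CNN's convolution and
#'   dense hidden activations (the refiner keeps a pure ReLU); a small
#'   nonzero slope keeps the all-dead activation state escapable
#' @param fc_sizes integer vector of dense hidden-layer widths after flatten
#' @param mlp_hidden hidden-layer widths of the probability refiner
#' @param mlp_epochs,mlp_lr training schedule of the refiner; the meta-MLP
#'   is tiny (inputs are class-probability vectors), so it is trained to
#'   convergence independently of the CNN schedule
#' @param epochs,batch_size,lr training schedule (Adam, cross-entropy)
#' @param clip_norm global gradient-norm clipping threshold (0 disables)
#' @param scheduler_patience,scheduler_factor reduce-on-plateau learning-rate
#'   scheduler: after `patience` epochs without validation-loss improvement
#'   the rate is multiplied by `factor`
#' @param class_weights `NULL` (uniform), `"balanced"`
#'   (inverse-frequency), or a numeric vector, one weight per class
#' @param seed integer seed controlling initialization, shuffling and
#'   dropout
#' @return an object of class `model_config`
#' @export
model_config <- function(n_classes, conv_filters = 64L, conv_kernel = 3L,
                         conv_stride = 1L, pool_size = 2L, pool_stride = 2L,
                         dropout_rate = 0.25, leaky = 0.01,
                         fc_sizes = 16L,
                         mlp_hidden = c(64L, 64L), mlp_epochs = 300L,
                         mlp_lr = 1e-3, epochs = 50L,
                         batch_size = 64L, lr = 3e-4, clip_norm = 1,
                         scheduler_patience = 5L, scheduler_factor = 0.5,
                         class_weights = NULL, seed = 1L) {
  assert_scalar_num(n_classes, "n_classes", lower = 2)
  if (conv_stride != 1L) stop("only conv_stride = 1 is supported")
  if (pool_size != 2L || pool_stride != 2L)
    stop("only pool_size = 2, pool_stride = 2 is supported")
  assert_scalar_num(conv_filters, "conv_filters", lower = 1)
  assert_scalar_num(conv_kernel, "conv_kernel", lower = 1)
  assert_scalar_num(dropout_rate, "dropout_rate", lower = 0, upper = 1 - 1e-9)
  assert_scalar_num(leaky, "leaky", lower = 0, upper = 0.999)
  assert_scalar_num(epochs, "epochs", lower = 1)
  assert_scalar_num(batch_size, "batch_size", lower = 1)
  assert_scalar_num(lr, "lr", lower = 1e-12)
  assert_scalar_num(clip_norm, "clip_norm", lower = 0)
  assert_scalar_num(scheduler_patience, "scheduler_patience", lower = 0)
  assert_scalar_num(scheduler_factor, "scheduler_factor", lower = 1e-6,
                    upper = 1)
  stopifnot(all(fc_sizes >= 1), all(mlp_hidden >= 1))
  assert_scalar_num(mlp_epochs, "mlp_epochs", lower = 1)
  assert_scalar_num(mlp_lr, "mlp_lr", lower = 1e-12)
  if (is.numeric(class_weights) && length(class_weights) != n_classes)
    stop("class_weights must have one weight per class")
  structure(list(n_classes = as.integer(n_classes),
                 conv_filters = as.integer(conv_filters),
                 conv_kernel = as.integer(conv_kernel),
                 conv_stride = 1L, pool_size = 2L, pool_stride = 2L,
                 dropout_rate = dropout_rate, leaky = leaky,
                 fc_sizes = as.integer(fc_sizes),
                 mlp_hidden = as.integer(mlp_hidden),
                 mlp_epochs = as.integer(mlp_epochs),
                 mlp_lr = mlp_lr,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 clip_norm = clip_norm,
                 scheduler_patience = as.integer(scheduler_patience),
                 scheduler_factor = scheduler_factor,
                 class_weights = class_weights, seed = as.integer(seed)),
            class = "model_config")
}

#' Describe the CNN layer stack for a given input length
#'
#' Reports exact per-layer output shapes of
#' conv(valid) -> ReLU -> dropout -> maxpool(2,2) -> flatten -> dense stack
#' -> softmax.
#'
#' @param cfg a [model_config()]
#' @param input_length number of spectral channels
#' @return an object of class `sers_cnn_spec`: a data.frame of layers with
#'   `conv_length`, `pool_length`, `flatten_size` attributes
#' @examples
#' build_cnn(model_config(2), 1401)  # conv 1399, pool 699, flatten 44736
#' @export
build_cnn <- function(cfg, input_length) {
  stopifnot(inherits(cfg, "model_config"))
  if (input_length <= cfg$conv_kernel)
    stop("input_length must exceed the convolution kernel size")
  conv_len <- input_length - cfg$conv_kernel + 1L
  pool_len <- conv_len %/% 2L
  if (pool_len < 1L) stop("input too short for pooling")
  flat <- cfg$conv_filters * pool_len
  widths <- c(flat, cfg$fc_sizes, cfg$n_classes)
  layers <- data.frame(
    layer = c("input",
              sprintf("conv1d(%d,k%d,s1)+relu", cfg$conv_filters,
                      cfg$conv_kernel),
              sprintf("dropout(%.2f)", cfg$dropout_rate), "maxpool(2,2)",
              "flatten",
              sprintf("dense(%d)+relu", cfg$fc_sizes),
              sprintf("dense(%d)+softmax", cfg$n_classes)),
    output_shape = c(sprintf("%d", input_length),
                     sprintf("%d x %d", conv_len, cfg$conv_filters),
                     sprintf("%d x %d", conv_len, cfg$conv_filters),
                     sprintf("%d x %d", pool_len, cfg$conv_filters),
                     sprintf("%d", flat),
                     sprintf("%d", cfg$fc_sizes),
                     sprintf("%d", cfg$n_classes)),
    stringsAsFactors = FALSE)
  rownames(layers) <- NULL
  structure(layers, class = c("sers_cnn_spec", "data.frame"),
            conv_length = conv_len, pool_length = pool_len,
            flatten_size = flat, widths = widths)
}

#' Stratified grouped k-fold assignment at the sample level
#'
#' Samples (not spectra) are partitioned so that every sample lands in
#' exactly one validation fold and per-fold class counts are within one
#' sample of the stratified target. All spectra of a sample inherit its
#' fold.
#'
#' @param ds a [sers_cohort()]
#' @param k number of folds
#' @param seed integer seed (deterministic assignment)
#' @return an object of class `sers_folds`: data.frame with `sample_id`,
#'   `class`, `fold` (1..k)
#' @export
make_folds <- function(ds, k = 5L, seed = 1L) {
  stopifnot(inherits(ds, "sers_cohort"), k >= 2L)
  smp <- unique(ds$info[c("sample_id", "class")])
  counts <- table(smp$class)
  if (any(counts < k))
    stop("class '", names(counts)[which.min(counts)],
         "' has fewer samples (", min(counts), ") than folds (", k, ")")
  set.seed(seed)
  out <- do.call(rbind, lapply(split(smp, smp$class), function(g) {
    g <- g[sample.int(nrow(g)), , drop = FALSE]
    g$fold <- rep_len(seq_len(k), nrow(g))
    g
  }))
  rownames(out) <- NULL
  structure(out[order(out$sample_id), ], class = c("sers_folds",
                                                   "data.frame"))
}

# map each spectrum to its sample's fold
fold_of_spectra <- function(folds, ds) {
  folds$fold[match(ds$info$sample_id, folds$sample_id)]
}

# resolve class weight spec to a numeric vector over `classes`
resolve_class_weights <- function(cfg, y, classes) {
  if (is.null(cfg$class_weights)) return(rep(1, length(classes)))
  if (identical(cfg$class_weights, "balanced")) {
    tab <- table(factor(y, levels = classes))
    w <- length(y) / (length(classes) * pmax(as.numeric(tab), 1))
    return(as.numeric(w))
  }
  as.numeric(cfg$class_weights)
}

#' Train the spectrum-level CNN
#'
#' Minimizes (optionally class-weighted) cross-entropy with Adam for
#' `cfg$epochs` epochs at batch size `cfg$batch_size`, reducing the learning
#' rate by `scheduler_factor` whenever the monitored loss (validation if
#' given, else training) fails to improve for `scheduler_patience` epochs.
#' Deterministic given `cfg$seed`.
#'
#' @param x numeric matrix of preprocessed spectra (rows = spectra)
#' @param y class labels (character or factor), one per row
#' @param cfg a [model_config()]
#' @param x_val,y_val optional validation split for the scheduler and the
#'   accuracy/loss history
#' @param classes class vocabulary; defaults to `sort(unique(y))`
#' @return an object of class `sers_cnn` with `weights`, `history`
#'   (per-epoch data.frame), `classes`, `cfg`, `input_length`
#' @export
train_cnn <- function(x, y, cfg, x_val = NULL, y_val = NULL,
                      classes = NULL) {
  stopifnot(is.matrix(x), nrow(x) == length(y),
            inherits(cfg, "model_config"))
  classes <- classes %||% sort(unique(as.character(y)))
  if (length(unique(as.character(y))) < 2L)
    stop("training split contains a single class")
  if (length(classes) != cfg$n_classes)
    stop("cfg$n_classes (", cfg$n_classes, ") does not match the class ",
         "vocabulary (", length(classes), ")")
  yi <- match(as.character(y), classes) - 1L
  if (anyNA(yi)) stop("labels outside the class vocabulary")
  has_val <- !is.null(x_val)
  yvi <- if (has_val) match(as.character(y_val), classes) - 1L else
    integer(0)
  cw <- resolve_class_weights(cfg, y, classes)
  fit <- nn_train_cpp(x, yi, if (has_val) x_val else
                        matrix(0, 0, ncol(x)), yvi,
                      use_conv = TRUE, n_classes = cfg$n_classes,
                      filters = cfg$conv_filters, kernel = cfg$conv_kernel,
                      fc_sizes = cfg$fc_sizes,
                      dropout = cfg$dropout_rate, leaky = cfg$leaky,
                      epochs = cfg$epochs,
                      batch = cfg$batch_size, lr0 = cfg$lr,
                      clip_norm = cfg$clip_norm,
                      patience = cfg$scheduler_patience,
                      factor = cfg$scheduler_factor, class_weights = cw,
                      seed = cfg$seed, restore_best = FALSE)
  history <- data.frame(epoch = seq_len(cfg$epochs),
                        train_loss = fit$history$train_loss,
                        train_acc = fit$history$train_acc,
                        val_loss = fit$history$val_loss,
                        val_acc = fit$history$val_acc,
                        lr = fit$history$lr)
  structure(list(weights = fit[c("Wc", "bc", "W", "b")], history = history,
                 classes = classes, cfg = cfg, input_length = ncol(x)),
            class = "sers_cnn")
}

#' @export
print.sers_cnn <- function(x, ...) {
  cat(sprintf("<sers_cnn> %d classes, input %d channels\n",
              length(x$classes), x$input_length))
  h <- x$history
  cat(sprintf("  final epoch: train loss %.4f acc %.3f\n",
              h$train_loss[nrow(h)], h$train_acc[nrow(h)]))
  invisible(x)
}

#' Predict class probabilities from a trained CNN
#'
#' @param object a [train_cnn()] fit
#' @param x matrix of spectra
#' @param ... unused
#' @return matrix of class probabilities (rows sum to 1)
#' @export
predict.sers_cnn <- function(object, x, ...) {
  stopifnot(is.matrix(x), ncol(x) == object$input_length)
  pr <- nn_predict_cpp(object$weights, x, use_conv = TRUE,
                       n_classes = object$cfg$n_classes,
                       filters = object$cfg$conv_filters,
                       kernel = object$cfg$conv_kernel,
                       fc_sizes = object$cfg$fc_sizes,
                       leaky = object$cfg$leaky,
                       batch = object$cfg$batch_size)
  colnames(pr) <- object$classes
  pr
}

#' Mark a probability matrix as out-of-fold
#'
#' The stacked refiner refuses probabilities that were not produced
#' out-of-fold (a CNN predicting spectra it trained on would leak); this
#' marks a matrix as safe, optionally recording which fold produced each
#' row.
#'
#' @param probs matrix of CNN class probabilities
#' @param fold optional integer vector, producing fold per row
#' @return `probs` with the `oof` attribute set
#' @export
oof_probs <- function(probs, fold = NULL) {
  stopifnot(is.matrix(probs))
  attr(probs, "oof") <- TRUE
  if (!is.null(fold)) attr(probs, "fold") <- fold
  probs
}

#' Train the stacked MLP probability refiner
#'
#' An MLP (`n_classes -> 64 -> 64 -> n_classes`, ReLU hidden, softmax
#' output) trained on out-of-fold CNN probabilities, implementing stacked
#' generalization. Inputs must be marked with [oof_probs()]; anything else
#' is treated as in-fold leakage and rejected.
#'
#' @param probs out-of-fold CNN probability matrix ([oof_probs()])
#' @param labels true class labels, one per row
#' @param cfg a [model_config()]
#' @param exclude_fold optional fold index; rows produced by this fold are
#'   dropped from refiner training (so the refiner never trains on the
#'   spectra it will refine)
#' @return an object of class `sers_mlp`
#' @export
train_refiner <- function(probs, labels, cfg, exclude_fold = NULL) {
  stopifnot(is.matrix(probs), nrow(probs) == length(labels),
            inherits(cfg, "model_config"))
  if (!isTRUE(attr(probs, "oof")))
    stop("in-fold leakage: refiner inputs must be out-of-fold CNN ",
         "probabilities (see oof_probs())")
  classes <- colnames(probs)
  if (is.null(classes)) stop("probs needs class column names")
  keep <- rep(TRUE, nrow(probs))
  if (!is.null(exclude_fold)) {
    fold <- attr(probs, "fold")
    if (is.null(fold)) stop("exclude_fold given but probs carry no fold ",
                            "attribute")
    keep <- fold != exclude_fold
  }
  rows <- which(keep)
  yi_all <- match(as.character(labels[rows]), classes) - 1L
  if (anyNA(yi_all)) stop("labels outside the probability class vocabulary")
  cw <- resolve_class_weights(cfg, labels[rows], classes)
  # hold out a slice of the refiner's own training rows: the meta-MLP is
  # early-stopped at its best held-out loss so it stays calibrated instead
  # of saturating (sharpened probabilities would defeat the soft
  # sample-level averaging downstream)
  set.seed(derive_seed(cfg$seed, 2e6))
  n_keep <- length(rows)
  val_idx <- sort(sample.int(n_keep, max(1L, round(0.2 * n_keep))))
  tr_idx <- setdiff(seq_len(n_keep), val_idx)
  fit <- nn_train_cpp(probs[rows[tr_idx], , drop = FALSE], yi_all[tr_idx],
                      probs[rows[val_idx], , drop = FALSE],
                      yi_all[val_idx],
                      use_conv = FALSE, n_classes = length(classes),
                      filters = 0L, kernel = 0L,
                      fc_sizes = cfg$mlp_hidden, dropout = 0, leaky = 0,
                      epochs = cfg$mlp_epochs, batch = cfg$batch_size,
                      lr0 = cfg$mlp_lr, clip_norm = cfg$clip_norm,
                      patience = cfg$scheduler_patience,
                      factor = cfg$scheduler_factor, class_weights = cw,
                      seed = derive_seed(cfg$seed, 1e6),
                      restore_best = TRUE)
  structure(list(weights = fit[c("W", "b")], classes = classes, cfg = cfg,
                 history = data.frame(epoch = seq_len(cfg$mlp_epochs),
                                      train_loss = fit$history$train_loss,
                                      train_acc = fit$history$train_acc)),
            class = "sers_mlp")
}

#' Refine CNN probabilities with a trained MLP
#'
#' @param object a [train_refiner()] fit
#' @param probs matrix of CNN class probabilities
#' @param ... unused
#' @return matrix of refined class probabilities
#' @export
predict.sers_mlp <- function(object, probs, ...) {
  stopifnot(is.matrix(probs), ncol(probs) == length(object$classes))
  pr <- nn_predict_cpp(object$weights, probs, use_conv = FALSE,
                       n_classes = length(object$classes), filters = 0L,
                       kernel = 0L, fc_sizes = object$cfg$mlp_hidden,
                       leaky = 0, batch = object$cfg$batch_size)
  colnames(pr) <- object$classes
  pr
}
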