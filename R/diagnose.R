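# Sample-level diagnosis: per-sample averaging of spectrum-level class
# probabilities, confusion-matrix / ROC evaluation, and the per-spectrum
# probability heatmap.

#' Aggregate spectrum-level probabilities into sample diagnoses
#'
#' The diagnostic probability vector of a sample is the unweighted
#' arithmetic mean of its spectra's class probabilities. The call is the
#' argmax class with a deterministic lowest-index tie-break; for binary
#' tasks an explicit `threshold` on the positive-class mean probability may
#' be used instead.
#'
#' @param x a [cross_validate()] result or a predictions data.frame with
#'   `sample_id`, `class` and probability columns
#' @param use `"refined"` or `"cnn"` probabilities
#' @param threshold optional positive-call threshold for binary tasks
#' @param positive positive class label for thresholded binary calls;
#'   defaults to the single non-`non_cancer` class
#' @return data.frame of class `sers_diagnoses`: `sample_id`, `truth`,
#'   `n_spectra`, one `mean_p_*` column per class, `call`
#' @export
aggregate_samples <- function(x, use = c("refined", "cnn"),
                              threshold = NULL, positive = NULL) {
  use <- match.arg(use)
  if (inherits(x, "sers_cv")) {
    probs <- cv_probs(x, use)
    info <- x$predictions
    classes <- x$classes
  } else {
    stopifnot(is.data.frame(x))
    pre <- if (use == "refined") "ref_p_" else "cnn_p_"
    pcols <- grep(paste0("^", pre), names(x), value = TRUE)
    if (!length(pcols)) stop("no ", pre, "* probability columns found")
    classes <- sub(pre, "", pcols)
    probs <- as.matrix(x[pcols])
    colnames(probs) <- classes
    info <- x
  }
  sid <- info$sample_id
  agg <- rowsum(probs, sid) # rows sorted by sample_id
  nsp <- as.vector(table(sid)[rownames(agg)])
  agg <- agg / nsp
  truth <- info$class[match(rownames(agg), sid)]

  call <- classes[max.col(agg, ties.method = "first")]
  if (!is.null(threshold)) {
    if (length(classes) != 2L)
      stop("threshold calls are defined for binary tasks only")
    positive <- positive %||% setdiff(classes, "non_cancer")
    if (length(positive) != 1L || !positive %in% classes)
      stop("cannot identify the positive class; pass `positive`")
    negative <- setdiff(classes, positive)
    call <- ifelse(agg[, positive] >= threshold, positive, negative)
  }
  out <- data.frame(sample_id = rownames(agg), truth = truth,
                    n_spectra = nsp, stringsAsFactors = FALSE)
  out[paste0("mean_p_", classes)] <- as.data.frame(agg)
  out$call <- call
  rownames(out) <- NULL
  structure(out, class = c("sers_diagnoses", "data.frame"),
            classes = classes)
}

#' Diagnosis for a single sample
#'
#' @param x see [aggregate_samples()]
#' @param sample_id the sample to diagnose
#' @param ... passed to [aggregate_samples()]
#' @return a one-row `sers_diagnoses` data.frame
#' @export
aggregate_sample <- function(x, sample_id, ...) {
  d <- aggregate_samples(x, ...)
  row <- d[d$sample_id == sample_id, , drop = FALSE]
  if (nrow(row) == 0L) stop("no predictions for sample '", sample_id, "'")
  row
}

# ROC by threshold sweep over unique scores; trapezoidal AUC
roc_curve <- function(scores, is_positive) {
  np <- sum(is_positive)
  nn <- sum(!is_positive)
  if (np == 0L || nn == 0L)
    return(list(points = data.frame(threshold = numeric(0),
                                    fpr = numeric(0), tpr = numeric(0)),
                auc = NA_real_))
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & is_positive) / np,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !is_positive) / nn,
                numeric(1))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(points = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
       auc = auc)
}

#' Evaluate sample diagnoses against truth
#'
#' Computes the integer confusion matrix (rows = truth, columns = call),
#' overall accuracy, one-vs-rest sensitivity (TP / (TP + FN)) and
#' specificity (TN / (TN + FP)) per class, and per-class ROC curves with
#' trapezoidal AUC from the mean probabilities (macro-averaged AUC for
#' multiclass).
#'
#' @param diagnoses a [aggregate_samples()] data.frame (carries truth)
#' @return an object of class `sers_eval`
#' @export
evaluate_diagnoses <- function(diagnoses) {
  stopifnot(inherits(diagnoses, "sers_diagnoses"))
  classes <- attr(diagnoses, "classes")
  truth <- diagnoses$truth
  if (!all(truth %in% classes))
    stop("unknown truth label: ",
         paste(setdiff(truth, classes), collapse = ", "))
  call <- factor(diagnoses$call, levels = classes)
  truth_f <- factor(truth, levels = classes)
  cm <- table(truth = truth_f, call = call)
  acc <- sum(diag(cm)) / sum(cm)

  per_class <- do.call(rbind, lapply(classes, function(cl) {
    tp <- sum(truth == cl & call == cl)
    fn <- sum(truth == cl & call != cl)
    fp <- sum(truth != cl & call == cl)
    tn <- sum(truth != cl & call != cl)
    data.frame(class = cl,
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
               n = tp + fn)
  }))

  roc <- lapply(classes, function(cl)
    roc_curve(diagnoses[[paste0("mean_p_", cl)]], truth == cl))
  names(roc) <- classes
  auc <- vapply(roc, `[[`, numeric(1), "auc")

  structure(list(confusion = cm, accuracy = acc, per_class = per_class,
                 roc = roc, auc = auc,
                 macro_auc = mean(auc, na.rm = TRUE),
                 macro_sensitivity = mean(per_class$sensitivity,
                                          na.rm = TRUE),
                 macro_specificity = mean(per_class$specificity,
                                          na.rm = TRUE),
                 n_samples = nrow(diagnoses), classes = classes),
            class = "sers_eval")
}

#' @export
print.sers_eval <- function(x, ...) {
  cat(sprintf("<sers_eval> %d samples, accuracy %.3f, macro AUC %.3f\n",
              x$n_samples, x$accuracy, x$macro_auc))
  print(x$confusion)
  invisible(x)
}

#' Per-spectrum classification probability heatmap
#'
#' Rows are spectra grouped by truth class then sample; columns are
#' classes; values are (refined) class probabilities. Optionally writes the
#' matrix as CSV and renders a raster image.
#'
#' @param x a [cross_validate()] result
#' @param use `"refined"` or `"cnn"`
#' @param subsample optional per-sample spectrum count (first `n` spectra
#'   per sample, deterministic); default all
#' @param csv optional CSV output path
#' @param plot optional image output path (png/pdf, via ggplot2)
#' @return the heatmap matrix (invisibly), rows named by spectrum_id
#' @export
probability_heatmap <- function(x, use = c("refined", "cnn"),
                                subsample = NULL, csv = NULL, plot = NULL) {
  use <- match.arg(use)
  stopifnot(inherits(x, "sers_cv"))
  probs <- cv_probs(x, use)
  info <- x$predictions
  ord <- order(info$class, info$sample_id, info$spectrum_id)
  probs <- probs[ord, , drop = FALSE]
  info <- info[ord, , drop = FALSE]
  if (!is.null(subsample)) {
    keep <- unlist(lapply(split(seq_len(nrow(info)), info$sample_id),
                          function(ix) head(ix, subsample)), use.names = FALSE)
    keep <- sort(keep)
    probs <- probs[keep, , drop = FALSE]
    info <- info[keep, , drop = FALSE]
  }
  rownames(probs) <- info$spectrum_id
  if (!is.null(csv)) {
    out <- data.frame(spectrum_id = info$spectrum_id,
                      sample_id = info$sample_id, class = info$class,
                      probs, check.names = FALSE)
    data.table::fwrite(out, csv)
  }
  if (!is.null(plot)) {
    df <- data.frame(spectrum = rep(seq_len(nrow(probs)), ncol(probs)),
                     class = rep(colnames(probs), each = nrow(probs)),
                     prob = as.vector(probs))
    gg <- ggplot2::ggplot(df, ggplot2::aes(.data$class, .data$spectrum,
                                           fill = .data$prob)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
      ggplot2::labs(x = NULL, y = "spectrum", fill = "probability") +
      ggplot2::theme_minimal()
    ggplot2::ggsave(plot, gg, width = 6, height = 8, dpi = 150)
  }
  invisible(probs)
}
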