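# ggplot2 renderers for the standard evaluation surfaces.

#' Plot ROC curves
#'
#' One-vs-rest ROC curve per class from an evaluation report.
#'
#' @param ev a [evaluate_diagnoses()] report
#' @param path optional image path; when `NULL` the ggplot object is
#'   returned
#' @return a ggplot object (invisibly when written to file)
#' @export
plot_roc <- function(ev, path = NULL) {
  stopifnot(inherits(ev, "sers_eval"))
  df <- do.call(rbind, lapply(names(ev$roc), function(cl) {
    pts <- ev$roc[[cl]]$points
    if (!nrow(pts)) return(NULL)
    data.frame(class = sprintf("%s (AUC %.3f)", cl, ev$auc[[cl]]),
               fpr = pts$fpr, tpr = pts$tpr)
  }))
  gg <- ggplot2::ggplot(df, ggplot2::aes(.data$fpr, .data$tpr,
                                         colour = .data$class)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (is.null(path)) return(gg)
  ggplot2::ggsave(path, gg, width = 6, height = 5, dpi = 150)
  invisible(gg)
}

#' Plot per-fold accuracy and loss curves
#'
#' @param cv a [cross_validate()] result
#' @param path optional image path
#' @return a ggplot object (invisibly when written to file)
#' @export
plot_history <- function(cv, path = NULL) {
  stopifnot(inherits(cv, "sers_cv"))
  df <- do.call(rbind, lapply(seq_along(cv$histories), function(f) {
    h <- cv$histories[[f]]
    rbind(data.frame(fold = f, epoch = h$epoch, metric = "loss",
                     split = "train", value = h$train_loss),
          data.frame(fold = f, epoch = h$epoch, metric = "loss",
                     split = "validation", value = h$val_loss),
          data.frame(fold = f, epoch = h$epoch, metric = "accuracy",
                     split = "train", value = h$train_acc),
          data.frame(fold = f, epoch = h$epoch, metric = "accuracy",
                     split = "validation", value = h$val_acc))
  }))
  gg <- ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$value,
                                         colour = .data$split,
                                         group = interaction(.data$fold,
                                                             .data$split))) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
  if (is.null(path)) return(gg)
  ggplot2::ggsave(path, gg, width = 8, height = 4, dpi = 150)
  invisible(gg)
}

#' Plot a differential-spectrum heatmap
#'
#' @param dmat a [differential_matrix()]
#' @param path optional image path
#' @return a ggplot object (invisibly when written to file)
#' @export
plot_differential <- function(dmat, path = NULL) {
  df <- data.frame(class = rep(rownames(dmat), ncol(dmat)),
                   wavenumber = rep(as.numeric(colnames(dmat)),
                                    each = nrow(dmat)),
                   delta = as.vector(dmat))
  gg <- ggplot2::ggplot(df, ggplot2::aes(.data$wavenumber, .data$class,
                                         fill = .data$delta)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red") +
    ggplot2::labs(x = "Raman shift (cm^-1)", y = NULL,
                  fill = "mean difference") +
    ggplot2::theme_minimal()
  if (is.null(path)) return(gg)
  ggplot2::ggsave(path, gg, width = 8, height = 4, dpi = 150)
  invisible(gg)
}
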