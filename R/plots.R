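# ggplot2 views of training logs and confusion matrices.

#' Plot training loss curves
#'
#' One line per loss component over training steps; validation accuracies
#' (if present) are drawn as points on a secondary panel row.
#'
#' @param log a training log tibble from [train_vae_phase()] or
#'   [train_rgn_phase()]
#' @return a ggplot object
#' @export
plot_train_log <- function(log) {
  comp_cols <- intersect(c("recon", "kl", "total", "cls", "adv_d", "adv_g",
                           "align"), names(log))
  long <- do.call(rbind, lapply(comp_cols, function(cc) {
    v <- log[[cc]]
    keep <- !is.na(v)
    if (!any(keep)) return(NULL)
    tibble::tibble(step = log$step[keep], component = cc, loss = v[keep])
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$loss,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "training step", y = "loss", colour = "component") +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix as a heat map
#'
#' @param cm a `C x C` confusion matrix (rows = true class)
#' @return a ggplot object
#' @export
plot_confusion <- function(cm) {
  cls_true <- rownames(cm); cls_pred <- colnames(cm)
  if (is.null(cls_true)) cls_true <- as.character(seq_len(nrow(cm)))
  if (is.null(cls_pred)) cls_pred <- as.character(seq_len(ncol(cm)))
  df <- expand.grid(true = cls_true, predicted = cls_pred,
                    stringsAsFactors = FALSE)
  df$count <- as.vector(cm)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::scale_y_discrete(limits = rev(cls_true)) +
    ggplot2::labs(x = "predicted", y = "true") +
    ggplot2::theme_minimal()
}
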