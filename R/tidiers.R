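#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the training record of a fit
#'
#' One row per epoch and measured quantity (`train_loss`, `train_acc`,
#' `val_loss`, `val_acc`), in long format.
#'
#' @param x An `otamnet_fit`.
#' @param ... Unused.
#' @return A tibble with columns `epoch`, `metric`, `value`.
#' @export
tidy.otamnet_fit <- function(x, ...) {
  tidyr::pivot_longer(x$record, -"epoch", names_to = "metric",
                      values_to = "value")
}

#' One-row summary of a fit
#'
#' @param x An `otamnet_fit`.
#' @param ... Unused.
#' @return A one-row tibble: epochs run, best epoch, best validation loss
#'   and accuracy, parameter count, fusion flag.
#' @export
glance.otamnet_fit <- function(x, ...) {
  tibble::tibble(
    epochs = x$stopped_epoch,
    best_epoch = x$best_epoch,
    best_val_loss = x$best_val_loss,
    best_val_acc = x$record$val_acc[x$best_epoch],
    n_parameters = sum(vapply(x$params, length, numeric(1))),
    fusion = x$arch$fusion_enabled
  )
}

#' @rdname tidy.otamnet_fit
#' @export
tidy.otamnet_eval <- function(x, ...) x$metrics

#' @rdname glance.otamnet_fit
#' @export
glance.otamnet_eval <- function(x, ...) {
  dplyr::bind_cols(x$macro, tibble::tibble(micro_accuracy = x$micro$accuracy))
}

#' Learning-curve plot of a training record
#'
#' @param object An `otamnet_fit`.
#' @param ... Unused.
#' @return A ggplot: loss and accuracy per epoch, training vs validation,
#'   with the best (restored) epoch marked.
#' @export
autoplot.otamnet_fit <- function(object, ...) {
  long <- tidy(object)
  long <- tidyr::separate_wider_delim(long, "metric", delim = "_",
                                      names = c("split", "measure"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::facet_wrap(ggplot2::vars(.data$measure), scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL,
                  title = "Training record (dashed: restored best epoch)")
}

#' Per-class metric plot of an evaluation
#'
#' @param object An `otamnet_eval`.
#' @param ... Unused.
#' @return A ggplot of the five per-class metrics.
#' @export
autoplot.otamnet_eval <- function(object, ...) {
  long <- tidyr::pivot_longer(object$metrics,
                              c("acc", "f1", "tpr", "fpr", "ppv"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$class),
                                     y = .data$value)) +
    ggplot2::geom_col(fill = "seagreen") +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "class", y = NULL,
                  title = "Per-class one-vs-rest metrics")
}

#' Transfer-function image of one filter in a bank
#'
#' @param bank A [build_bank()] result.
#' @param scale,orientation Filter indices.
#' @return A ggplot of the (DFT-shifted) transfer function.
#' @export
plot_filter <- function(bank, scale = 1, orientation = 1) {
  stopifnot(inherits(bank, "log_gabor_bank"))
  i <- which(bank$meta$scale == scale & bank$meta$orientation == orientation)
  stopifnot(length(i) == 1)
  tf <- bank$transfers[[i]]
  sh <- function(n) c((floor(n / 2) + 1):n, 1:floor(n / 2))
  tf <- tf[sh(nrow(tf)), sh(ncol(tf))]
  df <- tidyr::expand_grid(v = seq_len(nrow(tf)), u = seq_len(ncol(tf)))
  df$value <- as.numeric(tf[cbind(df$v, df$u)])
  ggplot2::ggplot(df, ggplot2::aes(.data$u, .data$v, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("Log-Gabor transfer (scale %d, orientation %d)",
                                  scale, orientation),
                  x = "u (centered)", y = "v (centered)", fill = "gain")
}
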