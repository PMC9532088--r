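# Training loop: stratified split, minibatch optimization, early stopping on
# validation loss, best-weight checkpointing.

dataset_tensor <- function(dataset, idx = seq_len(nrow(dataset$data))) {
  imgs <- dataset$data$image[idx]
  size <- dim(imgs[[1]])
  x <- array(0, c(size[1], size[2], 1, length(imgs)))
  for (i in seq_along(imgs)) x[, , 1, i] <- imgs[[i]]
  x
}

# Pooled Log-Gabor maps for every image, precomputed once per fusion-site
# spatial size. Returns list(sites = list of (H_s, W_s, K, N) arrays in site
# order, sizes = spatial sides).
gabor_pyramid <- function(images, config) {
  bank <- build_bank(config$gabor, nrow(images[[1]]), ncol(images[[1]]))
  trace <- channel_trace(config)
  sizes <- trace$spatial[trace$type == "fusion"]
  k <- fusion_channels(config)
  n <- length(images)
  full <- nrow(images[[1]])
  sites <- lapply(sizes, function(s) array(0, c(s, s, k, n)))
  for (i in seq_len(n)) {
    maps <- pool_responses(apply_bank(images[[i]], bank),
                           config$gabor_pooling)
    m <- array(unlist(maps, use.names = FALSE), c(full, full, k, 1))
    for (si in seq_along(sizes)) {
      ms <- m
      while (dim(ms)[1] > sizes[si]) ms <- cpp_avgpool2_forward(ms)
      sites[[si]][, , , i] <- ms
    }
  }
  list(sites = sites, sizes = sizes, k = k)
}

# Per-site, per-channel standardization statistics over the training images.
gabor_standardizer <- function(pyramid, train_idx) {
  lapply(pyramid$sites, function(arr) {
    sub <- arr[, , , train_idx, drop = FALSE]
    cm <- to_cmat(sub)
    mu <- colMeans(cm)
    sd <- sqrt(pmax(colMeans(cm^2) - mu^2, 0))
    list(mean = mu, sd = pmax(sd, 1e-8))
  })
}

standardize_pyramid <- function(pyramid, stats) {
  pyramid$sites <- purrr::map2(pyramid$sites, stats, function(arr, st) {
    cm <- sweep(sweep(to_cmat(arr), 2, st$mean), 2, st$sd, "/")
    from_cmat(cm, dim(arr))
  })
  pyramid
}

slice_sites <- function(sites, idx) {
  lapply(sites, function(a) a[, , , idx, drop = FALSE])
}

#' Train a dense network (with optional Log-Gabor fusion) on a dataset
#'
#' Implements the full training protocol: stratified 70:30 train/test split
#' with a 33% validation carve-out of the training pool, minibatch
#' optimization (Adam by default, batch size 8), early stopping once the
#' validation loss has not improved for `patience` epochs, and
#' best-epoch weight restoration. Log-Gabor maps for fusion are computed
#' once per image at input resolution, average-pooled to each fusion site's
#' spatial size, and standardized per channel with statistics frozen on the
#' training split.
#'
#' @param dataset A `leaf_dataset` (see [gen_dataset()] / [read_dataset()]).
#' @param arch An [arch_config()]; defaults to the lite fused preset sized
#'   to the dataset.
#' @param config A [train_config()].
#' @param split A [split_spec()]; defaults to the protocol split seeded from
#'   `config$seed`.
#' @return An object of class `otamnet_fit`: trained parameters (best
#'   epoch), batch-norm state, the network spec, the per-epoch `record`
#'   tibble (train/val loss and accuracy), `best_epoch`, `stopped_epoch`,
#'   `restored`, the split indices, and the frozen Log-Gabor
#'   standardization.
#' @export
fit_otamnet <- function(dataset, arch = NULL, config = train_config(),
                        split = NULL) {
  stopifnot(inherits(dataset, "leaf_dataset"),
            inherits(config, "train_config"))
  labels <- dataset$data$label
  n_classes <- max(labels)
  if (is.null(arch)) {
    arch <- arch_lite(num_classes = n_classes, input_size = dataset$size)
  }
  stopifnot(inherits(arch, "arch_config"))
  if (arch$num_classes != n_classes) {
    stop("arch$num_classes (", arch$num_classes,
         ") does not match the dataset (", n_classes, ")", call. = FALSE)
  }
  if (is.null(split)) split <- split_spec(seed = config$seed)
  idx <- split_dataset(labels, split)
  spec <- build_backbone(arch)
  x_all <- dataset_tensor(dataset)
  gstats <- NULL
  sites_all <- NULL
  if (arch$fusion_enabled) {
    pyr <- gabor_pyramid(dataset$data$image, arch)
    gstats <- gabor_standardizer(pyr, idx$train)
    sites_all <- standardize_pyramid(pyr, gstats)$sites
  }
  net <- init_network(spec, seed = config$seed)
  params <- net$params
  bn_state <- net$bn_state
  opt <- optim_init(params, config)
  record <- list()
  best <- list(loss = Inf, params = NULL, bn_state = NULL, epoch = 0L)
  stopped_epoch <- config$max_epochs
  withr::with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$max_epochs)) {
      order <- sample(idx$train)
      batches <- split(order, ceiling(seq_along(order) / config$batch_size))
      tr_loss <- 0; tr_acc <- 0; n_seen <- 0
      for (bt in batches) {
        xb <- x_all[, , , bt, drop = FALSE]
        gb <- if (!is.null(sites_all)) slice_sites(sites_all, bt)
        fwd <- network_forward(params, bn_state, spec, xb, gb,
                               training = TRUE)
        bn_state <- fwd$bn_state
        ls <- xent_loss(fwd$probs, labels[bt])
        if (!is.finite(ls$loss)) {
          stop("training diverged (non-finite loss) at epoch ", epoch,
               call. = FALSE)
        }
        grads <- network_backward(params, spec, fwd, labels[bt])
        upd <- optim_step(params, grads, opt, config)
        params <- upd$params
        opt <- upd$state
        nb <- length(bt)
        tr_loss <- tr_loss + ls$loss * nb
        tr_acc <- tr_acc + ls$acc * nb
        n_seen <- n_seen + nb
      }
      val <- eval_batches(params, bn_state, spec, x_all, sites_all,
                          idx$val, labels, config$batch_size)
      record[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = tr_loss / n_seen,
        train_acc = tr_acc / n_seen,
        val_loss = val$loss, val_acc = val$acc
      )
      if (val$loss < best$loss) {
        best <- list(loss = val$loss, params = params, bn_state = bn_state,
                     epoch = epoch)
      }
      dec <- should_stop(vapply(record, function(r) r$val_loss, numeric(1)),
                         config$patience)
      if (dec$stop) {
        stopped_epoch <- epoch
        break
      }
      stopped_epoch <- epoch
    }
  })
  structure(
    list(params = best$params, bn_state = best$bn_state, spec = spec,
         arch = arch, config = config, split = idx,
         record = dplyr::bind_rows(record),
         best_epoch = best$epoch, best_val_loss = best$loss,
         stopped_epoch = as.integer(stopped_epoch), restored = TRUE,
         gabor_stats = gstats, input_size = dataset$size,
         n_classes = n_classes),
    class = "otamnet_fit"
  )
}

eval_batches <- function(params, bn_state, spec, x_all, sites_all, idx,
                         labels, batch_size) {
  loss <- 0; acc <- 0
  batches <- split(idx, ceiling(seq_along(idx) / batch_size))
  for (bt in batches) {
    xb <- x_all[, , , bt, drop = FALSE]
    gb <- if (!is.null(sites_all)) slice_sites(sites_all, bt)
    fwd <- network_forward(params, bn_state, spec, xb, gb, training = FALSE)
    ls <- xent_loss(fwd$probs, labels[bt])
    loss <- loss + ls$loss * length(bt)
    acc <- acc + ls$acc * length(bt)
  }
  list(loss = loss / length(idx), acc = acc / length(idx))
}

#' @export
print.otamnet_fit <- function(x, ...) {
  cat("Trained dense network (", if (x$arch$fusion_enabled)
      "Log-Gabor fusion on" else "fusion off", "): ",
      x$n_classes, " classes\n", sep = "")
  cat("  best epoch ", x$best_epoch, " (val loss ",
      signif(x$best_val_loss, 5), "), stopped after epoch ",
      x$stopped_epoch, "\n", sep = "")
  invisible(x)
}

#' Predict classes or probabilities for new images
#'
#' @param object An `otamnet_fit`.
#' @param newdata A `leaf_dataset`, a list of grayscale matrices, or an
#'   (H, W, 1, N) array.
#' @param type `"class"` (default) or `"prob"`.
#' @param ... Unused.
#' @return Integer class labels, or a classes x N probability matrix. Ties
#'   in the argmax resolve to the lowest class index.
#' @export
predict.otamnet_fit <- function(object, newdata, type = c("class", "prob"),
                                ...) {
  type <- rlang::arg_match(type)
  images <- if (inherits(newdata, "leaf_dataset")) newdata$data$image
            else if (is.list(newdata)) newdata
            else if (is.array(newdata) && length(dim(newdata)) == 4)
              lapply(seq_len(dim(newdata)[4]), function(i) newdata[, , 1, i])
            else stop("unsupported newdata", call. = FALSE)
  images <- lapply(images, to_luminance)
  x <- array(unlist(images, use.names = FALSE),
             c(nrow(images[[1]]), ncol(images[[1]]), 1, length(images)))
  sites <- NULL
  if (object$arch$fusion_enabled) {
    pyr <- gabor_pyramid(images, object$arch)
    sites <- standardize_pyramid(pyr, object$gabor_stats)$sites
  }
  bs <- object$config$batch_size
  batches <- split(seq_along(images), ceiling(seq_along(images) / bs))
  probs <- matrix(0, object$n_classes, length(images))
  for (bt in batches) {
    gb <- if (!is.null(sites)) slice_sites(sites, bt)
    fwd <- network_forward(object$params, object$bn_state, object$spec,
                           x[, , , bt, drop = FALSE], gb, training = FALSE)
    probs[, bt] <- fwd$probs
  }
  if (type == "prob") probs else apply(probs, 2, which.max)
}

#' Evaluate a fit on a test set
#'
#' Predictions are the argmax of the forward probabilities (ties toward the
#' lowest class index); metrics come from the one-vs-rest confusion module.
#'
#' @param fit An `otamnet_fit`.
#' @param dataset The dataset to evaluate on.
#' @param indices Item indices; defaults to the fit's held-out test split.
#' @return A list of class `otamnet_eval` with `counts`, `metrics`
#'   (per-class tibbles), `macro` and `micro` summary tibbles, and
#'   `predictions`.
#' @export
evaluate_model <- function(fit, dataset, indices = fit$split$test) {
  stopifnot(inherits(fit, "otamnet_fit"), length(indices) > 0)
  pred <- predict(fit, dataset$data$image[indices])
  truth <- dataset$data$label[indices]
  counts <- confusion_counts(truth, pred, fit$n_classes)
  metrics <- class_metrics(counts)
  structure(
    list(counts = counts, metrics = metrics, macro = macro_summary(metrics),
         micro = micro_summary(counts),
         predictions = tibble::tibble(index = indices, truth = truth,
                                      estimate = pred)),
    class = "otamnet_eval"
  )
}

#' @export
print.otamnet_eval <- function(x, ...) {
  cat("Evaluation on", nrow(x$predictions), "items; overall accuracy",
      signif(x$micro$accuracy, 4), "\n")
  cat("Macro-averaged metrics:\n")
  print(x$macro)
  invisible(x)
}

#' Save / load a trained model
#'
#' Serializes the full fit (weights, batch-norm state, architecture, record,
#' frozen standardization) so a reloaded model reproduces identical forward
#' outputs.
#' @param fit An `otamnet_fit`.
#' @param path Checkpoint file path.
#' @return `save_model()` returns `path` invisibly; `load_model()` the fit.
#' @export
save_model <- function(fit, path) {
  stopifnot(inherits(fit, "otamnet_fit"))
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
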