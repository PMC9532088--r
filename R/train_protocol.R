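#' Dataset splitting specification
#'
#' The training protocol splits a dataset 70:30 into a training pool and a
#' test set, then carves a 33% validation split out of the training pool.
#' Splits are stratified by class by default so per-class test counts mirror
#' the class proportions.
#'
#' @param train_fraction Fraction of items in the training pool, in (0, 1)
#'   (default 0.70).
#' @param val_fraction_of_train Fraction of the training pool held out for
#'   validation, in (0, 1) (default 0.33).
#' @param stratified Stratify both splits by class (default `TRUE`).
#' @param seed Integer seed making the split deterministic.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(train_fraction = 0.70, val_fraction_of_train = 0.33,
                       stratified = TRUE, seed = 1) {
  stopifnot(
    "train_fraction must be in (0, 1)" =
      train_fraction > 0 && train_fraction < 1,
    "val_fraction_of_train must be in (0, 1)" =
      val_fraction_of_train > 0 && val_fraction_of_train < 1
  )
  structure(
    list(train_fraction = train_fraction,
         val_fraction_of_train = val_fraction_of_train,
         stratified = isTRUE(stratified), seed = as.integer(seed)),
    class = "split_spec"
  )
}

#' Split item indices into train / validation / test sets
#'
#' Deterministic given the spec's seed; stratified splits allocate
#' `round(n_c * train_fraction)` items of each class to the training pool and
#' `round(pool_c * val_fraction)` of those to validation. The three index
#' sets are disjoint and exhaustive.
#'
#' @param labels Integer class label per item.
#' @param spec A [split_spec()].
#' @return A list with integer index vectors `train`, `val`, `test`.
#' @examples
#' sp <- split_dataset(rep(1:49, each = 50), split_spec(seed = 7))
#' length(sp$test) # 735 of 2450
#' @export
split_dataset <- function(labels, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  n <- length(labels)
  if (spec$stratified && any(table(labels) < 2)) {
    stop("every class needs at least 2 items for a stratified split",
         call. = FALSE)
  }
  withr::with_seed(spec$seed, {
    groups <- if (spec$stratified) split(seq_len(n), labels)
              else list(seq_len(n))
    parts <- lapply(groups, function(idx) {
      idx <- sample(idx)
      n_pool <- round(length(idx) * spec$train_fraction)
      if (n_pool < 1 || n_pool >= length(idx)) {
        stop("class too small for the requested train fraction",
             call. = FALSE)
      }
      pool <- idx[seq_len(n_pool)]
      test <- idx[-seq_len(n_pool)]
      n_val <- round(n_pool * spec$val_fraction_of_train)
      n_val <- max(min(n_val, n_pool - 1), 0)
      list(train = pool[seq_len(n_pool - n_val)],
           val = if (n_val > 0) pool[(n_pool - n_val + 1):n_pool] else integer(),
           test = test)
    })
    list(
      train = sort(unlist(lapply(parts, `[[`, "train"), use.names = FALSE)),
      val = sort(unlist(lapply(parts, `[[`, "val"), use.names = FALSE)),
      test = sort(unlist(lapply(parts, `[[`, "test"), use.names = FALSE))
    )
  })
}

#' Early-stopping decision on a validation-loss history
#'
#' Training stops once the current epoch is at least `patience` epochs past
#' the running minimum of the validation loss (any strict decrease resets the
#' counter). The best epoch is the argmin, earliest on ties.
#'
#' @param val_loss_history Numeric vector of per-epoch validation losses.
#' @param patience Number of epochs to wait past the best epoch (default 5).
#' @return A list with `stop` (logical) and `best_epoch` (integer).
#' @examples
#' should_stop(c(1.0, 0.5, 0.6, 0.7, 0.8, 0.9, 1.0), 5) # stop, best epoch 2
#' @export
should_stop <- function(val_loss_history, patience = 5) {
  stopifnot(length(val_loss_history) >= 1, is_count(patience))
  best <- which.min(val_loss_history) # earliest on ties
  list(stop = (length(val_loss_history) - best) >= patience,
       best_epoch = as.integer(best))
}

#' Training configuration
#'
#' @param optimizer One of `"adam"`, `"sgd"`, `"rmsprop"` (default adam).
#' @param batch_size Minibatch size for training and evaluation (default 8).
#' @param max_epochs Epoch cap (default 100).
#' @param patience Early-stopping patience on validation loss (default 5).
#' @param learning_rate Step size; defaults per optimizer (adam/rmsprop 1e-3,
#'   sgd 1e-2).
#' @param momentum SGD momentum (default 0.9; ignored otherwise).
#' @param seed Integer seed controlling weight init and batch shuffling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(optimizer = c("adam", "sgd", "rmsprop"),
                         batch_size = 8, max_epochs = 100, patience = 5,
                         learning_rate = NULL, momentum = 0.9, seed = 1) {
  optimizer <- rlang::arg_match(optimizer)
  stopifnot(is_count(batch_size), is_count(max_epochs), is_count(patience))
  if (is.null(learning_rate)) {
    learning_rate <- switch(optimizer, adam = 1e-3, rmsprop = 1e-3,
                            sgd = 1e-2)
  }
  structure(
    list(optimizer = optimizer, batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs), patience = as.integer(patience),
         monitor = "val_loss", learning_rate = learning_rate,
         momentum = momentum, seed = as.integer(seed)),
    class = "train_config"
  )
}
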