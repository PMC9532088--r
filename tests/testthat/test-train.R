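test_that("the protocol split reproduces the 2450-image arithmetic", {
  labels <- rep(1:49, each = 50)
  idx <- split_dataset(labels, split_spec(seed = 1))
  expect_length(idx$test, 735)                     # 30% of 2450
  expect_length(c(idx$train, idx$val), 1715)       # 70% pool
  # stratified: 15 test items per class
  expect_true(all(table(labels[idx$test]) == 15))
  # identical under the same seed
  idx2 <- split_dataset(labels, split_spec(seed = 1))
  expect_identical(idx, idx2)
  expect_false(identical(idx, split_dataset(labels, split_spec(seed = 2))))
})

test_that("splits partition the indices for many seeds", {
  labels <- rep(1:7, times = c(9, 12, 15, 8, 20, 11, 10))
  for (seed in 1:100) {
    idx <- split_dataset(labels, split_spec(seed = seed))
    all_idx <- c(idx$train, idx$val, idx$test)
    expect_equal(sort(all_idx), seq_along(labels))
    expect_equal(anyDuplicated(all_idx), 0)
  }
})

test_that("split validation rejects degenerate requests", {
  expect_error(split_spec(train_fraction = 1), "train_fraction")
  expect_error(split_spec(train_fraction = 0), "train_fraction")
  expect_error(split_dataset(c(1, 1, 2), split_spec()), "2 items")
})

test_that("early stopping fires exactly patience epochs past the minimum", {
  # worked sequence: minimum at epoch 2, patience 5 -> stop after epoch 7
  hist <- c(1.0, 0.5, 0.6, 0.7, 0.8, 0.9, 1.0)
  d <- should_stop(hist, 5)
  expect_true(d$stop)
  expect_equal(d$best_epoch, 2L)
  expect_false(should_stop(hist[1:6], 5)$stop) # only 4 epochs past minimum
  # strictly decreasing history never stops
  expect_false(should_stop(seq(1, 0.1, length.out = 20), 5)$stop)
  # exhaustive property on random sequences: emulate epoch-by-epoch training
  set.seed(123)
  for (rep in 1:200) {
    len <- sample(1:20, 1)
    patience <- sample(1:6, 1)
    losses <- round(runif(len), 2) # ties likely
    stopped <- len
    for (e in seq_len(len)) {
      d <- should_stop(losses[1:e], patience)
      # oracle: stop iff current epoch is >= patience past the earliest argmin
      expect_identical(d$stop,
                       (e - which.min(losses[1:e])) >= patience)
      expect_identical(d$best_epoch, as.integer(which.min(losses[1:e])))
      if (d$stop) {
        stopped <- e
        break
      }
    }
    final <- should_stop(losses[1:stopped], patience)
    expect_lte(stopped - final$best_epoch, patience)
  }
})

test_that("training fits a separable two-class toy problem", {
  ds <- toy_two_class(16, seed = 3)
  fit <- fit_otamnet(ds, tiny_arch(2),
                     train_config(max_epochs = 30, seed = 3,
                                  learning_rate = 3e-3))
  expect_gte(max(fit$record$train_acc), 1.0)
  expect_lte(fit$stopped_epoch, 30)
  expect_lte(fit$stopped_epoch - fit$best_epoch, fit$config$patience)
})

test_that("max_epochs = 1 stops and restores epoch 1", {
  ds <- toy_two_class(4, seed = 1)
  fit <- fit_otamnet(ds, tiny_arch(2), train_config(max_epochs = 1, seed = 1))
  expect_equal(fit$stopped_epoch, 1L)
  expect_equal(fit$best_epoch, 1L)
  expect_true(fit$restored)
})

test_that("identical seeds reproduce the training record bit-exactly", {
  ds <- toy_two_class(6, seed = 4)
  f1 <- fit_otamnet(ds, tiny_arch(2, fusion_enabled = TRUE),
                    train_config(max_epochs = 3, seed = 11))
  f2 <- fit_otamnet(ds, tiny_arch(2, fusion_enabled = TRUE),
                    train_config(max_epochs = 3, seed = 11))
  expect_identical(f1$record, f2$record)
  expect_identical(f1$params, f2$params)
})

test_that("restored best weights reproduce the recorded validation loss", {
  ds <- toy_two_class(8, seed = 5)
  fit <- fit_otamnet(ds, tiny_arch(2), train_config(max_epochs = 8, seed = 2))
  val <- fit$split$val
  probs <- predict(fit, ds$data$image[val], type = "prob")
  loss <- xent_loss(probs, ds$data$label[val])$loss
  expect_equal(loss, fit$best_val_loss, tolerance = 1e-5)
  expect_equal(fit$record$val_loss[fit$best_epoch], fit$best_val_loss)
})

test_that("evaluation delegates to the one-vs-rest metrics module", {
  ds <- toy_two_class(8, seed = 6)
  fit <- fit_otamnet(ds, tiny_arch(2), train_config(max_epochs = 6, seed = 6))
  ev <- evaluate_model(fit, ds)
  expect_s3_class(ev$metrics, "tbl_df")
  expect_equal(nrow(ev$metrics), 2)
  expect_true(all(ev$metrics$tp + ev$metrics$fp + ev$metrics$fn +
                    ev$metrics$tn == ev$metrics$n))
  expect_error(evaluate_model(fit, ds, indices = integer()), "length")
  # tidiers
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(glance(fit)), 1)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(autoplot(ev), "ggplot")
})
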