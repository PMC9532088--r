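test_that("one-vs-rest counts match hand enumeration", {
  counts <- confusion_counts(c(1, 1, 2, 2), c(1, 2, 2, 2), 2)
  expect_equal(counts$tp, c(1, 2))
  expect_equal(counts$fn, c(1, 0))
  expect_equal(counts$fp, c(0, 1))
  expect_equal(counts$tn, c(2, 1))
  expect_true(all(counts$tp + counts$fp + counts$fn + counts$tn == 4))
  # perfect predictions: no confusion anywhere
  perfect <- confusion_counts(1:5, 1:5, 5)
  expect_true(all(perfect$fp == 0) && all(perfect$fn == 0))
  expect_error(confusion_counts(c(1, 9), c(1, 1), 3), "range")
  expect_error(confusion_counts(1:3, 1:2), "length")
})

test_that("count conservation holds on many random prediction fixtures", {
  set.seed(77)
  for (rep in 1:1000) {
    k <- sample(2:6, 1)
    n <- sample(5:20, 1)
    truth <- sample(k, n, replace = TRUE)
    est <- sample(k, n, replace = TRUE)
    counts <- confusion_counts(truth, est, k)
    expect_true(all(counts$tp + counts$fp + counts$fn + counts$tn == n))
    expect_equal(sum(counts$tp), sum(truth == est))
  }
})

test_that("metric formulas reproduce reconstructed table rows", {
  # smallest integer counts consistent with a published per-class row under
  # 735 test items: tp 15, fp 3, fn 0, tn 717
  m <- class_metrics(tibble::tibble(class = 1, tp = 15, fp = 3, fn = 0,
                                    tn = 717, n = 735))
  expect_equal(round(m$acc, 5), 0.99592)
  expect_equal(round(m$ppv, 5), 0.83333)
  expect_equal(round(m$fpr, 5), 0.00417)
  expect_equal(m$tpr, 1)
  # recall with 16 positives, 13 recovered
  m2 <- class_metrics(tibble::tibble(class = 1, tp = 13, fp = 0, fn = 3,
                                     tn = 719, n = 735))
  expect_equal(m2$tpr, 0.8125)
  expect_equal(m2$ppv, 1)
})

test_that("zero-denominator conventions return 0", {
  m <- class_metrics(tibble::tibble(class = 1, tp = 0, fp = 0, fn = 0,
                                    tn = 10, n = 10))
  expect_equal(m$tpr, 0)
  expect_equal(m$ppv, 0)
  expect_equal(m$fpr, 0)
  expect_equal(m$f1, 0)
  expect_equal(m$acc, 1) # degenerate absent class is fully 'correct'
})

test_that("F1 satisfies the harmonic-mean identity on random fixtures", {
  set.seed(5)
  for (rep in 1:50) {
    k <- sample(2:8, 1)
    truth <- sample(k, 60, replace = TRUE)
    est <- sample(k, 60, replace = TRUE)
    m <- class_metrics(confusion_counts(truth, est, k))
    pos <- m$ppv + m$tpr > 0
    expect_equal(m$f1[pos],
                 (2 * m$ppv * m$tpr / (m$ppv + m$tpr))[pos],
                 tolerance = 1e-12)
  }
  # harmonic mean of equal values is the value itself
  expect_equal(f1_score(0.7, 0.7), 0.7)
})

test_that("macro summary is the unweighted per-class mean", {
  m <- class_metrics(tibble::tibble(class = 1:2, tp = c(10, 5),
                                    fp = c(0, 5), fn = c(5, 0),
                                    tn = c(15, 20), n = 30))
  s <- macro_summary(m)
  expect_equal(s$acc, mean(m$acc))
  expect_equal(s$tpr, (10 / 15 + 1) / 2)
  # 49-class random fixture against independent re-averaging
  set.seed(9)
  truth <- rep(1:49, each = 15)
  est <- ifelse(stats::runif(735) < 0.9, truth, sample(49, 735, TRUE))
  mm <- class_metrics(confusion_counts(truth, est, 49))
  ss <- macro_summary(mm)
  for (col in c("acc", "f1", "tpr", "fpr", "ppv")) {
    expect_equal(ss[[col]], sum(mm[[col]]) / 49)
  }
  # micro summary is the plain multiclass accuracy
  expect_equal(micro_summary(confusion_counts(truth, est, 49))$accuracy,
               mean(truth == est))
})

test_that("reports round-trip with the published column layout", {
  set.seed(2)
  truth <- rep(1:4, each = 10)
  est <- ifelse(stats::runif(40) < 0.8, truth, sample(4, 40, TRUE))
  m <- class_metrics(confusion_counts(truth, est, 4))
  path <- withr::local_tempfile()
  tab <- write_metrics_report(m, path)
  csv <- utils::read.csv(paste0(path, ".csv"))
  expect_equal(names(csv), c("class", "ACC", "F1", "TPR", "FPR", "PPV"))
  expect_equal(nrow(csv), 5) # 4 classes + macro summary row
  js <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(round(js$ACC, 5), csv$ACC, tolerance = 1e-9)
  expect_equal(js$F1, tab$F1, tolerance = 1e-12)
  expect_equal(csv$class[5], "macro_average")
})
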