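#' Per-class one-vs-rest confusion counts
#'
#' Builds the N x N multiclass confusion matrix from predictions and derives,
#' for each class treated as positive against all others, the one-vs-rest
#' counts TP, FP, FN, TN. For every class `tp + fp + fn + tn` equals the
#' number of instances, and the TP column sums to the number of correctly
#' classified instances.
#'
#' @param truth Integer vector of true class labels in `1..n_classes`.
#' @param estimate Integer vector of predicted labels, same length.
#' @param n_classes Number of classes; defaults to the largest label seen.
#' @return A tibble with columns `class`, `tp`, `fp`, `fn`, `tn`, `n`.
#' @examples
#' confusion_counts(c(1, 1, 2, 2), c(1, 2, 2, 2))
#' @export
confusion_counts <- function(truth, estimate, n_classes = max(truth, estimate)) {
  stopifnot(
    "truth and estimate must have equal length" =
      length(truth) == length(estimate),
    "labels must be integers" =
      all(truth == as.integer(truth)) && all(estimate == as.integer(estimate))
  )
  if (any(truth < 1 | truth > n_classes | estimate < 1 | estimate > n_classes)) {
    stop("labels out of range 1..n_classes", call. = FALSE)
  }
  n <- length(truth)
  cm <- table(factor(truth, levels = seq_len(n_classes)),
              factor(estimate, levels = seq_len(n_classes)))
  tp <- as.numeric(diag(cm))
  fn <- as.numeric(rowSums(cm)) - tp
  fp <- as.numeric(colSums(cm)) - tp
  tibble::tibble(
    class = seq_len(n_classes),
    tp = tp, fp = fp, fn = fn, tn = n - tp - fp - fn, n = n
  )
}

#' One-vs-rest classification metrics
#'
#' The five per-class metrics derived from one-vs-rest confusion counts:
#' accuracy `(TP + TN) / N`, recall/true-positive rate `TP / (TP + FN)`,
#' precision/positive predictive value `TP / (TP + FP)`, false-positive rate
#' (fall-out) `FP / (FP + TN)`, and F1, the harmonic mean of precision and
#' recall. Zero denominators yield 0 by convention (flagged in reports); the
#' evaluated data never exhibit them for non-degenerate splits.
#'
#' @param counts A [confusion_counts()] tibble.
#' @return The input tibble with columns `acc`, `tpr`, `ppv`, `fpr`, `f1`
#'   appended.
#' @export
class_metrics <- function(counts) {
  stopifnot(all(c("tp", "fp", "fn", "tn", "n") %in% names(counts)))
  dplyr::mutate(
    counts,
    acc = (.data$tp + .data$tn) / .data$n,
    tpr = safe_ratio(.data$tp, .data$tp + .data$fn),
    ppv = safe_ratio(.data$tp, .data$tp + .data$fp),
    fpr = safe_ratio(.data$fp, .data$fp + .data$tn),
    f1 = f1_score(.data$ppv, .data$tpr)
  )
}

safe_ratio <- function(num, den) ifelse(den > 0, num / den, 0)

#' F1 score from precision and recall
#'
#' Harmonic mean `2 * ppv * tpr / (ppv + tpr)`, 0 when both are 0.
#' Vectorized.
#'
#' @param ppv Precision value(s) in `[0, 1]`.
#' @param tpr Recall value(s) in `[0, 1]`.
#' @return Numeric vector of F1 values.
#' @examples
#' f1_score(0.83333, 1) # 0.90909...
#' @export
f1_score <- function(ppv, tpr) {
  ifelse(ppv + tpr > 0, 2 * ppv * tpr / (ppv + tpr), 0)
}

#' Macro (and micro) summaries of per-class metrics
#'
#' `macro_summary()` is the unweighted mean over classes of each of the five
#' metrics. `micro_summary()` reports the overall multiclass accuracy
#' (`sum(tp) / n`, the usual single accuracy number) computed from the
#' counts; the two coincide only for balanced, error-free classifiers.
#'
#' @param metrics A [class_metrics()] tibble.
#' @return A one-row tibble with columns `acc`, `f1`, `tpr`, `fpr`, `ppv`
#'   (macro) or `accuracy` (micro).
#' @export
macro_summary <- function(metrics) {
  dplyr::summarise(
    metrics,
    acc = mean(.data$acc), f1 = mean(.data$f1), tpr = mean(.data$tpr),
    fpr = mean(.data$fpr), ppv = mean(.data$ppv)
  )
}

#' @rdname macro_summary
#' @param counts A [confusion_counts()] tibble.
#' @export
micro_summary <- function(counts) {
  tibble::tibble(accuracy = sum(counts$tp) / counts$n[1])
}

#' Write a per-class metrics report
#'
#' Emits the per-class table (one row per class, columns
#' `class, ACC, F1, TPR, FPR, PPV`) plus a macro-summary row, as CSV and/or a
#' JSON mirror carrying full precision. CSV values are rounded to 5 decimals
#' to match conventional reporting; the JSON file keeps full precision.
#'
#' @param metrics A [class_metrics()] tibble.
#' @param path Output path; `.csv` and/or `.json` extension(s) derive from
#'   `format`.
#' @param format `"csv"`, `"json"`, or `"both"` (writes `<path>.csv` and
#'   `<path>.json`).
#' @return The tibble that was written (per-class rows plus summary row),
#'   invisibly.
#' @export
write_metrics_report <- function(metrics, path, format = c("both", "csv", "json")) {
  format <- rlang::arg_match(format)
  tab <- dplyr::transmute(
    metrics,
    class = as.character(.data$class),
    ACC = .data$acc, F1 = .data$f1, TPR = .data$tpr, FPR = .data$fpr,
    PPV = .data$ppv
  )
  summ <- macro_summary(metrics)
  tab <- dplyr::bind_rows(
    tab,
    tibble::tibble(class = "macro_average", ACC = summ$acc, F1 = summ$f1,
                   TPR = summ$tpr, FPR = summ$fpr, PPV = summ$ppv)
  )
  if (format %in% c("both", "csv")) {
    rounded <- dplyr::mutate(tab, dplyr::across(-"class", ~ round(.x, 5)))
    utils::write.csv(rounded, paste0(path, ".csv"), row.names = FALSE,
                     quote = FALSE)
  }
  if (format %in% c("both", "json")) {
    jsonlite::write_json(tab, paste0(path, ".json"), digits = NA,
                         dataframe = "rows")
  }
  invisible(tab)
}
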