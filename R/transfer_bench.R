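#' Registry of pretrained bottleneck-feature extractors
#'
#' The reference table of ten ImageNet-pretrained backbones used as fixed
#' feature extractors: the layer named is the last layer before the
#' classification head and `feature_dim` its activation length. The weights
#' themselves are an optional plugin; the registry records the shapes so
#' feature pipelines can be validated without downloading anything.
#'
#' @return A tibble with columns `network`, `input_size`, `depth`,
#'   `feature_dim`, `layer`.
#' @examples
#' extractor_registry()[extractor_registry()$network == "resnet18", ]
#' @export
extractor_registry <- function() {
  tibble::tribble(
    ~network,      ~input_size, ~depth, ~feature_dim, ~layer,
    "alexnet",     227L,          8L,   4096L, "fc7",
    "densenet201", 224L,        201L,   1920L, "avg_pool",
    "googlenet",   224L,         22L,   1024L, "pool5-7x7_s1",
    "inceptionv3", 299L,         48L,   2048L, "avg_pool",
    "mobilenetv2", 224L,         53L,   1280L, "global_average_pooling2d_1",
    "resnet18",    224L,         18L,    512L, "pool5",
    "resnet50",    224L,         50L,   2048L, "avg_pool",
    "resnet101",   224L,        101L,   2048L, "pool5",
    "vgg16",       224L,         16L,   4096L, "fc7",
    "vgg19",       224L,         19L,   4096L, "fc7"
  )
}

#' Built-in feature extractors
#'
#' `extractor_loggabor()` is the handcrafted descriptor: the global
#' Log-Gabor energy vector (mean filter-response magnitude per filter, 80
#' dimensions for the default bank). `extractor_randproj()` is an
#' uninformative control: a seeded random linear projection of the flattened
#' image to `feature_dim` dimensions. `extractor_fn()` wraps an arbitrary
#' image -> vector function (the plugin point for real pretrained
#' backbones).
#'
#' @param params Bank parameters for the Log-Gabor extractor.
#' @param feature_dim Output dimension of the random projection.
#' @param seed Seed for the projection matrix.
#' @param name Extractor label used in reports.
#' @param fn Function taking a grayscale matrix, returning a numeric vector.
#' @param dim Declared output length of `fn`.
#' @return An object of class `feature_extractor`.
#' @export
extractor_loggabor <- function(params = log_gabor_params()) {
  structure(
    list(name = "loggabor", type = "loggabor", params = params,
         feature_dim = params$n_scales * params$n_orientations),
    class = "feature_extractor"
  )
}

#' @rdname extractor_loggabor
#' @export
extractor_randproj <- function(feature_dim = 512, seed = 1) {
  structure(
    list(name = "randproj", type = "randproj",
         feature_dim = as.integer(feature_dim), seed = as.integer(seed)),
    class = "feature_extractor"
  )
}

#' @rdname extractor_loggabor
#' @export
extractor_fn <- function(name, fn, dim) {
  structure(
    list(name = name, type = "fn", fn = fn, feature_dim = as.integer(dim)),
    class = "feature_extractor"
  )
}

resolve_extractor <- function(extractor) {
  if (inherits(extractor, "feature_extractor")) return(extractor)
  if (is.character(extractor) && length(extractor) == 1) {
    return(switch(extractor,
      loggabor = extractor_loggabor(),
      randproj = extractor_randproj(),
      stop("unknown extractor '", extractor, "'", call. = FALSE)
    ))
  }
  stop("extractor must be a feature_extractor or a registered name",
       call. = FALSE)
}

#' Extract fixed-length features from a set of images
#'
#' @param images List of grayscale matrices (or a `leaf_dataset`).
#' @param extractor A `feature_extractor` or built-in name
#'   (`"loggabor"`, `"randproj"`).
#' @return A numeric matrix, one row per image, `feature_dim` columns.
#' @export
extract_features <- function(images, extractor) {
  extractor <- resolve_extractor(extractor)
  if (inherits(images, "leaf_dataset")) images <- images$data$image
  images <- lapply(images, to_luminance)
  switch(extractor$type,
    loggabor = {
      bank <- build_bank(extractor$params, nrow(images[[1]]),
                         ncol(images[[1]]))
      t(vapply(images, function(im) {
        pool_responses(apply_bank(im, bank), "global_energy_vector")
      }, numeric(extractor$feature_dim)))
    },
    randproj = {
      npix <- length(images[[1]])
      proj <- withr::with_seed(extractor$seed, {
        matrix(stats::rnorm(npix * extractor$feature_dim, 0, 1 / sqrt(npix)),
               nrow = npix)
      })
      t(vapply(images, function(im) as.numeric(crossprod(proj, as.numeric(im))),
               numeric(extractor$feature_dim)))
    },
    fn = t(vapply(images, extractor$fn, numeric(extractor$feature_dim)))
  )
}

classifier_names <- c("naive_bayes", "svm", "knn", "decision_tree",
                      "logistic_regression", "random_forest")

fit_predict_classifier <- function(name, x_tr, y_tr, x_te, seed) {
  y_tr_f <- factor(y_tr, levels = sort(unique(y_tr)))
  scale_needed <- name %in% c("svm", "knn", "logistic_regression")
  if (scale_needed) {
    mu <- colMeans(x_tr)
    sd <- pmax(apply(x_tr, 2, stats::sd), 1e-8)
    x_tr <- sweep(sweep(x_tr, 2, mu), 2, sd, "/")
    x_te <- sweep(sweep(x_te, 2, mu), 2, sd, "/")
  }
  pred <- withr::with_seed(seed, switch(name,
    naive_bayes = {
      fit <- e1071::naiveBayes(x_tr, y_tr_f)
      stats::predict(fit, x_te)
    },
    svm = {
      fit <- e1071::svm(x_tr, y_tr_f, kernel = "radial", scale = FALSE)
      stats::predict(fit, x_te)
    },
    knn = class::knn(x_tr, x_te, y_tr_f, k = 5),
    decision_tree = {
      df_tr <- data.frame(y = y_tr_f, x_tr)
      fit <- rpart::rpart(y ~ ., df_tr, method = "class")
      stats::predict(fit, data.frame(x_te), type = "class")
    },
    logistic_regression = {
      df_tr <- data.frame(y = y_tr_f, x_tr)
      fit <- nnet::multinom(y ~ ., df_tr, trace = FALSE,
                            MaxNWts = 100000, maxit = 200)
      stats::predict(fit, data.frame(x_te))
    },
    random_forest = {
      fit <- randomForest::randomForest(x_tr, y_tr_f)
      stats::predict(fit, x_te)
    }
  ))
  as.integer(as.character(pred))
}

#' Evaluate six supervised classifiers on a feature matrix
#'
#' Trains naive Bayes, an RBF support vector machine, k-nearest neighbours
#' (k = 5), a decision tree, multinomial logistic regression and a random
#' forest on the training pool of a stratified split and evaluates them on
#' the held-out test set with the one-vs-rest metrics module. Features are
#' standardized (train-split statistics) for the scale-sensitive learners
#' (SVM, kNN, logistic regression). All stochastic learners run under a
#' fixed seed derived from the split seed, so results are reproducible.
#'
#' @param features Numeric item x dimension matrix (finite values).
#' @param labels Integer class labels (>= 2 classes).
#' @param split A [split_spec()]; the validation carve-out is not used by
#'   the classical learners, so training uses the full 70% pool.
#' @return A list of class `bench_result`: `per_classifier` (tibble of
#'   macro-averaged metrics and timing per classifier), `average` (one-row
#'   tibble, unweighted mean over the six classifiers), `per_class` (list of
#'   per-class metric tibbles keyed by classifier).
#' @export
run_classifier_suite <- function(features, labels, split = split_spec()) {
  stopifnot(is.matrix(features), all(is.finite(features)),
            nrow(features) == length(labels))
  if (length(unique(labels)) < 2) {
    stop("need at least 2 classes", call. = FALSE)
  }
  idx <- split_dataset(labels, split)
  tr <- c(idx$train, idx$val)
  te <- idx$test
  n_classes <- max(labels)
  per_class <- list()
  rows <- lapply(classifier_names, function(nm) {
    t0 <- proc.time()[["elapsed"]]
    pred <- fit_predict_classifier(nm, features[tr, , drop = FALSE],
                                   labels[tr], features[te, , drop = FALSE],
                                   seed = split$seed + 1000L)
    secs <- proc.time()[["elapsed"]] - t0
    m <- class_metrics(confusion_counts(labels[te], pred, n_classes))
    per_class[[nm]] <<- m
    dplyr::bind_cols(tibble::tibble(classifier = nm), macro_summary(m),
                     tibble::tibble(seconds = secs))
  })
  per_classifier <- dplyr::bind_rows(rows)
  average <- dplyr::summarise(
    per_classifier,
    dplyr::across(c("acc", "f1", "tpr", "fpr", "ppv", "seconds"), mean)
  )
  structure(
    list(per_classifier = per_classifier, average = average,
         per_class = per_class, split_seed = split$seed),
    class = "bench_result"
  )
}

#' @export
print.bench_result <- function(x, ...) {
  cat("Classifier benchmark (macro-averaged metrics):\n")
  print(x$per_classifier)
  cat("Average over the six classifiers:\n")
  print(x$average)
  invisible(x)
}

#' Compare feature extractors under the classifier suite
#'
#' Runs [run_classifier_suite()] once per extractor and ranks extractors by
#' the six-classifier average accuracy.
#'
#' @param extractors Non-empty list of extractors (objects or names).
#' @param images List of grayscale matrices or a `leaf_dataset`.
#' @param labels Integer labels (taken from the dataset if omitted).
#' @param split A [split_spec()].
#' @return A list of class `extractor_comparison`: `ranking` (tibble with
#'   extractor, ACC, F1, FPR, PPV, TPR, seconds, ranked by accuracy) and
#'   `results` (named list of `bench_result`s).
#' @export
compare_extractors <- function(extractors, images, labels = NULL,
                               split = split_spec()) {
  if (length(extractors) == 0) {
    stop("extractor list must be non-empty", call. = FALSE)
  }
  if (inherits(images, "leaf_dataset")) {
    if (is.null(labels)) labels <- images$data$label
    images <- images$data$image
  }
  results <- list()
  rows <- lapply(extractors, function(ex) {
    ex <- resolve_extractor(ex)
    t0 <- proc.time()[["elapsed"]]
    feats <- extract_features(images, ex)
    bench <- run_classifier_suite(feats, labels, split)
    secs <- proc.time()[["elapsed"]] - t0
    results[[ex$name]] <<- bench
    tibble::tibble(extractor = ex$name, acc = bench$average$acc,
                   f1 = bench$average$f1, fpr = bench$average$fpr,
                   ppv = bench$average$ppv, tpr = bench$average$tpr,
                   seconds = secs)
  })
  ranking <- dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$acc))
  structure(list(ranking = ranking, results = results),
            class = "extractor_comparison")
}

#' @export
print.extractor_comparison <- function(x, ...) {
  cat("Extractor comparison (ranked by six-classifier average accuracy):\n")
  print(x$ranking)
  invisible(x)
}
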