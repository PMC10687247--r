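#' Machine-learning classifier configuration
#'
#' Validates model/feature compatibility: the CNN consumes spectrogram
#' images; SVM and kNN consume pooled MFCC vectors (`mfcc20` or `mfcc40`).
#' `knn_k` must be one of 3, 5, 7 (odd, as in the study's variants).
#'
#' @param model `"svm"`, `"knn"` or `"cnn"`.
#' @param svm_kernel `"poly3"` (3rd-degree polynomial) or `"rbf"`.
#' @param knn_k neighbourhood size, one of 3, 5, 7.
#' @param feature_variant `"mfcc20"`, `"mfcc40"` or `"spectrogram"`.
#' @param task `"binary"` (normal vs abnormal) or `"three_class"`.
#' @param cnn_batch_size mini-batch size (default 32, as in the full-scale
#'   training runs).
#' @param cnn_max_steps maximum SGD steps (default 2000, scaled down from the
#'   full-scale 200,000-iteration budget).
#' @param cnn_image_size square input image size in pixels.
#' @param cnn_lr SGD learning rate.
#' @param seed integer seed used for any training randomness.
#' @return list of class `ml_config`.
#' @export
ml_config <- function(model = c("svm", "knn", "cnn"),
                      svm_kernel = c("rbf", "poly3"),
                      knn_k = 5,
                      feature_variant = c("mfcc20", "mfcc40", "spectrogram"),
                      task = c("three_class", "binary"),
                      cnn_batch_size = 32, cnn_max_steps = 2000,
                      cnn_image_size = 128, cnn_lr = 0.01, seed = 0) {
  model <- match.arg(model)
  svm_kernel <- match.arg(svm_kernel)
  feature_variant <- match.arg(feature_variant)
  task <- match.arg(task)
  if (model == "knn" && !knn_k %in% c(3, 5, 7))
    stop("knn_k must be one of 3, 5, 7")
  if (model == "cnn" && feature_variant != "spectrogram")
    stop("the CNN requires feature_variant = \"spectrogram\"")
  if (model %in% c("svm", "knn") && feature_variant == "spectrogram")
    stop("svm/knn require an MFCC feature variant (mfcc20 or mfcc40)")
  structure(list(model = model, svm_kernel = svm_kernel, knn_k = knn_k,
                 feature_variant = feature_variant, task = task,
                 cnn_batch_size = cnn_batch_size,
                 cnn_max_steps = cnn_max_steps,
                 cnn_image_size = cnn_image_size, cnn_lr = cnn_lr,
                 seed = seed),
            class = "ml_config")
}

#' Extract classifier features for a list of cycles
#'
#' For `mfcc20`/`mfcc40`: per-cycle pooled MFCC vectors (mean and SD of each
#' coefficient across frames), as an `n x 2k` matrix. For `spectrogram`:
#' a list of fixed-size grayscale images.
#'
#' @param cycles list of [breath_cycle()] objects.
#' @param config [ml_config()].
#' @return feature matrix or list of image matrices, with attribute `labels`
#'   (ground-truth labels, possibly `NA`).
#' @export
cycle_features <- function(cycles, config = ml_config()) {
  labs <- vapply(cycles, function(c) c$true_label, character(1))
  out <- if (config$feature_variant == "spectrogram") {
    lapply(cycles, function(cy)
      spectrogram_image(compute_spectrogram(cy), size = config$cnn_image_size))
  } else {
    k <- if (config$feature_variant == "mfcc20") 20L else 40L
    t(vapply(cycles, function(cy) pool_mfcc(compute_mfcc(cy, n_coeffs = k)),
             numeric(2L * k)))
  }
  attr(out, "labels") <- labs
  out
}

task_labels <- function(labels, task) {
  if (task == "binary") binary_view(labels) else validate_labels(labels)
}

#' Train a classifier
#'
#' Dispatches on `config$model`:
#' \describe{
#'   \item{svm}{one-vs-one soft-margin kernel SVM (SMO solver), kernels
#'     `poly3` / `rbf`; inputs standardised per feature on the training split.}
#'   \item{knn}{stores the standardised training set; Euclidean distance.}
#'   \item{cnn}{small convolutional network (4 conv-relu-maxpool blocks +
#'     softmax head) trained by mini-batch SGD on spectrogram images.}
#' }
#' Training is deterministic given `config$seed`, and a persisted model
#' ([ml_save()]) reloads to identical predictions.
#'
#' @param features matrix (`svm`/`knn`) or list of image matrices (`cnn`),
#'   e.g. from [cycle_features()].
#' @param labels character labels, `NS`/`VS`/`SS` (collapsed internally for
#'   `task = "binary"`).
#' @param config [ml_config()].
#' @return list of class `trained_model`.
#' @export
ml_train <- function(features, labels, config = ml_config()) {
  labels <- task_labels(validate_labels(labels), config$task)
  n <- if (is.list(features)) length(features) else nrow(features)
  if (length(labels) != n) stop("features and labels length mismatch")
  if (length(unique(labels)) < 2)
    stop("training set must contain at least 2 classes")
  state <- switch(config$model,
    svm = , knn = {
      if (!is.matrix(features)) stop("svm/knn require a feature matrix")
      if (any(!is.finite(features))) stop("features must be finite")
      mu <- colMeans(features)
      sdev <- pmax(apply(features, 2, sd), 1e-12)
      Xs <- scale(features, mu, sdev)
      if (config$model == "svm")
        list(std = list(mu = mu, sd = sdev),
             svm = svm_train(Xs, labels, kernel = config$svm_kernel,
                             seed = config$seed))
      else
        list(std = list(mu = mu, sd = sdev), X = unclass(Xs), y = labels,
             k = config$knn_k)
    },
    cnn = {
      if (!is.list(features)) stop("cnn requires a list of image matrices")
      cnn_train(features, labels, config)
    })
  structure(list(config = config, state = state,
                 classes = sort(unique(labels)),
                 dim = if (is.matrix(features)) ncol(features)
                       else dim(features[[1]]),
                 fingerprint = sprintf("n=%d;model=%s;variant=%s;seed=%d", n,
                                       config$model, config$feature_variant,
                                       config$seed)),
            class = "trained_model")
}

#' Predict with a trained classifier
#'
#' @param model a `trained_model` from [ml_train()].
#' @param features same representation and dimensionality as at training.
#' @return list: `labels` (one per cycle), `scores` (matrix of per-class
#'   scores; columns named by class — for the binary task the `"abnormal"`
#'   column is the ROC score).
#' @export
ml_predict <- function(model, features) {
  stopifnot(inherits(model, "trained_model"))
  cfg <- model$config
  if (cfg$model %in% c("svm", "knn")) {
    if (!is.matrix(features)) features <- matrix(features, nrow = 1)
    if (ncol(features) != model$dim)
      stop("feature dimensionality mismatch: expected ", model$dim,
           ", got ", ncol(features))
    Xs <- scale(features, model$state$std$mu, model$state$std$sd)
    if (cfg$model == "svm") {
      pr <- svm_predict(model$state$svm, Xs)
      sc <- pr$votes / max(1, length(model$state$svm$fits))
      if (length(model$classes) == 2)   # use signed margin for smooth scores
        sc <- cbind(-pr$margin[, 2], pr$margin[, 2]) |>
          (\(m) { colnames(m) <- model$classes; m })()
      list(labels = pr$labels, scores = sc)
    } else {
      knn_predict(model$state, Xs)
    }
  } else {
    if (!is.list(features)) features <- list(features)
    if (!all(vapply(features, function(im)
      identical(dim(im), model$dim), logical(1))))
      stop("image dimensionality mismatch: expected ",
           paste(model$dim, collapse = "x"))
    cnn_predict(model$state, features, model$classes)
  }
}

# Vectorised Euclidean kNN with majority vote; ties broken by summed
# neighbour distance (k is odd so binary ties cannot occur).
knn_predict <- function(state, X) {
  d2 <- outer(rowSums(X^2), rowSums(state$X^2), "+") - 2 * X %*% t(state$X)
  classes <- sort(unique(state$y))
  n <- nrow(X)
  labels <- character(n)
  scores <- matrix(0, n, length(classes), dimnames = list(NULL, classes))
  for (i in seq_len(n)) {
    nb <- order(d2[i, ])[seq_len(state$k)]
    tab <- table(factor(state$y[nb], levels = classes))
    scores[i, ] <- as.numeric(tab) / state$k
    best <- names(tab)[tab == max(tab)]
    if (length(best) > 1) {
      dsum <- vapply(best, function(cl)
        sum(d2[i, nb[state$y[nb] == cl]]), numeric(1))
      best <- best[which.min(dsum)]
    }
    labels[i] <- best
  }
  list(labels = labels, scores = scores)
}

#' Persist / reload a trained model
#'
#' Versioned single-file persistence; a reloaded model produces identical
#' predictions.
#'
#' @param model a `trained_model`.
#' @param path file path.
#' @return `ml_save`: `path` invisibly; `ml_load`: the `trained_model`.
#' @export
ml_save <- function(model, path) {
  stopifnot(inherits(model, "trained_model"))
  saveRDS(list(format_version = 1L, model = model), path)
  invisible(path)
}

#' @rdname ml_save
#' @export
ml_load <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$format_version) || obj$format_version != 1L)
    stop("unsupported model file version")
  obj$model
}
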