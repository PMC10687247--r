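gauss_clouds <- function(n = 40, sep = 8, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(2 * n), ncol = 2),
             matrix(rnorm(2 * n, mean = sep), ncol = 2))
  list(X = X, y = rep(c("NS", "VS"), each = n))
}

test_that("configuration validates model/feature compatibility", {
  expect_s3_class(ml_config("knn", knn_k = 3), "ml_config")
  expect_error(ml_config("knn", knn_k = 4), "3, 5, 7")
  expect_error(ml_config("cnn", feature_variant = "mfcc20"), "spectrogram")
  expect_error(ml_config("svm", feature_variant = "spectrogram"), "MFCC")
})

test_that("SVM separates toy clouds with both kernels", {
  d <- gauss_clouds()
  for (kern in c("rbf", "poly3")) {
    cfg <- ml_config("svm", svm_kernel = kern, task = "three_class", seed = 1)
    m <- ml_train(d$X, d$y, cfg)
    pr <- ml_predict(m, d$X)
    expect_identical(mean(pr$labels == d$y), 1)
  }
})

test_that("degenerate training inputs are rejected", {
  d <- gauss_clouds()
  cfg <- ml_config("svm")
  expect_error(ml_train(d$X, rep("NS", nrow(d$X)), cfg), "2 classes")
  expect_error(ml_train(d$X[1:10, ], d$y, cfg), "mismatch")
  m <- ml_train(d$X, d$y, cfg)
  expect_error(ml_predict(m, matrix(0, 2, 5)), "dimensionality")
})

test_that("prediction is order-equivariant", {
  d <- gauss_clouds(seed = 2)
  m <- ml_train(d$X, d$y, ml_config("knn", knn_k = 3))
  pr <- ml_predict(m, d$X)
  perm <- sample(nrow(d$X))
  pr2 <- ml_predict(m, d$X[perm, ])
  expect_identical(pr2$labels, pr$labels[perm])
})

knn_state_predict <- function(state, X)
  tracheosound:::knn_predict(state, X)$labels

test_that("kNN agrees with the exhaustive-search oracle", {
  set.seed(3)
  X <- matrix(rnorm(60 * 4), ncol = 4)
  y <- sample(c("NS", "VS", "SS"), 60, replace = TRUE)
  state <- list(X = X, y = y, k = 1L)
  # k = 1 on a training point returns that point's label
  for (i in c(1, 17, 42))
    expect_identical(knn_state_predict(state, X[i, , drop = FALSE]), y[i])
  for (k in c(3L, 5L, 7L)) {
    state$k <- k
    Q <- matrix(rnorm(50 * 4), ncol = 4)
    got <- knn_state_predict(state, Q)
    want <- vapply(seq_len(nrow(Q)), function(i)
      oracle_knn(X, y, Q[i, ], k), character(1))
    expect_identical(got, want)
  }
})

test_that("models persist and reload to identical predictions", {
  d <- gauss_clouds(seed = 4)
  m <- ml_train(d$X, d$y, ml_config("svm", seed = 2))
  f <- tempfile(fileext = ".rds")
  ml_save(m, f)
  m2 <- ml_load(f)
  expect_identical(ml_predict(m2, d$X), ml_predict(m, d$X))
})

test_that("binary task collapses labels consistently with the class taxonomy", {
  d <- gauss_clouds(seed = 5)
  y3 <- rep(c("NS", "VS"), each = nrow(d$X) / 2)
  m <- ml_train(d$X, y3, ml_config("svm", task = "binary", seed = 1))
  pr <- ml_predict(m, d$X)
  expect_true(all(pr$labels %in% c("normal", "abnormal")))
  expect_identical(pr$labels, binary_view(y3))
  expect_true("abnormal" %in% colnames(pr$scores))
})

test_that("CNN training loss decreases over the first 100 steps", {
  corpus <- default_corpus(8)   # 8/class, images kept small for CPU budget
  labs <- corpus_labels(corpus)
  cfg <- ml_config("cnn", feature_variant = "spectrogram",
                   cnn_image_size = 32, cnn_max_steps = 100,
                   cnn_batch_size = 8, seed = 1)
  imgs <- cycle_features(corpus, cfg)
  m <- ml_train(imgs, labs, cfg)
  lh <- m$state$loss_history
  expect_lt(mean(tail(lh, 10)), mean(head(lh, 10)))
  pr <- ml_predict(m, imgs)
  expect_identical(length(pr$labels), length(labs))
  # deterministic retrain under the same seed
  m2 <- ml_train(imgs, labs, cfg)
  expect_identical(m2$state$loss_history, lh)
})
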