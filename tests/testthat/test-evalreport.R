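test_that("train/test split arithmetic, stratification and determinism", {
  sp <- split_train_test(10, rep(c("NS", "VS"), 5), 0.8, seed = 1)
  expect_identical(length(sp$train), 8L)
  expect_identical(length(sp$test), 2L)
  expect_identical(sort(c(sp$train, sp$test)), 1:10)
  labs <- rep(c("NS", "VS", "SS"), c(60, 20, 20))
  sp2 <- split_train_test(100, labs, 0.8, seed = 2)
  expect_identical(as.integer(table(labs[sp2$train])[c("NS", "VS", "SS")]),
                   c(48L, 16L, 16L))
  expect_identical(split_train_test(100, labs, 0.8, seed = 7),
                   split_train_test(100, labs, 0.8, seed = 7))
  expect_error(split_train_test(3, c("NS", "NS", "VS"), 0.8), "fewer than 2")
  expect_error(split_train_test(10, labs[1:10], 1.2), "train_fraction")
})

test_that("binary metrics match hand-computed confusion arithmetic", {
  # TP=3 FN=1 TN=2 FP=2 with abnormal positive
  truth <- c("VS", "VS", "SS", "VS", "NS", "NS", "NS", "NS")
  pred  <- c("VS", "SS", "VS", "NS", "NS", "NS", "VS", "SS")
  m <- binary_metrics(truth, pred)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 0.5)
  expect_equal(m$accuracy, 0.625)
  expect_equal(m$ppv, 0.6)
  expect_equal(m$npv, 2 / 3)
  expect_identical(sum(m$confusion), 8L)
  perfect <- binary_metrics(truth, truth,
                            scores = ifelse(truth == "NS", 0, 1))
  for (v in c("accuracy", "sensitivity", "specificity", "ppv", "npv", "auc"))
    expect_equal(perfect[[v]], 1)
  # undefined ratios are absent, not zero
  allpos <- binary_metrics(c("VS", "SS"), c("VS", "VS"))
  expect_true(is.na(allpos$specificity))
  expect_true(is.na(allpos$npv))
  # identical scores give AUC 0.5
  expect_equal(binary_metrics(truth, pred, scores = rep(1, 8))$auc, 0.5)
})

test_that("three-class metrics implement accuracy-in-abnormal correctly", {
  r <- three_class_metrics(c("NS", "VS", "SS", "SS"),
                           c("NS", "SS", "SS", "VS"))
  expect_equal(r$accuracy, 0.5)
  expect_equal(r$accuracy_in_abnormal, 1 / 3)
  all_ok <- three_class_metrics(c("NS", "VS", "SS"), c("NS", "VS", "SS"))
  expect_equal(all_ok$accuracy, 1)
  expect_equal(all_ok$accuracy_in_abnormal, 1)
  expect_true(is.na(three_class_metrics(c("NS", "NS"),
                                        c("NS", "VS"))$accuracy_in_abnormal))
})

test_that("metric identities hold on random label sets", {
  set.seed(1)
  for (i in 1:10) {
    truth <- sample(c("NS", "VS", "SS"), 50, replace = TRUE)
    pred <- sample(c("NS", "VS", "SS"), 50, replace = TRUE)
    r <- three_class_metrics(truth, pred)
    expect_equal(r$accuracy, sum(diag(r$confusion)) / 50)
    b <- binary_metrics(truth, pred)
    expect_equal(b$accuracy, sum(diag(r$binary_confusion)) / 50)
  }
})

test_that("ROC staircase integrates to the rank AUC", {
  set.seed(2)
  truth <- sample(c("NS", "VS"), 40, replace = TRUE)
  scores <- rnorm(40) + (truth == "VS")
  roc <- roc_curve(truth, scores)
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
  expect_lt(abs(attr(roc, "auc") -
                binary_metrics(truth, truth, scores = scores)$auc), 1e-9)
  # perfectly separating scores pass through (0, 1)
  sep <- roc_curve(truth, as.numeric(truth == "VS"))
  expect_true(any(sep$fpr == 0 & sep$tpr == 1))
  expect_error(roc_curve(rep("NS", 5), rnorm(5)), "both classes")
})

test_that("trapezoid AUC equals the pairwise-comparison oracle", {
  set.seed(3)
  for (i in 1:50) {
    n <- sample(10:30, 1)
    truth <- c("NS", "VS", sample(c("NS", "VS"), n - 2, replace = TRUE))
    scores <- round(rnorm(n), sample(0:2, 1))   # induce ties
    roc <- roc_curve(truth, scores)
    expect_lt(abs(attr(roc, "auc") -
                  oracle_auc_pairwise(scores, truth == "VS")), 1e-9)
  }
})

test_that("random scores give a null AUC near 0.5", {
  set.seed(4)
  truth <- sample(c("NS", "VS"), 1000, replace = TRUE)
  expect_lt(abs(binary_metrics(truth, truth, scores = rnorm(1000))$auc - 0.5),
            0.05)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(5)
  truth <- sample(c("NS", "SS"), 60, replace = TRUE)
  scores <- rnorm(60)
  a1 <- binary_metrics(truth, truth, scores = scores)$auc
  a2 <- binary_metrics(truth, truth, scores = exp(3 * scores) + 7)$auc
  expect_equal(a1, a2)
})

test_that("class distribution reproduces printed-table arithmetic", {
  labels <- rep(c("NS", "VS", "SS"), c(1449, 1313, 1188))
  cd <- class_distribution(labels)
  expect_identical(cd$count[match(c("NS", "VS", "SS"), cd$label)],
                   c(1449L, 1313L, 1188L))
  expect_identical(cd$percent[match(c("NS", "VS", "SS"), cd$label)],
                   c(36.7, 33.2, 30.1))
  expect_identical(sum(cd$count), length(labels))
  one <- class_distribution(rep("VS", 4))
  expect_identical(one$percent, 100)
  # tally oracle on random vectors
  set.seed(6)
  v <- sample(c("NS", "VS", "SS"), 200, replace = TRUE)
  cd2 <- class_distribution(v)
  for (l in unique(v))
    expect_identical(cd2$count[cd2$label == l], sum(v == l))
  expect_error(class_distribution(character(0)), "at least one")
})

test_that("per-patient statistics follow mean/sample-SD conventions", {
  counts <- data.frame(NS = c(10, 20, 30), VS = c(5, 5, 5))
  st <- per_patient_stats(counts)
  expect_equal(st$mean[st$group == "NS"], 20)
  expect_equal(st$sd[st$group == "NS"], 10)
  expect_equal(st$mean[st$group == "total"], 25)
  one <- per_patient_stats(5)
  expect_equal(one$mean, 5)
  expect_true(is.na(one$sd))
})
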