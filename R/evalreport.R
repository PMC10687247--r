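#' Stratified train/test split
#'
#' `round(n_class * train_fraction)` items per class go to the training set
#' (per-class rounding, 80/20 by default); the split is disjoint, exhaustive,
#' and deterministic under `seed`.
#'
#' @param items vector or list of items, or an integer count.
#' @param labels class labels (required when `stratified = TRUE`).
#' @param train_fraction fraction of items used for training, in (0, 1).
#' @param stratified split within each class (default) or overall.
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(items, labels = NULL, train_fraction = 0.8,
                             seed = 0, stratified = TRUE) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  n <- if (length(items) == 1L && is.numeric(items)) as.integer(items)
       else length(items)
  with_seed(seed, {
    if (stratified) {
      if (is.null(labels)) stop("stratified split requires labels")
      if (length(labels) != n) stop("labels must match items")
      train <- integer(0)
      for (cl in unique(labels)) {
        idx <- which(labels == cl)
        if (length(idx) < 2)
          stop("class ", cl, " has fewer than 2 items; cannot stratify")
        k <- round_half_up(length(idx) * train_fraction)
        k <- min(max(k, 1L), length(idx) - 1L)
        train <- c(train, sample(idx, k))
      }
    } else {
      train <- sample(n, round_half_up(n * train_fraction))
    }
    list(train = sort(train), test = setdiff(seq_len(n), train))
  })
}

round_half_up <- function(x) as.integer(floor(x + 0.5))

# round half away from zero to `digits` decimals (table-reproduction
# convention; base R's round() is half-to-even)
round_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Binary (normal vs abnormal) evaluation metrics
#'
#' Positive class = abnormal (VS or SS) by default — the clinical question is
#' detecting airway problems; set `positive = "normal"` to flip. Metrics:
#' accuracy (TP+TN)/N, sensitivity TP/(TP+FN), specificity TN/(TN+FP),
#' PPV TP/(TP+FP), NPV TN/(TN+FN), and AUC as the rank statistic over the
#' positive-class scores. Ratios with zero denominator are reported `NA`
#' (absent), not 0.
#'
#' @param truth,predicted label vectors; either three-class `NS/VS/SS`
#'   (collapsed via [binary_view()]) or already `normal`/`abnormal`.
#' @param scores optional numeric positive-class scores for AUC/ROC.
#' @param positive `"abnormal"` (default) or `"normal"`.
#' @return list with `accuracy`, `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `auc` (NA without scores), and the 2x2 `confusion` matrix
#'   (rows = truth, cols = predicted).
#' @examples
#' binary_metrics(c("VS","VS","NS","NS"), c("VS","NS","NS","SS"))
#' @export
binary_metrics <- function(truth, predicted, scores = NULL,
                           positive = c("abnormal", "normal")) {
  positive <- match.arg(positive)
  truth <- as_binary(truth); predicted <- as_binary(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted must have the same length")
  neg <- setdiff(c("normal", "abnormal"), positive)
  tp <- sum(truth == positive & predicted == positive)
  tn <- sum(truth == neg & predicted == neg)
  fp <- sum(truth == neg & predicted == positive)
  fn <- sum(truth == positive & predicted == neg)
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  conf <- matrix(c(tp, fn, fp, tn), 2, 2,
                 dimnames = list(truth = c(positive, neg),
                                 predicted = c(positive, neg)))
  auc <- if (!is.null(scores)) {
    if (length(scores) != length(truth)) stop("scores length mismatch")
    rank_auc(scores, truth == positive)
  } else NA_real_
  list(accuracy = safe_div(tp + tn, length(truth)),
       sensitivity = safe_div(tp, tp + fn),
       specificity = safe_div(tn, tn + fp),
       ppv = safe_div(tp, tp + fp),
       npv = safe_div(tn, tn + fn),
       auc = auc, confusion = conf)
}

as_binary <- function(labels) {
  labels <- as.character(labels)
  if (all(labels %in% c("normal", "abnormal"))) return(labels)
  binary_view(labels)
}

# Mann-Whitney AUC with tie correction.
rank_auc <- function(scores, is_pos) {
  np <- sum(is_pos); nn <- sum(!is_pos)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[is_pos]) - np * (np + 1) / 2) / (np * nn)
}

#' Three-class evaluation metrics
#'
#' Total accuracy over all samples, plus "accuracy in abnormal sounds": the
#' fraction of truly abnormal samples (true label VS or SS) whose predicted
#' label equals their true label — so an abnormal cycle misclassified as NS
#' counts as an error. Absent (`NA`) when no abnormal samples exist.
#'
#' @param truth,predicted `NS`/`VS`/`SS` label vectors.
#' @return list: `accuracy`, `accuracy_in_abnormal`, `confusion` (3x3,
#'   rows = truth), and `binary_confusion` (the collapsed 2x2 view).
#' @examples
#' three_class_metrics(c("NS","VS","SS","SS"), c("NS","SS","SS","VS"))
#' @export
three_class_metrics <- function(truth, predicted) {
  truth <- validate_labels(truth); predicted <- validate_labels(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted must have the same length")
  lv <- class_labels()
  conf <- table(truth = factor(truth, lv), predicted = factor(predicted, lv))
  abn <- truth %in% c("VS", "SS")
  bt <- binary_view(truth); bp <- binary_view(predicted)
  bconf <- table(truth = factor(bt, c("abnormal", "normal")),
                 predicted = factor(bp, c("abnormal", "normal")))
  list(accuracy = mean(truth == predicted),
       accuracy_in_abnormal = if (any(abn))
         mean(truth[abn] == predicted[abn]) else NA_real_,
       confusion = conf, binary_confusion = bconf)
}

#' ROC curve of a binary score
#'
#' Monotone staircase from (0,0) to (1,1); score ties are grouped, so the
#' trapezoidal area equals the rank-statistic (Mann-Whitney) AUC exactly.
#'
#' @param truth labels (three-class or `normal`/`abnormal`).
#' @param scores numeric positive-class scores.
#' @param positive positive class, default `"abnormal"`.
#' @return data.frame with columns `fpr`, `tpr` and attribute `auc`.
#' @export
roc_curve <- function(truth, scores, positive = c("abnormal", "normal")) {
  positive <- match.arg(positive)
  truth <- as_binary(truth)
  if (length(truth) != length(scores)) stop("scores length mismatch")
  is_pos <- truth == positive
  np <- sum(is_pos); nn <- sum(!is_pos)
  if (np == 0 || nn == 0)
    stop("ROC requires both classes present in `truth`")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- is_pos[o]
  cut_end <- which(c(diff(s) != 0, TRUE))   # last index of each tie group
  tpr <- c(0, cumsum(y)[cut_end] / np)
  fpr <- c(0, cumsum(!y)[cut_end] / nn)
  out <- data.frame(fpr = fpr, tpr = tpr)
  attr(out, "auc") <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  out
}

#' Class counts and percentages
#'
#' Counts per class (summing to n) and percentages `100 * count / n` rounded
#' half-away-from-zero to 1 decimal, the table-printing convention.
#'
#' @param labels `NS`/`VS`/`SS` label vector.
#' @return data.frame `label`, `count`, `percent`.
#' @examples
#' class_distribution(rep(c("NS","VS","SS"), c(2, 1, 1)))
#' @export
class_distribution <- function(labels) {
  if (!length(labels)) stop("at least one label is required")
  labels <- validate_labels(labels)
  cnt <- table(factor(labels, class_labels()))
  cnt <- cnt[cnt > 0 | names(cnt) %in% unique(labels)]
  data.frame(label = names(cnt), count = as.integer(cnt),
             percent = round_away(100 * as.integer(cnt) / length(labels), 1),
             stringsAsFactors = FALSE)
}

#' Per-patient count statistics
#'
#' Arithmetic mean and sample SD (n-1) of per-patient counts, per class and
#' in total. With a single patient the SD is `NA`.
#'
#' @param per_patient_counts data.frame or matrix, one row per patient, one
#'   column per class (e.g. `NS`,`VS`,`SS`), or a plain numeric vector of
#'   totals.
#' @return data.frame `group`, `n_patients`, `mean`, `sd`.
#' @export
per_patient_stats <- function(per_patient_counts) {
  if (is.vector(per_patient_counts))
    per_patient_counts <- data.frame(total = per_patient_counts)
  m <- as.data.frame(per_patient_counts)
  if (!nrow(m)) stop("at least one patient is required")
  if (!"total" %in% names(m)) m$total <- rowSums(m)
  do.call(rbind, lapply(names(m), function(g)
    data.frame(group = g, n_patients = nrow(m), mean = mean(m[[g]]),
               sd = if (nrow(m) > 1) sd(m[[g]]) else NA_real_,
               stringsAsFactors = FALSE)))
}

#' Allocate per-class totals across patients
#'
#' Distributes each class's total count as evenly as possible over
#' `n_patients` rows (remainders go to the first rows). Useful for
#' reconstructing per-patient count tables from published per-class totals:
#' the per-patient *mean* equals `total / n_patients` whatever the
#' allocation, so [per_patient_stats()] on the result reproduces printed
#' per-person means exactly.
#'
#' @param counts named integer vector of per-class totals.
#' @param n_patients number of patients.
#' @return data.frame with one row per patient and one column per class.
#' @export
allocate_counts <- function(counts, n_patients) {
  stopifnot(n_patients >= 1, all(counts >= 0))
  cols <- lapply(counts, function(total) {
    base <- total %/% n_patients
    extra <- total %% n_patients
    base + as.integer(seq_len(n_patients) <= extra)
  })
  as.data.frame(cols)
}

#' Write a metrics report to CSV and a text summary
#'
#' @param metrics list from [binary_metrics()] and/or
#'   [three_class_metrics()].
#' @param path output CSV path (a sibling `.txt` human-readable report is
#'   written too).
#' @param fingerprint free-text configuration fingerprint recorded in the
#'   report.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path, fingerprint = "") {
  num <- metrics[vapply(metrics, function(x)
    is.numeric(x) && length(x) == 1L, logical(1))]
  df <- data.frame(metric = names(num), value = unlist(num),
                   row.names = NULL)
  write.csv(df, path, row.names = FALSE)
  txt <- sub("\\.csv$", ".txt", path)
  lines <- c("breathing-sound classifier evaluation",
             if (nzchar(fingerprint)) paste("config:", fingerprint),
             sprintf("%-22s %s", df$metric,
                     ifelse(is.na(df$value), "NA",
                            sprintf("%.4f", df$value))))
  writeLines(lines, txt)
  invisible(path)
}
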