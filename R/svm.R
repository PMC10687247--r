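# Kernel SVM via sequential minimal optimisation (no SVM library is assumed).
# Binary soft-margin C-SVM; multiclass by one-vs-one voting.

svm_kernel_matrix <- function(X, Y, kernel, gamma) {
  G <- X %*% t(Y)
  if (kernel == "rbf") {
    d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * G
    exp(-gamma * pmax(d2, 0))
  } else if (kernel == "poly3") {
    (gamma * G + 1)^3
  } else stop("unknown kernel: ", kernel)
}

# Simplified SMO (Platt). y in {-1, +1}. Returns alpha, b.
smo_fit <- function(K, y, C = 1, tol = 1e-3, max_passes = 10,
                    max_iter = 20000) {
  n <- length(y)
  alpha <- rep(0, n); b <- 0
  passes <- 0L; iter <- 0L
  fcache <- function(i) sum(alpha * y * K[, i]) + b
  while (passes < max_passes && iter < max_iter) {
    changed <- 0L
    for (i in seq_len(n)) {
      iter <- iter + 1L
      Ei <- fcache(i) - y[i]
      if ((y[i] * Ei < -tol && alpha[i] < C) ||
          (y[i] * Ei > tol && alpha[i] > 0)) {
        j <- sample(setdiff(seq_len(n), i), 1L)
        Ej <- fcache(j) - y[j]
        ai_old <- alpha[i]; aj_old <- alpha[j]
        if (y[i] != y[j]) {
          L <- max(0, aj_old - ai_old); H <- min(C, C + aj_old - ai_old)
        } else {
          L <- max(0, ai_old + aj_old - C); H <- min(C, ai_old + aj_old)
        }
        if (L >= H) next
        eta <- 2 * K[i, j] - K[i, i] - K[j, j]
        if (eta >= 0) next
        aj <- aj_old - y[j] * (Ei - Ej) / eta
        aj <- min(H, max(L, aj))
        if (abs(aj - aj_old) < 1e-5) next
        ai <- ai_old + y[i] * y[j] * (aj_old - aj)
        b1 <- b - Ei - y[i] * (ai - ai_old) * K[i, i] -
          y[j] * (aj - aj_old) * K[i, j]
        b2 <- b - Ej - y[i] * (ai - ai_old) * K[i, j] -
          y[j] * (aj - aj_old) * K[j, j]
        alpha[i] <- ai; alpha[j] <- aj
        b <- if (ai > 0 && ai < C) b1 else if (aj > 0 && aj < C) b2
             else (b1 + b2) / 2
        changed <- changed + 1L
      }
    }
    passes <- if (changed == 0L) passes + 1L else 0L
  }
  list(alpha = alpha, b = b)
}

# Train one-vs-one kernel SVM. X standardized upstream.
svm_train <- function(X, y, kernel = c("rbf", "poly3"), C = 1, gamma = NULL,
                      seed = 0) {
  kernel <- match.arg(kernel)
  classes <- sort(unique(y))
  if (is.null(gamma)) {
    v <- mean(apply(X, 2, stats::var))
    gamma <- if (kernel == "rbf") 1 / (ncol(X) * max(v, 1e-12)) else 1 / ncol(X)
  }
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  fits <- with_seed(seed, lapply(pairs, function(pr) {
    idx <- y %in% pr
    Xi <- X[idx, , drop = FALSE]
    yi <- ifelse(y[idx] == pr[2], 1, -1)     # +1 = second class of the pair
    K <- svm_kernel_matrix(Xi, Xi, kernel, gamma)
    fit <- smo_fit(K, yi, C = C)
    sv <- fit$alpha > 1e-8
    list(pair = pr, X = Xi[sv, , drop = FALSE],
         coef = (fit$alpha * yi)[sv], b = fit$b)
  }))
  list(classes = classes, kernel = kernel, gamma = gamma, C = C, fits = fits)
}

svm_decision <- function(fit, X, kernel, gamma) {
  K <- svm_kernel_matrix(X, fit$X, kernel, gamma)
  as.numeric(K %*% fit$coef + fit$b)
}

svm_predict <- function(model, X) {
  classes <- model$classes
  votes <- matrix(0, nrow(X), length(classes),
                  dimnames = list(NULL, classes))
  margin <- matrix(0, nrow(X), length(classes),
                   dimnames = list(NULL, classes))
  for (fit in model$fits) {
    d <- svm_decision(fit, X, model$kernel, model$gamma)
    win <- ifelse(d > 0, fit$pair[2], fit$pair[1])
    for (cl in fit$pair) votes[, cl] <- votes[, cl] + (win == cl)
    margin[, fit$pair[2]] <- margin[, fit$pair[2]] + d
    margin[, fit$pair[1]] <- margin[, fit$pair[1]] - d
  }
  # ties broken by accumulated margin
  scores <- votes + 1e-6 * (margin - min(margin))
  labels <- classes[max.col(scores, ties.method = "first")]
  list(labels = labels, votes = votes, margin = margin)
}
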