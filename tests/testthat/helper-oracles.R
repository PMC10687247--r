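# Independent brute-force oracles used to cross-check the package's
# implementations. Deliberately written as plain loops over definitions,
# sharing no code with the package internals.

# fraction of full-signal FFT energy inside [lo, hi) Hz
oracle_band_energy <- function(samples, fs, lo, hi) {
  X <- abs(fft(samples))^2
  n <- length(samples)
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f)
  sum(X[f >= lo & f < hi]) / sum(X)
}

# MFCC of a single windowed frame straight from the definition:
# one-sided power spectrum -> triangular mel filters -> log -> DCT-II.
oracle_mfcc_frame <- function(frame, fs, n_coeffs, n_mels = 48, fmin = 0,
                              fmax = 12000) {
  n <- length(frame)
  X <- fft(frame)
  nb <- n %/% 2 + 1
  pow <- abs(X[1:nb])^2 / n
  for (i in seq_len(nb)) {
    if (i > 1 && !(n %% 2 == 0 && i == nb)) pow[i] <- 2 * pow[i]
  }
  freqs <- (0:(nb - 1)) * fs / n
  mel <- function(f) 2595 * log10(1 + f / 700)
  imel <- function(m) 700 * (10^(m / 2595) - 1)
  edges <- imel(seq(mel(fmin), mel(fmax), length.out = n_mels + 2))
  energies <- numeric(n_mels)
  for (m in 1:n_mels) {
    w <- numeric(nb)
    for (i in 1:nb) {
      f <- freqs[i]
      if (f > edges[m] && f < edges[m + 2]) {
        w[i] <- if (f <= edges[m + 1]) (f - edges[m]) / (edges[m + 1] - edges[m])
                else (edges[m + 2] - f) / (edges[m + 2] - edges[m + 1])
      }
    }
    energies[m] <- sum(w * pow)
  }
  loge <- log(pmax(energies, 1e-12))
  out <- numeric(n_coeffs)
  for (k in 0:(n_coeffs - 1)) {
    acc <- 0
    for (m in 0:(n_mels - 1))
      acc <- acc + loge[m + 1] * cos(pi * k * (m + 0.5) / n_mels)
    out[k + 1] <- acc * if (k == 0) sqrt(1 / n_mels) else sqrt(2 / n_mels)
  }
  out
}

# exhaustive-scan k-nearest-neighbour vote
oracle_knn <- function(Xtr, ytr, xq, k) {
  d <- numeric(nrow(Xtr))
  for (i in seq_len(nrow(Xtr))) d[i] <- sqrt(sum((Xtr[i, ] - xq)^2))
  nb <- order(d)[1:k]
  votes <- table(ytr[nb])
  best <- names(votes)[votes == max(votes)]
  if (length(best) == 1) return(best)
  dsum <- sapply(best, function(cl) sum(d[nb[ytr[nb] == cl]]))
  best[which.min(dsum)]
}

# AUC as the fraction of positive/negative pairs ranked correctly
# (ties count half)
oracle_auc_pairwise <- function(scores, is_pos) {
  pos <- scores[is_pos]; neg <- scores[!is_pos]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

jaccard_interval <- function(a, b) {
  inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]))
  inter / (max(a[2], b[2]) - min(a[1], b[1]))
}
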