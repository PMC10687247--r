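#' Short-time Fourier transform spectrogram
#'
#' Magnitude-squared STFT with a Hann window (25 ms) and 10 ms hop by default.
#' `power` is linear one-sided power, scaled so that `sum(power)` equals the
#' total windowed time-domain energy (Parseval); [spectrogram_db()] gives the
#' dB view floored at -80 dB.
#'
#' @param x `breath_cycle`, `audio_signal` or numeric vector (+ `sample_rate`).
#' @param window_s,hop_s window length and hop, seconds.
#' @param window_fn `"hann"` or `"rect"`.
#' @param sample_rate needed for bare numeric input.
#' @return list of class `spectrogram`: `power` (freq x time matrix), `freqs`
#'   (Hz, 0..Nyquist), `times` (frame centres, s), `stft_params`.
#' @export
compute_spectrogram <- function(x, window_s = 0.025, hop_s = 0.010,
                                window_fn = c("hann", "rect"),
                                sample_rate = NULL) {
  window_fn <- match.arg(window_fn)
  sig <- as_audio(x, sample_rate)
  fs <- sig$sample_rate
  wl <- round(window_s * fs)
  hop <- max(1L, round(hop_s * fs))
  n <- length(sig$samples)
  if (n < wl) stop("signal shorter than one STFT window (", wl, " samples)")
  nfr <- 1L + (n - wl) %/% hop
  idx <- outer(seq_len(wl), (seq_len(nfr) - 1L) * hop, "+")
  frames <- matrix(sig$samples[idx], nrow = wl)
  w <- if (window_fn == "hann")
    0.5 - 0.5 * cos(2 * pi * (seq_len(wl) - 1) / (wl - 1)) else rep(1, wl)
  X <- mvfft(frames * w)
  nb <- wl %/% 2L + 1L
  pow <- Mod(X[seq_len(nb), , drop = FALSE])^2 / wl
  scale <- rep(2, nb); scale[1] <- 1
  if (wl %% 2 == 0) scale[nb] <- 1          # Nyquist bin not duplicated
  pow <- pow * scale
  structure(list(power = pow,
                 freqs = (seq_len(nb) - 1) * fs / wl,
                 times = ((seq_len(nfr) - 1L) * hop + wl / 2) / fs,
                 stft_params = list(window_s = wl / fs, hop_s = hop / fs,
                                    window_fn = window_fn, sample_rate = fs)),
            class = "spectrogram")
}

#' @rdname compute_spectrogram
#' @param spec a `spectrogram`.
#' @param floor_db dB floor (default -80).
#' @return `spectrogram_db`: matrix of dB values relative to the maximum bin.
#' @export
spectrogram_db <- function(spec, floor_db = -80) {
  ref <- max(spec$power, 1e-300)
  pmax(10 * log10(pmax(spec$power, 1e-300) / ref), floor_db)
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %d bins x %d frames, 0-%g Hz, window %.1f ms\n",
              nrow(x$power), ncol(x$power), max(x$freqs),
              1000 * x$stft_params$window_s))
  invisible(x)
}

# HTK mel scale
hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# Triangular mel filter bank: n_mels x n_bins matrix (unit peak triangles).
mel_filterbank <- function(n_mels, freqs, fmin, fmax) {
  mels <- seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_mels + 2L)
  edges <- mel_to_hz(mels)
  fb <- matrix(0, n_mels, length(freqs))
  for (m in seq_len(n_mels)) {
    lo <- edges[m]; ce <- edges[m + 1]; hi <- edges[m + 2]
    up <- (freqs - lo) / (ce - lo)
    down <- (hi - freqs) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

# Orthonormal DCT-II basis, n_out x n_in.
dct_basis <- function(n_out, n_in) {
  k <- seq_len(n_out) - 1L
  m <- seq_len(n_in) - 1L
  B <- sqrt(2 / n_in) * cos(pi * outer(k, m + 0.5) / n_in)
  B[1, ] <- sqrt(1 / n_in)
  B
}

#' Mel-frequency cepstral coefficients
#'
#' Per frame: one-sided power spectrum -> triangular mel filter bank (48
#' filters over 0–12,000 Hz, matching the spectrogram's analysed range) ->
#' log -> orthonormal DCT-II, keeping the first `n_coeffs` coefficients. The
#' two study variants are MFCC(20) and MFCC(40).
#'
#' @param x `breath_cycle`, `audio_signal` or numeric (+ `sample_rate`).
#' @param n_coeffs 20 or 40 (other values need `allow_any = TRUE`).
#' @param n_mels number of mel filters (default 48 so that 40 kept DCT
#'   coefficients remain well-posed).
#' @param fmin,fmax filter-bank frequency range, Hz.
#' @param window_s,hop_s STFT framing, seconds.
#' @param allow_any override the `n_coeffs %in% c(20, 40)` contract.
#' @param sample_rate needed for bare numeric input.
#' @return list of class `mfcc_matrix`: `coeffs` (`n_coeffs` x n_frames),
#'   `times`, and the extraction parameters in `mel_params`.
#' @export
compute_mfcc <- function(x, n_coeffs = 20, n_mels = 48, fmin = 0, fmax = 12000,
                         window_s = 0.025, hop_s = 0.010, allow_any = FALSE,
                         sample_rate = NULL) {
  if (!n_coeffs %in% c(20L, 40L) && !allow_any)
    stop("n_coeffs must be 20 or 40 (set allow_any = TRUE to override)")
  if (n_coeffs > n_mels) stop("n_coeffs cannot exceed n_mels")
  spec <- compute_spectrogram(x, window_s = window_s, hop_s = hop_s,
                              sample_rate = sample_rate)
  if (fmax > max(spec$freqs)) fmax <- max(spec$freqs)
  fb <- mel_filterbank(n_mels, spec$freqs, fmin, fmax)
  melE <- fb %*% spec$power
  logE <- log(pmax(melE, 1e-12))
  B <- dct_basis(n_coeffs, n_mels)
  structure(list(coeffs = B %*% logE, times = spec$times,
                 mel_params = list(n_mels = n_mels, fmin = fmin, fmax = fmax,
                                   window_s = window_s, hop_s = hop_s)),
            class = "mfcc_matrix")
}

#' Pool a per-frame MFCC matrix into a fixed-length cycle feature vector
#'
#' Mean and SD of each coefficient across frames (`2 * n_coeffs` values) —
#' the representation fed to the SVM/kNN classifiers, since cycles have
#' variable length.
#'
#' @param mfcc an `mfcc_matrix`.
#' @return named numeric vector `mean_1..mean_k, sd_1..sd_k`.
#' @export
pool_mfcc <- function(mfcc) {
  m <- mfcc$coeffs
  s <- if (ncol(m) > 1) apply(m, 1, sd) else rep(0, nrow(m))
  out <- c(rowMeans(m), s)
  names(out) <- c(paste0("mean_", seq_len(nrow(m))),
                  paste0("sd_", seq_len(nrow(m))))
  out
}

#' Fraction of spectral energy inside a frequency band
#'
#' Energy in `[band[1], band[2])` divided by total energy of the spectrogram.
#'
#' @param spec a `spectrogram`.
#' @param band `c(lo, hi)` in Hz, inside the spectrogram's range, `lo < hi`.
#' @return fraction in `[0, 1]`.
#' @export
band_energy_fraction <- function(spec, band) {
  stopifnot(inherits(spec, "spectrogram"))
  if (length(band) != 2L || band[1] >= band[2])
    stop("band must be c(lo, hi) with lo < hi")
  if (band[1] > max(spec$freqs) || band[2] < min(spec$freqs))
    stop("band lies outside the spectrogram's frequency range")
  rows <- spec$freqs >= band[1] & spec$freqs < band[2]
  if (!any(rows)) stop("band contains no frequency bins")
  tot <- sum(spec$power)
  if (tot == 0) return(0)
  sum(spec$power[rows, , drop = FALSE]) / tot
}

#' Amplitude-modulation peak of the high-band envelope
#'
#' VS breath sounds carry a repetitive ~100/s amplitude pattern. The cycle is
#' high-pass filtered above `band_min`, its amplitude envelope is extracted
#' (rectification + 1 ms smoothing, decimated to ~2 kHz), and a Welch
#' modulation spectrum (0.5 s Hann segments, 50% overlap) is searched for the
#' dominant peak in `mod_band` (20–300 Hz). The prominence is the peak power
#' relative to the median in-band modulation power; the peak is reported
#' absent when the envelope is essentially flat (coefficient of variation
#' < 0.05) or prominence is below `prom_threshold`. The default gate of 100
#' was calibrated once on the default synthetic corpus: coherent VS
#' modulation reaches prominence ~1500-2000 (~250-320 for mixed VS+SS
#' cycles), while the broadband/tonal null stays below ~50.
#'
#' @param x `breath_cycle`, `audio_signal` or numeric (+ `sample_rate`);
#'   at least 0.5 s long.
#' @param band_min high-pass edge of the carrier band, Hz.
#' @param mod_band modulation search band, Hz.
#' @param prom_threshold minimum prominence for a peak to count as present.
#' @param sample_rate needed for bare numeric input.
#' @return list: `present` (logical), `peak_hz` (`NA` when absent),
#'   `prominence`.
#' @export
modulation_peak <- function(x, band_min = 1500, mod_band = c(20, 300),
                            prom_threshold = 100, sample_rate = NULL) {
  sig <- as_audio(x, sample_rate)
  if (duration(sig) < 0.5) stop("cycle must be at least 0.5 s for modulation analysis")
  fs <- sig$sample_rate
  n <- length(sig$samples)
  # high band via FFT mask (zero-padded to a fast length)
  nf <- fft_length(n)
  X <- fft(c(sig$samples, rep(0, nf - n)))
  f <- (seq_len(nf) - 1) / nf * fs
  f <- pmin(f, fs - f)
  X[f < band_min] <- 0
  hp <- Re(fft(X, inverse = TRUE))[seq_len(n)] / nf
  env <- abs(hp)
  sm <- max(1L, round(0.001 * fs))          # 1 ms boxcar
  env <- as.numeric(stats::filter(env, rep(1 / sm, sm), sides = 2))
  env <- env[!is.na(env)]
  dec <- max(1L, floor(fs / 2000))
  env <- colMeans(matrix(env[seq_len((length(env) %/% dec) * dec)], nrow = dec))
  env_fs <- fs / dec
  cv <- sd(env) / max(mean(env), 1e-12)
  if (!is.finite(cv) || cv < 0.05)
    return(list(present = FALSE, peak_hz = NA_real_, prominence = 0))
  ps <- welch_psd(env - mean(env), env_fs, seg_s = 0.5)
  inb <- ps$freq >= mod_band[1] & ps$freq <= mod_band[2]
  if (!any(inb)) return(list(present = FALSE, peak_hz = NA_real_, prominence = 0))
  p <- ps$power[inb]; fr <- ps$freq[inb]
  i <- which.max(p)
  prom <- p[i] / max(median(p), 1e-300)
  list(present = prom >= prom_threshold, peak_hz = fr[i], prominence = prom)
}

# Welch averaged periodogram (Hann segments, 50% overlap).
welch_psd <- function(x, fs, seg_s = 0.5) {
  seg <- min(length(x), max(16L, round(seg_s * fs)))
  hop <- max(1L, seg %/% 2L)
  starts <- seq(1L, length(x) - seg + 1L, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(seg) - 1) / (seg - 1))
  nb <- seg %/% 2L + 1L
  acc <- rep(0, nb)
  for (s in starts) {
    X <- fft(x[s + seq_len(seg) - 1L] * w)
    acc <- acc + Mod(X[seq_len(nb)])^2
  }
  list(freq = (seq_len(nb) - 1) * fs / seg, power = acc / length(starts))
}

#' Persistence of stable high-frequency spectral lines
#'
#' SS breath sounds show sustained narrow spectral lines ("horizontal lines")
#' above 2000 Hz. Per frame, peak bins above `min_freq` are bins that are
#' local maxima and stand `peak_factor` (10x) above the local running-median
#' spectral background; a bin
#' (+/- 1) active in at least `stable_frac` of frames is a stable line. The
#' returned value is the fraction of frames in which at least one stable line
#' is active.
#'
#' @param spec a `spectrogram` with >= 5 frames.
#' @param min_freq lower frequency edge, Hz.
#' @param stable_frac persistence required for a bin to count as a line.
#' @param peak_factor multiple of the local background a peak must exceed.
#' @return fraction in `[0, 1]`.
#' @export
line_persistence <- function(spec, min_freq = 2000, stable_frac = 0.8,
                             peak_factor = 10) {
  stopifnot(inherits(spec, "spectrogram"))
  if (ncol(spec$power) < 5) stop("need at least 5 frames for line persistence")
  rows <- which(spec$freqs >= min_freq)
  P <- spec$power[rows, , drop = FALSE]
  nb <- nrow(P); nf <- ncol(P)
  # local spectral background: running median over ~51 bins per frame, so a
  # "peak" is a narrow line standing clear of its neighbourhood, not just a
  # bin inside a broad noise band
  k <- min(nb - (1 - nb %% 2), 51L)
  if (k %% 2 == 0) k <- k - 1L
  thr <- if (k >= 3)
    apply(P, 2, function(col) stats::runmed(col, k, endrule = "median"))
  else matrix(apply(P, 2, median), nb, nf, byrow = TRUE)
  thr <- peak_factor * pmax(thr, 1e-300)
  up <- rbind(P[-1, , drop = FALSE], -Inf)
  dn <- rbind(-Inf, P[-nb, , drop = FALSE])
  peaks <- (P >= up) & (P >= dn) & (P > thr)
  # dilate +/- 1 bin
  act <- peaks | rbind(peaks[-1, , drop = FALSE], FALSE) |
    rbind(FALSE, peaks[-nb, , drop = FALSE])
  coverage <- rowMeans(act)
  stable <- coverage >= stable_frac
  if (!any(stable)) return(0)
  mean(colSums(act[stable, , drop = FALSE]) > 0)
}

#' Acoustic descriptors of one breath cycle
#'
#' The compact per-cycle summary consumed by the rule classifier: band-energy
#' fractions (below 1500 Hz; in the NS band 1500–2000 Hz relative to energy
#' above 1500 Hz; above 2000 Hz), the envelope modulation peak, and the
#' high-frequency line persistence.
#'
#' @param cycle a [breath_cycle()] (or `audio_signal`).
#' @param window_s,hop_s STFT framing, seconds.
#' @return list of class `acoustic_descriptors`.
#' @export
acoustic_descriptors <- function(cycle, window_s = 0.025, hop_s = 0.010) {
  sig <- as_audio(cycle)
  spec <- compute_spectrogram(sig, window_s = window_s, hop_s = hop_s)
  nyq <- max(spec$freqs)
  above1500 <- band_energy_fraction(spec, c(1500, nyq + 1))
  ns_frac_global <- band_energy_fraction(spec, c(1500, 2000))
  mp <- if (duration(sig) >= 0.5) modulation_peak(sig)
        else list(present = FALSE, peak_hz = NA_real_, prominence = 0)
  structure(list(
    frac_below_1500 = band_energy_fraction(spec, c(0, 1500)),
    frac_above_2000 = band_energy_fraction(spec, c(2000, nyq + 1)),
    ns_band_fraction = if (above1500 > 0) ns_frac_global / above1500 else 0,
    modulation_present = mp$present,
    modulation_peak = mp$peak_hz,
    modulation_prominence = mp$prominence,
    line_persistence = line_persistence(spec)),
    class = "acoustic_descriptors")
}

#' Render a spectrogram as a fixed-size grayscale image
#'
#' dB view (floored at `floor_db`), min-max normalised to `[0, 1]`, resampled
#' by bilinear interpolation to `size x size` (frequency rows, time columns,
#' time-normalised per cycle). This is the CNN input representation.
#'
#' @param spec a `spectrogram`.
#' @param size output height/width in pixels (default 128).
#' @param floor_db dB floor.
#' @return `size` x `size` numeric matrix in `[0, 1]`, row 1 = highest
#'   frequency (so the image is "frequency up").
#' @export
spectrogram_image <- function(spec, size = 128, floor_db = -80) {
  db <- spectrogram_db(spec, floor_db)
  img <- resize_bilinear(db, size, size)
  rng <- range(img)
  if (diff(rng) > 0) img <- (img - rng[1]) / diff(rng) else img[] <- 0
  img[rev(seq_len(size)), , drop = FALSE]
}

resize_bilinear <- function(m, nr, nc) {
  ri <- seq(1, nrow(m), length.out = nr)
  ci <- seq(1, ncol(m), length.out = nc)
  r0 <- pmin(floor(ri), nrow(m) - 1L); rf <- ri - r0
  c0 <- pmin(floor(ci), ncol(m) - 1L); cf <- ci - c0
  if (nrow(m) == 1L) { r0 <- rep(1L, nr); rf <- rep(0, nr) }
  if (ncol(m) == 1L) { c0 <- rep(1L, nc); cf <- rep(0, nc) }
  a <- m[r0, c0, drop = FALSE] * outer(1 - rf, 1 - cf)
  b <- m[pmin(r0 + 1, nrow(m)), c0, drop = FALSE] * outer(rf, 1 - cf)
  d <- m[r0, pmin(c0 + 1, ncol(m)), drop = FALSE] * outer(1 - rf, cf)
  e <- m[pmin(r0 + 1, nrow(m)), pmin(c0 + 1, ncol(m)), drop = FALSE] *
    outer(rf, cf)
  a + b + d + e
}

#' Export a spectrogram as a grayscale PNG
#'
#' Frequency up, time right, dB grayscale.
#'
#' @param spec a `spectrogram`.
#' @param path output PNG path.
#' @param size image size in pixels.
#' @return `path`, invisibly.
#' @export
export_spectrogram_png <- function(spec, path, size = 128) {
  img <- spectrogram_image(spec, size)
  grDevices::png(path, width = size, height = size)
  op <- graphics::par(mar = c(0, 0, 0, 0))
  graphics::image(t(img[rev(seq_len(nrow(img))), , drop = FALSE]),
                  col = grDevices::gray.colors(256, 0, 1), axes = FALSE,
                  useRaster = TRUE)
  graphics::par(op)
  grDevices::dev.off()
  invisible(path)
}
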