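#' Construct a mono audio signal
#'
#' The basic container passed between every stage of the pipeline: a numeric
#' vector of amplitude samples (nominally in \[-1, 1\]) plus its sample rate.
#'
#' @param samples numeric vector of amplitude samples.
#' @param sample_rate sampling rate in Hz (single positive number).
#' @return An object of class `audio_signal` (a list with elements `samples`
#'   and `sample_rate`).
#' @examples
#' s <- audio_signal(sin(2 * pi * 440 * seq(0, 1, by = 1 / 8000)), 8000)
#' duration(s)
#' @export
audio_signal <- function(samples, sample_rate) {
  if (!is.numeric(samples)) stop("`samples` must be numeric")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("`sample_rate` must be a single positive number")
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate),
            class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal> %d samples @ %g Hz (%.3f s)\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate))
  invisible(x)
}

#' Duration of an audio signal or breath cycle, in seconds
#' @param x an `audio_signal` or `breath_cycle`.
#' @return duration in seconds.
#' @export
duration <- function(x) UseMethod("duration")

#' @export
duration.audio_signal <- function(x) length(x$samples) / x$sample_rate

#' @export
duration.breath_cycle <- function(x) x$end - x$start

#' Construct a breath cycle
#'
#' One respiratory cycle: a time interval within a parent recording, the audio
#' slice covering it, and (when known) the ground-truth class label.
#'
#' @param start,end interval bounds in seconds (half-open `[start, end)`),
#'   relative to the parent recording; `end > start`.
#' @param signal `audio_signal` holding the samples of the cycle itself.
#' @param true_label optional ground-truth label, one of `"NS"`, `"VS"`, `"SS"`.
#' @return An object of class `breath_cycle`.
#' @export
breath_cycle <- function(signal, start = 0, end = start + duration(signal),
                         true_label = NA_character_) {
  stopifnot(inherits(signal, "audio_signal"))
  if (!is.numeric(start) || !is.numeric(end) || end <= start)
    stop("breath cycle must have end > start")
  if (!is.na(true_label)) true_label <- validate_labels(true_label)
  structure(list(start = start, end = end, signal = signal,
                 true_label = true_label),
            class = "breath_cycle")
}

#' @export
print.breath_cycle <- function(x, ...) {
  cat(sprintf("<breath_cycle> [%.3f, %.3f) s (%.3f s)%s\n", x$start, x$end,
              x$end - x$start,
              if (is.na(x$true_label)) "" else paste0(" label=", x$true_label)))
  invisible(x)
}

#' Class labels of the three-category taxonomy
#'
#' `NS` = normal breathing sound, `VS` = vibrant breathing sound (movable
#' obstacle, ~100/s amplitude bursts), `SS` = sharp breathing sound (fixed
#' obstacle, sustained high-frequency lines). The binary view maps NS to
#' `"normal"` and VS/SS to `"abnormal"`.
#'
#' @return character vector `c("NS", "VS", "SS")`.
#' @export
class_labels <- function() c("NS", "VS", "SS")

#' Collapse three-class labels to the binary normal/abnormal view
#' @param labels character vector of `"NS"`/`"VS"`/`"SS"` labels.
#' @return character vector of `"normal"` / `"abnormal"`.
#' @export
binary_view <- function(labels) {
  labels <- validate_labels(labels)
  ifelse(labels == "NS", "normal", "abnormal")
}

validate_labels <- function(labels) {
  labels <- as.character(labels)
  bad <- !(labels %in% class_labels())
  if (any(bad))
    stop("unknown class label(s): ", paste(unique(labels[bad]), collapse = ", "),
         " (labels are case-sensitive; valid: NS, VS, SS)")
  labels
}

# Run code with a local, restored RNG state so generators are deterministic
# under an explicit seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

rms <- function(x) sqrt(mean(x^2))

# Smooth composite length for fast mixed-radix FFTs (R's fft degrades badly
# on lengths with large prime factors).
fft_length <- function(n) stats::nextn(n, c(2, 3, 5))

# Gaussian noise band-limited to [lo, hi] Hz by FFT masking, unit RMS.
# Synthesised at a padded fast length and truncated to n.
band_noise <- function(n, sample_rate, lo, hi) {
  stopifnot(n >= 2, lo < hi, hi <= sample_rate / 2)
  nf <- fft_length(n)
  x <- rnorm(nf)
  X <- fft(x)
  f <- (seq_len(nf) - 1) / nf * sample_rate
  f <- pmin(f, sample_rate - f)            # fold to [0, fs/2]
  X[f < lo | f > hi] <- 0
  y <- Re(fft(X, inverse = TRUE))[seq_len(n)] / nf
  r <- rms(y)
  if (r == 0) stop("band [", lo, ", ", hi, "] Hz contains no FFT bins")
  y / r
}

as_audio <- function(x, sample_rate = NULL) {
  if (inherits(x, "breath_cycle")) return(x$signal)
  if (inherits(x, "audio_signal")) return(x)
  if (is.numeric(x)) {
    if (is.null(sample_rate))
      stop("`sample_rate` required when passing a bare numeric vector")
    return(audio_signal(x, sample_rate))
  }
  stop("expected an audio_signal, breath_cycle, or numeric vector")
}
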