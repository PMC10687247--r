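#' Parameters of the synthetic breath-sound generator
#'
#' The defaults encode the cohort acoustics the generator emulates: per-class
#' respiratory-cycle durations (mean/SD seconds: NS 3.801/1.592, VS 3.033/0.949,
#' SS 3.876/1.246), a breathing rate of ~10.5 breaths/min, NS energy
#' concentrated in 1500–2000 Hz, abnormal (VS/SS) energy spanning
#' 500–12,000 Hz, VS amplitude modulation at ~100 events/s, SS spectral lines
#' above 2000 Hz, background noise below 1000 Hz and event noise (speech etc.)
#' below 1500 Hz.
#'
#' @param sample_rate sampling rate in Hz. Default 44100 (content reaches
#'   12 kHz, so Nyquist must exceed that; 44.1 kHz is the standard dialect).
#' @param cycle_mean,cycle_sd named numeric vectors (`NS`,`VS`,`SS`) of
#'   cycle-duration mean and SD in seconds.
#' @param min_cycle_duration truncation point of the duration distribution, s.
#' @param breaths_per_minute target overall breathing rate for assembled
#'   recordings.
#' @param vs_modulation_rate VS amplitude-modulation rate, Hz.
#' @param vs_modulation_depth VS modulation depth in `[0, 1]`.
#' @param ns_band NS energy-concentration band, Hz `c(lo, hi)`.
#' @param abnormal_band broadband excitation band of abnormal sounds, Hz.
#' @param ss_line_band band in which SS spectral lines are placed, Hz
#'   (lower edge 2000; content allowed up to 12000).
#' @param ss_n_lines integer range `c(min, max)` of SS tone count.
#' @param background_noise_band upper edge of background noise, Hz.
#' @param event_noise_band upper edge of event (speech-like) noise, Hz.
#' @param snr_db default signal-to-noise ratio in dB used when corpora are
#'   assembled with added noise.
#' @return A validated list of class `generator_params`.
#' @examples
#' p <- generator_params()
#' p$cycle_mean[["VS"]]
#' @export
generator_params <- function(sample_rate = 44100,
                             cycle_mean = c(NS = 3.801, VS = 3.033, SS = 3.876),
                             cycle_sd = c(NS = 1.592, VS = 0.949, SS = 1.246),
                             min_cycle_duration = 0.5,
                             breaths_per_minute = 10.5,
                             vs_modulation_rate = 100,
                             vs_modulation_depth = 0.9,
                             ns_band = c(1500, 2000),
                             abnormal_band = c(500, 12000),
                             ss_line_band = c(2000, 12000),
                             ss_n_lines = c(3, 6),
                             background_noise_band = 1000,
                             event_noise_band = 1500,
                             snr_db = 10) {
  p <- list(sample_rate = sample_rate, cycle_mean = cycle_mean,
            cycle_sd = cycle_sd, min_cycle_duration = min_cycle_duration,
            breaths_per_minute = breaths_per_minute,
            vs_modulation_rate = vs_modulation_rate,
            vs_modulation_depth = vs_modulation_depth,
            ns_band = ns_band, abnormal_band = abnormal_band,
            ss_line_band = ss_line_band, ss_n_lines = ss_n_lines,
            background_noise_band = background_noise_band,
            event_noise_band = event_noise_band, snr_db = snr_db)
  validate_generator_params(p)
}

validate_generator_params <- function(p) {
  nyq <- p$sample_rate / 2
  pos <- c(p$sample_rate, p$cycle_mean, p$cycle_sd, p$min_cycle_duration,
           p$breaths_per_minute, p$vs_modulation_rate,
           p$background_noise_band, p$event_noise_band)
  if (any(!is.finite(pos)) || any(pos <= 0))
    stop("generator_params: durations, rates and band edges must be strictly positive")
  if (!all(class_labels() %in% names(p$cycle_mean)) ||
      !all(class_labels() %in% names(p$cycle_sd)))
    stop("cycle_mean/cycle_sd must be named with NS, VS, SS")
  for (b in list(p$ns_band, p$abnormal_band, p$ss_line_band)) {
    if (length(b) != 2L || b[1] <= 0 || b[1] >= b[2])
      stop("generator_params: each band must satisfy 0 < lo < hi")
    if (b[2] >= nyq)
      stop("generator_params: band upper edge ", b[2],
           " Hz must be below Nyquist (", nyq, " Hz)")
  }
  if (p$background_noise_band >= nyq || p$event_noise_band >= nyq)
    stop("generator_params: noise band edge must be below Nyquist")
  if (p$vs_modulation_depth < 0 || p$vs_modulation_depth > 1)
    stop("generator_params: vs_modulation_depth must be in [0, 1]")
  structure(p, class = "generator_params")
}

# Rise–plateau–fall breath envelope: raised-cosine ramps over the first and
# last `frac` of the cycle, flat plateau in between.
breath_envelope <- function(n, frac = 0.2) {
  nr <- max(1L, round(n * frac))
  env <- rep(1, n)
  ramp <- 0.5 - 0.5 * cos(pi * seq_len(nr) / nr)
  env[seq_len(nr)] <- ramp
  env[n + 1L - seq_len(nr)] <- ramp
  env
}

#' Sample respiratory-cycle durations for a class
#'
#' Durations follow a normal distribution truncated below at
#' `params$min_cycle_duration` (rejection sampling). The location parameter is
#' adjusted so the *truncated* distribution's mean equals the configured
#' per-class mean — truncation otherwise biases the realised mean upward
#' (about +0.08 s for the NS parameters).
#'
#' @param label class label (`"NS"`, `"VS"`, `"SS"`).
#' @param n number of draws.
#' @param params [generator_params()].
#' @param seed optional integer seed.
#' @return numeric vector of durations in seconds.
#' @export
sample_cycle_durations <- function(label, n, params = generator_params(),
                                   seed = NULL) {
  label <- validate_labels(label)
  with_seed(seed, {
    m <- trunc_location(params$cycle_mean[[label]],
                        params$cycle_sd[[label]],
                        params$min_cycle_duration)
    s <- params$cycle_sd[[label]]
    out <- numeric(0)
    while (length(out) < n) {
      d <- rnorm(2L * (n - length(out)) + 8L, m, s)
      out <- c(out, d[d >= params$min_cycle_duration])
    }
    out[seq_len(n)]
  })
}

# location mu such that a normal(mu, s) truncated below at t has mean m
trunc_location <- function(m, s, t) {
  trunc_mean <- function(mu) {
    a <- (t - mu) / s
    mu + s * stats::dnorm(a) / stats::pnorm(a, lower.tail = FALSE)
  }
  stats::uniroot(function(mu) trunc_mean(mu) - m,
                 lower = m - 4 * s, upper = m, extendInt = "upX",
                 tol = 1e-10)$root
}

#' Generate one synthetic breath cycle
#'
#' Synthesises the class-specific acoustic structure:
#' \describe{
#'   \item{NS}{band-limited noise concentrated in `ns_band` (1500–2000 Hz) over
#'     a weak low-frequency floor — low energy, nothing above ~4 kHz.}
#'   \item{VS}{broadband 500–12,000 Hz noise, amplitude-modulated at
#'     `vs_modulation_rate` (~100 Hz, depth 0.9) — the "vertical lines"
#'     spectrogram signature of a movable obstacle.}
#'   \item{SS}{3–6 stationary, harmonically unrelated tones above 2000 Hz over
#'     a broadband floor — the "horizontal lines" signature of a fixed
#'     obstacle.}
#' }
#' Every cycle is shaped by a rise–plateau–fall (20/60/20) breath envelope.
#'
#' @param label `"NS"`, `"VS"` or `"SS"`. With `mixed = TRUE` the VS and SS
#'   signatures are superimposed; such cycles carry label `"VS"` (the clinical
#'   tie-break: mixed patterns are treated as suctionable).
#' @param duration cycle duration in seconds (> 0).
#' @param params [generator_params()].
#' @param seed optional integer seed (identical seed + params give
#'   bit-identical output).
#' @param mixed generate a combined VS+SS cycle (label must be `"VS"`).
#' @return A [breath_cycle()] with `true_label` set and bounds `[0, duration)`.
#' @examples
#' cyc <- generate_breath_cycle("VS", 3.0, seed = 1)
#' duration(cyc)
#' @export
generate_breath_cycle <- function(label, duration, params = generator_params(),
                                  seed = NULL, mixed = FALSE) {
  label <- validate_labels(label)
  params <- validate_generator_params(params)
  if (!is.numeric(duration) || length(duration) != 1L || !is.finite(duration) ||
      duration <= 0)
    stop("`duration` must be a single positive number of seconds")
  if (mixed && label != "VS")
    stop("mixed VS+SS cycles are labelled VS by the tie-break rule")
  fs <- params$sample_rate
  n <- round(duration * fs)
  if (n < 32L) stop("duration too short at this sample rate")
  x <- with_seed(seed, {
    core <- switch(label,
      NS = ns_core(n, params),
      VS = vs_core(n, params, with_ss = mixed),
      SS = ss_core(n, params))
    core
  })
  x <- x * breath_envelope(n)
  x <- 0.3 * x / max(abs(x))
  breath_cycle(audio_signal(x, fs), start = 0, end = n / fs, true_label = label)
}

ns_core <- function(n, p) {
  fs <- p$sample_rate
  main <- band_noise(n, fs, p$ns_band[1], p$ns_band[2])
  floor_lo <- band_noise(n, fs, 40, p$ns_band[1])
  tail_hi <- band_noise(n, fs, p$ns_band[2], min(2 * p$ns_band[2], fs / 2 - 1))
  main + 0.4 * floor_lo + 0.18 * tail_hi
}

vs_core <- function(n, p, with_ss = FALSE) {
  fs <- p$sample_rate
  wide <- band_noise(n, fs, p$abnormal_band[1], p$abnormal_band[2])
  t <- (seq_len(n) - 1) / fs
  d <- p$vs_modulation_depth
  mod <- (1 - d) + d * (0.5 - 0.5 * cos(2 * pi * p$vs_modulation_rate * t))
  x <- wide * mod + 0.15 * band_noise(n, fs, 40, p$abnormal_band[1])
  if (with_ss) x <- x + 0.8 * ss_tones(n, p)
  x
}

ss_tones <- function(n, p) {
  fs <- p$sample_rate
  k <- sample(seq(p$ss_n_lines[1], p$ss_n_lines[2]), 1L)
  lo <- p$ss_line_band[1] + 500
  hi <- min(p$ss_line_band[2] - 2000, 9500)
  freqs <- numeric(0)
  while (length(freqs) < k) {
    f <- runif(1, lo, hi)
    if (all(abs(freqs - f) > 300)) freqs <- c(freqs, f)
  }
  amps <- runif(k, 0.5, 1)
  phas <- runif(k, 0, 2 * pi)
  t <- (seq_len(n) - 1) / fs
  x <- rep(0, n)
  for (i in seq_len(k)) x <- x + amps[i] * sin(2 * pi * freqs[i] * t + phas[i])
  x / rms(x)
}

ss_core <- function(n, p) {
  fs <- p$sample_rate
  tones <- ss_tones(n, p)
  floor_bb <- band_noise(n, fs, p$abnormal_band[1], p$abnormal_band[2])
  tones + 0.3 * floor_bb
}

#' Add band-limited noise at a target SNR
#'
#' Background noise (no specific event) lives below 1000 Hz; event noise such
#' as speech is most prominent below 1500 Hz. The noise component is scaled so
#' the realised SNR over the full signal equals `snr_db`.
#'
#' @param signal an `audio_signal` (or `breath_cycle`, whose samples are used).
#' @param kind `"background"` (< 1000 Hz) or `"event"` (< 1500 Hz).
#' @param snr_db target signal-to-noise ratio in dB; `Inf` returns the input
#'   unchanged.
#' @param seed optional integer seed.
#' @param params [generator_params()] supplying the band edges.
#' @return An `audio_signal` of the same length.
#' @export
add_noise <- function(signal, kind = c("background", "event"), snr_db,
                      seed = NULL, params = generator_params()) {
  kind <- match.arg(kind)
  sig <- as_audio(signal)
  if (length(sig$samples) == 0L) stop("cannot add noise to an empty signal")
  if (is.infinite(snr_db) && snr_db > 0) return(sig)
  hi <- if (kind == "background") params$background_noise_band else
    params$event_noise_band
  noise <- with_seed(seed, band_noise(length(sig$samples), sig$sample_rate,
                                      20, hi))
  ps <- mean(sig$samples^2)
  noise <- noise * sqrt(ps / 10^(snr_db / 10))
  audio_signal(sig$samples + noise, sig$sample_rate)
}

#' Assemble a labelled synthetic recording
#'
#' Concatenates per-class cycles with background-noise gaps sized so the
#' overall breathing rate matches `params$breaths_per_minute` (~10–11
#' breaths/min post-tracheostomy), then overlays background noise at
#' `params$snr_db`. Cycle order is randomised.
#'
#' @param n_cycles named integer vector, e.g. `c(NS = 5, VS = 3, SS = 2)`.
#' @param params [generator_params()].
#' @param seed optional integer seed; identical seed + params give
#'   bit-identical output.
#' @return A list of class `labeled_recording`: `signal` (`audio_signal`),
#'   `labels` (data.frame `cycle_id,start_s,end_s,label`), `params`.
#' @examples
#' rec <- generate_recording(c(NS = 2, VS = 1, SS = 1), seed = 1)
#' rec$labels
#' @export
generate_recording <- function(n_cycles, params = generator_params(),
                               seed = NULL) {
  params <- validate_generator_params(params)
  n_cycles <- n_cycles[n_cycles > 0]
  labs <- validate_labels(names(n_cycles))
  total <- sum(n_cycles)
  if (is.na(total) || total < 1) stop("at least one cycle is required")
  fs <- params$sample_rate
  with_seed(seed, {
    order_labels <- sample(rep(labs, times = n_cycles))
    durs <- vapply(order_labels, function(l)
      sample_cycle_durations(l, 1L, params), numeric(1))
    target_total <- total * 60 / params$breaths_per_minute
    gap <- max(0.1, (target_total - sum(durs)) / (total + 1))
    gap_n <- round(gap * fs)
    pieces <- vector("list", 2L * total + 1L)
    pieces[[1L]] <- rep(0, gap_n)
    starts <- ends <- numeric(total)
    pos <- gap_n
    for (i in seq_len(total)) {
      cyc <- generate_breath_cycle(order_labels[i], durs[i], params)
      ns <- length(cyc$signal$samples)
      starts[i] <- pos / fs
      ends[i] <- (pos + ns) / fs
      pieces[[2L * i]] <- cyc$signal$samples
      pieces[[2L * i + 1L]] <- rep(0, gap_n)
      pos <- pos + ns + gap_n
    }
    x <- audio_signal(unlist(pieces), fs)
    x <- add_noise(x, "background", params$snr_db, params = params)
    structure(list(signal = x,
                   labels = data.frame(cycle_id = seq_len(total),
                                       start_s = starts, end_s = ends,
                                       label = order_labels,
                                       stringsAsFactors = FALSE),
                   params = params),
              class = "labeled_recording")
  })
}

#' Generate a labelled set of independent noisy cycles
#'
#' Convenience benchmark corpus: `n_per_class` cycles per class, each with its
#' own duration draw and background noise at `snr_db`. This is the default
#' corpus used for classifier benchmarking.
#'
#' @param n_per_class named integer vector (default 100 per class).
#' @param params [generator_params()].
#' @param snr_db SNR of the added background noise (default `params$snr_db`).
#' @param seed integer seed.
#' @return list of [breath_cycle()] objects with `true_label` set.
#' @export
generate_cycle_set <- function(n_per_class = c(NS = 100, VS = 100, SS = 100),
                               params = generator_params(),
                               snr_db = params$snr_db, seed = NULL) {
  labs <- validate_labels(names(n_per_class))
  with_seed(seed, {
    out <- list()
    for (l in labs) {
      for (i in seq_len(n_per_class[[l]])) {
        d <- sample_cycle_durations(l, 1L, params)
        cyc <- generate_breath_cycle(l, d, params)
        noisy <- add_noise(cyc$signal, "background", snr_db, params = params)
        out[[length(out) + 1L]] <- breath_cycle(noisy, true_label = l)
      }
    }
    out
  })
}
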