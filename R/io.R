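#' Read a PCM WAV file
#'
#' Reads 16-bit (also 8/24/32-bit integer and 32/64-bit float) PCM WAV.
#' Multi-channel input is downmixed to mono by averaging, with a warning.
#' Samples are returned in \[-1, 1\].
#'
#' @param path path to a WAV file.
#' @return An [audio_signal()].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF"))
    stop("not a RIFF/WAV file (bad magic at byte 0): ", path)
  readBin(con, "integer", 1, 4, endian = "little")   # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file (byte 8): ", path)
  fmt <- NULL; data_raw <- NULL; offset <- 12
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (length(sz) == 0L)
      stop("truncated WAV file at byte offset ", offset + 4, ": ", path)
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", sz)
      if (length(fmt_raw) < 16)
        stop("truncated fmt chunk at byte offset ", offset + 8, ": ", path)
      fmt <- list(
        audio_format = readBin(fmt_raw[1:2], "integer", 1, 2, endian = "little"),
        channels = readBin(fmt_raw[3:4], "integer", 1, 2, endian = "little"),
        sample_rate = readBin(fmt_raw[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(fmt_raw[15:16], "integer", 1, 2, endian = "little"))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      if (length(data_raw) < sz)
        stop("truncated data chunk: expected ", sz, " bytes at byte offset ",
             offset + 8, ", got ", length(data_raw), ": ", path)
    } else {
      seek(con, sz + sz %% 2, origin = "current")
    }
    offset <- offset + 8 + sz + sz %% 2
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop("WAV file missing fmt/data chunk: ", path)
  if (!fmt$audio_format %in% c(1L, 3L))
    stop("unsupported WAV encoding (format tag ", fmt$audio_format,
         "); only PCM (1) and IEEE float (3) are supported: ", path)
  x <- decode_pcm(data_raw, fmt$audio_format, fmt$bits)
  if (fmt$channels > 1L) {
    warning("downmixing ", fmt$channels, "-channel WAV to mono")
    n <- length(x) %/% fmt$channels
    x <- rowMeans(matrix(x[seq_len(n * fmt$channels)], ncol = fmt$channels,
                         byrow = TRUE))
  }
  audio_signal(x, fmt$sample_rate)
}

decode_pcm <- function(raw, format_tag, bits) {
  if (format_tag == 3L) {
    return(readBin(raw, "double", length(raw) %/% (bits / 8), bits / 8,
                   endian = "little"))
  }
  switch(as.character(bits),
    "16" = readBin(raw, "integer", length(raw) %/% 2, 2, signed = TRUE,
                   endian = "little") / 32768,
    "8"  = (as.integer(raw) - 128) / 128,
    "24" = {
      n <- length(raw) %/% 3
      m <- matrix(as.integer(raw[seq_len(3 * n)]), nrow = 3)
      v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
      v <- ifelse(v >= 2^23, v - 2^24, v)
      v / 2^23
    },
    "32" = readBin(raw, "integer", length(raw) %/% 4, 4, endian = "little") / 2^31,
    stop("unsupported PCM bit depth: ", bits))
}

#' Write a mono 16-bit PCM WAV file
#'
#' The package's canonical dialect: mono, 16-bit linear PCM. Samples are
#' clipped to \[-1, 1\] and quantised.
#'
#' @param signal an [audio_signal()] (or `breath_cycle`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path) {
  sig <- as_audio(signal)
  x <- pmax(-1, pmin(1, sig$samples))
  pcm <- as.integer(round(x * 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16), con, 4, endian = "little")
  writeBin(as.integer(1), con, 2, endian = "little")   # PCM
  writeBin(as.integer(1), con, 2, endian = "little")   # mono
  fs <- as.integer(round(sig$sample_rate))
  writeBin(fs, con, 4, endian = "little")
  writeBin(as.integer(fs * 2), con, 4, endian = "little")  # byte rate
  writeBin(as.integer(2), con, 2, endian = "little")   # block align
  writeBin(as.integer(16), con, 2, endian = "little")  # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}

#' Read / write a cycle label table
#'
#' CSV dialect `cycle_id,start_s,end_s,label` (header required, UTF-8; label
#' column optional for unlabelled cycle tables). Labels are validated against
#' `NS|VS|SS`, case-sensitively. Times are seconds; intervals are half-open
#' `[start_s, end_s)` and written with 3-decimal precision.
#'
#' @param path CSV path.
#' @return `read_labels`: a data.frame with columns `cycle_id`, `start_s`,
#'   `end_s` and (if present) `label`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("cycle_id", "start_s", "end_s")
  if (!all(need %in% names(df)))
    stop("label table must have header columns ", paste(need, collapse = ","))
  if ("label" %in% names(df)) {
    bad <- which(!(df$label %in% class_labels()))
    if (length(bad))
      stop("unknown label string(s) in rows ", paste(bad, collapse = ", "),
           ": ", paste(unique(df$label[bad]), collapse = ", "),
           " (case-sensitive; valid: NS, VS, SS)")
  }
  df
}

#' @rdname read_labels
#' @param labels data.frame with columns `cycle_id,start_s,end_s[,label]`.
#' @export
write_labels <- function(labels, path) {
  stopifnot(all(c("cycle_id", "start_s", "end_s") %in% names(labels)))
  if ("label" %in% names(labels)) validate_labels(labels$label)
  out <- labels
  out$start_s <- sprintf("%.3f", labels$start_s)
  out$end_s <- sprintf("%.3f", labels$end_s)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' Nested named list with one section per stage (`generator`, `preprocess`,
#' `features`, `rules`, `ml`, `eval`), every tunable default of the pipeline.
#' Round-trips through the flat `section.key = value` config-file format of
#' [read_config()] / [write_config()].
#'
#' @return nested named list.
#' @export
default_config <- function() {
  gp <- generator_params()
  sc <- segmentation_config()
  rt <- rule_thresholds()
  list(
    generator = list(
      sample_rate = gp$sample_rate,
      cycle_mean_ns = gp$cycle_mean[["NS"]], cycle_sd_ns = gp$cycle_sd[["NS"]],
      cycle_mean_vs = gp$cycle_mean[["VS"]], cycle_sd_vs = gp$cycle_sd[["VS"]],
      cycle_mean_ss = gp$cycle_mean[["SS"]], cycle_sd_ss = gp$cycle_sd[["SS"]],
      breaths_per_minute = gp$breaths_per_minute,
      vs_modulation_rate = gp$vs_modulation_rate,
      vs_modulation_depth = gp$vs_modulation_depth,
      ns_band_lo = gp$ns_band[1], ns_band_hi = gp$ns_band[2],
      abnormal_band_lo = gp$abnormal_band[1],
      abnormal_band_hi = gp$abnormal_band[2],
      ss_line_band_lo = gp$ss_line_band[1],
      ss_line_band_hi = gp$ss_line_band[2],
      background_noise_band = gp$background_noise_band,
      event_noise_band = gp$event_noise_band,
      snr_db = gp$snr_db),
    preprocess = list(
      highpass_cutoff = sc$highpass_cutoff,
      energy_band_lo = sc$energy_band[1], energy_band_hi = sc$energy_band[2],
      frame = sc$frame, on_threshold = sc$on_threshold,
      off_threshold = sc$off_threshold, min_cycle = sc$min_cycle,
      min_gap = sc$min_gap),
    features = list(window_s = 0.025, hop_s = 0.010, n_mels = 48,
                    mel_fmin = 0, mel_fmax = 12000, image_size = 128,
                    db_floor = -80),
    rules = list(
      vs_modulation_lo = rt$vs_modulation_band[1],
      vs_modulation_hi = rt$vs_modulation_band[2],
      vs_prominence_min = rt$vs_prominence_min,
      ss_highband_fraction_min = rt$ss_highband_fraction_min,
      ss_persistence_min = rt$ss_persistence_min,
      ns_band_fraction_min = rt$ns_band_fraction_min),
    ml = list(model = "svm", svm_kernel = "rbf", knn_k = 5,
              feature_variant = "mfcc20", task = "three_class",
              cnn_batch_size = 32, cnn_max_steps = 2000, cnn_image_size = 128),
    eval = list(train_fraction = 0.8, stratified = TRUE, seed = 0))
}

#' Read / write a flat key-value pipeline config file
#'
#' Format: one `section.key = value` per line; `#` comments and blank lines
#' ignored. Unknown keys (not present in [default_config()]) are rejected, and
#' a loaded config re-serialises identically.
#'
#' @param path config file path.
#' @return `read_config`: nested named list like [default_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  cfg <- default_config()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2L || is.null(cfg[[parts[1]]]) ||
        !parts[2] %in% names(cfg[[parts[1]]]))
      stop("unknown config key: ", key)
    old <- cfg[[parts[1]]][[parts[2]]]
    cfg[[parts[1]]][[parts[2]]] <-
      if (is.numeric(old)) as.numeric(val)
      else if (is.logical(old)) as.logical(val)
      else val
  }
  cfg
}

#' @rdname read_config
#' @param config nested named list (sections of scalars).
#' @export
write_config <- function(config, path) {
  lines <- character(0)
  for (sec in names(config))
    for (key in names(config[[sec]]))
      lines <- c(lines, sprintf("%s.%s = %s", sec, key,
                                format(config[[sec]][[key]], digits = 15)))
  writeLines(lines, path)
  invisible(path)
}
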