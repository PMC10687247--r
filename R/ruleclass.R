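#' Thresholds of the rule-based classifier
#'
#' Quantitative operationalisation of the spectrogram signatures (the source
#' descriptions are visual; these defaults were tuned once on the default
#' synthetic corpus and are all config-exposed):
#' a VS pattern is an envelope modulation peak inside `vs_modulation_band`
#' (50–150 Hz, around the ~100/s burst rate) with prominence at least
#' `vs_prominence_min`; an SS pattern needs at least
#' `ss_highband_fraction_min` of the energy above 2000 Hz **and** line
#' persistence at least `ss_persistence_min`; NS is the default class, whose
#' signature is energy concentration in 1500–2000 Hz
#' (`ns_band_fraction_min`).
#'
#' @param vs_modulation_band Hz interval for the VS modulation peak.
#' @param vs_prominence_min minimum modulation prominence.
#' @param ss_highband_fraction_min minimum fraction of energy above 2000 Hz.
#' @param ss_persistence_min minimum line persistence.
#' @param ns_band_fraction_min NS-band energy concentration (descriptive;
#'   NS is assigned by default when neither pattern fires).
#' @return list of class `rule_thresholds`.
#' @export
rule_thresholds <- function(vs_modulation_band = c(50, 150),
                            vs_prominence_min = 100,
                            ss_highband_fraction_min = 0.4,
                            ss_persistence_min = 0.6,
                            ns_band_fraction_min = 0.5) {
  stopifnot(vs_modulation_band[1] > 0,
            vs_modulation_band[1] < vs_modulation_band[2],
            vs_prominence_min > 0,
            ss_highband_fraction_min >= 0, ss_highband_fraction_min <= 1,
            ss_persistence_min >= 0, ss_persistence_min <= 1,
            ns_band_fraction_min >= 0, ns_band_fraction_min <= 1)
  structure(list(vs_modulation_band = vs_modulation_band,
                 vs_prominence_min = vs_prominence_min,
                 ss_highband_fraction_min = ss_highband_fraction_min,
                 ss_persistence_min = ss_persistence_min,
                 ns_band_fraction_min = ns_band_fraction_min),
            class = "rule_thresholds")
}

check_descriptors <- function(desc) {
  need <- c("frac_above_2000", "modulation_present", "modulation_peak",
            "modulation_prominence", "line_persistence")
  miss <- setdiff(need, names(desc))
  if (length(miss))
    stop("incomplete acoustic descriptors; missing: ",
         paste(miss, collapse = ", "))
  invisible(desc)
}

#' Detect the VS ("vertical lines") pattern
#'
#' True iff a modulation peak is present, lies inside the VS modulation band,
#' and its prominence reaches the threshold. The score is the prominence.
#'
#' @param desc [acoustic_descriptors()] of a cycle.
#' @param thr [rule_thresholds()].
#' @return list `flag` (logical), `score`.
#' @export
detect_vs_pattern <- function(desc, thr = rule_thresholds()) {
  check_descriptors(desc)
  flag <- isTRUE(desc$modulation_present) &&
    !is.na(desc$modulation_peak) &&
    desc$modulation_peak >= thr$vs_modulation_band[1] &&
    desc$modulation_peak <= thr$vs_modulation_band[2] &&
    desc$modulation_prominence >= thr$vs_prominence_min
  list(flag = flag, score = desc$modulation_prominence)
}

#' Detect the SS ("horizontal lines") pattern
#'
#' True iff the fraction of energy above 2000 Hz and the stable-line
#' persistence both reach their thresholds. The score is the smaller of the
#' two threshold ratios (1 means exactly at threshold).
#'
#' @inheritParams detect_vs_pattern
#' @return list `flag` (logical), `score`.
#' @export
detect_ss_pattern <- function(desc, thr = rule_thresholds()) {
  check_descriptors(desc)
  r1 <- desc$frac_above_2000 / thr$ss_highband_fraction_min
  r2 <- desc$line_persistence / max(thr$ss_persistence_min, 1e-12)
  list(flag = desc$frac_above_2000 >= thr$ss_highband_fraction_min &&
         desc$line_persistence >= thr$ss_persistence_min,
       score = min(r1, r2))
}

#' Classify one cycle with the deterministic rule set
#'
#' Precedence encodes the clinical tie-break: a cycle showing the VS pattern
#' is VS even when the SS pattern is also present (a mixed movable + fixed
#' obstacle is treated as suctionable first); otherwise SS if the SS pattern
#' fires; otherwise NS.
#'
#' @param desc [acoustic_descriptors()] of a cycle, or a [breath_cycle()]
#'   (descriptors are computed on the fly).
#' @param thr [rule_thresholds()].
#' @return list: `label`, `trace` (data.frame with both pattern flags/scores
#'   and the fired rule).
#' @export
classify_cycle <- function(desc, thr = rule_thresholds()) {
  if (inherits(desc, "breath_cycle")) desc <- acoustic_descriptors(desc)
  vs <- detect_vs_pattern(desc, thr)
  ss <- detect_ss_pattern(desc, thr)
  label <- if (vs$flag) "VS" else if (ss$flag) "SS" else "NS"
  rule <- if (vs$flag) "vs_pattern" else if (ss$flag) "ss_pattern"
          else "default_ns"
  list(label = label,
       trace = data.frame(vs_flag = vs$flag, vs_score = vs$score,
                          ss_flag = ss$flag, ss_score = ss$score,
                          rule_fired = rule, stringsAsFactors = FALSE))
}

#' Rule-classify a list of cycles
#'
#' @param cycles list of [breath_cycle()] objects.
#' @param thr [rule_thresholds()].
#' @return data.frame `cycle_id,label,vs_score,ss_score,rule_fired` (plus
#'   `true_label` when the cycles carry ground truth).
#' @export
classify_cycles <- function(cycles, thr = rule_thresholds()) {
  rows <- lapply(seq_along(cycles), function(i) {
    r <- classify_cycle(cycles[[i]], thr)
    data.frame(cycle_id = i, label = r$label,
               vs_score = r$trace$vs_score, ss_score = r$trace$ss_score,
               rule_fired = r$trace$rule_fired,
               true_label = cycles[[i]]$true_label,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (all(is.na(out$true_label))) out$true_label <- NULL
  out
}
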