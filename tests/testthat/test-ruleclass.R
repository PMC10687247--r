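mk_desc <- function(frac_above_2000 = 0.05, ns_band_fraction = 0.8,
                    modulation_present = FALSE, modulation_peak = NA_real_,
                    modulation_prominence = 0, line_persistence = 0,
                    frac_below_1500 = 0.2) {
  structure(list(frac_below_1500 = frac_below_1500,
                 frac_above_2000 = frac_above_2000,
                 ns_band_fraction = ns_band_fraction,
                 modulation_present = modulation_present,
                 modulation_peak = modulation_peak,
                 modulation_prominence = modulation_prominence,
                 line_persistence = line_persistence),
            class = "acoustic_descriptors")
}

test_that("VS detector keys on an in-band prominent modulation peak", {
  vs <- mk_desc(modulation_present = TRUE, modulation_peak = 100,
                modulation_prominence = 500)
  expect_true(detect_vs_pattern(vs)$flag)
  expect_false(detect_vs_pattern(mk_desc())$flag)
  # out-of-band peak or weak prominence do not fire
  expect_false(detect_vs_pattern(mk_desc(modulation_present = TRUE,
                                         modulation_peak = 250,
                                         modulation_prominence = 500))$flag)
  expect_false(detect_vs_pattern(mk_desc(modulation_present = TRUE,
                                         modulation_peak = 100,
                                         modulation_prominence = 2))$flag)
  expect_error(detect_vs_pattern(structure(list(), class = "acoustic_descriptors")),
               "incomplete")
})

test_that("SS detector requires both high-band energy and persistent lines", {
  ss <- mk_desc(frac_above_2000 = 0.7, line_persistence = 0.9)
  expect_true(detect_ss_pattern(ss)$flag)
  expect_false(detect_ss_pattern(mk_desc(frac_above_2000 = 0.7))$flag)
  expect_false(detect_ss_pattern(mk_desc(line_persistence = 0.9))$flag)
  expect_false(detect_ss_pattern(mk_desc())$flag)
})

test_that("classification precedence implements the VS-over-SS tie-break", {
  both <- mk_desc(frac_above_2000 = 0.8, line_persistence = 0.9,
                  modulation_present = TRUE, modulation_peak = 100,
                  modulation_prominence = 500)
  r <- classify_cycle(both)
  expect_identical(r$label, "VS")
  expect_identical(r$trace$rule_fired, "vs_pattern")
  expect_true(r$trace$ss_flag)
  neither <- classify_cycle(mk_desc())
  expect_identical(neither$label, "NS")
  expect_identical(neither$trace$rule_fired, "default_ns")
  # determinism: identical descriptors give identical labels
  expect_identical(classify_cycle(both)$label, classify_cycle(both)$label)
})

test_that("tie-break dominance holds over a grid of SS scores", {
  for (frac in c(0.4, 0.6, 0.9)) for (pers in c(0.6, 0.8, 1)) {
    d <- mk_desc(frac_above_2000 = frac, line_persistence = pers,
                 modulation_present = TRUE, modulation_peak = 100,
                 modulation_prominence = 500)
    expect_identical(classify_cycle(d)$label, "VS")
  }
})

test_that("raising the SS energy threshold never converts NS to SS", {
  descs <- list(mk_desc(frac_above_2000 = 0.3, line_persistence = 0.7),
                mk_desc(frac_above_2000 = 0.5, line_persistence = 0.7),
                mk_desc(frac_above_2000 = 0.9, line_persistence = 0.9))
  thrs <- c(0.3, 0.4, 0.6, 0.8, 0.95)
  prev <- NULL
  for (th in thrs) {
    labels <- vapply(descs, function(d)
      classify_cycle(d, rule_thresholds(ss_highband_fraction_min = th))$label,
      character(1))
    if (!is.null(prev))
      expect_true(all(!(prev == "NS" & labels == "SS")))
    prev <- labels
  }
})

test_that("rule classification of a small labelled corpus is accurate", {
  corpus <- default_corpus(10)   # 10/class scaled-down module check
  res <- classify_cycles(corpus)
  expect_identical(nrow(res), 30L)
  expect_true(all(c("cycle_id", "label", "vs_score", "ss_score",
                    "rule_fired", "true_label") %in% names(res)))
  expect_gte(mean(res$label == res$true_label), 0.9)
})
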