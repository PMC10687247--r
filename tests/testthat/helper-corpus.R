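# Shared synthetic corpora, memoised so expensive fixtures are built once per
# test run. The default benchmark corpus is 100 cycles per class at SNR 10 dB
# with a fixed seed; its descriptors and pooled MFCC(20) features are cached
# alongside.

.ts_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .ts_cache)) assign(key, force(expr), .ts_cache)
  get(key, .ts_cache)
}

CORPUS_SEED <- 20260912

default_corpus <- function(n_per_class = 100) {
  memo(paste0("corpus_", n_per_class),
       generate_cycle_set(c(NS = n_per_class, VS = n_per_class,
                            SS = n_per_class),
                          snr_db = 10, seed = CORPUS_SEED))
}

corpus_labels <- function(corpus)
  vapply(corpus, function(c) c$true_label, character(1))

corpus_descriptors <- function(n_per_class = 100) {
  memo(paste0("desc_", n_per_class),
       lapply(default_corpus(n_per_class), acoustic_descriptors))
}

corpus_mfcc20 <- function(n_per_class = 100) {
  memo(paste0("mfcc20_", n_per_class), {
    cfg <- ml_config(model = "svm", feature_variant = "mfcc20")
    cycle_features(default_corpus(n_per_class), cfg)
  })
}
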