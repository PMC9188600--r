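# Shared fixtures, built in code. Synthesis is the expensive step, so a few
# standard vowels are cached per test run.

.synth_cache <- new.env(parent = emptyenv())

cached_vowel <- function(...) {
  key <- paste(deparse(list(...)), collapse = "")
  if (is.null(.synth_cache[[key]])) {
    .synth_cache[[key]] <- synthesize_vowel(synth_spec(...))
  }
  .synth_cache[[key]]
}

# a clean, nearly unperturbed reference vowel used by several tests
clean_vowel <- function() {
  cached_vowel(duration = 0.8, f0 = 100, jitter_rel_target = 0,
               shimmer_rel_target = 0, noise_db = -60,
               tract_length_cm = 16.75, intensity_drift_db = 0, seed = 1)
}

sine_segment <- function(freq, fs = 44100, dur = 1, amp = 1) {
  audio_segment(amp * sin(2 * pi * freq * seq(0, dur - 1 / fs, by = 1 / fs)),
                fs)
}

rms <- function(x) sqrt(mean(x^2))

# build a pulse train directly from periods (seconds) and amplitudes
pt_from <- function(periods, amplitudes = rep(1, length(periods))) {
  pulse_train(c(0, cumsum(periods)), amplitudes)
}

# two-cluster Gaussian feature table for classifier tests
cluster_table <- function(n_per_class = 20, p = 4, sep = 10, sd = 1,
                          seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * p, 0, sd), n_per_class),
             matrix(rnorm(n_per_class * p, sep, sd), n_per_class))
  tab <- as.data.frame(x)
  names(tab) <- paste0("f", seq_len(p))
  tab$subject_id <- sprintf("s%02d", seq_len(2 * n_per_class))
  tab$group <- rep(c("CO", "PD"), each = n_per_class)
  tab$phoneme <- "a"
  tab$repetition <- 1L
  tab
}
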