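# Shared fixtures, built in code.

# a fixation table from a word-index sequence with given durations
fix_table <- function(word_index, duration_ms, subject = 1, trial = 1,
                      gap = 30) {
  onset <- cumsum(c(0, head(duration_ms, -1) + gap))
  tibble::tibble(subject = subject, trial = trial, word_index = word_index,
                 onset_ms = onset, duration_ms = duration_ms,
                 pass_label = NA_character_)
}

# a one-quad corpus with fixed geometry
fixed_quad <- function(len = 10, target = 6) {
  tibble::tibble(quad_id = 1L, sentence_length = as.integer(len),
                 target_index = as.integer(target),
                 words_ord = list(rep(5L, len)),
                 words_rdm = list(rep(5L, len)))
}

# deterministic scanpath config: no skips, no refixations, no regressions
det_scanpath_config <- function() {
  cfg <- frsp::default_scanpath_config()
  for (nm in names(cfg$conditions)) {
    cfg$conditions[[nm]]$refixation_prob <- 0
    cfg$conditions[[nm]]$regression_prob <- 0
  }
  cfg$skip_prob_target <- 0
  cfg$skip_prob_other <- 0
  cfg
}

# long tibble of subject x factor cells from a value matrix
# [subjects x cells], cells defined by an expand.grid of factor levels
cells_from_matrix <- function(Y, factors) {
  grid <- expand.grid(factors, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(Y)), function(i) {
    g <- grid
    g$subject <- i
    g$value <- Y[i, ]
    g
  }))
  tibble::as_tibble(out)
}

# brick-wall spectral band extraction, independent of the package's
# raised-cosine band splitter; good enough to measure band variances
band_component_for_test <- function(x, f_lo, f_hi, fs) {
  n <- length(x)
  f <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * fs / n
  X <- stats::fft(x)
  X[f < f_lo | f > f_hi] <- 0
  Re(stats::fft(X, inverse = TRUE) / n)
}

# a small synthetic frsp_result with constant dB value
constant_frsp <- function(value, channels = c("P5", "PO3"),
                          freqs = 3:20,
                          times_ms = seq(-500, 900, by = 20)) {
  db <- array(value, c(length(freqs), length(times_ms), length(channels)))
  structure(list(db = db, freqs = freqs, times_ms = times_ms,
                 mask = matrix(TRUE, length(freqs), length(times_ms)),
                 baseline_ms = c(-500, 0), scheme = "trial_mean",
                 n_trials = 1, channels = channels),
            class = "frsp_result")
}
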