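# Synthetic 64-channel, 500 Hz EEG aligned to simulated scanpaths.
#
# The background is 1/f^chi noise per channel plus a 10 Hz idle rhythm at
# posterior sites. Experimental effects are induced power changes: the
# band-limited component of the ongoing signal is multiplied by a tapered
# gain envelope around matching events (not an additive evoked transient),
# which is exactly the kind of modulation the spectral-perturbation
# measurement is designed to recover.

#' Electrode clusters used for band power aggregation
#'
#' Six clusters of five 10-10 electrodes each, three per hemisphere
#' (frontal, central, parieto-occipital).
#'
#' @return Named list of character vectors; names follow the pattern
#'   `<region>_<hemisphere>`.
#' @export
electrode_clusters <- function() {
  list(
    frontal_left = c("F1", "F3", "FC1", "FC3", "FC5"),
    frontal_right = c("F2", "F4", "FC2", "FC4", "FC6"),
    central_left = c("C1", "C3", "C5", "CP1", "CP3"),
    central_right = c("C2", "C4", "C6", "CP2", "CP4"),
    parieto_occipital_left = c("P5", "PO3", "P7", "PO7", "O1"),
    parieto_occipital_right = c("P6", "PO4", "P8", "PO8", "O2")
  )
}

#' 64-channel 10-10 montage
#'
#' The 30 cluster electrodes of [electrode_clusters()] plus 34 filler
#' labels completing a standard 64-channel cap.
#'
#' @return Character vector of 64 unique channel labels.
#' @export
montage_64 <- function() {
  fillers <- c("Fp1", "Fp2", "Fpz", "AF7", "AF3", "AFz", "AF4", "AF8",
               "F7", "F5", "Fz", "F6", "F8", "FT7", "FCz", "FT8",
               "T7", "Cz", "T8", "TP7", "CPz", "TP8",
               "P1", "P2", "P3", "P4", "Pz", "POz", "Oz", "Iz",
               "F9", "F10", "TP9", "TP10")
  c(unlist(electrode_clusters(), use.names = FALSE), fillers)
}

#' Generate continuous background EEG
#'
#' Each channel is independent `1/f^chi` noise (power spectral density
#' proportional to `f^-chi`), scaled to `sd_uv` microvolts and zero-mean.
#' Posterior channels (labels starting with P, PO or O) additionally carry
#' a 10 Hz idle rhythm with random phase.
#'
#' @param duration_s Recording length in seconds.
#' @param channels Channel labels (default full [montage_64()]).
#' @param fs Sampling rate (default 500).
#' @param noise_exponent Spectral exponent chi >= 0 (default 1; 0 gives
#'   white noise).
#' @param sd_uv Per-channel standard deviation of the noise in microvolts.
#' @param alpha_uv Amplitude of the posterior 10 Hz rhythm.
#' @return List of class `eeg_recording`: `samples` matrix
#'   `[time, channel]` in microvolts (columns named), `fs`, `channels`,
#'   and an empty `events` tibble.
#' @export
generate_background <- function(duration_s, channels = montage_64(),
                                fs = 500, noise_exponent = 1, sd_uv = 10,
                                alpha_uv = 2) {
  stopifnot(duration_s > 0)
  if (noise_exponent < 0) stop("noise_exponent must be >= 0")
  # pad to a 2-3-5-smooth length: all spectral operations on the recording
  # (synthesis, band-split filtering) stay O(n log n)
  n <- stats::nextn(as.integer(round(duration_s * fs)), c(2, 3, 5))
  freqs <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * fs / n
  amp <- c(0, freqs[-1]^(-noise_exponent / 2))
  posterior <- grepl("^(P|PO|O)", channels)

  samples <- matrix(0, n, length(channels),
                    dimnames = list(NULL, channels))
  tt <- (seq_len(n) - 1) / fs
  for (ch in seq_along(channels)) {
    w <- fft(rnorm(n)) * amp
    x <- Re(fft(w, inverse = TRUE) / n)
    x <- x / sd(x) * sd_uv
    if (posterior[ch]) {
      x <- x + alpha_uv * sin(2 * pi * 10 * tt + runif(1, 0, 2 * pi))
    }
    samples[, ch] <- x - mean(x)
  }
  structure(list(samples = samples, fs = fs, channels = channels,
                 events = tibble(sample = integer(0), class = character(0),
                                 trial = integer(0), condition = character(0),
                                 word_index = integer(0))),
            class = "eeg_recording")
}

#' Describe one event-locked band power effect
#'
#' @param band `c(f_lo, f_hi)` Hz, inclusive.
#' @param gain_db Power change in dB at the envelope plateau; a length-2
#'   vector describes a linear dB ramp across the window.
#' @param window_ms `c(t0, t1)` ms relative to the locking event.
#' @param clusters Cluster names (see [electrode_clusters()]) receiving the
#'   effect with weight 1; channels outside every cluster are untouched.
#' @param event_class Event class the effect locks to (`"target_fixation"`
#'   or `"sentence_onset"`).
#' @param conditions Conditions whose events carry the effect.
#' @param taper Fraction of the window tapered at each end (Hann ramps).
#' @return List of class `effect_template`.
#' @export
effect_template <- function(band, gain_db, window_ms, clusters,
                            event_class, conditions, taper = 0.3) {
  stopifnot(length(band) == 2, band[1] < band[2],
            length(gain_db) %in% 1:2, length(window_ms) == 2)
  structure(list(band = band, gain_db = gain_db, window_ms = window_ms,
                 clusters = clusters, event_class = event_class,
                 conditions = conditions, taper = taper),
            class = "effect_template")
}

#' Default effect templates
#'
#' The three effects the synthetic sessions emulate:
#' a lower-beta (13-18 Hz) desynchronization of -1 dB over 0-300 ms after
#' fixations on semantically unrelated targets in ordered sentences, at the
#' left parieto-occipital cluster; a theta (4-7 Hz) +1 dB elevation over
#' 300-900 ms after sentence onset for ordered sentences at both
#' parieto-occipital clusters; and a gamma (31-55 Hz) linear dB ramp from 0
#' to +1 dB over 0-1800 ms after sentence onset for ordered sentences at
#' the right parieto-occipital and right central clusters. Gains are sized
#' for reliable detection at 32 subjects; dB effect sizes for real data of
#' this kind are not established, so these are package choices.
#'
#' @return List of [effect_template()]s.
#' @export
default_effect_templates <- function() {
  list(
    lower_beta = effect_template(
      band = c(13, 18), gain_db = -1, window_ms = c(0, 300),
      clusters = "parieto_occipital_left",
      event_class = "target_fixation", conditions = "ORD_SEM"),
    theta = effect_template(
      band = c(4, 7), gain_db = 1, window_ms = c(300, 900),
      clusters = c("parieto_occipital_left", "parieto_occipital_right"),
      event_class = "sentence_onset", conditions = ORD_CONDITIONS),
    gamma_ramp = effect_template(
      band = c(31, 55), gain_db = c(0, 1), window_ms = c(0, 1800),
      clusters = c("parieto_occipital_right", "central_right"),
      event_class = "sentence_onset", conditions = ORD_CONDITIONS,
      taper = 0.1)
  )
}

# zero-phase band split via frequency-domain masking with raised-cosine
# transitions (`tw` Hz wide, centred on the band edges); returns the
# band-limited component of each column
band_component <- function(x, f_lo, f_hi, fs, tw = 2) {
  n <- nrow(x)
  f <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * fs / n
  h <- rep(0, n)
  h[f >= f_lo + tw / 2 & f <= f_hi - tw / 2] <- 1
  lo <- f > f_lo - tw / 2 & f < f_lo + tw / 2
  h[lo] <- 0.5 * (1 - cos(pi * (f[lo] - (f_lo - tw / 2)) / tw))
  hi <- f > f_hi - tw / 2 & f < f_hi + tw / 2
  h[hi] <- 0.5 * (1 + cos(pi * (f[hi] - (f_hi - tw / 2)) / tw))
  Re(mvfft(mvfft(x) * h, inverse = TRUE) / n)
}

#' Inject an event-locked band power modulation
#'
#' The band-limited component of every affected channel is multiplied by a
#' gain envelope and recombined with the band-stop remainder. The envelope
#' is 1 outside event windows; inside a window it reaches the amplitude
#' gain `10^(gain_db/20)` (power change `gain_db`) on a plateau with Hann
#' ramps over the tapered edges; a length-2 `gain_db` ramps linearly in dB
#' across the window. Overlapping windows on one channel compose
#' multiplicatively. `gain_db = 0` leaves the recording unchanged up to
#' numerical tolerance.
#'
#' @param rec An `eeg_recording`.
#' @param template An [effect_template()].
#' @param event_samples Onset sample indices of matching events.
#' @return The modified recording.
#' @export
inject_band_power <- function(rec, template, event_samples) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (template$band[1] <= 0 || template$band[2] >= rec$fs / 2) {
    stop("band must lie within (0, fs/2)")
  }
  chans <- intersect(
    unlist(electrode_clusters()[template$clusters], use.names = FALSE),
    rec$channels)
  if (!length(chans) || !length(event_samples)) return(rec)

  n <- nrow(rec$samples)
  s0 <- ms_to_samples(template$window_ms[1], rec$fs)
  s1 <- ms_to_samples(template$window_ms[2], rec$fs)
  nwin <- s1 - s0
  db <- if (length(template$gain_db) == 2) {
    seq(template$gain_db[1], template$gain_db[2], length.out = nwin)
  } else {
    rep(template$gain_db, nwin)
  }
  profile <- tukey_window(nwin, template$taper)
  g_win <- 1 + (10^(db / 20) - 1) * profile

  g <- rep(1, n)
  for (ev in event_samples) {
    idx <- (ev + s0):(ev + s1 - 1L)
    ok <- idx >= 1L & idx <= n
    if (!all(ok)) stop("injection window extends outside the recording")
    g[idx] <- g[idx] * g_win
  }
  cols <- match(chans, rec$channels)
  bp <- band_component(rec$samples[, cols, drop = FALSE],
                       template$band[1], template$band[2], rec$fs)
  rec$samples[, cols] <- rec$samples[, cols] - bp + bp * g
  rec
}

#' Assemble a continuous synthetic session for one subject
#'
#' Concatenates the subject's trials on a continuous time axis (inter-trial
#' intervals drawn uniformly from `iti_range_ms`, plus enough spacing for
#' sentence-locked epochs), generates the background EEG, builds the event
#' table (every fixation plus one sentence-onset event per trial) and
#' applies each effect template to its matching events.
#'
#' @param trials One subject's trial metadata (from
#'   [simulate_reading_experiment()]).
#' @param fixations The subject's fixation table (onsets in ms from trial
#'   start).
#' @param templates List of [effect_template()]s (default
#'   [default_effect_templates()]).
#' @param channels Channel labels to synthesize (default all 64).
#' @param fs Sampling rate (default 500).
#' @param iti_range_ms Inter-trial blank interval range (default 750-1220).
#' @param noise_exponent,sd_uv,alpha_uv Passed to [generate_background()].
#' @return An `eeg_recording` with populated `events` table (columns
#'   `sample`, `class`, `trial`, `condition`, `word_index`).
#' @export
assemble_session <- function(trials, fixations,
                             templates = default_effect_templates(),
                             channels = montage_64(), fs = 500,
                             iti_range_ms = c(750, 1220),
                             noise_exponent = 1, sd_uv = 10, alpha_uv = 2) {
  stopifnot(length(unique(trials$subject)) == 1)
  if (iti_range_ms[1] < 750) stop("inter-trial interval must be >= 750 ms")
  trials <- trials[order(trials$trial), ]
  fix_by_trial <- split(fixations, fixations$trial)

  lead_ms <- 2000
  t_cursor <- lead_ms
  trial_start <- numeric(nrow(trials))
  for (i in seq_len(nrow(trials))) {
    trial_start[i] <- t_cursor
    fx <- fix_by_trial[[as.character(trials$trial[i])]]
    trial_end <- max(fx$onset_ms + fx$duration_ms)
    iti <- runif(1, iti_range_ms[1], iti_range_ms[2])
    # keep the next sentence onset clear of this trial's 2.5 s analysis span
    t_cursor <- max(t_cursor + trial_end + iti,
                    t_cursor + trials$sentence_onset_ms[i] + 3000)
  }
  duration_s <- (t_cursor + 2000) / 1000

  rec <- generate_background(duration_s, channels = channels, fs = fs,
                             noise_exponent = noise_exponent, sd_uv = sd_uv,
                             alpha_uv = alpha_uv)

  ev_rows <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    fx <- fix_by_trial[[as.character(trials$trial[i])]]
    abs_ms <- trial_start[i] + fx$onset_ms
    target_first <- which(fx$word_index == trials$target_index[i] &
                            fx$pass_label == "first_pass")[1]
    cls <- rep("fixation", nrow(fx))
    if (!is.na(target_first)) cls[target_first] <- "target_fixation"
    ev <- tibble(sample = ms_to_samples(abs_ms, fs) + 1L, class = cls,
                 trial = trials$trial[i], condition = trials$condition[i],
                 word_index = fx$word_index)
    onset <- tibble(sample = ms_to_samples(
                      trial_start[i] + trials$sentence_onset_ms[i], fs) + 1L,
                    class = "sentence_onset", trial = trials$trial[i],
                    condition = trials$condition[i], word_index = 0L)
    ev_rows[[i]] <- bind_rows(ev, onset)
  }
  rec$events <- bind_rows(ev_rows) %>% arrange(.data$sample)

  for (tpl in templates) {
    ev <- rec$events %>%
      filter(.data$class == tpl$event_class,
             .data$condition %in% tpl$conditions)
    rec <- inject_band_power(rec, tpl, ev$sample)
  }
  rec
}
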