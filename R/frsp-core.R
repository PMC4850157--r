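# Wavelet time-frequency decomposition and event-locked spectral
# perturbation (dB log-ratio against a pre-event baseline).
#
# The analysis kernel is a Hann-tapered complex sinusoid with a constant
# number of cycles at every frequency (default 3), i.e. kernel length
# round(n_cycles * fs / f) samples. Kernels are normalized so that a
# unit-amplitude sinusoid at the kernel frequency yields a power estimate
# of 1; under this convention the expected wavelet power of white noise
# with variance s^2 is 2 * s^2 * f / fs (the kernel's noise bandwidth
# grows linearly with frequency).

#' Wavelet analysis specification
#'
#' @param freqs Frequency grid in Hz (default 3:70, 1 Hz steps).
#' @param n_cycles Cycles per kernel, constant across frequencies
#'   (default 3). Frequency-proportional cycle growth as used by some EEG
#'   toolboxes can be emulated by passing a vector of per-frequency cycles.
#' @param fs Sampling rate in Hz (default 500).
#' @return List of class `wavelet_spec`.
#' @export
wavelet_spec <- function(freqs = 3:70, n_cycles = 3, fs = 500) {
  stopifnot(all(freqs > 0), fs > 0)
  if (max(freqs) >= fs / 2) stop("max frequency must be below fs/2")
  n_cycles <- rep_len(n_cycles, length(freqs))
  structure(list(freqs = as.numeric(freqs), n_cycles = n_cycles, fs = fs),
            class = "wavelet_spec")
}

#' Build one complex wavelet kernel
#'
#' `kernel(t) = Hann(L) * exp(i 2 pi f t)` with nominal length
#' `L = round(n_cycles * fs / f)` samples, incremented to the next odd
#' length so the peak sits on a sample. Normalized so a unit-amplitude
#' sinusoid at `f` yields unit power.
#'
#' @param f Frequency in Hz, `0 < f < fs/2`.
#' @param spec A [wavelet_spec()].
#' @return Complex vector with attributes `nominal_length` and
#'   `half_width` (samples on each side of the centre).
#' @export
build_wavelet <- function(f, spec = wavelet_spec()) {
  stopifnot(f > 0, f < spec$fs / 2)
  idx <- which.min(abs(spec$freqs - f))
  nc <- spec$n_cycles[idx]
  L <- as.integer(round(nc * spec$fs / f))
  Lk <- if (L %% 2 == 0) L + 1L else L
  h <- hann_window(Lk)
  t <- ((0:(Lk - 1)) - (Lk - 1) / 2) / spec$fs
  k <- h * exp(2i * pi * f * t) * (2 / sum(h))
  attr(k, "nominal_length") <- L
  attr(k, "half_width") <- (Lk - 1L) %/% 2L
  k
}

# FFT-based complex convolution of every column of `x` with every kernel.
# Returns power array [freq, time_out, column]; `out_idx` are row indices
# of x retained on the output time axis. When `out_idx` is a regular grid
# with a stride dividing the FFT length, the inverse transform is taken at
# length nfft/stride after aliasing (spectral folding), which yields the
# decimated convolution exactly at a fraction of the cost.
wavelet_power <- function(x, spec, out_idx) {
  n <- nrow(x)
  nc <- ncol(x)
  kernels <- lapply(spec$freqs, build_wavelet, spec = spec)
  max_len <- max(vapply(kernels, length, integer(1)))
  if (n < max_len) {
    warning("signal shorter than the longest kernel; ",
            "low frequencies have no valid samples")
  }
  nfft <- next_pow2(n + max_len)
  X <- mvfft(rbind(x, matrix(0, nfft - n, nc)))
  P <- array(NA_real_, c(length(spec$freqs), length(out_idx), nc))

  step <- if (length(out_idx) > 1) unique(diff(out_idx)) else 1L
  fold <- length(step) == 1 && step > 1 && nfft %% step == 0
  M <- if (fold) nfft %/% step else nfft
  kk <- 0:(nfft - 1)

  for (j in seq_along(spec$freqs)) {
    k <- kernels[[j]]
    hw <- attr(k, "half_width")
    # shift so row m of the inverse corresponds to input sample
    # out_idx[1] + (m-1)*step, with the kernel centre aligned (offset hw)
    shift <- exp(2i * pi * kk * (out_idx[1] + hw - 1) / nfft)
    kf <- fft(c(as.complex(k), complex(nfft - length(k)))) * shift
    Z <- X * kf
    if (fold) {
      dim(Z) <- c(M, step, nc)
      Zf <- Z[, 1, ]
      for (d in 2:step) Zf <- Zf + Z[, d, ]
      dim(Zf) <- c(M, nc)
    } else {
      Zf <- Z
    }
    y <- mvfft(Zf, inverse = TRUE) / nfft
    rows <- if (fold) seq_along(out_idx) else out_idx - out_idx[1] + 1L
    P[j, , ] <- Mod(y[rows, , drop = FALSE])^2
  }
  P
}

#' Time-frequency decomposition
#'
#' Complex convolution of each channel with the wavelet bank; power is the
#' squared magnitude. In `epoched` mode the input is a `[time, channel,
#' trial]` array (see [epoch_by_events()]) and output samples within half a
#' kernel length of an epoch edge are masked invalid per frequency. In
#' `continuous` mode the input is a `[time, channel]` matrix spanning a
#' whole recording; all interior samples are valid and epochs can be sliced
#' afterwards with [tf_slice_epochs()].
#'
#' @param x Numeric matrix `[time, channel]` (continuous) or array
#'   `[time, channel, trial]` (epoched).
#' @param spec A [wavelet_spec()].
#' @param mode `"epoched"` or `"continuous"`.
#' @param times_ms Time axis in ms for the rows of `x` (epoched mode:
#'   relative to the locking event).
#' @param out_step Keep every `out_step`-th sample on the output time axis
#'   (default 8, i.e. 16 ms at 500 Hz; powers of two allow the fast
#'   spectral-folding decimation).
#' @return List of class `tf_decomposition`: `power` array
#'   `[freq, time, channel, trial]` (trial dimension dropped in continuous
#'   mode), `freqs`, `times_ms`, `mask` `[freq, time]`, `fs`, `mode`.
#' @export
tf_transform <- function(x, spec = wavelet_spec(),
                         mode = c("epoched", "continuous"),
                         times_ms = NULL, out_step = 8) {
  mode <- match.arg(mode)
  if (anyNA(x)) stop("NaN/NA samples in input")
  if (mode == "continuous") {
    stopifnot(is.matrix(x))
    dims <- c(dim(x), 1L)
    xm <- x
  } else {
    stopifnot(length(dim(x)) == 3)
    dims <- dim(x)
    xm <- matrix(x, nrow = dims[1])    # columns: channel varying fastest
  }
  n <- dims[1]
  if (is.null(times_ms)) times_ms <- (seq_len(n) - 1) / spec$fs * 1000
  out_idx <- seq(1L, n, by = out_step)

  P <- wavelet_power(xm, spec, out_idx)
  half_widths <- vapply(spec$freqs, function(f) {
    k <- build_wavelet(f, spec); attr(k, "half_width")
  }, integer(1))
  mask <- outer(half_widths, out_idx,
                function(hw, i) i - hw >= 1 & i + hw <= n)
  if (mode == "continuous") {
    power <- array(P, c(length(spec$freqs), length(out_idx), dims[2]))
  } else {
    power <- array(P, c(length(spec$freqs), length(out_idx), dims[2], dims[3]))
  }
  structure(list(power = power, freqs = spec$freqs,
                 times_ms = times_ms[out_idx], mask = mask, fs = spec$fs,
                 mode = mode),
            class = "tf_decomposition")
}

#' Slice event-locked epochs out of a recording
#'
#' Sample-accurate half-open slices `[onset + t0, onset + t1)` with time 0
#' at the event onset sample (the onset sample belongs to the post-event
#' side). Events whose window does not fit inside the recording are dropped
#' and counted.
#'
#' @param rec An `eeg_recording` (see [generate_background()]) or a
#'   `[time, channel]` matrix plus `fs`.
#' @param event_samples 1-based onset sample indices.
#' @param window_ms `c(t0, t1)` in ms relative to the event.
#' @param fs Sampling rate; taken from `rec` if it is a recording.
#' @return List: `epochs` array `[time, channel, trial]`, `times_ms`,
#'   `n_dropped`, `kept` (logical per input event).
#' @export
epoch_by_events <- function(rec, event_samples, window_ms = c(-1000, 1500),
                            fs = NULL) {
  if (inherits(rec, "eeg_recording")) {
    samples <- rec$samples
    fs <- rec$fs
  } else {
    samples <- rec
    if (is.null(fs)) stop("fs required for a bare matrix")
  }
  n <- nrow(samples)
  off0 <- ms_to_samples(window_ms[1], fs)
  off1 <- ms_to_samples(window_ms[2], fs)
  len <- off1 - off0
  starts <- as.integer(event_samples) + off0
  kept <- starts >= 1L & (starts + len - 1L) <= n
  if (!any(kept)) stop("no events with a complete epoch window")
  idx <- lapply(starts[kept], function(s) s:(s + len - 1L))
  epochs <- array(0, c(len, ncol(samples), sum(kept)))
  for (i in seq_along(idx)) epochs[, , i] <- samples[idx[[i]], , drop = FALSE]
  list(epochs = epochs,
       times_ms = (seq_len(len) - 1 + off0) / fs * 1000,
       n_dropped = sum(!kept), kept = kept)
}

#' Slice epochs out of a continuous-mode TF decomposition
#'
#' Natural-reading fixations follow each other within a few hundred ms, so
#' zero-padded per-epoch convolution can be replaced by one convolution of
#' the continuous recording followed by slicing on the decimated time axis.
#'
#' @param tf A continuous-mode [tf_transform()] result.
#' @param event_samples 1-based onset sample indices into the recording.
#' @param window_ms `c(t0, t1)` ms relative to the event.
#' @return A `tf_decomposition` in epoched layout; interior samples are all
#'   valid except near recording edges (mask inherited from the recording).
#' @export
tf_slice_epochs <- function(tf, event_samples, window_ms = c(-1000, 1500)) {
  stopifnot(tf$mode == "continuous")
  step_ms <- diff(tf$times_ms[1:2])
  rel <- seq(window_ms[1], window_ms[2] - step_ms, by = step_ms)
  keep_ev <- logical(length(event_samples))
  cols <- vector("list", length(event_samples))
  for (i in seq_along(event_samples)) {
    ev_ms <- (event_samples[i] - 1) / tf$fs * 1000
    want <- ev_ms + rel
    j <- round((want - tf$times_ms[1]) / step_ms) + 1
    keep_ev[i] <- all(j >= 1 & j <= length(tf$times_ms))
    if (keep_ev[i]) cols[[i]] <- as.integer(j)
  }
  if (!any(keep_ev)) stop("no events with a complete epoch window")
  cols <- cols[keep_ev]
  nf <- dim(tf$power)[1]; nch <- dim(tf$power)[3]
  power <- array(NA_real_, c(nf, length(rel), nch, length(cols)))
  mask <- matrix(TRUE, nf, length(rel))
  for (i in seq_along(cols)) {
    power[, , , i] <- tf$power[, cols[[i]], , drop = FALSE]
    mask <- mask & tf$mask[, cols[[i]], drop = FALSE]
  }
  structure(list(power = power, freqs = tf$freqs, times_ms = rel,
                 mask = mask, fs = tf$fs, mode = "epoched"),
            class = "tf_decomposition")
}

#' Baseline-normalize a TF decomposition into dB power change
#'
#' `trial_mean` (default): average power over trials first, then divide by
#' the mean baseline power and take `10 * log10`, i.e.
#' `dB(f, t) = 10 log10( mean_trials P(f, t) / mean_{trials, t in baseline} P(f, t) )`.
#' `single_trial`: each trial is divided by its own baseline mean and the
#' per-trial dB values are averaged. Both schemes are exactly invariant to
#' rescaling the raw signal, and a statistically stationary signal gives
#' 0 dB in expectation.
#'
#' @param tf An epoched `tf_decomposition` with a trial dimension.
#' @param baseline_ms `c(t0, t1)` ms, must contain valid samples at every
#'   frequency.
#' @param scheme `"trial_mean"` or `"single_trial"`.
#' @return List of class `frsp_result`: `db` array `[freq, time, channel]`,
#'   `freqs`, `times_ms`, `mask`, `baseline_ms`, `scheme`, `n_trials`.
#' @export
baseline_normalize <- function(tf, baseline_ms = c(-1000, 0),
                               scheme = c("trial_mean", "single_trial")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(tf, "tf_decomposition"), length(dim(tf$power)) == 4)
  in_base <- tf$times_ms >= baseline_ms[1] & tf$times_ms < baseline_ms[2]
  if (!any(in_base)) stop("baseline window contains no samples")
  nf <- dim(tf$power)[1]; nt <- dim(tf$power)[2]
  nch <- dim(tf$power)[3]; ntr <- dim(tf$power)[4]

  db <- array(NA_real_, c(nf, nt, nch))
  for (f in seq_len(nf)) {
    base_cols <- which(in_base & tf$mask[f, ])
    if (!length(base_cols)) next
    pf <- tf$power[f, , , , drop = FALSE]
    dim(pf) <- c(nt, nch, ntr)
    if (scheme == "trial_mean") {
      pm <- apply(pf, c(1, 2), mean)                      # [time, channel]
      base <- colMeans(pm[base_cols, , drop = FALSE])     # per channel
      if (any(base <= 0)) stop("zero baseline power (degenerate input)")
      db[f, , ] <- 10 * log10(sweep(pm, 2, base, "/"))
    } else {
      base <- apply(pf[base_cols, , , drop = FALSE], c(2, 3), mean)
      if (any(base <= 0)) stop("zero baseline power (degenerate input)")
      dbt <- 10 * log10(sweep(pf, c(2, 3), base, "/"))
      db[f, , ] <- apply(dbt, c(1, 2), mean)
    }
  }
  db[!array(tf$mask, c(nf, nt, nch))] <- NA_real_
  structure(list(db = db, freqs = tf$freqs, times_ms = tf$times_ms,
                 mask = tf$mask, baseline_ms = baseline_ms, scheme = scheme,
                 n_trials = ntr),
            class = "frsp_result")
}
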