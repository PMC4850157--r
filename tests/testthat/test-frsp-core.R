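test_that("kernel lengths follow the constant-cycle rule", {
  spec <- wavelet_spec(3:70, 3, 500)
  k10 <- build_wavelet(10, spec)
  expect_equal(attr(k10, "nominal_length"), 150)   # 3 * 500 / 10
  expect_true(length(k10) %% 2 == 1)
  k3 <- build_wavelet(3, spec)
  expect_equal(attr(k3, "nominal_length"), 500)
  expect_equal(attr(k3, "half_width"), 250)        # 500 ms at 500 Hz
  expect_error(build_wavelet(300, spec))
})

test_that("the kernel bank peaks at the tone frequency, agreeing with FFT", {
  fs <- 500
  spec <- wavelet_spec(3:70, 3, fs)
  n <- 4000
  tone <- cos(2 * pi * 15 * (0:(n - 1)) / fs)
  tf <- tf_transform(matrix(tone, ncol = 1), spec, "continuous",
                     out_step = 1)
  mid <- 1500:2500
  mean_pow <- rowMeans(tf$power[, mid, 1])
  expect_equal(spec$freqs[which.max(mean_pow)], 15)
  # FFT oracle on the same tone
  spec_fft <- Mod(fft(tone))^2
  f_axis <- (0:(n - 1)) * fs / n
  keep <- f_axis > 0 & f_axis < fs / 2
  expect_equal(round(f_axis[keep][which.max(spec_fft[keep])]), 15)
})

test_that("a unit-amplitude grid tone yields unit power (normalization)", {
  fs <- 500
  spec <- wavelet_spec(c(5, 10, 20, 40), 3, fs)
  n <- 3000
  for (f in spec$freqs) {
    a <- 1.7
    tone <- a * cos(2 * pi * f * (0:(n - 1)) / fs)
    tf <- tf_transform(matrix(tone, ncol = 1), spec, "continuous",
                       out_step = 1)
    j <- which(spec$freqs == f)
    mid <- 1000:2000
    expect_equal(mean(tf$power[j, mid, 1]), a^2, tolerance = 0.01)
    # stable over time in the interior
    expect_lt(sd(tf$power[j, mid, 1]) / a^2, 0.02)
  }
})

test_that("white-noise power follows the analytic noise-bandwidth law", {
  # with unit-sinusoid normalization, E[P(f)] = 2 * sigma^2 * f / fs
  set.seed(8)
  fs <- 500
  spec <- wavelet_spec(c(5, 10, 20, 40, 60), 3, fs)
  n <- 60000
  sigma <- 2
  x <- matrix(rnorm(n, sd = sigma), ncol = 1)
  tf <- tf_transform(x, spec, "continuous", out_step = 4)
  interior <- which(colSums(!tf$mask) == 0)
  got <- rowMeans(tf$power[, interior, 1])
  expected <- 2 * sigma^2 * spec$freqs / fs
  expect_equal(got, expected, tolerance = 0.06)
})

test_that("epoch slicing is sample-accurate and drops boundary events", {
  fs <- 500
  x <- matrix(seq_len(6000), ncol = 1)
  ep <- epoch_by_events(x, c(5000, 100), window_ms = c(-1000, 1500),
                        fs = fs)
  expect_equal(ep$n_dropped, 1)          # the early event cannot fit
  expect_equal(dim(ep$epochs), c(1250, 1, 1))
  expect_equal(ep$epochs[1, 1, 1], 4500) # 5000 - 500 samples
  expect_equal(ep$epochs[1250, 1, 1], 5749)
  expect_equal(ep$times_ms[1], -1000)
  expect_equal(ep$times_ms[1250], 1498)  # half-open [t0, t1)
  expect_error(epoch_by_events(x, 10, window_ms = c(-1000, 1500), fs = fs),
               "no events")
})

test_that("the edge validity mask reflects half-kernel arithmetic", {
  fs <- 500
  spec <- wavelet_spec(c(3, 10), 3, fs)
  set.seed(1)
  ep <- array(rnorm(1250 * 1 * 2), c(1250, 1, 2))
  tf <- tf_transform(ep, spec, "epoched",
                     times_ms = seq(-1000, by = 2, length.out = 1250),
                     out_step = 1)
  # 3 Hz kernel: 250-sample (500 ms) half width; valid -500..998 ms
  valid3 <- range(tf$times_ms[tf$mask[1, ]])
  expect_equal(valid3[1], -500)
  expect_gte(valid3[2], 990)
  # 10 Hz kernel: 151 samples -> 75-sample (150 ms) half width
  valid10 <- range(tf$times_ms[tf$mask[2, ]])
  expect_equal(valid10[1], -850)
})

test_that("dB normalization: identity, exact power doubling, scale invariance", {
  freqs <- c(10, 20)
  times <- seq(-400, 398, by = 2)
  nt <- length(times)
  base_level <- 4
  pow <- array(base_level, c(2, nt, 1, 3))
  pow[, times >= 0, , ] <- 2 * base_level
  tf <- structure(list(power = pow, freqs = freqs, times_ms = times,
                       mask = matrix(TRUE, 2, nt), fs = 500,
                       mode = "epoched"),
                  class = "tf_decomposition")
  fr <- baseline_normalize(tf, baseline_ms = c(-400, 0))
  expect_equal(unique(as.vector(fr$db[, times < 0, ])), 0)
  expect_equal(unique(as.vector(fr$db[, times >= 0, ])),
               10 * log10(2), tolerance = 1e-12)

  # scale invariance of the dB ratio: assertable exactly on raw signals
  set.seed(3)
  ep <- array(rnorm(600 * 1 * 4), c(600, 1, 4))
  spec <- wavelet_spec(c(10, 20), 3, 500)
  t_ms <- seq(-600, by = 2, length.out = 600)
  f1 <- baseline_normalize(
    tf_transform(ep, spec, times_ms = t_ms, out_step = 2),
    baseline_ms = c(-300, 0))
  f2 <- baseline_normalize(
    tf_transform(ep * 7.3, spec, times_ms = t_ms, out_step = 2),
    baseline_ms = c(-300, 0))
  expect_equal(f1$db, f2$db, tolerance = 1e-9)
})

test_that("baseline schemes behave as documented on stationary data", {
  set.seed(21)
  spec <- wavelet_spec(c(8, 15, 30), 3, 500)
  t_ms <- seq(-1000, by = 2, length.out = 1000)
  tf <- tf_transform(array(rnorm(1000 * 1 * 30), c(1000, 1, 30)), spec,
                     times_ms = t_ms, out_step = 4)
  f_tm <- baseline_normalize(tf, c(-1000, 0), scheme = "trial_mean")
  f_st <- baseline_normalize(tf, c(-1000, 0), scheme = "single_trial")
  # trial-mean: 0 dB in expectation
  expect_lt(abs(mean(f_tm$db, na.rm = TRUE)), 0.35)
  # single-trial dB averaging carries a negative log-of-noisy-power offset
  # on stationary data ...
  expect_lt(mean(f_st$db, na.rm = TRUE), 0)
  expect_equal(f_st$scheme, "single_trial")
  # ... which cancels in comparisons between equally sized conditions
  tf2 <- tf_transform(array(rnorm(1000 * 1 * 30), c(1000, 1, 30)), spec,
                      times_ms = t_ms, out_step = 4)
  f_st2 <- baseline_normalize(tf2, c(-1000, 0), scheme = "single_trial")
  expect_lt(abs(mean(f_st$db - f_st2$db, na.rm = TRUE)), 0.6)
})

test_that("continuous and epoched modes agree on the valid region", {
  set.seed(5)
  fs <- 500
  n <- 8000
  x <- matrix(rnorm(2 * n), ncol = 2)
  spec <- wavelet_spec(c(6, 12, 24), 3, fs)
  events <- c(3001, 5001)
  tfc <- tf_transform(x, spec, "continuous", out_step = 1)
  sliced <- tf_slice_epochs(tfc, events, window_ms = c(-1000, 1000))
  ep <- epoch_by_events(x, events, window_ms = c(-1000, 1000), fs = fs)
  tfe <- tf_transform(ep$epochs, spec, "epoched", times_ms = ep$times_ms,
                      out_step = 1)
  common <- tfe$mask & matrix(sliced$mask[, seq_len(ncol(tfe$mask))],
                              nrow = nrow(tfe$mask))
  for (j in seq_along(spec$freqs)) {
    cols <- which(common[j, ])
    expect_equal(tfe$power[j, cols, , ], sliced$power[j, cols, , ],
                 tolerance = 1e-8)
  }
})

test_that("NaN input is rejected", {
  x <- matrix(rnorm(100), ncol = 1)
  x[5] <- NA
  expect_error(tf_transform(x, wavelet_spec(c(10), 3, 500), "continuous"),
               "NaN")
})
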