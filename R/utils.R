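#' Derive independent child seeds from one root seed
#'
#' Each pipeline stage consumes its own RNG stream so that, e.g., adding EEG
#' synthesis does not perturb the scanpaths generated from the same root seed.
#'
#' @param seed Integer root seed.
#' @param n Number of child seeds.
#' @return Integer vector of length `n`, all below 2^31 - 1.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, n >= 1)
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  sample.int(2147483646L, n)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# symmetric Hann window, endpoints at zero
hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
}

# tapered-cosine (Tukey) window: Hann ramps over fraction `taper` of each
# side, flat plateau of 1 in between
tukey_window <- function(n, taper = 0.3) {
  if (n == 1) return(1)
  w <- rep(1, n)
  m <- floor(taper * (n - 1) / 2)
  if (m > 0) {
    ramp <- 0.5 * (1 - cos(pi * (0:(m - 1)) / m))
    w[1:m] <- ramp
    w[(n - m + 1):n] <- rev(ramp)
  }
  w
}

next_pow2 <- function(n) 2^ceiling(log2(n))

ms_to_samples <- function(ms, fs) as.integer(round(ms * fs / 1000))

`%||%` <- function(a, b) if (is.null(a)) b else a
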