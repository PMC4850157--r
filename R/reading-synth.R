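# Synthetic stimulus corpus and fixation scanpaths.
#
# Word identities are never modelled: downstream eye-movement and EEG
# computations only consult word positions and fixation timing, so a
# "sentence" is a vector of word lengths (characters). Scanpath timing is
# calibrated so that the expected first-fixation duration, gaze duration and
# total viewing time on the target word equal typical self-paced reading
# values per condition (see `default_scanpath_config()`).

# fixed word-length distribution over 2..12 characters, mean ~6.4
WORD_LENGTH_SUPPORT <- 2:12
WORD_LENGTH_PROBS <- c(0.05, 0.08, 0.11, 0.14, 0.15, 0.14,
                       0.12, 0.09, 0.06, 0.04, 0.02)

#' Generate a corpus of sentence quadruples
#'
#' Each quadruple consists of an ordered word-length sequence (`words_ord`)
#' and a pseudo-random permutation of the same words (`words_rdm`) with the
#' target word held at its original position. A quadruple yields four
#' experimental versions (ORD/RDM crossed with COR/SEM), but because word
#' identities are not modelled the COR/SEM distinction lives entirely in the
#' condition label attached to a trial.
#'
#' Sentence lengths are `round(Normal(length_mean, length_sd))` clipped to a
#' minimum of 4 words (round-half-to-even). The 1-based target position is
#' drawn conditionally on the sentence length,
#' `round(Normal(pos_mean + pos_slope * (L - length_mean), resid_sd))`, and
#' resampled until it is neither the first nor the last word. The positive
#' length-position coupling (`pos_slope`, default 0.8) is required for the
#' marginal position mean to match `pos_mean` under the never-first/never-last
#' constraint; with an independent draw the truncation at `L - 1` pulls the
#' realized mean well below the nominal one.
#'
#' @param n_quads Number of quadruples (default 120).
#' @param length_mean,length_sd Sentence length distribution in words
#'   (defaults 9.56 and 1.61).
#' @param pos_mean,pos_sd Target-word position distribution, 1-based
#'   (defaults 7.1 and 1.37).
#' @param pos_slope Regression of target position on sentence length.
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble of class `frsp_corpus` with columns `quad_id`,
#'   `sentence_length`, `target_index` (0-based), and list-columns
#'   `words_ord`, `words_rdm` of word lengths.
#' @export
generate_corpus <- function(n_quads = 120, length_mean = 9.56,
                            length_sd = 1.61, pos_mean = 7.1, pos_sd = 1.37,
                            pos_slope = 0.8, seed = NULL) {
  stopifnot(n_quads >= 1, length_mean >= 4)
  if (length_sd < 0 || pos_sd < 0) {
    stop("standard deviations must be non-negative")
  }
  if (pos_mean >= length_mean) {
    warning("pos_mean >= length_mean: position resampling may be slow")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))

  lens <- pmax(4L, as.integer(round(rnorm(n_quads, length_mean, length_sd))))
  resid_sd <- sqrt(max(pos_sd^2 - (pos_slope * length_sd)^2, 0.3))

  draw_position <- function(len) {
    mu <- pos_mean + pos_slope * (len - length_mean)
    for (i in 1:10000) {
      p <- as.integer(round(rnorm(1, mu, resid_sd)))
      if (p >= 2L && p <= len - 1L) return(p)
    }
    stop("target position resampling did not converge; check pos_mean/pos_sd")
  }

  quads <- lapply(seq_len(n_quads), function(q) {
    len <- lens[q]
    pos <- draw_position(len)            # 1-based, never first or last
    words <- sample(WORD_LENGTH_SUPPORT, len, replace = TRUE,
                    prob = WORD_LENGTH_PROBS)
    perm <- seq_len(len)
    others <- setdiff(perm, pos)
    perm[others] <- sample(others)       # target stays in place
    list(quad_id = q, sentence_length = len, target_index = pos - 1L,
         words_ord = words, words_rdm = words[perm])
  })

  out <- tibble(
    quad_id = vapply(quads, `[[`, integer(1), "quad_id"),
    sentence_length = vapply(quads, `[[`, integer(1), "sentence_length"),
    target_index = vapply(quads, `[[`, integer(1), "target_index"),
    words_ord = lapply(quads, `[[`, "words_ord"),
    words_rdm = lapply(quads, `[[`, "words_rdm")
  )
  class(out) <- c("frsp_corpus", class(out))
  out
}

#' Default per-condition scanpath timing parameters
#'
#' Mean durations are in ms. The per-condition entries are calibrated so that
#' the closed-form expectations
#' \deqn{FFD = m_1,\quad GD = m_1 + p_{refix} m_{refix},\quad
#'       TVT = GD + p_{reg} m_{2nd}}
#' on the target word equal 198/227/239 (ORD_COR), 203/237/270 (ORD_SEM),
#' 211/248/273 (RDM_COR) and 217/260/290 ms (RDM_SEM). Durations are Gamma
#' distributed with common shape `duration_shape`; the default of 35 keeps
#' P(duration < 80 ms) below 0.001 for every default mean.
#'
#' @return A list with per-condition parameter lists and shared fields
#'   `duration_shape`, `skip_prob_target`, `skip_prob_other`,
#'   `saccade_gap_ms` and `fs`.
#' @export
default_scanpath_config <- function() {
  cond <- function(ffd, p_refix, m_refix, p_reg, m_second) {
    list(first_fixation_mean = ffd, refixation_prob = p_refix,
         refixation_mean = m_refix, regression_prob = p_reg,
         second_pass_mean = m_second)
  }
  list(
    conditions = list(
      ORD_COR = cond(198, 0.20, 145, 0.08, 150),
      ORD_SEM = cond(203, 0.20, 170, 0.22, 150),
      RDM_COR = cond(211, 0.20, 185, 1 / 6, 150),
      RDM_SEM = cond(217, 0.20, 215, 0.20, 150)
    ),
    duration_shape = 35,
    skip_prob_target = 0.05,
    skip_prob_other = 0.10,
    saccade_gap_ms = 30,
    fs = 500
  )
}

validate_scanpath_config <- function(cfg) {
  for (nm in names(cfg$conditions)) {
    p <- cfg$conditions[[nm]]
    probs <- c(p$refixation_prob, p$regression_prob)
    if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
    means <- c(p$first_fixation_mean, p$refixation_mean, p$second_pass_mean)
    if (any(means <= 80)) stop("mean durations must exceed 80 ms")
  }
  if (any(c(cfg$skip_prob_target, cfg$skip_prob_other) < 0) ||
      any(c(cfg$skip_prob_target, cfg$skip_prob_other) > 1)) {
    stop("skip probabilities must lie in [0, 1]")
  }
  invisible(cfg)
}

#' Simulate a fixation scanpath for one trial
#'
#' A left-to-right first pass over the words: each word is fixated unless
#' skipped (the first word is never skipped, since a trial starts with the
#' gaze entering the sentence at its left edge). First-pass fixation
#' durations are Gamma distributed around the condition's
#' `first_fixation_mean`; with probability `refixation_prob` an immediate
#' same-word refixation (mean `refixation_mean`) follows, contributing to
#' gaze duration. After the first pass, with probability `regression_prob`
#' a single second-pass fixation on the target (mean `second_pass_mean`)
#' is appended, contributing to total viewing time only. Consecutive
#' fixations are separated by a fixed saccade gap.
#'
#' @param quad One row of an [generate_corpus()] corpus (list or 1-row tibble).
#' @param condition One of `"ORD_COR"`, `"ORD_SEM"`, `"RDM_COR"`, `"RDM_SEM"`.
#' @param cfg Scanpath configuration, see [default_scanpath_config()].
#' @return Tibble with `word_index` (0-based), `onset_ms`, `duration_ms`,
#'   `pass_label` (`"first_pass"`/`"second_pass"`).
#' @export
generate_scanpath <- function(quad, condition, cfg = default_scanpath_config()) {
  condition <- match.arg(condition, FRSP_CONDITIONS)
  validate_scanpath_config(cfg)
  p <- cfg$conditions[[condition]]
  len <- quad$sentence_length[[1]]
  target <- quad$target_index[[1]]
  shape <- cfg$duration_shape
  gap <- cfg$saccade_gap_ms

  word <- integer(0); onset <- numeric(0); dur <- numeric(0); pass <- character(0)
  t <- 0
  for (w in 0:(len - 1)) {
    skip_p <- if (w == 0L) 0 else if (w == target) cfg$skip_prob_target else
      cfg$skip_prob_other
    if (runif(1) < skip_p) next
    d <- rgamma(1, shape, scale = p$first_fixation_mean / shape)
    word <- c(word, w); onset <- c(onset, t); dur <- c(dur, d)
    pass <- c(pass, "first_pass")
    t <- t + d + gap
    if (runif(1) < p$refixation_prob) {
      d2 <- rgamma(1, shape, scale = p$refixation_mean / shape)
      word <- c(word, w); onset <- c(onset, t); dur <- c(dur, d2)
      pass <- c(pass, "first_pass")
      t <- t + d2 + gap
    }
  }
  target_fixated <- any(word == target)
  if (target_fixated && runif(1) < p$regression_prob) {
    d3 <- rgamma(1, shape, scale = p$second_pass_mean / shape)
    word <- c(word, target); onset <- c(onset, t); dur <- c(dur, d3)
    pass <- c(pass, "second_pass")
  }
  tibble(word_index = word, onset_ms = onset, duration_ms = dur,
         pass_label = pass)
}

#' Assign quadruples to subjects in two counterbalanced lists
#'
#' The quadruples are split at random into two halves. Subjects in list 1
#' see the first half as ORD_COR plus RDM_SEM and the second half as
#' ORD_SEM plus RDM_COR; list 2 swaps the pairings. Every subject therefore
#' reads each quadruple exactly twice (once ORD, once RDM, with opposite
#' COR/SEM versions) and contributes trials to all four conditions. Trial
#' order is randomized per subject.
#'
#' @param subjects Even number of subjects, split half and half across lists.
#' @param corpus A [generate_corpus()] corpus.
#' @param seed Optional integer seed.
#' @return Tibble of trial skeletons: `subject`, `trial` (presentation
#'   order), `quad_id`, `condition`, `list_version`.
#' @export
assign_experiment_lists <- function(subjects, corpus, seed = NULL) {
  if (subjects %% 2 != 0) stop("number of subjects must be even")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n_quads <- nrow(corpus)
  half <- sample(n_quads) <= ceiling(n_quads / 2)  # TRUE: ORD_COR/RDM_SEM in list 1

  pairing <- function(in_first_half, version) {
    flip <- xor(in_first_half, version == 2L)
    if (flip) c("ORD_COR", "RDM_SEM") else c("ORD_SEM", "RDM_COR")
  }

  rows <- lapply(seq_len(subjects), function(s) {
    version <- if (s <= subjects / 2) 1L else 2L
    conds <- t(vapply(half, pairing, character(2), version = version))
    skel <- tibble(
      subject = s,
      quad_id = rep(corpus$quad_id, 2L),
      condition = c(conds[, 1], conds[, 2]),
      list_version = version
    )
    skel <- skel[sample(nrow(skel)), ]
    skel$trial <- seq_len(nrow(skel))
    skel
  })
  out <- bind_rows(rows)
  out[, c("subject", "trial", "quad_id", "condition", "list_version")]
}

#' Simulate a complete reading experiment
#'
#' Convenience driver: corpus generation, list assignment and per-trial
#' scanpath simulation, each on its own child RNG stream derived from
#' `seed`.
#'
#' @param n_subjects Number of subjects (even; default 32).
#' @param n_quads Number of sentence quadruples (default 120).
#' @param seed Integer root seed.
#' @param cfg Scanpath configuration.
#' @param corpus_args Named list of extra arguments for [generate_corpus()].
#' @return List with `corpus`, `trials` (trial metadata incl. target index,
#'   `target_skipped` and within-trial `sentence_onset_ms`) and `fixations`
#'   (one row per fixation, onsets in ms from trial start).
#' @export
simulate_reading_experiment <- function(n_subjects = 32, n_quads = 120,
                                        seed = 1,
                                        cfg = default_scanpath_config(),
                                        corpus_args = list()) {
  seeds <- derive_seeds(seed, 3)
  corpus <- do.call(generate_corpus,
                    c(list(n_quads = n_quads, seed = seeds[1]), corpus_args))
  trials <- assign_experiment_lists(n_subjects, corpus, seed = seeds[2])

  set.seed(seeds[3])
  corpus_by_id <- split(corpus, corpus$quad_id)
  n_tr <- nrow(trials)
  fix_list <- vector("list", n_tr)
  target_skipped <- logical(n_tr)
  sentence_onset <- numeric(n_tr)
  for (i in seq_len(n_tr)) {
    quad <- corpus_by_id[[as.character(trials$quad_id[i])]]
    sp <- generate_scanpath(quad, trials$condition[i], cfg)
    sp$subject <- trials$subject[i]
    sp$trial <- trials$trial[i]
    fix_list[[i]] <- sp
    target_skipped[i] <- !any(sp$word_index == quad$target_index)
    sentence_onset[i] <- sp$onset_ms[match(0L, sp$word_index)]
  }
  fixations <- bind_rows(fix_list)[, c("subject", "trial", "word_index",
                                       "onset_ms", "duration_ms", "pass_label")]
  trials$target_index <- corpus$target_index[match(trials$quad_id,
                                                   corpus$quad_id)]
  trials$sentence_length <- corpus$sentence_length[match(trials$quad_id,
                                                         corpus$quad_id)]
  trials$target_skipped <- target_skipped
  trials$sentence_onset_ms <- sentence_onset
  list(corpus = corpus, trials = trials, fixations = fixations)
}
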