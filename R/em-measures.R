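# Word-level eye-movement reading measures.
#
# FFD: duration of the first fixation on a word during first-pass reading.
# GD:  sum of all first-pass fixation durations on the word.
# TVT: sum of all fixation durations on the word (first plus second pass).

#' Label fixations as first-pass or second-pass reading
#'
#' For each word, first pass is the maximal run of consecutive fixations on
#' that word starting at its first fixation, before gaze leaves the word in
#' either direction; every later fixation on the word is second pass.
#' Fixations with `NA` word index (off-word) get `NA` pass labels.
#'
#' @param fixations Tibble with `subject`, `trial`, `word_index`, `onset_ms`,
#'   `duration_ms` (time-ordered within trial).
#' @return The input with a recomputed `pass_label` column.
#' @export
first_pass_segment <- function(fixations) {
  label_trial <- function(widx) {
    n <- length(widx)
    if (n == 0) return(character(0))
    key <- ifelse(is.na(widx), -1L, widx)
    run <- cumsum(c(TRUE, key[-1] != key[-n]))
    first_run <- tapply(run, key, min)
    lab <- as.vector(ifelse(run == first_run[as.character(key)],
                            "first_pass", "second_pass"))
    lab[is.na(widx)] <- NA_character_
    lab
  }
  fixations %>%
    arrange(.data$subject, .data$trial, .data$onset_ms) %>%
    group_by(.data$subject, .data$trial) %>%
    mutate(pass_label = label_trial(.data$word_index)) %>%
    ungroup()
}

#' Apply fixation-duration exclusion rules
#'
#' Removes fixations shorter than `min_ms` and, per subject, fixations whose
#' duration strictly exceeds the subject's mean plus `sd_mult` standard
#' deviations. The mean and SD are computed over the subject's raw fixation
#' durations pooled across trials and words, after the short-fixation cut,
#' in one pass (no re-iteration after trimming).
#'
#' @param fixations Fixation tibble with `subject` and `duration_ms`.
#' @param min_ms Short-fixation cutoff in ms (default 80).
#' @param sd_mult Upper trim in subject SD units (default 3).
#' @return List with `fixations` (retained rows) and `report`, a one-row
#'   tibble with `n_fixations_total`, `n_below_min`, `n_above_sd` and
#'   `fraction_removed`.
#' @export
apply_exclusions <- function(fixations, min_ms = 80, sd_mult = 3) {
  n_total <- nrow(fixations)
  short <- fixations$duration_ms < min_ms
  kept <- fixations[!short, , drop = FALSE]

  upper <- tapply(kept$duration_ms, kept$subject, function(d) {
    if (length(d) < 2) {
      warning("subject with < 2 fixations: SD undefined, no upper trim")
      return(Inf)
    }
    mean(d) + sd_mult * sd(d)
  })
  above <- kept$duration_ms > upper[as.character(kept$subject)]
  report <- tibble(
    n_fixations_total = n_total,
    n_below_min = sum(short),
    n_above_sd = sum(above),
    fraction_removed = (sum(short) + sum(above)) / max(n_total, 1)
  )
  list(fixations = kept[!above, , drop = FALSE], report = report)
}

#' Compute word-level reading measures
#'
#' @param fixations Fixation tibble with recomputed pass labels (see
#'   [first_pass_segment()]) and exclusions already applied.
#' @return Tibble with one row per (subject, trial, word): `FFD`, `GD`,
#'   `TVT` in ms. Words with no surviving first-pass fixation are absent;
#'   see [target_measures()] for explicit skip flags.
#' @export
compute_measures <- function(fixations) {
  fixations %>%
    filter(!is.na(.data$word_index)) %>%
    arrange(.data$subject, .data$trial, .data$onset_ms) %>%
    group_by(.data$subject, .data$trial, .data$word_index) %>%
    summarise(
      FFD = .data$duration_ms[.data$pass_label == "first_pass"][1],
      GD = sum(.data$duration_ms[.data$pass_label == "first_pass"]),
      TVT = sum(.data$duration_ms),
      .groups = "drop"
    ) %>%
    filter(!is.na(.data$FFD))
}

#' Extract target-word measures with skip flags
#'
#' @param measures Output of [compute_measures()].
#' @param trials Trial metadata with `subject`, `trial`, `condition`,
#'   `target_index`.
#' @return One row per trial: condition, target measures, and `skipped`
#'   (no surviving first-pass fixation on the target).
#' @export
target_measures <- function(measures, trials) {
  trials %>%
    select(all_of(c("subject", "trial", "condition", "target_index"))) %>%
    left_join(measures,
              by = c("subject", "trial", "target_index" = "word_index")) %>%
    mutate(skipped = is.na(.data$FFD))
}

#' Condition-level statistics for the reading measures
#'
#' Follows the standard reading-research analysis: measures on the target
#' word are natural-log-transformed, aggregated to subject-by-condition
#' means, submitted to a one-way repeated-measures ANOVA over the four
#' conditions, and followed by paired t-tests of the semantic manipulation
#' within each word-order level (ORD_SEM vs ORD_COR, RDM_SEM vs RDM_COR).
#' Raw (ms) condition means are reported alongside for interpretability.
#'
#' @param targets Output of [target_measures()]; skipped-target trials are
#'   excluded.
#' @param measures Character vector of measures to analyse.
#' @return List with `raw_means` (condition means in ms), `cell_means`
#'   (subject x condition, log scale), `anova` (one [rm_anova()] table per
#'   measure) and `ttests` (paired contrasts per measure).
#' @export
em_condition_stats <- function(targets, measures = c("FFD", "GD", "TVT")) {
  used <- targets %>% filter(!.data$skipped)
  if (length(unique(used$subject)) < 2) stop("need at least 2 subjects")

  cells <- used %>%
    group_by(.data$subject, .data$condition) %>%
    summarise(across(all_of(measures), ~ mean(log(.x))), .groups = "drop")
  complete <- cells %>%
    group_by(.data$subject) %>%
    filter(dplyr::n() == length(FRSP_CONDITIONS)) %>%
    ungroup()
  dropped <- setdiff(unique(cells$subject), unique(complete$subject))
  if (length(dropped)) {
    warning("dropping subjects with missing condition cells: ",
            paste(dropped, collapse = ", "))
  }

  raw_means <- used %>%
    filter(.data$subject %in% unique(complete$subject)) %>%
    group_by(.data$subject, .data$condition) %>%
    summarise(across(all_of(measures), mean), .groups = "drop") %>%
    group_by(.data$condition) %>%
    summarise(across(all_of(measures), mean), .groups = "drop")

  paired_t <- function(df, m, a, b) {
    wide <- pivot_wider(df[, c("subject", "condition", m)],
                        names_from = "condition", values_from = all_of(m))
    d <- wide[[a]] - wide[[b]]
    if (var(d) < 1e-24) {
      return(tibble(measure = m, contrast = paste(a, "vs", b), t = 0,
                    df = length(d) - 1, p = 1))
    }
    ht <- t.test(wide[[a]], wide[[b]], paired = TRUE)
    tibble(measure = m, contrast = paste(a, "vs", b),
           t = unname(ht$statistic), df = unname(ht$parameter),
           p = ht$p.value)
  }

  anovas <- list()
  tt <- list()
  for (m in measures) {
    cell_tab <- complete %>%
      select(all_of(c("subject", "condition", m))) %>%
      rename(value = all_of(m))
    anovas[[m]] <- rm_anova(cell_tab, within = "condition")
    tt[[paste0(m, "_ORD")]] <- paired_t(complete, m, "ORD_SEM", "ORD_COR")
    tt[[paste0(m, "_RDM")]] <- paired_t(complete, m, "RDM_SEM", "RDM_COR")
  }
  list(raw_means = raw_means, cell_means = complete, anova = anovas,
       ttests = bind_rows(tt))
}
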