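# End-to-end drivers: simulate a co-registered session per subject, run
# the fixation-locked and sentence-locked spectral analyses, and collect
# the cell tables and inferential statistics. The command-line interface
# in `inst/cli/frsp-pipeline.R` is a thin wrapper over `run_pipeline()`.

config_wavelet_spec <- function(config) {
  fr <- config$analysis$freqs
  wavelet_spec(seq(fr$min, fr$max, by = fr$step),
               n_cycles = config$analysis$n_cycles, fs = config$eeg$fs)
}

# FRSP maps for one subject and one event-locking, split by condition group
subject_frsp <- function(rec, groups, window_ms, spec, config) {
  out <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    ev <- rec$events %>%
      filter(.data$class == groups[[g]]$class,
             .data$condition %in% groups[[g]]$conditions)
    ep <- epoch_by_events(rec, ev$sample, window_ms)
    tf <- tf_transform(ep$epochs, spec, mode = config$analysis$mode,
                       times_ms = ep$times_ms,
                       out_step = config$analysis$out_step)
    fr <- baseline_normalize(tf, config$analysis$baseline_ms,
                             scheme = config$analysis$baseline_scheme)
    fr$channels <- rec$channels
    out[[g]] <- tibble(condition = names(groups)[g], frsp = list(fr))
  }
  bind_rows(out)
}

#' Run the full spectral-perturbation study on synthetic sessions
#'
#' For every subject: assemble a continuous EEG session aligned to the
#' subject's scanpaths (with the configured effect templates), epoch it
#' time-locked to (a) the first fixation on the target word in the two
#' syntactically ordered conditions and (b) sentence onsets pooled into
#' ordered (ORD) vs randomized (RDM) word order, wavelet-transform,
#' baseline-normalize, and aggregate into cluster x band x window cells.
#' Inference: lower-beta planned contrast ORD_SEM vs ORD_COR at the
#' target level, theta ANOVA/contrasts and the gamma slope test at the
#' sentence level.
#'
#' @param experiment A [simulate_reading_experiment()] result.
#' @param config Configuration list (see [default_config()]);
#'   `config$eeg$n_quads_eeg` restricts each session to the trials of the
#'   first so-many quadruples to bound runtime.
#' @param templates Effect templates for the synthetic sessions.
#' @param progress Print one line per subject.
#' @return List with `target_cells`, `sentence_cells` (cell tables) and
#'   `stats` (planned contrasts, ANOVA tables, slope tests).
#' @export
run_frsp_study <- function(experiment, config = default_config(),
                           templates = default_effect_templates(),
                           progress = FALSE) {
  spec <- config_wavelet_spec(config)
  subjects <- sort(unique(experiment$trials$subject))
  seeds <- derive_seeds(config$seed + 104729, length(subjects))

  target_groups <- list(
    ORD_COR = list(class = "target_fixation", conditions = "ORD_COR"),
    ORD_SEM = list(class = "target_fixation", conditions = "ORD_SEM"))
  sentence_groups <- list(
    ORD = list(class = "sentence_onset", conditions = ORD_CONDITIONS),
    RDM = list(class = "sentence_onset", conditions = RDM_CONDITIONS))

  tcells <- list(); scells <- list()
  for (i in seq_along(subjects)) {
    s <- subjects[i]
    tr <- experiment$trials %>% filter(.data$subject == s)
    if (!is.null(config$eeg$n_quads_eeg) && !is.na(config$eeg$n_quads_eeg)) {
      keep <- sort(unique(experiment$corpus$quad_id))[
        seq_len(config$eeg$n_quads_eeg)]
      tr <- tr %>% filter(.data$quad_id %in% keep)
    }
    fx <- experiment$fixations %>%
      filter(.data$subject == s, .data$trial %in% tr$trial)
    set.seed(seeds[i])
    rec <- assemble_session(tr, fx, templates = templates,
                            channels = config$eeg$channels,
                            fs = config$eeg$fs,
                            noise_exponent = config$eeg$noise_exponent,
                            sd_uv = config$eeg$sd_uv,
                            alpha_uv = config$eeg$alpha_uv)
    tset <- subject_frsp(rec, target_groups,
                         config$analysis$target_window_ms, spec, config)
    sset <- subject_frsp(rec, sentence_groups,
                         config$analysis$sentence_window_ms, spec, config)
    tset$subject <- s; sset$subject <- s
    tcells[[i]] <- aggregate_cells(tset,
                                   windows = analysis_windows("target"))
    scells[[i]] <- aggregate_cells(sset,
                                   windows = analysis_windows("sentence"))
    if (progress) message("subject ", s, " done")
  }
  target_cells <- bind_rows(tcells)
  sentence_cells <- bind_rows(scells)

  stats <- list()
  beta_cells <- target_cells %>% filter(.data$band == "lower_beta")
  stats$lower_beta_planned <- planned_contrasts(beta_cells, "ORD_SEM",
                                                "ORD_COR")
  if (setequal(unique(beta_cells$cluster), names(electrode_clusters()))) {
    stats$lower_beta_followup <- target_level_followup(beta_cells)
  }
  theta_cells <- sentence_cells %>% filter(.data$band == "theta")
  stats$theta_contrasts <- planned_contrasts(theta_cells, "ORD", "RDM")
  if (setequal(unique(theta_cells$cluster), names(electrode_clusters()))) {
    stats$theta_anova <- rm_anova(theta_cells,
                                  within = c("window", "cluster",
                                             "condition"))
  }
  gamma_cells <- sentence_cells %>% filter(.data$band == "gamma")
  stats$gamma_slopes <- lapply(
    setNames(nm = unique(gamma_cells$cluster)),
    function(cl) slope_test(gamma_cells, cluster = cl))

  list(target_cells = target_cells, sentence_cells = sentence_cells,
       stats = stats)
}

#' Eye-movement analysis pipeline
#'
#' Pass segmentation, duration exclusions, word measures, target
#' extraction and condition statistics in one call.
#'
#' @param fixations Fixation table.
#' @param trials Trial metadata.
#' @return List with `measures`, `targets`, `exclusions` (report) and
#'   `stats` (see [em_condition_stats()]).
#' @export
run_em_pipeline <- function(fixations, trials) {
  fx <- first_pass_segment(fixations)
  excl <- apply_exclusions(fx)
  measures <- compute_measures(excl$fixations)
  targets <- target_measures(measures, trials)
  stats <- em_condition_stats(targets)
  list(measures = measures, targets = targets,
       exclusions = excl$report, stats = stats)
}

write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

corpus_to_json <- function(corpus, path) {
  lst <- lapply(seq_len(nrow(corpus)), function(i) {
    list(quad_id = corpus$quad_id[i],
         sentence_length = corpus$sentence_length[i],
         target_index = corpus$target_index[i],
         words_ord = corpus$words_ord[[i]],
         words_rdm = corpus$words_rdm[[i]])
  })
  write_json(lst, path)
}

#' Run one pipeline stage
#'
#' Subcommands: `generate` (corpus, trials, fixation tables and, when
#' `config$eeg$write_files` is set, per-subject BrainVision sessions);
#' `em-stats` (eye-movement measures and statistics from the generated
#' tables); `frsp-target` / `frsp-sentence` (the respective spectral
#' analyses on in-memory synthetic sessions); `report` (collates the JSON
#' outputs in `out_dir`). Each stage logs seed and configuration digest
#' and is a pure function of (config, seed).
#'
#' @param subcommand One of `generate`, `em-stats`, `frsp-target`,
#'   `frsp-sentence`, `report`.
#' @param config Configuration list or path to a YAML configuration.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional override for `config$seed`.
#' @return Invisible list of artifact paths (and results for the frsp
#'   stages).
#' @export
run_pipeline <- function(subcommand, config = default_config(),
                         out_dir = ".", seed = NULL) {
  valid <- c("generate", "em-stats", "frsp-target", "frsp-sentence",
             "report")
  if (!subcommand %in% valid) {
    stop("unknown subcommand '", subcommand, "'; expected one of: ",
         paste(valid, collapse = ", "))
  }
  if (is.character(config)) config <- load_config(config)
  if (!is.null(seed)) config$seed <- seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  log_meta <- list(subcommand = subcommand, seed = config$seed,
                   package_version = as.character(
                     utils::packageVersion("frsp")),
                   config_digest = sum(utf8ToInt(
                     paste(deparse(config), collapse = ""))))

  regen <- function() {
    simulate_reading_experiment(
      n_subjects = config$n_subjects,
      n_quads = config$corpus$n_quads,
      seed = config$seed, cfg = config$scanpath,
      corpus_args = config$corpus[setdiff(names(config$corpus), "n_quads")])
  }

  paths <- list()
  if (subcommand == "generate") {
    exp <- regen()
    paths$corpus <- file.path(out_dir, "corpus.json")
    corpus_to_json(exp$corpus, paths$corpus)
    paths$trials <- file.path(out_dir, "trials.tsv")
    write.table(exp$trials, paths$trials, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths$fixations <- file.path(out_dir, "fixations.tsv")
    write_fixation_table(exp$fixations, paths$fixations, exp$trials)
    if (isTRUE(config$eeg$write_files)) {
      seeds <- derive_seeds(config$seed + 104729, config$n_subjects)
      for (s in sort(unique(exp$trials$subject))) {
        tr <- exp$trials %>% filter(.data$subject == s)
        fx <- exp$fixations %>% filter(.data$subject == s)
        set.seed(seeds[match(s, sort(unique(exp$trials$subject)))])
        rec <- assemble_session(tr, fx, channels = config$eeg$channels,
                                fs = config$eeg$fs,
                                noise_exponent = config$eeg$noise_exponent,
                                sd_uv = config$eeg$sd_uv,
                                alpha_uv = config$eeg$alpha_uv)
        base <- file.path(out_dir, sprintf("subject%02d", s))
        write_brainvision(rec, base, format = config$eeg$file_format)
        paths[[basename(base)]] <- base
      }
    }
  } else if (subcommand == "em-stats") {
    fixations <- read_fixation_table(file.path(out_dir, "fixations.tsv"))
    trials <- as_tibble(read.delim(file.path(out_dir, "trials.tsv")))
    res <- run_em_pipeline(fixations, trials)
    paths$measures <- file.path(out_dir, "em_measures.tsv")
    write.table(res$measures, paths$measures, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths$stats <- file.path(out_dir, "em_stats.json")
    write_json(list(meta = log_meta,
                    raw_means = res$stats$raw_means,
                    anova = res$stats$anova,
                    ttests = res$stats$ttests,
                    exclusions = res$exclusions), paths$stats)
  } else if (subcommand %in% c("frsp-target", "frsp-sentence")) {
    exp <- regen()
    study <- run_frsp_study(exp, config)
    if (subcommand == "frsp-target") {
      paths$cells <- file.path(out_dir, "frsp_target_cells.tsv")
      write.table(study$target_cells, paths$cells, sep = "\t",
                  quote = FALSE, row.names = FALSE)
      paths$stats <- file.path(out_dir, "frsp_target_stats.json")
      write_json(list(meta = log_meta,
                      lower_beta_planned = study$stats$lower_beta_planned),
                 paths$stats)
    } else {
      paths$cells <- file.path(out_dir, "frsp_sentence_cells.tsv")
      write.table(study$sentence_cells, paths$cells, sep = "\t",
                  quote = FALSE, row.names = FALSE)
      gs <- lapply(study$stats$gamma_slopes, function(x) {
        list(group_tests = x$group_tests, paired = x$paired)
      })
      paths$stats <- file.path(out_dir, "frsp_sentence_stats.json")
      write_json(list(meta = log_meta,
                      theta_contrasts = study$stats$theta_contrasts,
                      gamma_slopes = gs), paths$stats)
    }
    paths$result <- study
  } else if (subcommand == "report") {
    jsons <- list.files(out_dir, pattern = "_stats\\.json$",
                        full.names = TRUE)
    collated <- lapply(setNames(jsons, basename(jsons)),
                       jsonlite::read_json)
    paths$report <- file.path(out_dir, "report.json")
    write_json(list(meta = log_meta, stages = collated), paths$report)
  }
  invisible(paths)
}
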