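# File I/O: BrainVision recordings, tab-separated fixation event tables,
# YAML run configuration, and persisted analysis results.

#' Write an EEG recording as a BrainVision triplet
#'
#' Produces `<base>.vhdr` (text header), `<base>.vmrk` (markers) and
#' `<base>.eeg` (binary, multiplexed). Events are written as `Stimulus`
#' markers whose description encodes `class:trial:condition:word_index`.
#'
#' @param rec An `eeg_recording`.
#' @param base Path without extension.
#' @param format `"float32"` (IEEE float, lossless) or `"int16"`
#'   (quantized by `resolution`).
#' @param resolution Microvolts per bit for `int16` (default 0.1).
#' @return `base`, invisibly.
#' @export
write_brainvision <- function(rec, base, format = c("float32", "int16"),
                              resolution = 0.1) {
  format <- match.arg(format)
  vhdr <- paste0(base, ".vhdr")
  vmrk <- paste0(base, ".vmrk")
  eeg <- paste0(base, ".eeg")
  nm <- basename(base)
  n_ch <- ncol(rec$samples)

  res <- if (format == "int16") resolution else 1
  ch_lines <- sprintf("Ch%d=%s,,%g,µV", seq_len(n_ch), rec$channels,
                      res)
  header <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "", "[Common Infos]", "Codepage=UTF-8",
    paste0("DataFile=", nm, ".eeg"),
    paste0("MarkerFile=", nm, ".vmrk"),
    "DataFormat=BINARY", "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", n_ch),
    paste0("SamplingInterval=", format(1e6 / rec$fs, scientific = FALSE)),
    "", "[Binary Infos]",
    paste0("BinaryFormat=",
           if (format == "float32") "IEEE_FLOAT_32" else "INT_16"),
    "", "[Channel Infos]", ch_lines)
  writeLines(header, vhdr)

  ev <- rec$events
  mk <- c("Brain Vision Data Exchange Marker File, Version 1.0",
          "", "[Common Infos]", "Codepage=UTF-8",
          paste0("DataFile=", nm, ".eeg"),
          "", "[Marker Infos]",
          "Mk1=New Segment,,1,1,0")
  if (nrow(ev)) {
    desc <- sprintf("%s:%d:%s:%d", ev$class, ev$trial, ev$condition,
                    ev$word_index)
    mk <- c(mk, sprintf("Mk%d=Stimulus,%s,%d,1,0",
                        seq_len(nrow(ev)) + 1L, desc, ev$sample))
  }
  writeLines(mk, vmrk)

  x <- as.vector(t(rec$samples))     # multiplexed: channels interleaved
  con <- file(eeg, "wb")
  on.exit(close(con))
  if (format == "float32") {
    writeBin(x, con, size = 4, endian = "little")
  } else {
    q <- as.integer(pmax(pmin(round(x / resolution), 32767), -32768))
    writeBin(q, con, size = 2, endian = "little")
  }
  invisible(base)
}

parse_vhdr_entries <- function(lines) {
  kv <- grep("^[A-Za-z0-9]+=", lines, value = TRUE)
  keys <- sub("=.*", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  setNames(vals, keys)
}

#' Read a BrainVision recording
#'
#' Supports multiplexed binary data in IEEE float32 or int16 (with
#' per-channel resolution) dialects. Markers become the recording's event
#' table; `Stimulus` descriptions of the form `class:trial:condition:word`
#' are parsed back into columns.
#'
#' @param vhdr Path to the `.vhdr` header.
#' @return An `eeg_recording`.
#' @export
read_brainvision <- function(vhdr) {
  if (!file.exists(vhdr)) stop("header not found: ", vhdr)
  lines <- readLines(vhdr, warn = FALSE)
  info <- parse_vhdr_entries(lines)
  dirn <- dirname(vhdr)
  eeg <- file.path(dirn, info[["DataFile"]])
  vmrk <- file.path(dirn, info[["MarkerFile"]])
  if (!file.exists(vmrk)) stop("marker file missing: ", vmrk)
  if (!file.exists(eeg)) stop("data file missing: ", eeg)
  if (info[["DataOrientation"]] != "MULTIPLEXED") {
    stop("only multiplexed orientation is supported")
  }
  n_ch <- as.integer(info[["NumberOfChannels"]])
  fs <- 1e6 / as.numeric(info[["SamplingInterval"]])
  fmt <- info[["BinaryFormat"]]

  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  parts <- strsplit(sub("^Ch[0-9]+=", "", ch_lines), ",")
  channels <- vapply(parts, `[`, character(1), 1)
  res <- vapply(parts, function(p) {
    v <- suppressWarnings(as.numeric(p[3]))
    if (is.na(v)) 1 else v
  }, numeric(1))

  sz <- file.size(eeg)
  bytes <- if (fmt == "IEEE_FLOAT_32") 4L else if (fmt == "INT_16") 2L else
    stop("unsupported BinaryFormat: ", fmt)
  if (sz %% (bytes * n_ch) != 0) {
    stop("data file size inconsistent with channel count: ", eeg)
  }
  n <- sz / bytes / n_ch
  con <- file(eeg, "rb")
  on.exit(close(con))
  raw <- if (fmt == "IEEE_FLOAT_32") {
    readBin(con, "numeric", n * n_ch, size = 4, endian = "little")
  } else {
    readBin(con, "integer", n * n_ch, size = 2, endian = "little")
  }
  samples <- t(matrix(raw, n_ch, n))
  if (fmt == "INT_16") samples <- sweep(samples, 2, res, "*")
  colnames(samples) <- channels

  mlines <- grep("^Mk[0-9]+=Stimulus", readLines(vmrk, warn = FALSE),
                 value = TRUE)
  events <- tibble(sample = integer(0), class = character(0),
                   trial = integer(0), condition = character(0),
                   word_index = integer(0))
  if (length(mlines)) {
    fields <- strsplit(sub("^Mk[0-9]+=", "", mlines), ",")
    desc <- vapply(fields, `[`, character(1), 2)
    pos <- as.integer(vapply(fields, `[`, character(1), 3))
    dp <- strsplit(desc, ":")
    events <- tibble(
      sample = pos,
      class = vapply(dp, `[`, character(1), 1),
      trial = as.integer(vapply(dp, `[`, character(1), 2)),
      condition = vapply(dp, `[`, character(1), 3),
      word_index = as.integer(vapply(dp, `[`, character(1), 4)))
  }
  structure(list(samples = samples, fs = fs, channels = channels,
                 events = events),
            class = "eeg_recording")
}

#' Write a fixation event table as TSV
#'
#' Schema: `subject`, `trial`, `condition`, `word_index` (0-based, -1 for
#' off-word fixations), `onset_ms`, `duration_ms`, `pass_label`. This is
#' also the import target for fixation reports converted from eye-tracker
#' ASC output.
#'
#' @param fixations Fixation tibble (a `condition` column is joined from
#'   `trials` when supplied).
#' @param path Output path.
#' @param trials Optional trial metadata providing `condition`.
#' @return `path`, invisibly.
#' @export
write_fixation_table <- function(fixations, path, trials = NULL) {
  out <- fixations
  if (!is.null(trials) && !"condition" %in% names(out)) {
    out <- left_join(out,
                     trials[, c("subject", "trial", "condition")],
                     by = c("subject", "trial"))
  }
  if (!"condition" %in% names(out)) out$condition <- NA_character_
  out$word_index <- ifelse(is.na(out$word_index), -1L, out$word_index)
  out <- out[, c("subject", "trial", "condition", "word_index",
                 "onset_ms", "duration_ms", "pass_label")]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a fixation event table
#'
#' Validates types and within-trial onset monotonicity; word indices
#' outside `0..1000` (including the -1 sentinel) become `NA` (off-word).
#'
#' @param path TSV path with the [write_fixation_table()] schema.
#' @return Fixation tibble.
#' @export
read_fixation_table <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("subject", "trial", "condition", "word_index", "onset_ms",
            "duration_ms", "pass_label")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0) return(as_tibble(df))
  dur <- suppressWarnings(as.numeric(df$duration_ms))
  if (anyNA(dur)) {
    stop("malformed duration_ms at row ", which(is.na(dur))[1])
  }
  if (any(dur <= 0)) {
    stop("non-positive duration_ms at row ", which(dur <= 0)[1])
  }
  df$duration_ms <- dur
  df$onset_ms <- as.numeric(df$onset_ms)
  df$word_index <- suppressWarnings(as.integer(df$word_index))
  df$word_index[is.na(df$word_index) | df$word_index < 0 |
                  df$word_index > 1000] <- NA_integer_
  key <- paste(df$subject, df$trial)
  ord_ok <- unlist(tapply(df$onset_ms, factor(key, unique(key)),
                          function(o) c(TRUE, diff(o) > 0)))
  if (!all(ord_ok)) {
    stop("non-monotone onsets within a trial at row ", which(!ord_ok)[1])
  }
  as_tibble(df)
}

#' Default run configuration
#'
#' All generator and analysis parameters in one serializable list:
#' corpus distributions, per-condition scanpath timing, effect templates,
#' wavelet/baseline settings and channel selection. Every field can be
#' overridden via [load_config()] or `modifyList()`.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1,
    n_subjects = 32,
    corpus = list(n_quads = 120, length_mean = 9.56, length_sd = 1.61,
                  pos_mean = 7.1, pos_sd = 1.37, pos_slope = 0.8),
    scanpath = default_scanpath_config(),
    eeg = list(channels = unlist(electrode_clusters(), use.names = FALSE),
               fs = 500, noise_exponent = 1, sd_uv = 10, alpha_uv = 2,
               write_files = FALSE, file_format = "float32",
               n_quads_eeg = NA),  # NA: use every quadruple
    analysis = list(
      freqs = list(min = 3, max = 70, step = 1), n_cycles = 3,
      out_step = 8, mode = "epoched", baseline_scheme = "trial_mean",
      target_window_ms = c(-1000, 1500),
      sentence_window_ms = c(-1000, 2500),
      baseline_ms = c(-1000, 0), alpha = 0.05)
  )
}

#' Save / load a run configuration as YAML
#'
#' `load_config(save_config(cfg))` round-trips the default configuration.
#'
#' @param config Configuration list.
#' @param path YAML file path.
#' @return `save_config`: `path` invisibly; `load_config`: the
#'   configuration list with defaults filled in for absent fields.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 12)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  modifyList(default_config(), user)
}
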