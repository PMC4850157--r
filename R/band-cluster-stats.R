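# Band x cluster x time-window aggregation of spectral perturbation maps
# and the within-subject inferential layer: repeated-measures ANOVA,
# planned paired contrasts and per-subject linear-trend (slope) tests.

#' Frequency band definitions
#'
#' Inclusive integer-bin edges: theta 4-7, alpha 8-12, lower beta 13-18,
#' upper beta 19-30, gamma 31-55 Hz.
#'
#' @return Named list of `c(f_lo, f_hi)` pairs.
#' @export
band_specs <- function() {
  list(theta = c(4, 7), alpha = c(8, 12), lower_beta = c(13, 18),
       upper_beta = c(19, 30), gamma = c(31, 55))
}

#' Standard 300 ms analysis windows
#'
#' @param level `"target"` (two windows, 0-600 ms) or `"sentence"` (six
#'   windows, 0-1800 ms).
#' @return Tibble with `window` label, `win_index`, `t0`, `t1` (ms).
#' @export
analysis_windows <- function(level = c("target", "sentence")) {
  level <- match.arg(level)
  k <- if (level == "target") 2 else 6
  t0 <- (seq_len(k) - 1) * 300
  tibble(window = sprintf("%d-%d", t0, t0 + 300),
         win_index = seq_len(k), t0 = t0, t1 = t0 + 300)
}

#' Aggregate spectral perturbation maps into analysis cells
#'
#' Unweighted mean of the dB values over a cluster's channels, the band's
#' inclusive frequency bins, and the valid time points inside each window
#' (half-open `[t0, t1)`).
#'
#' @param frsp_set Tibble with columns `subject`, `condition` and a
#'   list-column `frsp` of `frsp_result` objects whose channel dimension is
#'   named (attribute `channels`), or a list of such entries.
#' @param clusters Named list of channel vectors (default
#'   [electrode_clusters()], restricted to channels present).
#' @param bands Named band list (default [band_specs()]).
#' @param windows Window tibble (default target-level).
#' @return A `CellTable`: tibble with `subject`, `condition`, `cluster`,
#'   `band`, `window`, `win_index`, `value` (mean dB).
#' @export
aggregate_cells <- function(frsp_set, clusters = electrode_clusters(),
                            bands = band_specs(),
                            windows = analysis_windows("target")) {
  if (!is.data.frame(frsp_set)) frsp_set <- bind_rows(frsp_set)
  out <- vector("list", nrow(frsp_set))
  for (i in seq_len(nrow(frsp_set))) {
    fr <- frsp_set$frsp[[i]]
    chans <- attr(fr, "channels") %||% fr$channels
    rows <- list()
    for (cl in names(clusters)) {
      ch_idx <- match(intersect(clusters[[cl]], chans), chans)
      if (!length(ch_idx)) next
      for (bd in names(bands)) {
        f_idx <- which(fr$freqs >= bands[[bd]][1] &
                         fr$freqs <= bands[[bd]][2])
        for (w in seq_len(nrow(windows))) {
          t_idx <- which(fr$times_ms >= windows$t0[w] &
                           fr$times_ms < windows$t1[w])
          vals <- fr$db[f_idx, t_idx, ch_idx]
          if (all(is.na(vals))) {
            stop(sprintf(
              "no valid samples in cell subject=%s condition=%s %s/%s/%s",
              frsp_set$subject[i], frsp_set$condition[i], cl, bd,
              windows$window[w]))
          }
          rows[[length(rows) + 1]] <- tibble(
            subject = frsp_set$subject[i],
            condition = frsp_set$condition[i],
            cluster = cl, band = bd, window = windows$window[w],
            win_index = windows$win_index[w],
            value = mean(vals, na.rm = TRUE))
        }
      }
    }
    out[[i]] <- bind_rows(rows)
  }
  bind_rows(out)
}

# normalized Helmert contrasts: k x (k-1), columns orthonormal and
# orthogonal to the unit vector
orthonormal_contrasts <- function(k) {
  if (k == 1) return(matrix(nrow = 1, ncol = 0))
  m <- stats::contr.helmert(k)
  sweep(m, 2, sqrt(colSums(m^2)), "/")
}

#' Repeated-measures ANOVA for fully crossed within-subject designs
#'
#' Classical univariate mixed-model ANOVA with subject as the random
#' factor: every within-subject effect is tested against its interaction
#' with subject. Implemented by projecting each subject's cell-mean vector
#' onto orthonormal effect contrasts (Kronecker products of per-factor
#' Helmert contrasts); the effect sum of squares is `n * ||mean score||^2`
#' and the error sum of squares is the within-column scatter of the scores,
#' which reproduces the textbook sums-of-squares decomposition exactly on
#' balanced data. Greenhouse-Geisser correction (from the covariance of the
#' contrast scores) is available but off by default.
#'
#' @param cells Long tibble with a `subject` column, one column per
#'   within-subject factor, and the dependent variable.
#' @param within Character vector of factor column names.
#' @param dv Name of the dependent-variable column (default `"value"`).
#' @param sphericity `"none"` (default) or `"greenhouse-geisser"`.
#' @return Tibble with one row per effect: `effect`, `df_num`, `df_den`,
#'   `F`, `p` (and `ges_eps` under the correction).
#' @export
rm_anova <- function(cells, within, dv = "value",
                     sphericity = c("none", "greenhouse-geisser")) {
  sphericity <- match.arg(sphericity)
  cells <- as.data.frame(cells)
  for (f in within) cells[[f]] <- factor(cells[[f]])
  levs <- lapply(cells[within], levels)
  k <- vapply(levs, length, integer(1))

  grid <- expand.grid(levs, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  cell_key <- do.call(paste, c(grid, sep = "\r"))
  row_key <- do.call(paste, c(lapply(cells[within], as.character),
                              sep = "\r"))
  subj <- factor(cells$subject)
  n <- nlevels(subj)
  tab <- table(subj, factor(row_key, levels = cell_key))
  if (any(tab != 1)) {
    stop("design must be balanced with exactly one value per ",
         "subject x cell; aggregate first")
  }
  Y <- matrix(NA_real_, n, length(cell_key))
  Y[cbind(as.integer(subj), match(row_key, cell_key))] <- cells[[dv]]

  effects <- unlist(lapply(seq_along(within), function(m) {
    utils::combn(within, m, simplify = FALSE)
  }), recursive = FALSE)

  res <- lapply(effects, function(eff) {
    mats <- lapply(seq_along(within), function(j) {
      if (within[j] %in% eff) orthonormal_contrasts(k[j])
      else matrix(1 / sqrt(k[j]), k[j], 1)
    })
    # expand.grid varies the first factor fastest -> it is the innermost
    # Kronecker operand
    M <- Reduce(function(a, b) kronecker(b, a), mats)
    S <- Y %*% M                                   # subjects x df scores
    q <- ncol(S)
    mu <- colMeans(S)
    ss_eff <- n * sum(mu^2)
    R <- sweep(S, 2, mu)
    ss_err <- sum(R^2)
    df1 <- q
    df2 <- q * (n - 1)
    Fv <- if (ss_eff < 1e-12 && ss_err < 1e-12) 0 else {
      (ss_eff / df1) / (ss_err / df2)
    }
    eps <- 1
    if (sphericity == "greenhouse-geisser" && q > 1) {
      Sig <- cov(S)
      eps <- sum(diag(Sig))^2 / (q * sum(Sig^2))
      eps <- max(min(eps, 1), 1 / q)
    }
    tibble(effect = paste(eff, collapse = ":"),
           df_num = df1 * eps, df_den = df2 * eps, F = Fv,
           p = pf(Fv, df1 * eps, df2 * eps, lower.tail = FALSE),
           ss_effect = ss_eff, ss_error = ss_err)
  })
  out <- bind_rows(res)
  # within-subject total scatter; equals the sum of all effect and error SS
  attr(out, "ss_total") <- sum(sweep(Y, 1, rowMeans(Y))^2)
  attr(out, "n_subjects") <- n
  out
}

#' Paired t-tests between two conditions for each analysis cell
#'
#' Two-sided paired t across subjects, one test per combination of the
#' `by` columns; no multiple-comparison correction.
#'
#' @param cells A `CellTable`.
#' @param cond_a,cond_b Condition labels; the difference is `a - b`.
#' @param by Columns defining the cells (default cluster/band/window).
#' @return Tibble with mean difference, `t`, `df`, `p` per cell.
#' @export
planned_contrasts <- function(cells, cond_a, cond_b,
                              by = c("cluster", "band", "window")) {
  if (length(unique(cells$subject)) < 3) stop("need at least 3 subjects")
  sub <- cells %>% filter(.data$condition %in% c(cond_a, cond_b))
  groups <- sub %>% distinct(across(all_of(by)))
  res <- lapply(seq_len(nrow(groups)), function(i) {
    g <- sub
    for (col in by) g <- g[g[[col]] == groups[[col]][i], ]
    wide <- pivot_wider(g[, c("subject", "condition", "value")],
                        names_from = "condition", values_from = "value")
    d <- wide[[cond_a]] - wide[[cond_b]]
    if (var(d) < 1e-24) {
      return(bind_cols(groups[i, ],
                       tibble(mean_diff = mean(d), t = 0,
                              df = length(d) - 1, p = 1)))
    }
    ht <- t.test(wide[[cond_a]], wide[[cond_b]], paired = TRUE)
    bind_cols(groups[i, ],
              tibble(mean_diff = unname(ht$estimate),
                     t = unname(ht$statistic), df = unname(ht$parameter),
                     p = ht$p.value))
  })
  bind_rows(res)
}

#' Hierarchical follow-up for the target-level analysis
#'
#' Implements the gated testing sequence used for fixation-locked band
#' effects: an overall Time x Hemisphere x Cluster x Condition ANOVA; if
#' the Time:Cluster:Condition interaction is significant, per-hemisphere
#' Time x Cluster x Condition ANOVAs; within a hemisphere showing the
#' interaction, per-window Cluster x Condition ANOVAs; and per-cluster
#' paired t-tests in windows with a Cluster:Condition interaction.
#'
#' @param cells Target-level `CellTable` for one band, two conditions,
#'   with `cluster` names of the form `<region>_<hemisphere>`.
#' @param cond_a,cond_b Contrast direction for the final per-cluster
#'   t-tests (`a - b`); by default the second sorted condition label minus
#'   the first (e.g. the violation condition minus its control).
#' @param alpha Gating significance level (default 0.05).
#' @return Nested list with `overall`, `by_hemisphere`, `by_window` and
#'   `cluster_tests` components (later stages `NULL` when not reached).
#' @export
target_level_followup <- function(cells, cond_a = NULL, cond_b = NULL,
                                  alpha = 0.05) {
  conds <- sort(unique(cells$condition))
  stopifnot(length(conds) == 2)
  cond_a <- cond_a %||% conds[2]
  cond_b <- cond_b %||% conds[1]
  cells <- cells %>%
    mutate(hemisphere = sub(".*_", "", .data$cluster),
           region = sub("_(left|right)$", "", .data$cluster))
  overall <- rm_anova(cells,
                      within = c("window", "hemisphere", "region",
                                 "condition"))
  key <- overall$p[overall$effect == "window:region:condition"]
  out <- list(overall = overall, by_hemisphere = NULL, by_window = NULL,
              cluster_tests = NULL)
  if (!length(key) || key >= alpha) return(out)

  out$by_hemisphere <- lapply(split(cells, cells$hemisphere), rm_anova,
                              within = c("window", "region", "condition"))
  sig_hemi <- names(Filter(function(a) {
    p <- a$p[a$effect == "window:region:condition"]
    length(p) && p < alpha
  }, out$by_hemisphere))
  if (!length(sig_hemi)) return(out)

  hemi_cells <- cells %>% filter(.data$hemisphere %in% sig_hemi)
  out$by_window <- lapply(split(hemi_cells, hemi_cells$window), rm_anova,
                          within = c("region", "condition"))
  sig_win <- names(Filter(function(a) {
    p <- a$p[a$effect == "region:condition"]
    length(p) && p < alpha
  }, out$by_window))
  if (!length(sig_win)) return(out)

  out$cluster_tests <- planned_contrasts(
    hemi_cells %>% filter(.data$window %in% sig_win),
    cond_a, cond_b, by = c("cluster", "band", "window"))
  out
}

#' Per-subject linear-trend test on successive window means
#'
#' Fits an ordinary least-squares line to each subject's window means
#' (regressor: window index 1..k, so slopes are in dB per 300 ms step),
#' then tests, per condition, whether the individual slopes are greater
#' than zero (one-sample, one-sided t) and whether the two conditions'
#' slopes differ (paired, two-sided t).
#'
#' @param cells Sentence-level `CellTable` restricted to one band and one
#'   cluster (or pre-filtered via `cluster`/`band` arguments).
#' @param cluster,band Optional filters applied to `cells`.
#' @return List with `slopes` (per subject x condition), `group_tests`
#'   (one-sided one-sample t per condition) and `paired` (two-sided paired
#'   t between the first two conditions).
#' @export
slope_test <- function(cells, cluster = NULL, band = NULL) {
  if (!is.null(cluster)) cells <- cells %>%
      filter(.data$cluster == !!cluster)
  if (!is.null(band)) cells <- cells %>% filter(.data$band == !!band)
  if (length(unique(cells$win_index)) < 2) {
    stop("need at least 2 windows for a slope")
  }
  slopes <- cells %>%
    group_by(.data$subject, .data$condition) %>%
    summarise(slope = {
      x <- .data$win_index - mean(.data$win_index)
      sum(x * .data$value) / sum(x^2)
    }, .groups = "drop")

  group_tests <- bind_rows(lapply(split(slopes, slopes$condition),
    function(g) {
      if (var(g$slope) < 1e-24) {
        # degenerate: identical slopes across subjects
        m <- mean(g$slope)
        return(tibble(condition = g$condition[1], mean_slope = m,
                      t = if (m == 0) 0 else sign(m) * Inf,
                      df = length(g$slope) - 1,
                      p_one_sided = if (m > 0) 0 else if (m < 0) 1 else 0.5))
      }
      ht <- t.test(g$slope, alternative = "greater")
      tibble(condition = g$condition[1], mean_slope = mean(g$slope),
             t = unname(ht$statistic), df = unname(ht$parameter),
             p_one_sided = ht$p.value)
    }))

  conds <- sort(unique(slopes$condition))
  paired <- NULL
  if (length(conds) == 2) {
    wide <- pivot_wider(slopes, names_from = "condition",
                        values_from = "slope")
    d <- wide[[conds[1]]] - wide[[conds[2]]]
    if (var(d) < 1e-24) {
      paired <- tibble(contrast = paste(conds[1], "vs", conds[2]),
                       mean_diff = mean(d), t = 0,
                       df = length(d) - 1, p = 1)
    } else {
      ht <- t.test(wide[[conds[1]]], wide[[conds[2]]], paired = TRUE)
      paired <- tibble(contrast = paste(conds[1], "vs", conds[2]),
                       mean_diff = unname(ht$estimate),
                       t = unname(ht$statistic), df = unname(ht$parameter),
                       p = ht$p.value)
    }
  }
  list(slopes = slopes, group_tests = group_tests, paired = paired)
}
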