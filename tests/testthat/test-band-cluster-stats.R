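test_that("cell aggregation averages over cluster, band and window", {
  # constant map: every cell equals the constant
  frsp_set <- tibble::tibble(subject = 1, condition = "ORD_COR",
                             frsp = list(constant_frsp(0.7)))
  cells <- aggregate_cells(frsp_set,
                           clusters = list(parieto_occipital_left =
                                             c("P5", "PO3")),
                           bands = list(theta = c(4, 7),
                                        lower_beta = c(13, 18)),
                           windows = analysis_windows("target"))
  expect_true(all(abs(cells$value - 0.7) < 1e-12))
  expect_equal(nrow(cells), 1 * 2 * 2)

  # an effect on an off-cluster channel leaves cluster cells unaffected
  fr <- constant_frsp(0, channels = c("P5", "PO3", "Cz"))
  fr$db[, , 3] <- 5
  cells2 <- aggregate_cells(
    tibble::tibble(subject = 1, condition = "X", frsp = list(fr)),
    clusters = list(parieto_occipital_left = c("P5", "PO3")),
    bands = list(theta = c(4, 7)), windows = analysis_windows("target"))
  expect_true(all(cells2$value == 0))

  # hand-built 2-channel, 2-bin, small-window mean
  fr3 <- constant_frsp(0, channels = c("P5", "PO3"), freqs = c(4, 5),
                       times_ms = c(0, 100))
  fr3$db[1, 1, 1] <- 1; fr3$db[2, 1, 1] <- 2
  fr3$db[1, 1, 2] <- 3; fr3$db[2, 1, 2] <- 6
  fr3$db[, 2, ] <- fr3$db[, 1, ]
  cells3 <- aggregate_cells(
    tibble::tibble(subject = 1, condition = "X", frsp = list(fr3)),
    clusters = list(po = c("P5", "PO3")), bands = list(theta = c(4, 5)),
    windows = tibble::tibble(window = "0-300", win_index = 1,
                             t0 = 0, t1 = 300))
  expect_equal(cells3$value, 3)
})

test_that("cells with no valid samples raise a named error", {
  fr <- constant_frsp(1)
  fr$mask[, ] <- FALSE
  fr$db[, , ] <- NA_real_
  expect_error(aggregate_cells(
    tibble::tibble(subject = 7, condition = "ORD", frsp = list(fr)),
    clusters = list(po = c("P5")), bands = list(theta = c(4, 7)),
    windows = analysis_windows("target")),
    "subject=7")
})

test_that("RM-ANOVA matches a brute-force oracle on a 2x2 design", {
  # hand-chosen integers, 4 subjects, factors A(2) x B(2)
  Y <- matrix(c(12, 15, 13, 20,
                10, 14, 11, 17,
                14, 18, 12, 22,
                11, 13, 12, 16), nrow = 4, byrow = TRUE)
  cells <- cells_from_matrix(Y, list(A = c("a1", "a2"), B = c("b1", "b2")))
  an <- rm_anova(cells, within = c("A", "B"))

  # oracle: stats::aov with per-effect error strata (independent path)
  df <- as.data.frame(cells)
  df$subject <- factor(df$subject)
  df$A <- factor(df$A); df$B <- factor(df$B)
  fit <- summary(aov(value ~ A * B + Error(subject / (A * B)), data = df))
  oracle_F <- c(
    A = fit[["Error: subject:A"]][[1]]["A", "F value"],
    B = fit[["Error: subject:B"]][[1]]["B", "F value"],
    `A:B` = fit[["Error: subject:A:B"]][[1]]["A:B", "F value"])
  got <- setNames(an$F, an$effect)[names(oracle_F)]
  expect_equal(unname(got), unname(oracle_F), tolerance = 1e-10)

  # the SS decomposition over all effects reproduces the total
  expect_equal(sum(an$ss_effect + an$ss_error),
               attr(an, "ss_total"), tolerance = 1e-8)
})

test_that("RM-ANOVA handles the paper's factorial layouts", {
  set.seed(60)
  # Time(2) x Hemisphere(2) x Cluster(3) x Condition(2), 6 subjects
  layout <- list(window = c("0-300", "300-600"),
                 hemisphere = c("left", "right"),
                 region = c("frontal", "central", "po"),
                 condition = c("ORD_COR", "ORD_SEM"))
  Y <- matrix(rnorm(6 * 24), 6, 24)
  an <- rm_anova(cells_from_matrix(Y, layout), within = names(layout))
  expect_equal(nrow(an), 15)                      # all effect combinations
  expect_equal(an$df_num[an$effect == "region"], 2)
  expect_equal(an$df_den[an$effect == "region"], 10)
  expect_equal(an$df_num[an$effect ==
                           "window:hemisphere:region:condition"], 2)
  expect_true(all(an$F >= 0))
  expect_equal(sum(an$ss_effect + an$ss_error), attr(an, "ss_total"),
               tolerance = 1e-8)
})

test_that("two-level RM-ANOVA F equals the squared paired t", {
  set.seed(61)
  Y <- matrix(rnorm(8 * 2, mean = c(0, 0.8)), 8, 2, byrow = TRUE)
  an <- rm_anova(cells_from_matrix(Y, list(condition = c("A", "B"))),
                 within = "condition")
  tt <- t.test(Y[, 1], Y[, 2], paired = TRUE)
  expect_equal(an$F, unname(tt$statistic)^2, tolerance = 1e-10)
})

test_that("constant data yield zero F and an unbalanced table errors", {
  Y <- matrix(5, 4, 2)
  an <- rm_anova(cells_from_matrix(Y, list(condition = c("A", "B"))),
                 within = "condition")
  expect_equal(an$F, 0)
  bad <- cells_from_matrix(matrix(rnorm(8), 4, 2),
                           list(condition = c("A", "B")))[-1, ]
  expect_error(rm_anova(bad, within = "condition"), "balanced")
})

test_that("Greenhouse-Geisser correction shrinks the dfs", {
  set.seed(62)
  Y <- matrix(rnorm(10 * 4), 10, 4)
  Y[, 4] <- Y[, 4] * 4                     # break sphericity
  cells <- cells_from_matrix(Y, list(cond = letters[1:4]))
  an_gg <- rm_anova(cells, within = "cond",
                    sphericity = "greenhouse-geisser")
  an <- rm_anova(cells, within = "cond")
  expect_lt(an_gg$df_num, an$df_num)
  expect_equal(an_gg$F, an$F)              # F itself is unchanged
  expect_gte(an_gg$df_num, 1)              # eps lower bound 1/(k-1)
})

test_that("planned contrasts match the textbook paired-t formula", {
  cells <- tibble::tibble(
    subject = rep(1:6, each = 2),
    condition = rep(c("ORD_SEM", "ORD_COR"), 6),
    cluster = "parieto_occipital_left", band = "lower_beta",
    window = "0-300",
    value = c(-0.9, -0.2, -0.5, -0.1, -0.7, -0.4,
              -0.6, 0.0, -0.8, -0.3, -0.2, -0.2))
  res <- planned_contrasts(cells, "ORD_SEM", "ORD_COR")
  d <- c(-0.7, -0.4, -0.3, -0.6, -0.5, 0.0)
  t_oracle <- mean(d) / (sd(d) / sqrt(6))
  expect_equal(res$t, t_oracle, tolerance = 1e-12)
  expect_equal(res$df, 5)
  expect_equal(res$p, 2 * pt(-abs(t_oracle), 5), tolerance = 1e-12)

  # identical conditions: t = 0, p = 1
  cells$value <- rep(c(0.3, 0.3), 6)
  res0 <- planned_contrasts(cells, "ORD_SEM", "ORD_COR")
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)
  expect_error(planned_contrasts(cells[1:4, ], "ORD_SEM", "ORD_COR"),
               "3 subjects")
})

test_that("the hierarchical follow-up gates on the interaction", {
  set.seed(63)
  # no condition effect anywhere: the gate stays closed
  base <- tidyr::expand_grid(subject = 1:8,
                             window = c("0-300", "300-600"),
                             cluster = c("frontal_left", "frontal_right",
                                         "central_left", "central_right",
                                         "parieto_occipital_left",
                                         "parieto_occipital_right"),
                             condition = c("ORD_COR", "ORD_SEM"))
  base$band <- "lower_beta"
  null_cells <- base
  null_cells$value <- rnorm(nrow(base), sd = 0.05)
  res <- target_level_followup(null_cells)
  if (res$overall$p[res$overall$effect ==
                      "window:region:condition"] >= 0.05) {
    expect_null(res$by_hemisphere)
  }
  # a strong early left parieto-occipital desynchronization opens it
  eff_cells <- base
  eff_cells$value <- rnorm(nrow(base), sd = 0.05) +
    ifelse(eff_cells$condition == "ORD_SEM" &
             eff_cells$cluster == "parieto_occipital_left" &
             eff_cells$window == "0-300", -1, 0)
  res2 <- target_level_followup(eff_cells)
  expect_false(is.null(res2$by_hemisphere))
  expect_false(is.null(res2$cluster_tests))
  po <- res2$cluster_tests[
    res2$cluster_tests$cluster == "parieto_occipital_left", ]
  expect_lt(po$p, 0.05)
  expect_lt(po$mean_diff, 0)
})

test_that("slope estimation is exact, shift-invariant and null-calibrated", {
  cells <- tibble::tibble(subject = rep(1:4, each = 6),
                          condition = "ORD",
                          cluster = "parieto_occipital_right",
                          band = "gamma", win_index = rep(1:6, 4),
                          value = rep(1:6, 4))
  st <- slope_test(cells)
  expect_true(all(st$slopes$slope == 1))

  # adding a constant to all windows leaves slopes unchanged
  cells2 <- cells
  cells2$value <- cells2$value + 100
  expect_equal(slope_test(cells2)$slopes$slope, st$slopes$slope)

  # all-zero slopes: one-sided p = 0.5 under the null symmetry
  cells3 <- cells
  cells3$value <- rep(c(2, 2, 2, 2, 2, 2), 4) +
    rep(c(0.01, -0.01), each = 12) * rep(c(1, -1), times = 12)
  st3 <- slope_test(dplyr::mutate(cells3, value = 2))
  expect_equal(st3$group_tests$p_one_sided, 0.5)
  expect_error(slope_test(cells[cells$win_index == 1, ]), "2 windows")
})
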