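test_that("the unscaled MAD matches hand-enumerated values", {
  expect_equal(median_absolute_deviation(c(1, 1, 2, 2, 4, 6, 9)), 1)
  expect_equal(median_absolute_deviation(rep(7, 5)), 0)
  expect_equal(median_absolute_deviation(c(-3, 3)), 3)
  expect_error(median_absolute_deviation(numeric(0)), "empty")
})

test_that("B-score reproduces the 2x2 hand computation", {
  plate <- tibble::tibble(array_id = 1, frame = 1,
                          row = c(1, 1, 2, 2), col = c(1, 2, 1, 2),
                          value = c(0, 0, 0, 4))
  out <- bscore_normalize(plate, value_cols = "value")
  expect_equal(out$value, c(1, -1, -1, 1))
  resid <- bscore_normalize(plate, value_cols = "value", scale = FALSE)
  expect_equal(resid$value, c(1, -1, -1, 1))
})

test_that("perfectly additive plates degenerate to zero with a warning", {
  plate <- tidyr::expand_grid(row = 1:4, col = 1:5)
  plate$array_id <- 1
  plate$frame <- 1
  plate$value <- 2 * plate$row + 3 * plate$col
  expect_warning(out <- bscore_normalize(plate, value_cols = "value"),
                 "zero residual MAD")
  expect_true(all(out$value == 0))
})

test_that("B-score residuals have exactly zero row and column means", {
  plate <- tidyr::expand_grid(row = 1:11, col = 1:25)
  plate$array_id <- 1
  plate$frame <- 1
  plate$value <- withr::with_seed(3, stats::rnorm(275, 50, 5)) +
    3 * (plate$row == 1)
  resid <- bscore_normalize(plate, value_cols = "value", scale = FALSE)
  expect_equal(max(abs(tapply(resid$value, resid$row, mean))), 0,
               tolerance = 1e-12)
  expect_equal(max(abs(tapply(resid$value, resid$col, mean))), 0,
               tolerance = 1e-12)
})

test_that("masked spots propagate and all-masked plates error", {
  plate <- tidyr::expand_grid(row = 1:3, col = 1:4)
  plate$array_id <- 1; plate$frame <- 1
  plate$value <- withr::with_seed(4, stats::rnorm(12))
  plate$value[5] <- NA
  out <- bscore_normalize(plate, value_cols = "value")
  expect_true(is.na(out$value[5]))
  expect_equal(sum(is.na(out$value)), 1)
  plate$value <- NA_real_
  expect_error(bscore_normalize(plate, value_cols = "value"), "all-masked")
})

test_that("window arithmetic and AUC integrals follow the trapezoid rule", {
  # 120 h span, 24 h window, 8 h shift: 13 frames
  tr <- tibble::tibble(spot = 1, time_h = seq(0, 120, 2 / 3), value = 1)
  ws <- window_signal(tr, value_cols = "value")
  expect_equal(max(ws$time_frame), 13)
  expect_equal(ws$t_start, seq(0, 96, 8))
  expect_equal(ws$t_end - ws$t_start, rep(24, 13))
  expect_equal(ws$auc, rep(24, 13))             # constant trace: 24 * v
  # linear trace on [0, 24]: exactly 288
  lin <- tibble::tibble(spot = 1, time_h = seq(0, 24, 0.5),
                        value = seq(0, 24, 0.5))
  expect_equal(window_signal(lin, value_cols = "value")$auc, 288)
  # irregular 35-40 min sampling still integrates the same constant
  irr_t <- cumsum(c(0, withr::with_seed(5, stats::runif(60, 35 / 60, 40 / 60))))
  irr <- tibble::tibble(spot = 1, time_h = irr_t, value = 2)
  ws_irr <- window_signal(irr, value_cols = "value")
  expect_equal(ws_irr$auc, rep(48, nrow(ws_irr)))
  expect_error(window_signal(irr[irr$time_h < 20, ], value_cols = "value"),
               "shorter than window")
})

test_that("rank-sum p-values match the exact combinatorial oracle", {
  # 4 replicates all above 8 reference spots: p = 1 / C(12, 4)
  layout_cols <- tibble::tibble(
    gene = c(rep("G1", 4), rep(NA, 8)),
    sirna = c(rep("G1_si1", 4), rep(NA, 8)),
    role = c(rep("sample", 4), rep("mock", 8)))
  sig <- dplyr::bind_cols(layout_cols,
                          tibble::tibble(phenotype = "cell_death",
                                         time_frame = 1,
                                         auc = c(9:12, 1:8)))
  sig <- dplyr::bind_rows(sig, dplyr::mutate(sig, phenotype = "mitosis"))
  p <- phenotype_pvalues(sig)$p[1]
  expect_equal(p, 1 / choose(12, 4))
  # independent oracle: enumerate every placement of the 4 replicate ranks
  ranks <- utils::combn(12, 4)
  stat <- colSums(ranks)
  p_brute <- mean(stat >= sum(9:12))
  expect_equal(p, p_brute)
})

test_that("rank-sum p-values are direction-sensitive and tie-safe", {
  base <- tibble::tibble(
    gene = c(rep("G1", 4), rep(NA, 8)),
    sirna = c(rep("G1_si1", 4), rep(NA, 8)),
    role = c(rep("sample", 4), rep("mock", 8)),
    phenotype = "mitosis", time_frame = 1)
  tied <- dplyr::mutate(base, auc = 5)        # identical constants
  expect_equal(phenotype_pvalues(tied, phenotypes = "mitosis")$p, 1)
  below <- dplyr::mutate(base, auc = c(1:4, 5:12)) # replicates lowest
  expect_gt(phenotype_pvalues(below, phenotypes = "mitosis")$p[1], 0.5)
})

test_that("rank-sum p-values are invariant to monotone rescaling", {
  set.seed(8)
  sig <- tibble::tibble(
    gene = c(rep("G1", 4), rep(NA, 20)),
    sirna = c(rep("G1_si1", 4), rep(NA, 20)),
    role = c(rep("sample", 4), rep("mock", 20)),
    phenotype = "mitosis", time_frame = 1,
    auc = stats::rnorm(24))
  p1 <- phenotype_pvalues(sig, phenotypes = "mitosis")$p
  sig2 <- dplyr::mutate(sig, auc = exp(3 * .data$auc + 2))
  p2 <- phenotype_pvalues(sig2, phenotypes = "mitosis")$p
  expect_equal(p1, p2)
})

test_that("the death-in/after-mitosis rule drives candidate calls", {
  mk_profile <- function(gene, pm, pd) {
    dplyr::bind_rows(
      tibble::tibble(gene = gene, sirna = paste0(gene, "_si1"),
                     phenotype = "mitosis", time_frame = seq_along(pm),
                     p = pm),
      tibble::tibble(gene = gene, sirna = paste0(gene, "_si1"),
                     phenotype = "cell_death", time_frame = seq_along(pd),
                     p = pd))
  }
  pm <- rep(1, 13); pd <- rep(1, 13)
  # death one frame after mitosis: candidate with t0 = 5
  pm5 <- replace(pm, 5, 0.01); pd6 <- replace(pd, 6, 0.03)
  out <- call_candidates(mk_profile("A", pm5, pd6), level = "sirna")
  expect_true(out$candidate)
  expect_equal(out$t0, 5)
  # death two frames later: no candidate
  pd7 <- replace(pd, 7, 0.04)
  expect_false(call_candidates(mk_profile("B", pm5, pd7),
                               level = "sirna")$candidate)
  # boundary: p exactly 0.05 on both at the same frame counts
  pm2 <- replace(pm, 2, 0.05); pd2 <- replace(pd, 2, 0.05)
  expect_true(call_candidates(mk_profile("C", pm2, pd2),
                              level = "sirna")$candidate)
  # gene level: any siRNA flags the gene
  two <- dplyr::bind_rows(
    mk_profile("D", pm5, pd6),
    dplyr::mutate(mk_profile("D", pm, pd), sirna = "D_si2"))
  g <- call_candidates(two, level = "gene")
  expect_true(g$candidate)
  expect_equal(g$sirnas_flagged, 1)
})

test_that("hypergeometric overlap enrichment matches enumeration", {
  expect_equal(overlap_enrichment(10, 4, 5, 4), 5 / 210)
  # brute-force oracle: enumerate all C(10, 5) draws of list B
  draws <- utils::combn(10, 5)
  marked <- seq_len(4)
  ov <- apply(draws, 2, function(d) sum(d %in% marked))
  expect_equal(overlap_enrichment(10, 4, 5, 4), mean(ov >= 4))
  expect_equal(overlap_enrichment(10, 4, 5, 0), 1)
  expect_equal(overlap_enrichment(10, 10, 5, 5), 1)
  expect_error(overlap_enrichment(10, 4, 5, 6), "inconsistent")
})

test_that("periodicity fitting recovers a known period from 40 frames", {
  tt <- seq(0, 120, 2 / 3)
  yy <- 0.03 * sin(2 * pi * tt / 35 + 1) + 0.001 * tt + 0.4
  fit <- fit_periodicity(yy, tt, integration = 3)
  expect_equal(fit$n_frames, 40)
  expect_equal(fit$period, 35, tolerance = 0.1 / 35)
  expect_equal(fit$amplitude, 0.03, tolerance = 0.05)
  expect_true(fit$identifiable)
  # broom-style accessors
  td <- generics::tidy(fit)
  expect_equal(td$estimate[td$term == "period_h"], fit$period)
  expect_true(generics::glance(fit)$identifiable)
})

test_that("a trend without oscillation is flagged unidentifiable", {
  tt <- seq(0, 120, 2 / 3)
  fit <- fit_periodicity(0.002 * tt + 1, tt)
  expect_false(fit$identifiable)
  expect_equal(fit$amplitude, 0)
  expect_true(is.na(fit$period))
})

test_that("control QC flags reduced proliferation of positive controls", {
  base <- tidyr::expand_grid(spot = 1:8, time_frame = 1:5)
  base$phenotype <- "interphase"
  base$role <- ifelse(base$spot <= 4, "positive_control", "negative_control")
  base$auc <- ifelse(base$role == "positive_control", 10, 50) +
    withr::with_seed(10, stats::rnorm(nrow(base)))
  qc <- qc_controls(base)
  expect_true(all(qc$pass))
  expect_false(any(qc$underpowered))
  # single spot per arm: underpowered, not significant
  single <- dplyr::filter(base, .data$spot %in% c(1, 5))
  qc1 <- qc_controls(single)
  expect_true(all(qc1$underpowered))
  expect_true(all(qc1$p >= 0.5))
  expect_error(qc_controls(dplyr::filter(base, .data$role ==
                                           "negative_control")),
               "missing controls")
})
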