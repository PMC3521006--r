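traj <- function(labels, branch = 1, parent = NA_integer_,
                 frames = NULL, cluster = NULL) {
  n <- length(labels)
  out <- tibble::tibble(
    branch_id = branch, parent_branch = parent,
    frame = if (is.null(frames)) seq_len(n) else frames,
    object_id = seq_len(n), label = labels)
  if (!is.null(cluster)) out$is_cluster <- cluster
  out
}

split_fixture <- function(mother_labels, d1_labels, d2_labels) {
  nm <- length(mother_labels)
  dplyr::bind_rows(
    traj(mother_labels, branch = 1),
    tibble::tibble(branch_id = 2, parent_branch = 1,
                   frame = nm + seq_along(d1_labels),
                   object_id = 100 + seq_along(d1_labels),
                   label = d1_labels),
    tibble::tibble(branch_id = 3, parent_branch = 1,
                   frame = nm + seq_along(d2_labels),
                   object_id = 200 + seq_along(d2_labels),
                   label = d2_labels))
}

test_that("rule 1 relabels split mothers and daughters as mitosis", {
  lab <- split_fixture(rep("interphase", 3),
                       rep("interphase", 2), rep("interphase", 2))
  out <- apply_correction(lab)
  mother_last <- out$corrected_label[out$branch_id == 1 & out$frame == 3]
  d_first <- out$corrected_label[out$frame == 4]
  expect_equal(mother_last, "mitosis")
  expect_equal(d_first, rep("mitosis", 2))
  expect_equal(out$rule[out$branch_id == 1 & out$frame == 3], "R1")
  # non-split, non-daughter objects untouched
  expect_equal(out$corrected_label[out$branch_id == 1 & out$frame < 3],
               rep("interphase", 2))
})

test_that("rule 2 corrects isolated mitosis calls to interphase", {
  out <- apply_correction(traj(c("interphase", "mitosis", "interphase",
                                 "interphase", "interphase", "interphase")))
  expect_equal(out$corrected_label[2], "interphase")
  expect_equal(out$rule[2], "R2")
})

test_that("rule 2 keeps mitosis near splits, before clusters, before death", {
  # within K = 2 frames of a split on the same branch
  lab <- split_fixture(c("interphase", "mitosis", "interphase", "interphase"),
                       rep("interphase", 2), rep("interphase", 2))
  out <- apply_correction(lab, lookaround = 2)
  expect_equal(out$corrected_label[out$branch_id == 1][2], "mitosis")
  expect_equal(out$rule[out$branch_id == 1][2], "none")
  # succeeded by a cluster object
  lab2 <- traj(c("interphase", "mitosis", "interphase"),
               cluster = c(FALSE, FALSE, TRUE))
  out2 <- apply_correction(lab2)
  expect_equal(out2$corrected_label[2], "mitosis")
  # succeeded by cell death (and the death run is kept by rule 3)
  out3 <- apply_correction(traj(c("interphase", "mitosis", "cell_death",
                                  "cell_death", "cell_death")))
  expect_equal(out3$corrected_label[2], "mitosis")
  expect_equal(out3$corrected_label[3], "cell_death")
})

test_that("rule 3 removes death blips and honours the 50% tie", {
  # one-frame blip: 0% of the remaining trajectory is death
  out <- apply_correction(traj(c("interphase", "cell_death", "interphase",
                                 "interphase", "interphase")))
  expect_equal(out$corrected_label[2], "interphase")
  expect_equal(out$rule[2], "R3")
  # exactly 50% of the remainder is death: kept ("at least 50%")
  out2 <- apply_correction(traj(c("cell_death", "cell_death", "interphase",
                                  "cell_death", "interphase")))
  expect_equal(out2$corrected_label[1], "cell_death")
})

test_that("artifact labels pass through every rule unchanged", {
  lab <- split_fixture(c("interphase", "artifact", "interphase"),
                       c("artifact", "interphase"), rep("interphase", 2))
  out <- apply_correction(lab)
  expect_true(all(out$corrected_label[out$label == "artifact"] == "artifact"))
  expect_true(all(out$corrected_label %in%
                    c("interphase", "mitosis", "cell_death", "artifact")))
})

test_that("correction improves noisy labels on a truth-labelled movie", {
  cfg <- sim_config(n_cells_initial = 40, total_duration = 90)
  truth <- simulate_population(
    cfg, knockdown_effect("interphase_death", penetrance = 0.35,
                          onset = 30, delay = 15), seed = 7)
  tt <- truth_trajectories(truth)
  noisy <- withr::with_seed(42, {
    flip <- stats::runif(nrow(tt)) < 0.10
    lab <- tt$label
    lab[flip & tt$label %in% c("mitosis", "cell_death")] <- "interphase"
    i_flip <- flip & tt$label == "interphase"
    lab[i_flip] <- sample(c("mitosis", "cell_death"), sum(i_flip),
                          replace = TRUE)
    lab
  })
  lab <- tt
  lab$label <- noisy
  corr <- apply_correction(lab)
  ev <- evaluate_correction(tt$label, noisy, corr$corrected_label)
  expect_gt(ev$after$accuracy, ev$before$accuracy)
  rec <- function(r) r$per_class$recall[r$per_class$class == "mitosis"]
  expect_gt(rec(ev$after), rec(ev$before))
})

test_that("a second correction pass changes almost nothing at baseline", {
  cfg <- sim_config(n_cells_initial = 40, total_duration = 90)
  truth <- simulate_population(cfg, seed = 8)
  tt <- truth_trajectories(truth)
  noisy <- withr::with_seed(43, {
    flip <- stats::runif(nrow(tt)) < 0.10
    lab <- tt$label
    lab[flip & tt$label %in% c("mitosis", "cell_death")] <- "interphase"
    i_flip <- flip & tt$label == "interphase"
    lab[i_flip] <- sample(c("mitosis", "cell_death"), sum(i_flip),
                          replace = TRUE)
    lab
  })
  lab <- tt
  lab$label <- noisy
  corr <- apply_correction(lab)
  second <- apply_correction(dplyr::mutate(corr,
                                           label = .data$corrected_label))
  expect_lte(mean(second$corrected_label != corr$corrected_label), 0.01)
})

test_that("evaluation reports are consistent and guard alignment", {
  truth <- c("interphase", "mitosis", "cell_death")
  expect_equal(evaluate_correction(truth, truth, truth)$after$accuracy, 1)
  same <- evaluate_correction(truth, c("interphase", "mitosis", "mitosis"),
                              c("interphase", "mitosis", "mitosis"))
  expect_equal(same$before, same$after)
  expect_equal(same$delta, 0)
  expect_error(evaluate_correction(truth, truth[1:2], truth), "mismatch")
})
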