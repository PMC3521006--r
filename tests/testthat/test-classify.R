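test_that("class weights follow the largest-class rule", {
  labels <- rep(c("interphase", "mitosis", "cell_death", "artifact"),
                c(174, 94, 204, 118)) # typical annotation imbalance
  w <- class_weights(labels)
  expect_equal(unname(w["cell_death"]), 1)
  expect_equal(unname(w["mitosis"]), 204 / 94)
  expect_equal(unname(w["interphase"]), 204 / 174)
  expect_true(all(w >= 1))
})

test_that("grid search covers the full default grid and separates blobs", {
  train <- blob_training(20, list(a = c(0, 0), b = c(40, 40)), sd = 5,
                         seed = 2)
  model <- train_classifier(train, inner_folds = 5, seed = 1)
  expect_equal(nrow(model$grid), 10 * 11) # 110 (C, gamma) pairs
  expect_equal(min(model$grid$error), 0)  # separable: some pair errs 0
  # tie-break: smallest C, then smallest gamma among zero-error pairs
  zero <- model$grid[model$grid$error == 0, ]
  expect_equal(model$C, min(zero$C))
  expect_equal(model$gamma, min(zero$gamma[zero$C == model$C]))
  held_out <- tibble::tibble(f1 = c(-5, 45), f2 = c(2, 38))
  pred <- predict_with_reliability(model, held_out)
  expect_equal(pred$pred_label, c("a", "b"))
})

test_that("degenerate training sets are rejected", {
  one_class <- blob_training(20, list(a = c(0, 0)), seed = 3)
  expect_error(train_classifier(one_class), "2 classes")
  tiny <- blob_training(3, list(a = c(0, 0), b = c(4, 4)), seed = 3)
  expect_error(train_classifier(tiny, inner_folds = 10), "degenerate class")
})

test_that("reliability is the gap between the top two likelihoods", {
  expect_equal(reliability_score(c(0.50, 0.35, 0.10, 0.05)), 0.15)
  expect_equal(reliability_score(c(0.97, 0.01, 0.01, 0.01)), 0.96)
  expect_equal(reliability_score(rep(0.25, 4)), 0)
})

test_that("the reliability filter discards r <= threshold inclusively", {
  preds <- tibble::tibble(object_id = 1:3,
                          reliability = c(0.15, 0.21, 0.20))
  flt <- reliability_filter(preds, threshold = 0.2)
  expect_equal(flt$kept$object_id, 2)
  expect_equal(sort(flt$discarded$object_id), c(1, 3))
  empty <- reliability_filter(preds[0, ])
  expect_equal(nrow(empty$kept), 0)
  expect_equal(nrow(empty$discarded), 0)
})

test_that("posterior likelihoods are a proper distribution with argmax label", {
  train <- blob_training(25, list(a = c(0, 0), b = c(3, 3), c = c(-3, 3)),
                         seed = 4)
  model <- train_classifier(train, C_grid = 2^(1:3),
                            gamma_grid = 2^c(-4, -2), inner_folds = 5,
                            seed = 2)
  pred <- predict_with_reliability(model, train)
  lik <- as.matrix(pred[paste0("l_", model$levels)])
  expect_equal(unname(rowSums(lik)), rep(1, nrow(lik)), tolerance = 1e-6)
  # on confidently classified samples the posteriors agree with the vote
  sure <- pred$reliability > 0.5
  expect_gt(mean(sure), 0.5)
  expect_equal(pred$pred_label[sure],
               model$levels[max.col(lik)][sure])
  expect_error(predict_with_reliability(model,
                                        tibble::tibble(f1 = 1)),
               "feature mismatch")
})

test_that("nested cross-validation is honest: permuted labels score at chance", {
  train <- blob_training(15, list(a = c(0, 0), b = c(4, 4),
                                  c = c(4, 0), d = c(0, 4)), seed = 5)
  cv <- cross_validate(train, C_grid = 2^(1:3), gamma_grid = 2^c(-4, -2),
                       inner_folds = 5, seed = 6)
  expect_gte(cv$accuracy, 0.95)
  perm <- train
  perm$label <- withr::with_seed(7, sample(perm$label))
  cv_perm <- cross_validate(perm, C_grid = 2^(1:3),
                            gamma_grid = 2^c(-4, -2), inner_folds = 5,
                            seed = 6)
  # binomial null around 1/4 for 60 samples: 3 sd band
  expect_lt(cv_perm$accuracy, 0.25 + 3 * sqrt(0.25 * 0.75 / 60))
})

test_that("leave-one-out-style outer folds fit one model per fold", {
  train <- blob_training(5, list(a = c(0, 0), b = c(4, 4)), seed = 8)
  cv <- cross_validate(train, outer_folds = 10, inner_folds = 2,
                       C_grid = 2^(1:2), gamma_grid = 2^c(-3, -1), seed = 9)
  expect_equal(nrow(cv$per_fold), 10)
  expect_equal(sum(cv$per_fold$n_test), 10)
  expect_equal(sum(cv$confusion), 10)
})

test_that("class weighting protects minority-class recall", {
  # heavily imbalanced, overlapping blobs
  train <- dplyr::bind_rows(
    blob_training(200, list(major = c(0, 0)), sd = 1.2, seed = 10),
    blob_training(14, list(minor = c(2.2, 2.2)), sd = 1.2, seed = 11))
  test <- dplyr::bind_rows(
    blob_training(100, list(major = c(0, 0)), sd = 1.2, seed = 12),
    blob_training(100, list(minor = c(2.2, 2.2)), sd = 1.2, seed = 13))
  xm <- as.matrix(train[c("f1", "f2")])
  y <- factor(train$label)
  fit_w <- e1071::svm(xm, y, kernel = "radial", cost = 4, gamma = 0.25,
                      class.weights = class_weights(y))
  fit_u <- e1071::svm(xm, y, kernel = "radial", cost = 4, gamma = 0.25)
  tst <- as.matrix(test[c("f1", "f2")])
  rec <- function(fit) {
    mean(stats::predict(fit, tst)[test$label == "minor"] == "minor")
  }
  expect_gte(rec(fit_w), rec(fit_u))
})

test_that("grid selection is reproducible under a fixed seed", {
  train <- blob_training(12, list(a = c(0, 0), b = c(2, 2)), sd = 1,
                         seed = 14)
  m1 <- train_classifier(train, C_grid = 2^(1:3), gamma_grid = 2^c(-3, -1),
                         inner_folds = 4, seed = 5)
  m2 <- train_classifier(train, C_grid = 2^(1:3), gamma_grid = 2^c(-3, -1),
                         inner_folds = 4, seed = 5)
  expect_identical(m1$grid, m2$grid)
  expect_identical(c(m1$C, m1$gamma), c(m2$C, m2$gamma))
})
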