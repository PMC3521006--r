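#' Class weights for an imbalanced training set
#'
#' Stratifies an imbalanced training set by weighting each sample of class
#' c by `w_c = n_l / n_c`, where `n_l` is the size of the largest class.
#' The largest class has weight 1 and all weights are >= 1.
#'
#' @param labels Factor or character vector of class labels.
#' @return Named numeric vector of weights, one per class.
#' @export
class_weights <- function(labels) {
  n <- table(labels)
  w <- max(n) / n
  stats::setNames(as.numeric(w), names(n))
}

# stratified fold assignment, seeded
.make_folds <- function(labels, k, seed) {
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

.check_training <- function(training, inner_folds) {
  stopifnot("label" %in% names(training))
  n <- table(training$label)
  n <- n[n > 0]
  if (length(n) < 2) stop("degenerate training set: need at least 2 classes")
  if (any(n < inner_folds)) {
    stop("degenerate class: ", paste(names(n)[n < inner_folds], collapse = ", "),
         " has fewer samples than inner folds (", inner_folds, ")")
  }
  invisible(NULL)
}

.feature_matrix <- function(data, feature_names = NULL) {
  if (is.null(feature_names)) {
    feature_names <- setdiff(names(data), "label")
    feature_names <- feature_names[vapply(data[feature_names], is.numeric,
                                          logical(1))]
  } else if (!all(feature_names %in% names(data))) {
    stop("feature mismatch: missing column(s) ",
         paste(setdiff(feature_names, names(data)), collapse = ", "))
  }
  as.matrix(data[feature_names])
}

#' Train a class-weighted SVM-RBF phenotype classifier
#'
#' One-against-one multiclass SVM with a radial-basis kernel. The cost C
#' and kernel width gamma are chosen by grid search (defaults: C = 2^1..2^10,
#' gamma = 2^-16..2^-6, 110 pairs), scored by seeded `inner_folds`-fold
#' cross-validated class-weighted misclassification; ties prefer the
#' smaller C, then the smaller gamma (smoother models). The returned model
#' is refit on the full training set with class weights and a posterior
#' probability model (pairwise coupling).
#'
#' @param training Tibble with a `label` column plus numeric feature
#'   columns. Every class needs at least `inner_folds` samples.
#' @param C_grid,gamma_grid Numeric grids for the search.
#' @param inner_folds Folds of the inner cross-validation.
#' @param seed Integer seed for the fold assignment.
#' @return A `nuclei_svm` object: the fitted model, the grid with
#'   cross-validated errors, the chosen `(C, gamma)`, class weights and
#'   feature names.
#' @export
train_classifier <- function(training, C_grid = 2^(1:10),
                             gamma_grid = 2^(-16:-6),
                             inner_folds = 10, seed = 1) {
  .check_training(training, inner_folds)
  y <- factor(training$label)
  xm <- .feature_matrix(training)
  keep <- apply(xm, 2, stats::sd) > 1e-12
  xm <- xm[, keep, drop = FALSE]
  w <- class_weights(y)
  fold <- .make_folds(y, inner_folds, seed)

  grid <- tidyr::expand_grid(C = sort(C_grid), gamma = sort(gamma_grid))
  grid <- dplyr::arrange(grid, .data$C, .data$gamma)
  err <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    e <- 0
    for (k in seq_len(inner_folds)) {
      tr <- fold != k
      fit <- e1071::svm(xm[tr, , drop = FALSE], y[tr], kernel = "radial",
                        cost = grid$C[g], gamma = grid$gamma[g],
                        class.weights = w)
      pred <- stats::predict(fit, xm[!tr, , drop = FALSE])
      wrong <- pred != y[!tr]
      e <- e + sum(w[as.character(y[!tr][wrong])])
    }
    err[g] <- e
  }
  best <- which.min(err) # grid sorted by C then gamma: ties resolve as spec'd
  model <- e1071::svm(xm, y, kernel = "radial",
                      cost = grid$C[best], gamma = grid$gamma[best],
                      class.weights = w, probability = TRUE)
  structure(list(
    model = model,
    feature_names = colnames(xm),
    levels = levels(y),
    weights = w,
    grid = dplyr::mutate(grid, error = err),
    C = grid$C[best], gamma = grid$gamma[best],
    seed = seed
  ), class = "nuclei_svm")
}

#' @export
print.nuclei_svm <- function(x, ...) {
  cat("SVM-RBF phenotype classifier (", length(x$levels), " classes, ",
      length(x$feature_names), " features)\n", sep = "")
  cat("  chosen C =", x$C, ", gamma =", x$gamma, "\n")
  cat("  class weights:",
      paste(names(x$weights), round(x$weights, 2), sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Predict phenotype labels with posterior likelihoods and reliability
#'
#' Applies a trained classifier and reports, per object, the posterior
#' likelihood of every class (a proper distribution from pairwise
#' coupling), the predicted label (the machine's one-against-one voting
#' decision) and the reliability score `r = |l1 - l2|`, the gap between
#' the two largest likelihoods. Ambiguous objects have small r; for them
#' the coupled posteriors may also disagree with the voting decision,
#' which is precisely what the reliability filter removes.
#'
#' @param model A `nuclei_svm` from [train_classifier()].
#' @param objects Tibble containing the model's feature columns.
#' @return `objects` with appended `pred_label`, one `l_<class>` column per
#'   class, and `reliability`.
#' @export
predict_with_reliability <- function(model, objects) {
  if (nrow(objects) == 0) {
    return(dplyr::mutate(objects, pred_label = character(0),
                         reliability = numeric(0)))
  }
  xm <- .feature_matrix(objects, model$feature_names)
  # the vote must come from a plain predict: with probability = TRUE libsvm
  # labels by the coupled posteriors, whose Platt calibration is fitted on
  # an internal random CV and is not reproducible across call histories
  vote <- stats::predict(model$model, xm)
  pred <- stats::predict(model$model, xm, probability = TRUE)
  probs <- attr(pred, "probabilities")[, model$levels, drop = FALSE]
  top2 <- t(apply(probs, 1, function(p) sort(p, decreasing = TRUE)[1:2]))
  out <- objects
  # label: the one-vs-one voting decision of the machine itself; the
  # coupled posteriors provide the likelihoods and the reliability gap
  out$pred_label <- as.character(vote)
  for (cl in model$levels) out[[paste0("l_", cl)]] <- probs[, cl]
  out$reliability <- top2[, 1] - top2[, 2]
  out
}

#' Reliability score from class likelihoods
#'
#' @param likelihoods Numeric vector (or matrix with one row per object) of
#'   class likelihoods.
#' @return `|l1 - l2|`, the gap between the two largest likelihoods.
#' @examples
#' reliability_score(c(0.50, 0.35, 0.10, 0.05)) # 0.15
#' @export
reliability_score <- function(likelihoods) {
  if (is.matrix(likelihoods)) {
    apply(likelihoods, 1, reliability_score)
  } else {
    s <- sort(likelihoods, decreasing = TRUE)
    abs(s[1] - s[2])
  }
}

#' Discard ambiguous predictions
#'
#' Objects with reliability `r <= threshold` are discarded from phenotype
#' counting; they keep their identity (rows are returned, not dropped) so
#' that tracking can pass through them.
#'
#' @param predictions Tibble with a `reliability` column, e.g. from
#'   [predict_with_reliability()].
#' @param threshold Reliability cut-off; `r <= threshold` is discarded.
#' @return List with `kept` and `discarded` tibbles.
#' @export
reliability_filter <- function(predictions, threshold = 0.2) {
  if (nrow(predictions) == 0) {
    return(list(kept = predictions, discarded = predictions))
  }
  keep <- predictions$reliability > threshold
  list(kept = predictions[keep, , drop = FALSE],
       discarded = predictions[!keep, , drop = FALSE])
}

#' Nested cross-validation of the phenotype classifier
#'
#' Outer stratified folds estimate performance; the (C, gamma) grid search
#' is re-run inside every outer training split, so no test sample ever
#' influences its own model. Reports aggregated confusion matrices, plain
#' and balanced (mean per-class recall) accuracy, and the parameters
#' chosen per fold.
#'
#' @param training Tibble with `label` plus feature columns.
#' @param outer_folds,inner_folds Fold counts of the two loops.
#' @param C_grid,gamma_grid Grids for the inner search.
#' @param seed Integer seed (fold assignments and inner seeds derive from
#'   it).
#' @return A `nuclei_cv` object: `confusion` (classes x classes matrix,
#'   true class in columns), `accuracy`, `balanced_accuracy`, `per_class`
#'   recall/precision, `per_fold` chosen parameters and accuracies.
#' @export
cross_validate <- function(training, outer_folds = 5, inner_folds = 10,
                           C_grid = 2^(1:10), gamma_grid = 2^(-16:-6),
                           seed = 1) {
  .check_training(training, inner_folds)
  y <- factor(training$label)
  fold <- .make_folds(y, outer_folds, seed)
  classes <- levels(y)
  confusion <- matrix(0L, length(classes), length(classes),
                      dimnames = list(predicted = classes, true = classes))
  per_fold <- list()
  for (k in seq_len(outer_folds)) {
    tr <- training[fold != k, , drop = FALSE]
    te <- training[fold == k, , drop = FALSE]
    mod <- train_classifier(tr, C_grid = C_grid, gamma_grid = gamma_grid,
                            inner_folds = inner_folds, seed = seed + k)
    pred <- predict_with_reliability(mod, te)
    tab <- table(factor(pred$pred_label, levels = classes),
                 factor(te$label, levels = classes))
    confusion <- confusion + as.matrix(tab)
    per_fold[[k]] <- tibble::tibble(
      fold = k, C = mod$C, gamma = mod$gamma,
      n_test = nrow(te),
      accuracy = mean(pred$pred_label == as.character(te$label)))
  }
  recall <- diag(confusion) / pmax(colSums(confusion), 1)
  precision <- diag(confusion) / pmax(rowSums(confusion), 1)
  structure(list(
    confusion = confusion,
    accuracy = sum(diag(confusion)) / sum(confusion),
    balanced_accuracy = mean(recall),
    per_class = tibble::tibble(class = classes, recall = recall,
                               precision = precision),
    per_fold = dplyr::bind_rows(per_fold),
    outer_folds = outer_folds, inner_folds = inner_folds, seed = seed
  ), class = "nuclei_cv")
}

#' @export
print.nuclei_cv <- function(x, ...) {
  cat("Nested cross-validation (", x$outer_folds, " outer x ",
      x$inner_folds, " inner folds)\n", sep = "")
  cat(sprintf("  overall accuracy  %.1f%%\n", 100 * x$accuracy))
  cat(sprintf("  balanced accuracy %.1f%%\n", 100 * x$balanced_accuracy))
  cat("  confusion matrix (true class in columns):\n")
  print(x$confusion)
  invisible(x)
}
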