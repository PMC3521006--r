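#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a periodicity fit
#'
#' @param x A `period_fit` from [fit_periodicity()].
#' @param ... Unused.
#' @return One row per model term with its estimate.
#' @export
tidy.period_fit <- function(x, ...) {
  tibble::tibble(
    term = c("amplitude", "period_h", "phase_rad", "slope", "intercept"),
    estimate = c(x$amplitude, x$period, x$phase, x$slope, x$intercept))
}

#' @rdname tidy.period_fit
#' @export
glance.period_fit <- function(x, ...) {
  tibble::tibble(period_h = x$period, amplitude = x$amplitude,
                 rss = x$rss, sigma = x$sigma, n_frames = x$n_frames,
                 identifiable = x$identifiable)
}

#' Tidy a nested cross-validation report
#'
#' @param x A `nuclei_cv` from [cross_validate()].
#' @param ... Unused.
#' @return Per-class recall and precision.
#' @export
tidy.nuclei_cv <- function(x, ...) x$per_class

#' @rdname tidy.nuclei_cv
#' @export
glance.nuclei_cv <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy,
                 balanced_accuracy = x$balanced_accuracy,
                 outer_folds = x$outer_folds, inner_folds = x$inner_folds)
}

#' Tidy a trained classifier's grid search
#'
#' @param x A `nuclei_svm` from [train_classifier()].
#' @param ... Unused.
#' @return The (C, gamma) grid with cross-validated weighted errors.
#' @export
tidy.nuclei_svm <- function(x, ...) x$grid

#' @rdname tidy.nuclei_svm
#' @export
glance.nuclei_svm <- function(x, ...) {
  tibble::tibble(C = x$C, gamma = x$gamma,
                 n_features = length(x$feature_names),
                 n_classes = length(x$levels))
}
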