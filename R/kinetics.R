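#' Median absolute deviation (unscaled)
#'
#' The robust scale estimate used by B-score normalization:
#' `median(|x - median(x)|)`, with no consistency constant.
#'
#' @param values Non-empty numeric vector (`NA`s dropped).
#' @return A scalar.
#' @examples
#' median_absolute_deviation(c(1, 1, 2, 2, 4, 6, 9)) # 1
#' @export
median_absolute_deviation <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("empty input: need at least one value")
  stats::mad(values, constant = 1)
}

# B-score one plate/timepoint vector given row/col indices
.bscore_vec <- function(x, row, col, scale = TRUE) {
  if (all(is.na(x))) stop("all-masked plate: no values to normalize")
  mu <- mean(x, na.rm = TRUE)
  mr <- tapply(x, row, mean, na.rm = TRUE)
  mc <- tapply(x, col, mean, na.rm = TRUE)
  resid <- x - mr[as.character(row)] - mc[as.character(col)] + mu
  if (!scale) return(as.numeric(resid))
  mad <- median_absolute_deviation(resid)
  if (mad == 0) {
    out <- ifelse(is.na(resid), NA_real_, 0)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  as.numeric(resid / mad)
}

#' B-score normalization of plate count tables
#'
#' Removes additive row and column (spatial/edge) effects from each plate
#' at each timepoint and rescales robustly: the residual at row r, column c
#' is `x - rowmean(r) - colmean(c) + platemean`, which has exactly zero row
#' and column means, and is then divided by the plate's median absolute
#' deviation of residuals. A plate whose residual MAD is zero (e.g. a
#' perfectly additive plate) yields all zeros with a warning.
#'
#' @param counts Tidy count table with `row`, `col`, the grouping columns in
#'   `by`, and the count columns in `value_cols`. Masked (empty) spots may
#'   be `NA`.
#' @param value_cols Columns to normalize (one per phenotype class).
#' @param by Columns defining one plate at one timepoint.
#' @param scale If `FALSE`, return the additive residuals without MAD
#'   scaling (useful for checking the zero-mean identity).
#' @return `counts` with `value_cols` replaced by their B-scores.
#' @export
bscore_normalize <- function(counts,
                             value_cols = intersect(
                               c("interphase", "mitosis", "cell_death",
                                 "artifact", "value"), names(counts)),
                             by = intersect(c("array_id", "frame"),
                                            names(counts)),
                             scale = TRUE) {
  stopifnot(all(c("row", "col") %in% names(counts)),
            length(value_cols) > 0)
  n_degenerate <- 0L
  wrap <- function(x, row, col) {
    out <- .bscore_vec(x, row, col, scale = scale)
    if (isTRUE(attr(out, "degenerate"))) {
      n_degenerate <<- n_degenerate + 1L
    }
    as.numeric(out)
  }
  out <- dplyr::group_by(counts, dplyr::across(dplyr::all_of(by)))
  out <- dplyr::mutate(out, dplyr::across(
    dplyr::all_of(value_cols), ~ wrap(.x, .data$row, .data$col)))
  out <- dplyr::ungroup(out)
  if (n_degenerate > 0) {
    warning(n_degenerate,
            " plate/timepoint group(s) had zero residual MAD; set to 0")
  }
  out
}

# exact integral of the piecewise-linear trace (t, v) over [a, b]
.trapz_window <- function(t, v, a, b) {
  f <- stats::approxfun(t, v, rule = 2)
  sel <- t > a & t < b
  ts <- c(a, t[sel], b)
  vs <- c(f(a), v[sel], f(b))
  pracma::trapz(ts, vs)
}

#' Windowed phenotype signals (area under the curve per time-frame)
#'
#' Slices each spot's (normalized) count trace into overlapping
#' time-frames -- by default 24 h windows shifted by 8 h, giving 13 frames
#' over a 120 h screen -- and integrates the trace over each window with
#' the trapezoidal rule against the actual acquisition times. The AUC of a
#' window is the phenotype signal of that time-frame.
#'
#' @param counts Tidy table with `time_h`, the columns in `value_cols`, and
#'   id columns identifying each spot trace (all remaining columns except
#'   `frame`).
#' @param window Window width in hours.
#' @param shift Shift between consecutive windows in hours.
#' @param value_cols Count columns to integrate.
#' @return Tibble with the spot id columns plus `phenotype`, `time_frame`,
#'   `t_start`, `t_end`, `auc`.
#' @export
window_signal <- function(counts, window = 24, shift = 8,
                          value_cols = intersect(
                            c("interphase", "mitosis", "cell_death",
                              "artifact", "value"), names(counts))) {
  stopifnot("time_h" %in% names(counts))
  span <- max(counts$time_h) - min(counts$time_h)
  if (span < window) stop("time span (", span, " h) shorter than window")
  t0 <- min(counts$time_h)
  n_frames <- floor((span - window) / shift) + 1
  starts <- t0 + (seq_len(n_frames) - 1) * shift
  id_cols <- setdiff(names(counts), c(value_cols, "frame", "time_h"))

  long <- tidyr::pivot_longer(counts, dplyr::all_of(value_cols),
                              names_to = "phenotype", values_to = "count")
  long <- dplyr::group_by(long,
                          dplyr::across(dplyr::all_of(c(id_cols, "phenotype"))))
  out <- dplyr::reframe(long, {
    auc <- vapply(starts, function(a) {
      .trapz_window(.data$time_h, .data$count, a, a + window)
    }, numeric(1))
    tibble::tibble(time_frame = seq_len(n_frames), t_start = starts,
                   t_end = starts + window, auc = auc)
  })
  out
}

#' Per-time-frame significance of a knockdown's phenotype signal
#'
#' For every gene, siRNA, phenotype and time-frame, compares the AUC
#' signals of the siRNA's replicate spots against a reference population
#' (all sample and mock spots of the screen; positive controls excluded)
#' with a one-sided Wilcoxon rank-sum test (alternative: replicates
#' elevated). The exact null distribution is used automatically when both
#' groups are small and untied, the normal approximation with tie
#' correction otherwise.
#'
#' @param signal Output of [window_signal()] carrying layout columns
#'   `gene`, `sirna`, `role`.
#' @param phenotypes Phenotype classes to score.
#' @param alternative Test direction (default `"greater"`: elevated signal).
#' @param reference_roles Spot roles forming the reference population.
#' @return Tibble `gene`, `sirna`, `phenotype`, `time_frame`, `n_replicates`,
#'   `p`.
#' @export
phenotype_pvalues <- function(signal,
                              phenotypes = c("mitosis", "cell_death"),
                              alternative = "greater",
                              reference_roles = c("sample", "mock")) {
  stopifnot(all(c("gene", "sirna", "role", "phenotype", "time_frame",
                  "auc") %in% names(signal)))
  sig <- dplyr::filter(signal, .data$phenotype %in% phenotypes)
  ref <- dplyr::filter(sig, .data$role %in% reference_roles)
  if (nrow(ref) == 0) stop("reference population is empty")
  strata <- paste(ref$phenotype, ref$time_frame, sep = ".")
  ref_split <- split(ref$auc, strata)
  # tag of the spot each reference value came from, to exclude a
  # siRNA's own replicates from its reference population
  tag_split <- split(paste(ref$gene, ref$sirna, sep = "\r"), strata)

  reps <- dplyr::filter(sig, .data$role == "sample", !is.na(.data$gene))
  reps <- dplyr::group_by(reps, .data$gene, .data$sirna, .data$phenotype,
                          .data$time_frame)
  out <- dplyr::summarise(reps, n_replicates = dplyr::n(), {
    key <- paste(.data$phenotype[1], .data$time_frame[1], sep = ".")
    own <- paste(.data$gene[1], .data$sirna[1], sep = "\r")
    pop <- ref_split[[key]][tag_split[[key]] != own]
    if (dplyr::n() < 2) stop("insufficient replicates for ",
                             .data$gene[1], " / ", .data$sirna[1])
    if (length(pop) == 0) stop("reference population is empty")
    pv <- suppressWarnings(stats::wilcox.test(
      .data$auc, pop, alternative = alternative)$p.value)
    tibble::tibble(p = pv)
  }, .groups = "drop")
  out
}

#' Call candidate genes with cell death in or directly after mitosis
#'
#' A gene-siRNA is flagged when some time-frame t0 shows a significant
#' mitosis signal and the cell-death signal is significant at the same
#' frame or the next one (death in, or directly after, mitotic arrest). A
#' gene is a candidate when any of its siRNAs is flagged.
#'
#' @param profiles Tibble from [phenotype_pvalues()] containing `mitosis`
#'   and `cell_death` rows.
#' @param alpha Significance threshold (frames with `p <= alpha` count).
#' @param level `"gene"` (default) or `"sirna"` granularity of the result.
#' @return For `level = "sirna"`: tibble `gene`, `sirna`, `candidate`, `t0`
#'   (first supporting time-frame, `NA` if none). For `level = "gene"`:
#'   tibble `gene`, `candidate`, `sirnas_flagged`, `t0`.
#' @export
call_candidates <- function(profiles, alpha = 0.05,
                            level = c("gene", "sirna")) {
  level <- match.arg(level)
  wide <- tidyr::pivot_wider(
    dplyr::select(profiles, dplyr::all_of(
      c("gene", "sirna", "phenotype", "time_frame", "p"))),
    names_from = "phenotype", values_from = "p")
  if (!all(c("mitosis", "cell_death") %in% names(wide))) {
    stop("profiles must contain mitosis and cell_death p-values")
  }
  wide <- dplyr::arrange(wide, .data$gene, .data$sirna, .data$time_frame)
  per_sirna <- dplyr::summarise(
    dplyr::group_by(wide, .data$gene, .data$sirna), {
      if (any(duplicated(.data$time_frame))) {
        stop("misaligned time-frames for ", .data$gene[1])
      }
      pm <- .data$mitosis
      pd <- .data$cell_death
      pd_next <- c(pd[-1], NA)
      hit <- pm <= alpha & (pd <= alpha | (!is.na(pd_next) & pd_next <= alpha))
      any_hit <- any(hit, na.rm = TRUE)
      t0_hit <- if (any_hit) .data$time_frame[which(hit)[1]] else NA_integer_
      tibble::tibble(candidate = any_hit, t0 = t0_hit)
    }, .groups = "drop")
  if (level == "sirna") return(per_sirna)
  dplyr::summarise(dplyr::group_by(per_sirna, .data$gene),
                   candidate = any(.data$candidate),
                   sirnas_flagged = sum(.data$candidate),
                   t0 = if (any(.data$candidate)) {
                     min(.data$t0, na.rm = TRUE)
                   } else NA_integer_,
                   .groups = "drop")
}

#' Quality control: positive- vs negative-control proliferation
#'
#' Tests, per time-frame, whether positive-control spots show reduced
#' interphase signal relative to negative controls (one-sided rank-sum,
#' positive < negative). Frames with `p <= alpha` pass.
#'
#' @param signal Output of [window_signal()] carrying a `role` column.
#' @param phenotype Phenotype class used as the proliferation readout.
#' @param alpha Significance threshold.
#' @return Tibble `time_frame`, `n_positive`, `n_negative`, `p`, `pass`,
#'   `underpowered` (TRUE when either group has a single spot).
#' @export
qc_controls <- function(signal, phenotype = "interphase", alpha = 0.05) {
  sig <- dplyr::filter(signal, .data$phenotype == !!phenotype,
                       .data$role %in% c("positive_control",
                                         "negative_control"))
  if (!any(sig$role == "positive_control") ||
      !any(sig$role == "negative_control")) {
    stop("missing controls: need at least one positive and one negative spot")
  }
  out <- dplyr::summarise(dplyr::group_by(sig, .data$time_frame), {
    pos <- .data$auc[.data$role == "positive_control"]
    neg <- .data$auc[.data$role == "negative_control"]
    p <- suppressWarnings(
      stats::wilcox.test(pos, neg, alternative = "less")$p.value)
    tibble::tibble(n_positive = length(pos), n_negative = length(neg),
                   p = p, pass = p <= alpha,
                   underpowered = length(pos) < 2 || length(neg) < 2)
  }, .groups = "drop")
  out
}

#' Overlap enrichment between two hit lists
#'
#' Upper-tail hypergeometric probability of observing at least the given
#' overlap when `hits_b` genes are drawn from a universe containing
#' `hits_a` marked genes.
#'
#' @param universe_size Number of genes screened in both experiments.
#' @param hits_a,hits_b Hit-list sizes.
#' @param overlap Observed overlap.
#' @return The p-value `P(X >= overlap)`.
#' @examples
#' overlap_enrichment(10, 4, 5, 4) # 5/210
#' @export
overlap_enrichment <- function(universe_size, hits_a, hits_b, overlap) {
  if (overlap > min(hits_a, hits_b) || max(hits_a, hits_b) > universe_size ||
      min(universe_size, hits_a, hits_b, overlap) < 0) {
    stop("inconsistent counts: need overlap <= min(hits) <= universe_size")
  }
  stats::phyper(overlap - 1, hits_a, universe_size - hits_a, hits_b,
                lower.tail = FALSE)
}

#' Estimate the cell-cycle period from synchronized interphase dynamics
#'
#' Rebins an interphase-count time series into integration frames (3 h by
#' default, reducing a 120 h screen to 40 frames) and fits a sinusoid plus
#' linear trend, `f(t) = a * sin(2*pi*t/P + delta) + m*t + c`, by nonlinear
#' least squares. The period P (hours) is initialized from the dominant
#' discrete-Fourier frequency of the linearly detrended series and refined
#' from several restarts (period halved/doubled, four phase offsets); the
#' restart with the lowest residual sum of squares wins. With a
#' transfection-synchronized population the recovered P estimates the
#' cell-cycle duration.
#'
#' @param x Numeric series of interphase counts (typically averaged over
#'   spots, B-scored, or log2-transformed to make multiplicative growth
#'   additive).
#' @param time_h Acquisition times in hours, same length as `x`.
#' @param integration Rebinning width in hours.
#' @return A `period_fit` object: list with `amplitude`, `period`, `phase`,
#'   `slope`, `intercept`, `rss`, `sigma`, `n_frames`, `identifiable`
#'   (FALSE when the fitted amplitude is below the residual noise floor),
#'   and `data` (the rebinned series with fitted values).
#' @export
fit_periodicity <- function(x, time_h, integration = 3) {
  stopifnot(length(x) == length(time_h), length(x) > 3)
  span <- max(time_h) - min(time_h)
  n_bins <- max(floor(span / integration), 1)
  bin <- pmin(floor((time_h - min(time_h)) / integration), n_bins - 1)
  yb <- as.numeric(tapply(x, bin, mean))
  tb <- as.numeric(tapply(time_h, bin, mean))
  if (span < 2 * integration) stop("series too short to rebin")

  detr <- stats::lm(yb ~ tb)
  res <- stats::residuals(detr)
  n <- length(res)
  if (stats::sd(res) < 1e-10 * (stats::sd(yb) + abs(mean(yb)) + 1e-300)) {
    # no oscillation above numerical noise: amplitude zero, P unidentifiable
    return(structure(list(
      amplitude = 0, period = NA_real_, phase = 0,
      slope = unname(stats::coef(detr)[2]),
      intercept = unname(stats::coef(detr)[1]),
      rss = sum(res^2), sigma = 0, n_frames = n, identifiable = FALSE,
      data = tibble::tibble(time_h = tb, value = yb,
                            fitted = stats::fitted(detr))
    ), class = "period_fit"))
  }
  spec <- Mod(stats::fft(res))[2:max(2, n %/% 2)]
  freqs <- seq_along(spec) / (n * integration)
  # restart from the strongest spectral peaks (the dominant bin can be a
  # residual low-frequency trend), plus their harmonics
  top <- utils::head(order(spec, decreasing = TRUE), 3)
  p_tops <- 1 / freqs[top]
  fits <- list()
  for (p_init in unique(pmin(pmax(c(p_tops, p_tops / 2, 2 * p_tops), 4),
                             span)))
    for (d_init in c(0, pi / 2, pi, 3 * pi / 2)) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          yb ~ a * sin(2 * pi * tb / P + delta) + m * tb + c0,
          start = list(a = stats::sd(res) * sqrt(2), P = p_init,
                       delta = d_init, m = unname(stats::coef(detr)[2]),
                       c0 = unname(stats::coef(detr)[1])),
          lower = c(a = -Inf, P = 4, delta = -2 * pi, m = -Inf, c0 = -Inf),
          upper = c(a = Inf, P = 2 * span, delta = 4 * pi, m = Inf, c0 = Inf),
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(fit)) fits[[length(fits) + 1]] <- fit
    }
  if (length(fits) == 0) {
    stop("periodicity fit did not converge from any restart")
  }
  rss <- vapply(fits, function(f) sum(stats::residuals(f)^2), numeric(1))
  best <- fits[[which.min(rss)]]
  cf <- stats::coef(best)
  sigma <- sqrt(min(rss) / max(n - 5, 1))
  # canonical form: positive amplitude
  amp <- cf[["a"]]; del <- cf[["delta"]]
  if (amp < 0) { amp <- -amp; del <- del + pi }
  del <- ((del + pi) %% (2 * pi)) - pi
  structure(list(
    amplitude = amp, period = cf[["P"]], phase = del,
    slope = cf[["m"]], intercept = cf[["c0"]],
    rss = min(rss), sigma = sigma, n_frames = n,
    identifiable = amp > sigma,
    data = tibble::tibble(time_h = tb, value = yb,
                          fitted = stats::fitted(best))
  ), class = "period_fit")
}

#' @export
print.period_fit <- function(x, ...) {
  cat("Cell-cycle periodicity fit (", x$n_frames, " frames)\n", sep = "")
  cat(sprintf("  period    %.2f h%s\n", x$period,
              if (x$identifiable) "" else "  [amplitude below noise floor]"))
  cat(sprintf("  amplitude %.4g  phase %.2f rad\n", x$amplitude, x$phase))
  cat(sprintf("  trend     slope %.4g /h, intercept %.4g\n",
              x$slope, x$intercept))
  cat(sprintf("  residual sd %.4g\n", x$sigma))
  invisible(x)
}
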