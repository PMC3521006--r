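#' Histogram signature of an image's foreground
#'
#' Summarizes the grey-value histogram of the foreground pixels by three
#' features: the location of the maximum peak and its widths to the left
#' and to the right, measured at half maximum. Foreground is defined by an
#' Otsu threshold on the image.
#'
#' @param img Numeric matrix with values in `[0, 1]`.
#' @param n_bins Number of histogram bins over `[0, 1]`.
#' @return List `peak`, `left_width`, `right_width` (grey units, widths
#'   at least one bin).
#' @export
histogram_signature <- function(img, n_bins = 256) {
  thr <- tryCatch(EBImage::otsu(EBImage::Image(img), range = c(0, 1),
                                levels = n_bins),
                  error = function(e) NA_real_)
  fg <- img[!is.na(thr) & img > thr]
  if (length(fg) < 2 || stats::sd(fg) == 0 ||
      length(fg) > 0.95 * length(img)) {
    stop("degenerate histogram: image has no distinct foreground")
  }
  breaks <- seq(0, 1, length.out = n_bins + 1)
  h <- graphics::hist(fg, breaks = breaks, plot = FALSE)
  # smooth the sparse empirical histogram so peak and half-maximum
  # crossings are stable estimates
  kern <- c(1, 2, 3, 2, 1) / 9
  cnt <- stats::filter(h$counts, kern, sides = 2)
  cnt[is.na(cnt)] <- 0
  cnt <- as.numeric(cnt)
  pk <- which.max(cnt)
  half <- cnt[pk] / 2
  bw <- 1 / n_bins
  # half-maximum crossings with linear interpolation between bin centres
  cross_left <- pk
  left_w <- bw
  for (i in seq(pk - 1, 1)) {
    if (pk == 1) break
    if (cnt[i] <= half) {
      frac <- (cnt[i + 1] - half) / max(cnt[i + 1] - cnt[i], 1e-9)
      left_w <- (pk - i - 1 + frac) * bw
      break
    }
    if (i == 1) left_w <- (pk - 1) * bw
  }
  right_w <- bw
  for (i in seq(pk + 1, n_bins)) {
    if (pk == n_bins) break
    if (cnt[i] <= half) {
      frac <- (cnt[i - 1] - half) / max(cnt[i - 1] - cnt[i], 1e-9)
      right_w <- (i - pk - 1 + frac) * bw
      break
    }
    if (i == n_bins) right_w <- (n_bins - pk) * bw
  }
  list(peak = h$mids[pk],
       left_width = max(left_w, bw),
       right_width = max(right_w, bw))
}

#' Mean histogram signature of a dataset
#'
#' @param signatures List of signatures from [histogram_signature()].
#' @return A signature list with the element-wise means.
#' @export
mean_signature <- function(signatures) {
  if (length(signatures) == 0) stop("need at least one signature")
  list(peak = mean(purrr::map_dbl(signatures, "peak")),
       left_width = mean(purrr::map_dbl(signatures, "left_width")),
       right_width = mean(purrr::map_dbl(signatures, "right_width")))
}

#' Map images onto a common grey-value range
#'
#' Brings all images of a screen to a comparable grey-value range: each
#' image's foreground-histogram signature is mapped onto the dataset-wide
#' mean signature by a piecewise-linear transform anchored at the peak --
#' grey values below the peak are scaled by the ratio of left widths,
#' values above by the ratio of right widths, and the peak is shifted onto
#' the mean peak. The mapping is idempotent up to one grey level.
#'
#' @param frames A list of image matrices (or one matrix).
#' @param target Target signature; defaults to the mean signature of
#'   `frames`.
#' @return List of normalized matrices (or one matrix if one was given),
#'   clipped to `[0, 1]`, with the target signature attached as attribute
#'   `target_signature`.
#' @export
normalize_greyvalues <- function(frames, target = NULL) {
  single <- is.matrix(frames)
  if (single) frames <- list(frames)
  sigs <- purrr::map(frames, histogram_signature)
  if (is.null(target)) target <- mean_signature(sigs)
  out <- purrr::map2(frames, sigs, function(img, s) {
    lw <- target$left_width / s$left_width
    rw <- target$right_width / s$right_width
    d <- img - s$peak
    mapped <- target$peak + ifelse(d < 0, d * lw, d * rw)
    matrix(pmin(pmax(mapped, 0), 1), nrow = nrow(img))
  })
  attr(out, "target_signature") <- target
  if (single) out[[1]] else out
}

# local mean / sd via box filtering (FFT convolution, circular padding)
.box_stats <- function(img, window) {
  kern <- matrix(1 / window^2, window, window)
  m <- EBImage::filter2(img, kern)
  v <- EBImage::filter2(img^2, kern) - m^2
  list(mean = m, sd = sqrt(pmax(v, 0)))
}

#' Region-adaptive nucleus segmentation
#'
#' A pixel is foreground when it exceeds its local mean (over a
#' `window` x `window` neighbourhood) by more than `offset_k` local
#' standard deviations, so nuclei of varying contrast are detected
#' together. Connected components smaller than `min_area` pixels are
#' removed.
#'
#' @param img Numeric image matrix.
#' @param window Odd neighbourhood size in pixels.
#' @param offset_k Threshold offset in local standard deviations.
#' @param min_area Minimum component area in pixels.
#' @return Integer label matrix (0 = background).
#' @export
segment_nuclei <- function(img, window = 51, offset_k = 0.5, min_area = 40) {
  stopifnot(window > 1, window %% 2 == 1)
  st <- .box_stats(img, window)
  # small epsilon guards against FFT round-off on exactly flat regions
  fg <- img > st$mean + offset_k * st$sd + 1e-6
  lab <- EBImage::bwlabel(EBImage::Image(fg * 1))
  lab <- EBImage::imageData(lab)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0], nbins = max(lab))
    drop <- which(sizes < min_area)
    if (length(drop)) lab[lab %in% drop] <- 0L
    # relabel consecutively
    keep <- sort(unique(lab[lab > 0]))
    lab[] <- match(lab, keep, nomatch = 0L)
  }
  matrix(as.integer(lab), nrow = nrow(img))
}

#' Split touching nuclei by distance-transform watershed
#'
#' Resolves clusters of touching cells: the Euclidean distance transform
#' of the binary segmentation is watershed-transformed, splitting convex
#' touching pairs at their saddle. Components that remain larger than
#' `cluster_factor` times the median single-nucleus area are dense
#' aggregates that cannot be resolved and are flagged as cluster objects.
#'
#' @param mask Integer label matrix from [segment_nuclei()].
#' @param tolerance Minimum watershed object height (px of distance map).
#' @param cluster_factor Area multiple of the median object area above
#'   which an object is flagged `is_cluster`.
#' @return List with `mask` (relabelled integer matrix) and `is_cluster`
#'   (logical vector indexed by label).
#' @export
split_clusters <- function(mask, tolerance = 1, cluster_factor = 3) {
  bin <- EBImage::Image((mask > 0) * 1)
  if (max(mask) == 0) {
    return(list(mask = mask, is_cluster = logical(0)))
  }
  dm <- EBImage::distmap(bin)
  wt <- EBImage::watershed(dm, tolerance = tolerance, ext = 1)
  lab <- matrix(as.integer(EBImage::imageData(wt)), nrow = nrow(mask))
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- which(sizes > 0)
  lab[] <- match(lab, keep, nomatch = 0L)
  sizes <- sizes[keep]
  med <- stats::median(sizes)
  list(mask = lab, is_cluster = sizes > cluster_factor * med)
}
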