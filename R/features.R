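# Zernike radial polynomial R_nm(rho)
.zernike_radial <- function(n, m, rho) {
  s_max <- (n - m) / 2
  out <- 0
  for (s in 0:s_max) {
    coef <- (-1)^s * factorial(n - s) /
      (factorial(s) * factorial((n + m) / 2 - s) * factorial((n - m) / 2 - s))
    out <- out + coef * rho^(n - 2 * s)
  }
  out
}

#' Zernike moment magnitudes of a masked intensity patch
#'
#' Magnitudes of the Zernike moments up to the given radial order, computed
#' on the unit disc spanned by the object mask (centred at the mask
#' centroid, scaled by its maximal radius) with intensities normalized to
#' unit mass. Magnitudes are invariant under rotation of the patch.
#'
#' @param patch Numeric intensity matrix.
#' @param pmask Logical matrix, same size, selecting the object's pixels.
#' @param order Maximum radial order n (default 9).
#' @return Named numeric vector `zer_n<m>_m<m>` of magnitudes.
#' @export
zernike_features <- function(patch, pmask, order = 9) {
  idx <- which(pmask, arr.ind = TRUE)
  f <- patch[pmask]
  f <- f / max(sum(f), 1e-12)
  cy <- sum(idx[, 1] * f) / sum(f); cx <- sum(idx[, 2] * f) / sum(f)
  dy <- idx[, 1] - cy; dx <- idx[, 2] - cx
  rmax <- max(sqrt(dx^2 + dy^2), 1)
  rho <- sqrt(dx^2 + dy^2) / rmax
  theta <- atan2(dy, dx)
  inside <- rho <= 1
  out <- c()
  for (n in 0:order) for (m in seq(n %% 2, n, by = 2)) {
    R <- .zernike_radial(n, m, rho[inside])
    A <- (n + 1) / pi * sum(f[inside] * R * exp(-1i * m * theta[inside]))
    out[sprintf("zer_n%d_m%d", n, m)] <- Mod(A)
  }
  out
}

# 2-level Haar sub-band energies (fractions of total energy)
.haar_energies <- function(patch) {
  dims <- dim(patch)
  pad <- ceiling(dims / 4) * 4
  m <- matrix(0, pad[1], pad[2])
  m[seq_len(dims[1]), seq_len(dims[2])] <- patch
  step <- function(x) {
    a <- (x[seq(1, nrow(x), 2), , drop = FALSE] +
            x[seq(2, nrow(x), 2), , drop = FALSE]) / sqrt(2)
    d <- (x[seq(1, nrow(x), 2), , drop = FALSE] -
            x[seq(2, nrow(x), 2), , drop = FALSE]) / sqrt(2)
    list(a = a, d = d)
  }
  decompose <- function(x) {
    r <- step(x)
    ca <- step(t(r$a)); cd <- step(t(r$d))
    list(ll = t(ca$a), lh = t(ca$d), hl = t(cd$a), hh = t(cd$d))
  }
  l1 <- decompose(m)
  l2 <- decompose(l1$ll)
  e <- c(wav_lh1 = sum(l1$lh^2), wav_hl1 = sum(l1$hl^2),
         wav_hh1 = sum(l1$hh^2), wav_lh2 = sum(l2$lh^2),
         wav_hl2 = sum(l2$hl^2), wav_hh2 = sum(l2$hh^2),
         wav_ll2 = sum(l2$ll^2))
  e / max(sum(e), 1e-12)
}

# granulometry: fraction of masked mass removed by greyscale openings of
# increasing disc size
.granulometry <- function(patch, pmask, sizes = c(3, 5, 7, 9, 11)) {
  masked <- patch * pmask
  total <- max(sum(masked), 1e-12)
  prev <- total
  out <- numeric(length(sizes))
  for (i in seq_along(sizes)) {
    op <- EBImage::opening(EBImage::Image(masked),
                           EBImage::makeBrush(sizes[i], shape = "disc"))
    s <- sum(EBImage::imageData(op) * pmask)
    out[i] <- (prev - s) / total
    prev <- s
  }
  stats::setNames(out, paste0("gran_", sizes))
}

#' Extract per-nucleus feature vectors
#'
#' Computes a fixed-length feature vector for every labelled object:
#' intensity statistics; morphology (area, perimeter, circularity
#' `4*pi*A/P^2`, radius statistics, eccentricity); Haralick co-occurrence
#' texture; Zernike moment magnitudes (rotation invariant); a granulometry
#' spectrum; and 2-level Haar wavelet sub-band energies. Which groups are
#' computed is configuration, so the vector length is fixed per
#' configuration.
#'
#' @param img Numeric image matrix (normalized grey values).
#' @param mask Integer label matrix (e.g. from [split_clusters()]).
#' @param groups Feature groups to include.
#' @param zernike_order Maximum Zernike radial order.
#' @param is_cluster Optional logical vector by label (from
#'   [split_clusters()]), carried through to the output.
#' @param margin Patch margin in pixels around each object's bounding box.
#' @return Tibble with one row per object: `object_id`, `x`, `y`, `area`,
#'   `mean_intensity`, `is_cluster`, then one column per feature.
#' @export
extract_features <- function(img, mask,
                             groups = c("intensity", "shape", "haralick",
                                        "zernike", "granulometry", "wavelet"),
                             zernike_order = 9,
                             is_cluster = NULL, margin = 3) {
  labels <- sort(unique(mask[mask > 0]))
  if (length(labels) == 0) {
    stop("empty mask: no objects to extract features from")
  }
  rows <- purrr::map(labels, function(lb) {
    sel <- which(mask == lb, arr.ind = TRUE)
    if (nrow(sel) == 0) stop("empty mask for label ", lb)
    r0 <- max(min(sel[, 1]) - margin, 1); r1 <- min(max(sel[, 1]) + margin, nrow(img))
    c0 <- max(min(sel[, 2]) - margin, 1); c1 <- min(max(sel[, 2]) + margin, ncol(img))
    patch <- img[r0:r1, c0:c1, drop = FALSE]
    pmask <- mask[r0:r1, c0:c1, drop = FALSE] == lb
    px <- patch[pmask]
    feats <- c()

    if ("intensity" %in% groups) {
      qs <- stats::quantile(px, c(0.1, 0.9), names = FALSE)
      feats <- c(feats,
                 int_mean = mean(px), int_sd = stats::sd(px),
                 int_mad = stats::mad(px, constant = 1),
                 int_min = min(px), int_max = max(px),
                 int_q10 = qs[1], int_q90 = qs[2])
      if (is.na(feats["int_sd"])) feats["int_sd"] <- 0
    }
    lab_img <- EBImage::Image(pmask * 1)
    if ("shape" %in% groups) {
      sh <- EBImage::computeFeatures.shape(lab_img)
      mo <- EBImage::computeFeatures.moment(lab_img, EBImage::Image(patch))
      circ <- 4 * pi * sh[1, "s.area"] / max(sh[1, "s.perimeter"], 1)^2
      feats <- c(feats,
                 shp_area = unname(sh[1, "s.area"]),
                 shp_perimeter = unname(sh[1, "s.perimeter"]),
                 shp_circularity = min(unname(circ), 1),
                 shp_radius_mean = unname(sh[1, "s.radius.mean"]),
                 shp_radius_sd = unname(sh[1, "s.radius.sd"]),
                 shp_radius_max = unname(sh[1, "s.radius.max"]),
                 shp_eccentricity = unname(mo[1, "m.eccentricity"]))
    }
    if ("haralick" %in% groups) {
      ha <- EBImage::computeFeatures.haralick(lab_img, EBImage::Image(patch),
                                              haralick.nbins = 32,
                                              haralick.scales = 1)
      feats <- c(feats, stats::setNames(as.numeric(ha[1, ]),
                                        paste0("har_", colnames(ha))))
    }
    if ("zernike" %in% groups) {
      feats <- c(feats, zernike_features(patch, pmask, zernike_order))
    }
    if ("granulometry" %in% groups) {
      feats <- c(feats, .granulometry(patch, pmask))
    }
    if ("wavelet" %in% groups) {
      feats <- c(feats, .haar_energies(patch * pmask))
    }
    tibble::tibble(
      object_id = lb,
      x = mean(sel[, 2]) - 1, y = mean(sel[, 1]) - 1, # 0-based pixel coords
      area = nrow(sel),
      mean_intensity = mean(px),
      is_cluster = if (!is.null(is_cluster)) isTRUE(is_cluster[lb]) else FALSE,
      !!!as.list(feats))
  })
  dplyr::bind_rows(rows)
}

#' Segment one frame end-to-end
#'
#' Convenience wrapper: adaptive segmentation, watershed cluster
#' splitting, then feature extraction.
#'
#' @param img Image matrix.
#' @param window,offset_k,min_area See [segment_nuclei()].
#' @param ... Passed to [extract_features()].
#' @return Tibble of objects with features (empty tibble when nothing is
#'   detected).
#' @export
segment_frame <- function(img, window = 51, offset_k = 0.5, min_area = 40,
                          ...) {
  mask <- segment_nuclei(img, window, offset_k, min_area)
  if (max(mask) == 0) return(tibble::tibble())
  sp <- split_clusters(mask)
  extract_features(img, sp$mask, is_cluster = sp$is_cluster, ...)
}

#' Build a labelled training set from rendered patches
#'
#' Extracts features from each patch of [render_nuclei_patches()], using
#' the largest connected region of the patch's truth mask as the object.
#'
#' @param patches Output of [render_nuclei_patches()].
#' @param ... Passed to [extract_features()].
#' @return Tibble with `label` plus feature columns.
#' @export
training_set_from_patches <- function(patches, ...) {
  rows <- purrr::pmap(list(patches$image, patches$mask, patches$label),
                      function(img, msk, lab) {
    bin <- EBImage::bwlabel(EBImage::Image((msk > 0) * 1))
    bin <- matrix(as.integer(EBImage::imageData(bin)), nrow = nrow(img))
    if (max(bin) == 0) return(NULL)
    # merge all fragments of the rendered cell into one object
    bin[bin > 0] <- 1L
    ft <- extract_features(img, bin, ...)
    dplyr::mutate(ft, label = lab, .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  dplyr::select(out, -dplyr::any_of(c("object_id", "is_cluster")))
}
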