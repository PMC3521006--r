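#' Render one synthetic nucleus-channel frame
#'
#' Draws the cells of one timepoint as an H2B-GFP-like greyscale image:
#' interphase nuclei are smooth textured ellipses, mitotic figures are
#' small, bright, condensed (often bilobed) shapes, dying cells are
#' clusters of small bright fragments, and artifacts are unresolvable
#' multi-nucleus aggregates. Cells whose rendered masks overlap
#' substantially are merged in the image and flagged `artifact` in the
#' returned truth table. Rendering is bit-identical under a fixed seed.
#'
#' @param cells Tibble with `cell_id`, `label` (`interphase`, `mitosis`,
#'   `cell_death` or `artifact`) and pixel positions `x`, `y`.
#' @param image_shape `c(width, height)` in pixels.
#' @param noise List with `background` (baseline grey, 0-1) and `sd`
#'   (additive Gaussian noise sd).
#' @param seed Integer seed for textures, shapes and noise.
#' @param overlap_frac Fraction of the smaller object's area that must
#'   overlap before the touching cells are flagged as one artifact.
#' @return List with `image` (matrix in `[0, 1]`, height x width), `mask`
#'   (integer label matrix, one label per input cell, 0 = background) and
#'   `truth` (the input tibble plus `rendered_label`, where merged cells
#'   become `artifact`).
#' @export
render_frame <- function(cells, image_shape = c(256, 256),
                         noise = list(background = 0.1, sd = 0.02),
                         seed = 1, overlap_frac = 0.2) {
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  w <- image_shape[1]; h <- image_shape[2]
  img <- matrix(0, nrow = h, ncol = w)
  mask <- matrix(0L, nrow = h, ncol = w)
  n <- nrow(cells)
  overlap_px <- matrix(0, n, n)
  areas <- numeric(n)

  paint <- function(i, px, py, val) {
    keep <- px >= 1 & px <= w & py >= 1 & py <= h
    px <- px[keep]; py <- py[keep]; val <- val[keep]
    if (!length(px)) return(invisible())
    idx <- cbind(py, px)
    prev <- mask[idx]
    hit <- prev != 0L & prev != i
    if (any(hit)) {
      for (j in unique(prev[hit])) {
        overlap_px[i, j] <<- overlap_px[i, j] + sum(prev[hit] == j)
      }
    }
    img[idx] <<- pmax(img[idx], val)
    mask[idx][prev == 0L] <<- i
    areas[i] <<- areas[i] + sum(prev == 0L | prev == i)
    invisible()
  }

  ellipse_pixels <- function(cx, cy, a, b, theta) {
    r <- ceiling(max(a, b)) + 1
    gx <- seq(floor(cx - r), ceiling(cx + r))
    gy <- seq(floor(cy - r), ceiling(cy + r))
    gg <- expand.grid(px = gx, py = gy)
    dx <- gg$px - cx; dy <- gg$py - cy
    u <- dx * cos(theta) + dy * sin(theta)
    v <- -dx * sin(theta) + dy * cos(theta)
    r2 <- (u / a)^2 + (v / b)^2
    keep <- r2 <= 1
    list(px = gg$px[keep], py = gg$py[keep], r2 = r2[keep])
  }

  draw_ellipse <- function(i, cx, cy, a, b, base, texture = TRUE) {
    e <- ellipse_pixels(cx, cy, a, b, stats::runif(1, 0, pi))
    val <- base * (1 - 0.35 * e$r2)
    if (texture) {
      fx <- stats::runif(1, 0.08, 0.18); fy <- stats::runif(1, 0.08, 0.18)
      ph <- stats::runif(1, 0, 2 * pi)
      val <- val * (1 + 0.12 * sin(2 * pi * (e$px * fx + e$py * fy) + ph))
    }
    paint(i, e$px, e$py, val)
  }

  for (i in seq_len(n)) {
    cx <- cells$x[i]; cy <- cells$y[i]
    lab <- as.character(cells$label[i])
    if (lab == "interphase") {
      a <- stats::rnorm(1, 8, 0.8); b <- stats::rnorm(1, 6, 0.6)
      draw_ellipse(i, cx, cy, max(a, 4), max(b, 3.5),
                   base = stats::rnorm(1, 0.38, 0.03))
    } else if (lab == "mitosis") {
      base <- stats::rnorm(1, 0.75, 0.04)
      nb <- "newborn" %in% names(cells) && isTRUE(cells$newborn[i])
      if (nb) {
        # freshly divided daughter: compact telophase nucleus with about
        # half the mitotic mother's chromatin footprint
        draw_ellipse(i, cx, cy, 4.4, 3.4, base, texture = FALSE)
      } else if (stats::runif(1) < 0.5) { # condensed metaphase plate
        draw_ellipse(i, cx, cy, 6.5, 4.8, base, texture = FALSE)
      } else {                     # anaphase-like bilobed figure
        th <- stats::runif(1, 0, pi)
        for (s in c(-1, 1)) {
          draw_ellipse(i, cx + s * 2.8 * cos(th), cy + s * 2.8 * sin(th),
                       4.5, 3.6, base, texture = FALSE)
        }
      }
    } else if (lab == "cell_death") {
      nf <- sample(3:5, 1)
      base <- stats::rnorm(1, 0.8, 0.04)
      # fragments fan out around the former nucleus centre
      ang <- 2 * pi * seq_len(nf) / nf + stats::rnorm(nf, 0, 0.25)
      rad <- stats::runif(nf, 2.4, 3.6)
      for (f in seq_len(nf)) {
        draw_ellipse(i, cx + rad[f] * cos(ang[f]), cy + rad[f] * sin(ang[f]),
                     3.0, 2.6, base, texture = FALSE)
      }
    } else { # artifact: unresolvable aggregate
      for (f in 1:3) {
        draw_ellipse(i, cx + stats::rnorm(1, 0, 3.5), cy + stats::rnorm(1, 0, 3.5),
                     7.5, 5.5, stats::rnorm(1, 0.45, 0.05))
      }
    }
  }

  img <- pmax(img, noise$background)
  if (noise$sd > 0) img <- img + stats::rnorm(length(img), 0, noise$sd)
  img <- matrix(pmin(pmax(img, 0), 1), nrow = h, ncol = w)

  # merge flagging: connected groups of substantially overlapping cells
  rendered <- as.character(cells$label)
  if (n > 1) {
    ov <- overlap_px + t(overlap_px)
    merged <- rep(FALSE, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i < j && ov[i, j] > 0) {
        thr <- overlap_frac * min(max(areas[i], 1), max(areas[j], 1))
        if (ov[i, j] >= thr) merged[c(i, j)] <- TRUE
      }
    }
    rendered[merged] <- "artifact"
  }
  truth <- dplyr::mutate(cells, rendered_label = rendered)
  list(image = img, mask = mask, truth = truth)
}

#' Render isolated nucleus patches of each phenotype class
#'
#' Convenience generator for classifier training/validation data: one cell
#' per patch, centred, rendered with [render_frame()].
#'
#' @param n_per_class Patches per class.
#' @param classes Character vector of phenotype classes to render.
#' @param patch_px Patch side length in pixels.
#' @param noise Noise spec as in [render_frame()].
#' @param seed Integer seed.
#' @return A list with elements `image` (list of matrices), `mask` (list of
#'   integer matrices) and `label` (character vector).
#' @export
render_nuclei_patches <- function(n_per_class = 50,
                                  classes = c("interphase", "mitosis",
                                              "cell_death", "artifact"),
                                  patch_px = 48,
                                  noise = list(background = 0.1, sd = 0.02),
                                  seed = 1) {
  labels <- rep(classes, each = n_per_class)
  seeds <- spot_seed(seq_along(labels), 1, 1, seed)
  # a third of the mitosis patches are freshly divided daughter nuclei
  newborn <- labels == "mitosis" & (seq_along(labels) %% 3 == 0)
  out <- purrr::map2(seq_along(labels), seeds, function(i, s) {
    lab <- labels[i]
    cell <- tibble::tibble(cell_id = 1L, label = lab, newborn = newborn[i],
                           x = patch_px / 2, y = patch_px / 2)
    fr <- render_frame(cell, image_shape = c(patch_px, patch_px),
                       noise = noise, seed = s)
    list(image = fr$image, mask = fr$mask)
  })
  list(image = purrr::map(out, "image"),
       mask = purrr::map(out, "mask"),
       label = labels)
}

#' Inject additive row/column plate effects into a count table
#'
#' Emulates spatial (edge) effects on a cell array: each value gains its
#' row effect plus its column effect, clipped at zero.
#'
#' @param counts Tibble with `row`, `col` and the count columns named in
#'   `columns`.
#' @param row_effects,col_effects Numeric effect vectors indexed by plate
#'   row/column; lengths must cover the grid.
#' @param columns Count columns to perturb.
#' @return `counts` with the listed columns shifted and clipped at 0.
#' @export
inject_spatial_bias <- function(counts, row_effects, col_effects,
                                columns = intersect(
                                  c("interphase", "mitosis", "cell_death",
                                    "artifact", "value"),
                                  names(counts))) {
  if (max(counts$row) > length(row_effects) ||
      max(counts$col) > length(col_effects)) {
    stop("effect vectors do not match the plate grid dimensions")
  }
  add <- row_effects[counts$row] + col_effects[counts$col]
  for (cl in columns) counts[[cl]] <- pmax(counts[[cl]] + add, 0)
  counts
}

#' Default edge-effect vectors for a plate grid
#'
#' Mimics the classic pattern of elevated counts along the top row and
#' outer columns of a cell array.
#'
#' @param n_rows,n_cols Grid dimensions.
#' @param strength Added count at the strongest edge.
#' @return List with `row_effects` and `col_effects`.
#' @export
edge_bias <- function(n_rows, n_cols, strength = 10) {
  row_effects <- numeric(n_rows)
  row_effects[1] <- strength
  if (n_rows > 1) row_effects[n_rows] <- strength / 2
  col_effects <- numeric(n_cols)
  col_effects[1] <- strength / 2
  col_effects[n_cols] <- strength / 2
  list(row_effects = row_effects, col_effects = col_effects)
}
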