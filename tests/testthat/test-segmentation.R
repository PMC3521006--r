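# synthetic Gaussian blob image helper
blob_image <- function(centers, amps, sigma = 5, dims = c(96, 96), bg = 0.1) {
  img <- matrix(bg, dims[1], dims[2])
  for (i in seq_along(amps)) {
    rr <- outer((seq_len(dims[1]) - centers[[i]][2])^2,
                (seq_len(dims[2]) - centers[[i]][1])^2, "+")
    img <- img + amps[i] * exp(-rr / (2 * sigma^2))
  }
  img
}

test_that("histogram normalization maps peaks onto the mean signature", {
  # two images whose foreground peaks sit at 100/256 and 140/256
  mk <- function(peak) {
    img <- matrix(0.02, 64, 64)
    img[20:44, 20:44] <- peak + stats::rnorm(625, 0, 0.01)
    pmin(pmax(img, 0), 1)
  }
  set.seed(1)
  imgs <- list(mk(100 / 256), mk(140 / 256))
  norm <- normalize_greyvalues(imgs)
  tgt <- attr(norm, "target_signature")
  expect_equal(tgt$peak, 120 / 256, tolerance = 0.02)
  s1 <- histogram_signature(norm[[1]])
  s2 <- histogram_signature(norm[[2]])
  expect_equal(s1$peak, tgt$peak, tolerance = 1 / 256)
  expect_equal(s2$peak, tgt$peak, tolerance = 1 / 256)
})

test_that("an image already at the mean signature maps to itself", {
  set.seed(2)
  img <- matrix(0.02, 64, 64)
  img[10:50, 10:50] <- 0.5 + stats::rnorm(1681, 0, 0.03)
  img <- pmin(pmax(img, 0), 1)
  sig <- histogram_signature(img)
  out <- normalize_greyvalues(img, target = sig)
  expect_lt(max(abs(out - img)), 1 / 256 + 1e-9)
})

test_that("histogram normalization is idempotent within one grey level", {
  set.seed(3)
  imgs <- purrr::map(c(0.3, 0.5, 0.7), function(p) {
    img <- matrix(0.02, 64, 64)
    img[15:45, 15:45] <- p + stats::rnorm(961, 0, 0.04)
    pmin(pmax(img, 0), 1)
  })
  once <- normalize_greyvalues(imgs)
  tgt <- attr(once, "target_signature")
  twice <- normalize_greyvalues(once, target = tgt)
  for (i in seq_along(imgs)) {
    expect_lt(stats::median(abs(twice[[i]] - once[[i]])), 1.5 / 256)
  }
})

test_that("an all-background image raises a degenerate-histogram error", {
  expect_error(histogram_signature(matrix(0.1, 50, 50)), "foreground")
})

test_that("adaptive thresholding detects blobs of unequal contrast", {
  img <- blob_image(list(c(25, 25), c(70, 70)), amps = c(0.6, 0.12))
  mask <- segment_nuclei(img, min_area = 20)
  expect_equal(max(mask), 2)
  # a global (Otsu-style) threshold set for the bright blob misses the dim one
  glob <- img > 0.3
  lab <- EBImage::bwlabel(EBImage::Image(glob * 1))
  expect_equal(max(lab), 1)
})

test_that("uniform images contain no objects", {
  expect_equal(max(segment_nuclei(matrix(0.3, 80, 80))), 0)
})

test_that("watershed splits touching pairs but not single convex objects", {
  disc <- function(img, cx, cy, r, v) {
    for (row in seq_len(nrow(img))) for (col in seq_len(ncol(img))) {
      if ((row - cy)^2 + (col - cx)^2 <= r^2) img[row, col] <- v
    }
    img
  }
  img <- matrix(0.05, 80, 80)
  img <- disc(img, 25, 40, 9, 0.7)  # dumbbell: two overlapping discs
  img <- disc(img, 39, 40, 9, 0.7)
  img <- disc(img, 62, 20, 8, 0.7)  # isolated disc
  mask <- segment_nuclei(img)
  expect_equal(max(mask), 2)
  sp <- split_clusters(mask)
  expect_equal(max(sp$mask), 3)
  expect_false(any(sp$is_cluster))
})

test_that("unresolvable aggregates are flagged as cluster objects", {
  disc <- function(img, cx, cy, r, v) {
    for (row in seq_len(nrow(img))) for (col in seq_len(ncol(img))) {
      if ((row - cy)^2 + (col - cx)^2 <= r^2) img[row, col] <- v
    }
    img
  }
  img <- matrix(0.05, 120, 120)
  # five heavily merged discs: one giant blob with shallow saddles
  for (c0 in list(c(50, 50), c(58, 50), c(54, 56), c(46, 56), c(62, 58))) {
    img <- disc(img, c0[1], c0[2], 9, 0.7)
  }
  # several normal singles fix the median object area
  for (c0 in list(c(20, 100), c(100, 20), c(100, 100), c(20, 20))) {
    img <- disc(img, c0[1], c0[2], 5, 0.7)
  }
  mask <- segment_nuclei(img)
  sp <- split_clusters(mask, tolerance = 6) # shallow saddles stay merged
  sizes <- tabulate(sp$mask[sp$mask > 0])
  expect_true(any(sp$is_cluster))
  big <- which.max(sizes)
  expect_true(sp$is_cluster[big])
})

test_that("segmentation recovers nearly all rendered non-overlapping nuclei", {
  mv <- fixture("movie4", function() build_movie(4))
  truth <- mv$truth
  # centroid match within 5 px, non-merged cells only
  matched <- match_truth_objects(truth, mv$objects, tol = 5)
  # exclude truth cells overlapping another cell (within 12 px of a neighbour)
  neighbours <- dplyr::inner_join(truth, truth, by = "frame",
                                  relationship = "many-to-many")
  crowded <- dplyr::filter(neighbours,
                           .data$cell_id.x != .data$cell_id.y,
                           (.data$x.x - .data$x.y)^2 +
                             (.data$y.x - .data$y.y)^2 < 12^2)
  iso <- dplyr::anti_join(truth,
                          dplyr::distinct(crowded, .data$frame,
                                          cell_id = .data$cell_id.x),
                          by = c("frame", "cell_id"))
  hit <- dplyr::semi_join(iso, matched, by = c("frame", "cell_id"))
  expect_gte(nrow(hit) / nrow(iso), 0.95)
})
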