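# Shared fixtures, built once per test run and memoized.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Render + segment a short no-effect movie; returns truth, objects, tracking.
build_movie <- function(seed, n0 = 10, duration = 45, arena = 256) {
  cfg <- sim_config(n_cells_initial = n0, total_duration = duration,
                    arena_px = c(arena, arena))
  truth <- simulate_population(cfg, seed = seed)
  frames <- sort(unique(truth$frame))
  objs <- purrr::map_dfr(frames, function(fr) {
    cells <- dplyr::filter(truth, .data$frame == fr)
    rf <- render_frame(cells, image_shape = c(arena, arena),
                       seed = seed * 1000 + fr)
    ft <- segment_frame(rf$image)
    if (nrow(ft) > 0) dplyr::mutate(ft, frame = fr) else NULL
  })
  objs$object_id <- seq_len(nrow(objs))
  list(truth = truth, objects = objs, tracking = track_movie(objs))
}

# Match truth cells to segmented objects by centroid (<= tol px).
match_truth_objects <- function(truth, objects, tol = 5) {
  frames <- intersect(unique(truth$frame), unique(objects$frame))
  purrr::map_dfr(frames, function(fr) {
    tt <- dplyr::filter(truth, .data$frame == fr)
    oo <- dplyr::filter(objects, .data$frame == fr)
    if (nrow(tt) == 0 || nrow(oo) == 0) return(NULL)
    d2 <- outer(tt$x, oo$x, "-")^2 + outer(tt$y, oo$y, "-")^2
    j <- apply(d2, 1, which.min)
    ok <- sqrt(d2[cbind(seq_len(nrow(tt)), j)]) <= tol
    tibble::tibble(frame = fr, cell_id = tt$cell_id[ok],
                   object_id = oo$object_id[j[ok]])
  })
}

# Well-separated Gaussian blob classes for classifier tests.
blob_training <- function(n_per_class, centers, sd = 0.5, seed = 1) {
  withr::with_seed(seed, {
    purrr::imap_dfr(centers, function(mu, lab) {
      tibble::tibble(label = lab,
                     f1 = stats::rnorm(n_per_class, mu[1], sd),
                     f2 = stats::rnorm(n_per_class, mu[2], sd))
    })
  })
}

# Labelled training set from rendered nucleus patches (shared by tests).
patch_training <- function() {
  fixture("patch_training", function() {
    training_set_from_patches(render_nuclei_patches(40, seed = 11))
  })
}
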