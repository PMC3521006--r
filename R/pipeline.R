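#' Configuration for an end-to-end screen analysis
#'
#' Collects every tunable constant of the pipeline with the screen's
#' standard defaults: 8 arrays of 275 spots, 2 siRNAs x 4 replicates per
#' gene, imaging from 16 h post seeding for 120 h at ~40 min intervals,
#' 24 h / 8 h scoring windows, significance threshold 0.05, reliability
#' cut-off 0.2, and 3 h integration frames for the periodicity fit.
#'
#' @param genes Character vector of screened genes.
#' @param n_arrays,spots_per_array,sirnas_per_gene,replicates,controls
#'   Layout parameters, see [build_layout()].
#' @param sim A [sim_config()] for the per-spot populations.
#' @param effects Named list of [knockdown_effect()]s by gene.
#' @param bias Spatial bias as in [simulate_screen()] (default: mild edge
#'   effect).
#' @param start_offset_h Imaging start relative to seeding (h); recorded in
#'   outputs.
#' @param window,shift,alpha Scoring constants (h, h, significance level).
#' @param integration Periodicity rebin width (h).
#' @param reliability_threshold Reliability filter cut-off.
#' @param lookaround,death_fraction Correction-rule constants.
#' @param image_spots Number of spots additionally pushed through the
#'   imaging path (render, segment, track, classify, correct); the
#'   phenotype scoring runs on the full screen's simulated counts.
#' @param patch_train_n Rendered training patches per class for the
#'   pipeline classifier.
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(genes,
                            n_arrays = 8, spots_per_array = 275,
                            sirnas_per_gene = 2, replicates = 4,
                            controls = c(negative_control = 8,
                                         positive_control = 8,
                                         mock = 10),
                            sim = sim_config(),
                            effects = list(),
                            bias = NULL,
                            start_offset_h = 16,
                            window = 24, shift = 8, alpha = 0.05,
                            integration = 3,
                            reliability_threshold = 0.2,
                            lookaround = 2, death_fraction = 0.5,
                            image_spots = 2, patch_train_n = 40,
                            seed = 1) {
  cfg <- list(genes = genes, n_arrays = n_arrays,
              spots_per_array = spots_per_array,
              sirnas_per_gene = sirnas_per_gene, replicates = replicates,
              controls = controls, sim = sim, effects = effects,
              bias = bias, start_offset_h = start_offset_h,
              window = window, shift = shift, alpha = alpha,
              integration = integration,
              reliability_threshold = reliability_threshold,
              lookaround = lookaround, death_fraction = death_fraction,
              image_spots = image_spots, patch_train_n = patch_train_n,
              seed = seed)
  structure(cfg, class = "pipeline_config")
}

#' Hash of a pipeline configuration
#'
#' MD5 of the serialized configuration; every output table carries it so
#' that stages can verify they read inputs produced under the same
#' configuration.
#'
#' @param config A [pipeline_config()] (or any R object).
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  saveRDS(config, f, version = 2)
  unname(tools::md5sum(f))
}

#' Write a pipeline table as CSV with an embedded configuration hash
#'
#' @param x Data frame.
#' @param path Output path.
#' @param hash Configuration hash to embed (comment line); `NULL` for none.
#' @return `path`, invisibly.
#' @export
write_screen_table <- function(x, path, hash = NULL) {
  if (!is.null(hash)) {
    writeLines(paste0("# mitokin_config_hash: ", hash), path)
    readr::write_csv(x, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_csv(x, path)
  }
  invisible(path)
}

#' Read a pipeline table, checking its schema and configuration hash
#'
#' @param path CSV path (optionally with an embedded hash comment).
#' @param required Character vector of required columns; a missing column
#'   raises a schema error naming it.
#' @param expect_hash If non-`NULL`, the embedded hash must match unless
#'   `override = TRUE`.
#' @param override Skip the hash check.
#' @return Tibble with attribute `config_hash`.
#' @export
read_screen_table <- function(path, required = NULL, expect_hash = NULL,
                              override = FALSE) {
  first <- readLines(path, n = 1)
  hash <- if (grepl("^# mitokin_config_hash:", first)) {
    trimws(sub("^# mitokin_config_hash:", "", first))
  } else NA_character_
  x <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  if (!is.null(required)) {
    missing <- setdiff(required, names(x))
    if (length(missing) > 0) {
      stop("schema violation: missing column(s) ",
           paste(missing, collapse = ", "), " in ", path)
    }
  }
  if (!is.null(expect_hash) && !override && !is.na(hash) &&
      !identical(hash, expect_hash)) {
    stop("configuration hash mismatch for ", path,
         " (use override = TRUE to force)")
  }
  attr(x, "config_hash") <- hash
  x
}

#' Run the full analysis pipeline on a synthetic screen
#'
#' Executes simulate -> (render/segment/track/classify/correct on a subset
#' of spots) -> B-score -> windowed signals -> phenotype p-values ->
#' candidate calls -> control QC -> periodicity, writing one CSV per stage
#' (plus a manifest) when `out_dir` is given. Spot-level phenotype counts
#' come from the population simulator; the imaging path is exercised on
#' `image_spots` spots and its per-object classifications are written
#' alongside.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (`NULL`: nothing written).
#' @param quiet Suppress progress messages.
#' @return List with `layout`, `counts`, `bscore`, `signal`, `profiles`,
#'   `candidates`, `qc`, `period`, `objects` (imaging-path objects, may be
#'   empty), `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (length(config$genes) == 0) stop("config validation: no genes")
  if (!inherits(config$sim, "sim_config")) {
    stop("config validation: sim must be a sim_config")
  }
  hash <- config_hash(config)
  say <- function(...) if (!quiet) message(...)

  say("stage simulate: layout + population counts")
  layout <- build_layout(config$n_arrays, config$spots_per_array,
                         config$genes, config$sirnas_per_gene,
                         config$replicates, config$controls,
                         seed = config$seed)
  counts <- simulate_screen(layout, config$sim, config$effects,
                            bias = config$bias, seed = config$seed)
  counts$time_h <- counts$time_h + config$start_offset_h

  objects <- tibble::tibble()
  if (config$image_spots > 0) {
    say("stage segment/track/classify/correct on ", config$image_spots,
        " imaged spot(s)")
    objects <- .image_path(layout, config)
  }

  say("stage score: B-score + windowed signals")
  bsc <- bscore_normalize(counts)
  sig <- window_signal(bsc, window = config$window, shift = config$shift)
  say("stage score: phenotype p-values")
  profiles <- phenotype_pvalues(sig)
  say("stage candidates")
  candidates <- call_candidates(profiles, alpha = config$alpha)
  qc <- qc_controls(window_signal(counts, window = config$window,
                                  shift = config$shift),
                    alpha = config$alpha)
  say("stage periodicity")
  pop <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(counts, .data$role != "empty"),
                    .data$frame, .data$time_h),
    interphase = mean(.data$interphase), .groups = "drop")
  period <- fit_periodicity(log2(pmax(pop$interphase, 0.5)), pop$time_h,
                            integration = config$integration)

  manifest <- tibble::tibble(
    key = c("package_version", "r_version", "config_hash", "seed",
            "n_spots", "n_frames"),
    value = c(as.character(utils::packageVersion("mitokin")),
              paste(R.version$major, R.version$minor, sep = "."),
              hash, as.character(config$seed),
              as.character(nrow(layout)),
              as.character(length(unique(counts$frame)))))

  out <- list(layout = layout, counts = counts, bscore = bsc, signal = sig,
              profiles = profiles, candidates = candidates, qc = qc,
              period = period, objects = objects, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in c("layout", "counts", "bscore", "signal", "profiles",
                 "candidates", "qc", "manifest")) {
      write_screen_table(out[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                         hash = hash)
    }
    if (nrow(objects) > 0) {
      write_screen_table(objects, file.path(out_dir, "objects.csv"),
                         hash = hash)
    }
    write_screen_table(
      tibble::tibble(period_h = period$period, amplitude = period$amplitude,
                     phase = period$phase, slope = period$slope,
                     intercept = period$intercept,
                     identifiable = period$identifiable),
      file.path(out_dir, "period.csv"), hash = hash)
  }
  out
}

# imaging path: render movies for a few spots, segment, track, classify,
# correct; returns the per-object table
.image_path <- function(layout, config) {
  spots <- utils::head(dplyr::filter(layout, .data$role != "empty"),
                       config$image_spots)
  say_train <- training_set_from_patches(
    render_nuclei_patches(config$patch_train_n, seed = config$seed + 7))
  model <- train_classifier(say_train, C_grid = 2^(1:4),
                            gamma_grid = 2^(c(-8, -6, -4)),
                            inner_folds = 5, seed = config$seed + 8)
  all_obj <- list()
  for (i in seq_len(nrow(spots))) {
    s <- spots[i, ]
    eff <- if (s$role == "positive_control") {
      knockdown_effect("death_in_mitosis", penetrance = 1)
    } else if (!is.na(s$gene) && s$gene %in% names(config$effects)) {
      config$effects[[s$gene]]
    } else knockdown_effect("none")
    truth <- simulate_population(config$sim, eff,
                                 seed = spot_seed(s$array_id, s$row, s$col,
                                                  config$seed))
    frames <- sort(unique(truth$frame))
    objs <- purrr::map(frames, function(fr) {
      cells <- dplyr::filter(truth, .data$frame == fr)
      rf <- render_frame(cells, image_shape = config$sim$arena_px,
                         seed = spot_seed(s$array_id, s$row, s$col,
                                          config$seed + fr))
      ft <- segment_frame(rf$image)
      if (nrow(ft) > 0) dplyr::mutate(ft, frame = fr) else NULL
    })
    objs <- dplyr::bind_rows(objs)
    if (nrow(objs) == 0) next
    objs$object_id <- seq_len(nrow(objs)) # globally unique ids
    trk <- track_movie(objs)
    pred <- predict_with_reliability(model, objs)
    flt <- reliability_filter(pred, config$reliability_threshold)
    lab <- dplyr::inner_join(
      trk$trajectories,
      dplyr::select(flt$kept, dplyr::all_of(c("object_id", "pred_label",
                                              "is_cluster", "reliability"))),
      by = "object_id")
    lab <- dplyr::rename(lab, label = "pred_label")
    corr <- apply_correction(lab, config$lookaround, config$death_fraction)
    corr <- dplyr::mutate(corr, array_id = s$array_id, row = s$row,
                          col = s$col)
    all_obj[[i]] <- dplyr::left_join(
      corr, dplyr::select(objs, dplyr::all_of(c("object_id", "x", "y",
                                                "area", "mean_intensity"))),
      by = "object_id")
  }
  dplyr::bind_rows(all_obj)
}
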