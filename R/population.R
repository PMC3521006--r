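#' Configuration for a synthetic nucleus population
#'
#' Describes one imaged spot: an exponentially proliferating, optionally
#' transfection-synchronized population of nuclei sampled at the screen's
#' acquisition interval. Presets fix the mean cell-cycle duration at 35 h
#' (`"SH-EP"`) and 31 h (`"SK-N-BE(2)-C"`).
#'
#' The per-cell generation time is drawn from a normal distribution
#' truncated below at half its mean (default sd = 10% of the mean), so
#' synchrony decays over successive division waves. The visible mitosis
#' duration defaults to one acquisition interval: at the screen's sampling
#' rate a division is typically caught in a single snapshot.
#'
#' @param preset `"SH-EP"`, `"SK-N-BE(2)-C"` or `"custom"`.
#' @param n_cells_initial Mean number of seeded cells in the imaged field.
#' @param division_time_mean Mean generation time in hours (fixed by the
#'   non-custom presets).
#' @param division_time_sd Sd of the generation time in hours (default 10%
#'   of the mean).
#' @param mitosis_duration Visible mitosis duration in hours (default one
#'   acquisition interval).
#' @param synchronization Logical; if `TRUE` all founder cells start a fresh
#'   cycle at time zero (transfection-induced synchronization).
#' @param acquisition_interval Imaging interval in minutes (35-40 in a
#'   typical screen).
#' @param total_duration Screen span in hours (default 120 = five days).
#' @param arena_px Width/height of the imaged field in pixels.
#' @param drift_rate Random-walk cell motility in px/h.
#' @param dead_visible_h Hours a dead cell's fragments stay visible
#'   (default `Inf`: at this magnification the bright fragment clusters
#'   remain detectable for the rest of the movie).
#' @param basal_death_rate Baseline per-hour death hazard of any live cell
#'   (spontaneous/transfection-stress apoptosis present in every spot of a
#'   real screen).
#' @return A `sim_config` list.
#' @export
sim_config <- function(preset = c("SH-EP", "SK-N-BE(2)-C", "custom"),
                       n_cells_initial = 50,
                       division_time_mean = NULL,
                       division_time_sd = NULL,
                       mitosis_duration = NULL,
                       synchronization = TRUE,
                       acquisition_interval = 40,
                       total_duration = 120,
                       arena_px = c(256, 256),
                       drift_rate = 5,
                       dead_visible_h = Inf,
                       basal_death_rate = 0.0015) {
  preset <- match.arg(preset)
  if (is.null(division_time_mean)) {
    division_time_mean <- switch(preset,
      "SH-EP" = 35, "SK-N-BE(2)-C" = 31,
      stop("preset \"custom\" requires division_time_mean")
    )
  } else if (preset != "custom") {
    stop("division_time_mean is fixed by the preset; use preset = \"custom\"")
  }
  if (is.null(division_time_sd)) division_time_sd <- 0.1 * division_time_mean
  if (is.null(mitosis_duration)) mitosis_duration <- acquisition_interval / 60
  stopifnot(
    division_time_mean > 0, division_time_sd >= 0,
    acquisition_interval > 0, total_duration > 0, n_cells_initial >= 0
  )
  structure(list(
    preset = preset,
    n_cells_initial = n_cells_initial,
    division_time_mean = division_time_mean,
    division_time_sd = division_time_sd,
    mitosis_duration = mitosis_duration,
    synchronization = synchronization,
    acquisition_interval = acquisition_interval,
    total_duration = total_duration,
    arena_px = arena_px,
    drift_rate = drift_rate,
    dead_visible_h = dead_visible_h,
    basal_death_rate = basal_death_rate
  ), class = "sim_config")
}

#' Describe a knockdown effect archetype
#'
#' The effect archetypes mirror the classic fates of a mitotic-gene
#' knockdown: death during mitotic arrest, mitotic slippage followed by
#' death in interphase, direct interphase death, clean cell-cycle arrest,
#' or no effect.
#'
#' @param kind One of `"none"`, `"death_in_mitosis"`,
#'   `"slippage_then_death"`, `"interphase_death"`, `"arrest"`.
#' @param penetrance Per-cell probability of being affected (0-1).
#' @param onset Hours after seeding at which the knockdown becomes active.
#' @param delay Mean death lag in hours (after slippage, or after onset for
#'   interphase death); individual lags are exponential with this mean.
#' @param arrest_h Hours an affected cell stays arrested in mitosis before
#'   dying (death in mitosis) or slipping (slippage).
#' @return A `knockdown_effect` list.
#' @export
knockdown_effect <- function(kind = c("none", "death_in_mitosis",
                                      "slippage_then_death",
                                      "interphase_death", "arrest"),
                             penetrance = 1, onset = 24, delay = 12,
                             arrest_h = 6) {
  kind <- match.arg(kind)
  stopifnot(penetrance >= 0, penetrance <= 1, onset >= 0, delay >= 0,
            arrest_h >= 0)
  structure(list(kind = kind, penetrance = penetrance, onset = onset,
                 delay = delay, arrest_h = arrest_h),
            class = "knockdown_effect")
}

# truncated-normal generation times (lower bound half the mean)
.draw_cycle <- function(n, mean, sd) {
  if (n == 0) return(numeric(0))
  x <- stats::rnorm(n, mean, sd)
  lo <- 0.5 * mean
  while (any(bad <- x < lo)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Simulate a nucleus population under a knockdown effect
#'
#' Discrete-time branching simulation sampled at the acquisition interval.
#' Cells progress interphase -> mitosis -> two daughters; knockdown effects
#' divert this into mitotic death, slippage followed by interphase death,
#' direct interphase death, or arrest. Dead cells never re-enter another
#' phase. The first frame of each daughter is labelled `mitosis` (chromatin
#' is still condensed right after anaphase), thereafter `interphase`.
#'
#' @param config A [sim_config()].
#' @param effect A [knockdown_effect()] (default: no effect).
#' @param seed Integer seed.
#' @param keep `"truth"` to return the per-timepoint ground-truth table,
#'   `"counts"` to return per-frame phenotype counts only (faster).
#' @return For `keep = "truth"`: a tibble with one row per visible cell per
#'   frame (`frame`, `time_h`, `cell_id`, `parent_id`, `label`, `x`, `y`).
#'   For `keep = "counts"`: a tibble `frame`, `time_h`, `interphase`,
#'   `mitosis`, `cell_death`.
#' @examples
#' truth <- simulate_population(sim_config(n_cells_initial = 10), seed = 1)
#' head(truth)
#' @export
simulate_population <- function(config, effect = knockdown_effect("none"),
                                seed = 1, keep = c("truth", "counts")) {
  keep <- match.arg(keep)
  stopifnot(inherits(config, "sim_config"), inherits(effect, "knockdown_effect"))
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)

  dt <- config$acquisition_interval / 60
  times <- seq(0, config$total_duration, by = dt)
  n_frames <- length(times)
  m_dur <- config$mitosis_duration
  kind <- effect$kind
  pen <- effect$penetrance
  onset <- effect$onset

  n0 <- stats::rpois(1, config$n_cells_initial)
  # state vectors, one slot per cell ever created
  id <- seq_len(n0)
  parent <- rep(NA_integer_, n0)
  cyc <- .draw_cycle(n0, config$division_time_mean, config$division_time_sd)
  birth <- if (config$synchronization) rep(0, n0) else -stats::runif(n0, 0, cyc)
  phase <- rep(1L, n0)               # 1 interphase, 2 mitosis, 3 dead, 4 removed
  phase_entry <- rep(0, n0)
  mit_due <- birth + pmax(cyc - m_dur, 0.25 * cyc)
  affected <- rep(NA, n0)            # assigned when onset passes / at birth
  death_due <- rep(Inf, n0)
  mrg <- 10 # keep nuclei fully inside the imaged field
  x <- stats::runif(n0, mrg, config$arena_px[1] - mrg)
  y <- stats::runif(n0, mrg, config$arena_px[2] - mrg)
  next_id <- n0 + 1L

  rows <- vector("list", n_frames)
  counts <- matrix(0L, n_frames, 3,
                   dimnames = list(NULL, c("interphase", "mitosis", "cell_death")))

  assign_affected <- function(idx, t) {
    # penetrance draw once the knockdown is active
    new <- idx[is.na(affected[idx]) & t >= onset]
    if (length(new)) {
      affected[new] <<- stats::runif(length(new)) < pen
      if (kind == "arrest") {
        hit <- new[affected[new] & phase[new] == 1L]
        mit_due[hit] <<- Inf
      }
      if (kind == "interphase_death") {
        hit <- new[affected[new] & phase[new] == 1L]
        death_due[hit] <<- t + stats::rexp(length(hit), 1 / max(effect$delay, 1e-6))
      }
    }
  }

  for (k in seq_len(n_frames)) {
    t <- times[k]
    assign_affected(which(phase <= 2L), t)

    # basal (spontaneous) deaths
    base_rate <- config$basal_death_rate
    if (is.null(base_rate)) base_rate <- 0
    if (base_rate > 0) {
      live <- which(phase == 1L)
      hit <- live[stats::runif(length(live)) < base_rate * dt]
      if (length(hit)) death_due[hit] <- pmin(death_due[hit], t)
    }
    # interphase deaths due
    dying <- which(phase == 1L & death_due <= t)
    if (length(dying)) {
      phase[dying] <- 3L
      phase_entry[dying] <- t
    }

    # mitosis exits
    in_m <- which(phase == 2L)
    if (length(in_m)) {
      eff_m <- in_m[!is.na(affected[in_m]) & affected[in_m] &
                      kind %in% c("death_in_mitosis", "slippage_then_death")]
      norm_m <- setdiff(in_m, eff_m)
      # normal division after the visible mitosis duration
      div <- norm_m[t - phase_entry[norm_m] >= m_dur - 1e-9]
      if (length(div)) {
        nd <- 2L * length(div)
        d_cyc <- .draw_cycle(nd, config$division_time_mean, config$division_time_sd)
        d_id <- seq.int(next_id, length.out = nd)
        next_id <- next_id + nd
        id <- c(id, d_id)
        parent <- c(parent, rep(id[div], each = 2L))
        cyc <- c(cyc, d_cyc)
        birth <- c(birth, rep(t, nd))
        phase <- c(phase, rep(1L, nd))
        phase_entry <- c(phase_entry, rep(t, nd))
        mit_due <- c(mit_due, t + pmax(d_cyc - m_dur, 0.25 * d_cyc))
        affected <- c(affected, if (t >= onset) stats::runif(nd) < pen
                      else rep(NA, nd))
        death_due <- c(death_due, rep(Inf, nd))
        if (kind == "arrest") {
          hit <- which(utils::tail(affected, nd)) + length(phase) - nd
          mit_due[hit] <- Inf
        }
        if (kind == "interphase_death") {
          hit <- which(utils::tail(affected, nd)) + length(phase) - nd
          death_due[hit] <- t + stats::rexp(length(hit), 1 / max(effect$delay, 1e-6))
        }
        # daughters separate in opposite directions (anaphase axis)
        th <- rep(stats::runif(length(div), 0, pi), each = 2L)
        sgn <- rep(c(-1, 1), length(div))
        x <- c(x, rep(x[div], each = 2L) + sgn * 7 * cos(th))
        y <- c(y, rep(y[div], each = 2L) + sgn * 7 * sin(th))
        phase[div] <- 4L  # mother replaced by daughters
      }
      # affected cells resolve after the arrest duration
      res <- eff_m[t - phase_entry[eff_m] >= effect$arrest_h - 1e-9]
      if (length(res)) {
        if (kind == "death_in_mitosis") {
          phase[res] <- 3L
          phase_entry[res] <- t
        } else { # slippage: back to (arrested) interphase, death later
          phase[res] <- 1L
          phase_entry[res] <- t
          birth[res] <- t - m_dur - 1e-6 # not re-labelled as fresh daughter
          mit_due[res] <- Inf
          death_due[res] <- t + stats::rexp(length(res),
                                            1 / max(effect$delay, 1e-6))
        }
      }
    }

    # mitosis entries
    entering <- which(phase == 1L & mit_due <= t)
    if (length(entering)) {
      phase[entering] <- 2L
      phase_entry[entering] <- t
    }

    # dead fragments fade out
    gone <- which(phase == 3L & t - phase_entry > config$dead_visible_h)
    if (length(gone)) phase[gone] <- 4L

    # random-walk motility
    alive <- which(phase <= 3L)
    if (length(alive)) {
      step <- config$drift_rate * dt
      x[alive] <- pmin(pmax(x[alive] + stats::rnorm(length(alive), 0, step),
                            mrg), config$arena_px[1] - mrg)
      y[alive] <- pmin(pmax(y[alive] + stats::rnorm(length(alive), 0, step),
                            mrg), config$arena_px[2] - mrg)
    }

    vis <- which(phase <= 3L)
    lab <- character(length(vis))
    lab[phase[vis] == 2L] <- "mitosis"
    lab[phase[vis] == 3L] <- "cell_death"
    ip <- phase[vis] == 1L
    # daughters keep condensed chromatin for their first frame
    newborn <- !is.na(parent[vis]) & t - birth[vis] < m_dur - 1e-9 &
      phase[vis] == 1L
    lab[ip] <- ifelse(newborn[ip], "mitosis", "interphase")
    if (keep == "counts") {
      counts[k, ] <- tabulate(match(lab, colnames(counts)), 3L)
    } else {
      rows[[k]] <- tibble::tibble(
        frame = k, time_h = t,
        cell_id = id[vis], parent_id = parent[vis],
        label = lab, newborn = newborn, x = x[vis], y = y[vis]
      )
    }
  }

  if (keep == "counts") {
    out <- tibble::as_tibble(counts)
    out <- dplyr::mutate(out, frame = seq_len(n_frames), time_h = times,
                         .before = 1)
  } else {
    out <- dplyr::bind_rows(rows)
  }
  attr(out, "config") <- config
  attr(out, "effect") <- effect
  out
}

#' Per-frame phenotype counts from a ground-truth (or classified) table
#'
#' @param truth Tibble with `frame`, `time_h` and `label` columns (e.g. from
#'   [simulate_population()]), optionally grouped by extra id columns passed
#'   in `by`.
#' @param by Character vector of extra grouping columns (e.g. spot ids).
#' @param label_col Name of the label column to tabulate.
#' @return Wide tibble of counts per frame (and `by` groups) with one column
#'   per phenotype class.
#' @export
count_phenotypes <- function(truth, by = character(),
                             label_col = "label") {
  classes <- c("interphase", "mitosis", "cell_death", "artifact")
  out <- dplyr::count(truth,
                      dplyr::across(dplyr::all_of(c(by, "frame", "time_h"))),
                      label = factor(.data[[label_col]], levels = classes))
  out <- tidyr::pivot_wider(out, names_from = "label", values_from = "n",
                            values_fill = 0L, names_expand = TRUE)
  dplyr::arrange(out, dplyr::across(dplyr::all_of(c(by, "frame"))))
}
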