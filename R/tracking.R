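#' Link segmented objects between two consecutive frames
#'
#' One-to-one assignment of objects by a combined cost: spatial distance
#' plus feature dissimilarity (Euclidean distance on z-scored area, mean
#' intensity and circularity), each normalized by the median over candidate
#' pairs so the two terms are commensurate. Pairs farther apart than
#' `gate_radius` are never linked. Matching is greedy by ascending cost;
#' unmatched objects open or close trajectories.
#'
#' @param objects_t,objects_t1 Tibbles of segmented objects in frames t and
#'   t+1 with columns `object_id`, `x`, `y`, `area`, `mean_intensity` and
#'   optionally `circularity`.
#' @param gate_radius Maximum link distance in pixels.
#' @return Tibble `from`, `to`, `spatial`, `feature`, `cost`, one row per
#'   link.
#' @export
link_frames <- function(objects_t, objects_t1, gate_radius = 25) {
  stopifnot(gate_radius > 0)
  if (nrow(objects_t) == 0 || nrow(objects_t1) == 0) {
    return(tibble::tibble(from = integer(0), to = integer(0),
                          spatial = numeric(0), feature = numeric(0),
                          cost = numeric(0)))
  }
  feat_cols <- intersect(c("area", "mean_intensity", "circularity"),
                         intersect(names(objects_t), names(objects_t1)))
  pool <- rbind(as.matrix(objects_t[feat_cols]),
                as.matrix(objects_t1[feat_cols]))
  mu <- colMeans(pool); sd <- pmax(apply(pool, 2, stats::sd), 1e-9)
  f_t <- sweep(sweep(as.matrix(objects_t[feat_cols]), 2, mu), 2, sd, "/")
  f_t1 <- sweep(sweep(as.matrix(objects_t1[feat_cols]), 2, mu), 2, sd, "/")

  dx <- outer(objects_t$x, objects_t1$x, "-")
  dy <- outer(objects_t$y, objects_t1$y, "-")
  d_sp <- sqrt(dx^2 + dy^2)
  cand <- which(d_sp <= gate_radius, arr.ind = TRUE)
  if (nrow(cand) == 0) {
    return(tibble::tibble(from = integer(0), to = integer(0),
                          spatial = numeric(0), feature = numeric(0),
                          cost = numeric(0)))
  }
  d_ft <- sqrt(rowSums((f_t[cand[, 1], , drop = FALSE] -
                          f_t1[cand[, 2], , drop = FALSE])^2))
  sp <- d_sp[cand]
  s_spatial <- max(stats::median(sp), 1e-9)
  s_feature <- max(stats::median(d_ft), 1e-9)
  cost <- sp / s_spatial + d_ft / s_feature

  ord <- order(cost)
  used_t <- logical(nrow(objects_t)); used_t1 <- logical(nrow(objects_t1))
  keep <- integer(0)
  for (k in ord) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!used_t[i] && !used_t1[j]) {
      used_t[i] <- TRUE; used_t1[j] <- TRUE
      keep <- c(keep, k)
    }
  }
  tibble::tibble(from = objects_t$object_id[cand[keep, 1]],
                 to = objects_t1$object_id[cand[keep, 2]],
                 spatial = sp[keep], feature = d_ft[keep],
                 cost = cost[keep])
}

#' Detect mitosis (cell-splitting) events
#'
#' For each candidate mother (a trajectory end at frame t), examines pairs
#' of nearby candidate daughters at t+1 and evaluates a mitosis likelihood:
#' a product of Gaussian terms on the combined daughter/mother area ratio
#' (mode 1), the daughter area asymmetry (mode 0) and the daughter/mother
#' intensity ratio (mitotic chromatin is brighter, so ratios above the mode
#' are not penalized). Candidate daughters dimmer than `intensity_frac`
#' times the frame's mean object intensity are disregarded, which
#' suppresses splits onto debris.
#'
#' @param ends Tibble of candidate mothers (columns as in [link_frames()]).
#' @param new_objects Tibble of unmatched objects at t+1.
#' @param frame_mean_intensity Mean object intensity of frame t+1; computed
#'   from `new_objects` when `NULL`.
#' @param gate_radius Search radius around the mother in pixels.
#' @param threshold Minimum likelihood to accept a split.
#' @param intensity_frac Minimum daughter intensity as a fraction of the
#'   frame mean object intensity.
#' @param sigma_sum,sigma_asym,sigma_int Widths of the Gaussian terms.
#' @param intensity_mode Mode of the daughter/mother intensity ratio term.
#'   When `ends` carries a `ref_intensity` column (the mother's intensity
#'   one frame earlier, where it is still an uncondensed interphase
#'   nucleus), the ratio uses it as the denominator; two touching
#'   interphase cells that drift apart then yield a ratio near 1 and are
#'   penalized, while genuine mitoses (bright condensed daughters) are
#'   not.
#' @return Tibble `mother`, `daughter1`, `daughter2`, `likelihood`.
#' @export
detect_splits <- function(ends, new_objects, frame_mean_intensity = NULL,
                          gate_radius = 25, threshold = 0.15,
                          intensity_frac = 0.5,
                          sigma_sum = 0.25, sigma_asym = 0.25,
                          sigma_int = 0.08, intensity_mode = 1.2) {
  out <- tibble::tibble(mother = integer(0), daughter1 = integer(0),
                        daughter2 = integer(0), likelihood = numeric(0))
  if (nrow(ends) == 0 || nrow(new_objects) < 2) return(out)
  if (is.null(frame_mean_intensity)) {
    frame_mean_intensity <- mean(new_objects$mean_intensity)
  }
  pool <- dplyr::filter(new_objects,
                        .data$mean_intensity >=
                          intensity_frac * frame_mean_intensity)
  if (nrow(pool) < 2) return(out)
  taken <- character(0)
  for (i in seq_len(nrow(ends))) {
    d <- sqrt((pool$x - ends$x[i])^2 + (pool$y - ends$y[i])^2)
    near <- which(d <= gate_radius & !(as.character(pool$object_id) %in% taken))
    if (length(near) < 2) next
    near <- near[order(d[near])][1:2]
    a1 <- pool$area[near[1]]; a2 <- pool$area[near[2]]
    am <- ends$area[i]
    im <- if ("ref_intensity" %in% names(ends)) ends$ref_intensity[i] else
      ends$mean_intensity[i]
    s <- (a1 + a2) / am
    asym <- abs(a1 - a2) / am
    ir <- mean(pool$mean_intensity[near]) / im
    l1 <- exp(-((s - 1) / sigma_sum)^2 / 2)
    l2 <- exp(-(asym / sigma_asym)^2 / 2)
    l3 <- if (ir >= intensity_mode) 1 else {
      exp(-((ir - intensity_mode) / sigma_int)^2 / 2)
    }
    lik <- l1 * l2 * l3
    if (lik > threshold) {
      out <- dplyr::bind_rows(out, tibble::tibble(
        mother = ends$object_id[i],
        daughter1 = pool$object_id[near[1]],
        daughter2 = pool$object_id[near[2]],
        likelihood = lik))
      taken <- c(taken, as.character(pool$object_id[near]))
    }
  }
  out
}

#' Assemble trajectories from frame links and split events
#'
#' Builds the trajectory forest: chains of linked objects form branches; a
#' split ends the mother branch and starts two daughter branches that point
#' back to it. Every object belongs to exactly one branch; an object
#' claimed by two links (or by a link and a split) raises an error.
#'
#' @param objects Tibble of all objects (`object_id`, `frame`).
#' @param assignments Tibble of links (`from`, `to`), e.g. accumulated from
#'   [link_frames()].
#' @param splits Tibble of split events (`mother`, `daughter1`,
#'   `daughter2`) from [detect_splits()].
#' @return Tibble `track_id`, `branch_id`, `parent_branch`, `frame`,
#'   `object_id`, ordered by branch and frame.
#' @export
build_trajectories <- function(objects, assignments,
                               splits = tibble::tibble(
                                 mother = integer(0), daughter1 = integer(0),
                                 daughter2 = integer(0))) {
  incoming <- c(assignments$to, splits$daughter1, splits$daughter2)
  if (any(duplicated(incoming))) {
    stop("inconsistent links: object(s) claimed twice: ",
         paste(unique(incoming[duplicated(incoming)]), collapse = ", "))
  }
  pred <- stats::setNames(assignments$from, assignments$to)
  mother_of <- stats::setNames(rep(splits$mother, 2),
                               c(splits$daughter1, splits$daughter2))

  ord <- order(objects$frame)
  branch <- stats::setNames(rep(NA_integer_, nrow(objects)),
                            objects$object_id)
  track <- branch
  parent_branch <- integer(0)
  track_of_branch <- integer(0)
  n_branch <- 0L; n_track <- 0L
  for (k in ord) {
    oid <- as.character(objects$object_id[k])
    if (!is.na(pred[oid])) {          # continuation of a branch
      branch[oid] <- branch[as.character(pred[oid])]
      track[oid] <- track[as.character(pred[oid])]
    } else {
      n_branch <- n_branch + 1L
      branch[oid] <- n_branch
      if (!is.na(mother_of[oid])) {   # daughter branch after a split
        mb <- branch[as.character(mother_of[oid])]
        parent_branch[n_branch] <- mb
        track[oid] <- track[as.character(mother_of[oid])]
      } else {                        # new root
        parent_branch[n_branch] <- NA_integer_
        n_track <- n_track + 1L
        track[oid] <- n_track
      }
      track_of_branch[n_branch] <- track[oid]
    }
  }
  tibble::tibble(
    track_id = unname(track[as.character(objects$object_id)]),
    branch_id = unname(branch[as.character(objects$object_id)]),
    parent_branch = parent_branch[
      unname(branch[as.character(objects$object_id)])],
    frame = objects$frame,
    object_id = objects$object_id
  ) |> dplyr::arrange(.data$branch_id, .data$frame)
}

#' Track segmented objects across a whole movie
#'
#' Runs [link_frames()] over consecutive frame pairs, closes single-frame
#' gaps (an object missed by segmentation for one frame can still continue
#' its trajectory), detects mitosis events among the remaining trajectory
#' ends with [detect_splits()], and assembles the trajectory forest with
#' [build_trajectories()]. When a split is accepted for a mother that had
#' already claimed one of the daughters as a plain link, the link is
#' revoked in favour of the split.
#'
#' @param objects Tibble of segmented objects over all frames
#'   (`object_id`, `frame`, `x`, `y`, `area`, `mean_intensity`, ...).
#' @param gate_radius Link gate in pixels.
#' @param gap_frames Maximum number of missed frames to bridge (0 or 1).
#' @param split_args List of arguments passed on to [detect_splits()].
#' @return List with `trajectories` (from [build_trajectories()]),
#'   `assignments` and `splits`.
#' @export
track_movie <- function(objects, gate_radius = 25, gap_frames = 1,
                        split_args = list()) {
  frames <- sort(unique(objects$frame))
  assignments <- list()
  splits <- list()
  prev_unmatched <- NULL # ends of frame t-1 unmatched at t (for gap closing)
  int_of <- stats::setNames(objects$mean_intensity,
                            as.character(objects$object_id))
  ref_map <- int_of # predecessor intensity; self until an object is linked
  for (fi in seq_along(frames)[-1]) {
    t0 <- frames[fi - 1]; t1 <- frames[fi]
    obj0 <- dplyr::filter(objects, .data$frame == t0)
    obj0$ref_intensity <- unname(ref_map[as.character(obj0$object_id)])
    obj1 <- dplyr::filter(objects, .data$frame == t1)
    links <- link_frames(obj0, obj1, gate_radius)
    un1 <- dplyr::filter(obj1, !(.data$object_id %in% links$to))
    # single-frame gap closing against stale ends
    if (gap_frames >= 1 && !is.null(prev_unmatched) &&
        nrow(prev_unmatched) > 0 && nrow(un1) > 0) {
      gap_links <- link_frames(prev_unmatched, un1, gate_radius)
      links <- dplyr::bind_rows(links, gap_links)
      un1 <- dplyr::filter(un1, !(.data$object_id %in% links$to))
    }
    # split detection: ends of t (unmatched or matched to a putative
    # daughter) against unmatched objects of t+1 plus their own partner
    ends <- dplyr::filter(obj0, !(.data$object_id %in% links$from))
    cand_mothers <- dplyr::bind_rows(
      ends,
      dplyr::filter(obj0, .data$object_id %in%
                      links$from[links$to %in% obj1$object_id]))
    pool <- dplyr::bind_rows(
      un1,
      dplyr::semi_join(obj1,
                       tibble::tibble(object_id = links$to),
                       by = "object_id"))
    sp <- do.call(detect_splits, c(list(
      ends = cand_mothers, new_objects = pool,
      frame_mean_intensity = mean(obj1$mean_intensity),
      gate_radius = gate_radius), split_args))
    if (nrow(sp) > 0) {
      # keep only splits whose daughters are free or linked to this mother
      ok <- logical(nrow(sp))
      for (i in seq_len(nrow(sp))) {
        ds <- c(sp$daughter1[i], sp$daughter2[i])
        owners <- links$from[links$to %in% ds]
        ok[i] <- all(owners %in% sp$mother[i])
      }
      sp <- sp[ok, , drop = FALSE]
      links <- dplyr::filter(links,
                             !(.data$to %in% c(sp$daughter1, sp$daughter2)),
                             !(.data$from %in% sp$mother))
    }
    assignments[[fi]] <- links
    splits[[fi]] <- sp
    ref_map[as.character(links$to)] <- int_of[as.character(links$from)]
    if (nrow(sp) > 0) {
      ref_map[as.character(c(sp$daughter1, sp$daughter2))] <-
        int_of[as.character(rep(sp$mother, 2))]
    }
    prev_unmatched <- dplyr::filter(
      obj0, !(.data$object_id %in% c(links$from, sp$mother)))
    prev_unmatched <- utils::head(prev_unmatched, 200) # stale-end cap
  }
  assignments <- dplyr::bind_rows(assignments)
  splits <- dplyr::bind_rows(splits)
  list(trajectories = build_trajectories(objects, assignments, splits),
       assignments = assignments, splits = splits)
}
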