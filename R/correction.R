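#' Trajectory view of a ground-truth table
#'
#' Converts a [simulate_population()] truth table into labelled
#' trajectories: each cell is one branch, daughter branches point to the
#' mother branch, and track ids group whole lineage trees. The result has
#' the same shape as [build_trajectories()] output plus the truth `label`.
#'
#' @param truth Truth tibble (`frame`, `cell_id`, `parent_id`, `label`).
#' @return Tibble `track_id`, `branch_id`, `parent_branch`, `frame`,
#'   `object_id`, `label` (one row per cell per frame).
#' @export
truth_trajectories <- function(truth) {
  ids <- sort(unique(truth$cell_id))
  branch_of <- stats::setNames(seq_along(ids), ids)
  first <- dplyr::slice_min(dplyr::group_by(truth, .data$cell_id),
                            .data$frame, n = 1, with_ties = FALSE)
  parent <- stats::setNames(first$parent_id, first$cell_id)
  root <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  find_root <- function(cid) {
    chain <- character(0)
    cur <- as.character(cid)
    while (is.na(root[cur]) && !is.na(parent[cur])) {
      chain <- c(chain, cur)
      cur <- as.character(parent[cur])
    }
    r <- if (is.na(parent[cur])) branch_of[cur] else root[cur]
    root[c(chain, cur)] <<- r
    r
  }
  track_of <- vapply(ids, function(i) find_root(i), numeric(1))
  tibble::tibble(
    track_id = unname(track_of[as.character(truth$cell_id)]),
    branch_id = unname(branch_of[as.character(truth$cell_id)]),
    parent_branch = unname(branch_of[as.character(
      parent[as.character(truth$cell_id)])]),
    frame = truth$frame,
    object_id = seq_len(nrow(truth)),
    label = truth$label
  ) |> dplyr::arrange(.data$branch_id, .data$frame)
}

#' Apply tracking-based classification correction rules
#'
#' Overlays per-object phenotype labels on trajectories and applies three
#' rules, in a single R1 -> R2 -> R3 pass:
#'
#' * **R1** (no missed mitoses): at every splitting event the mother
#'   nucleus and both immediate daughter nuclei are labelled `mitosis`.
#' * **R2** (no spurious mitoses): an object labelled `mitosis` keeps the
#'   label only if it is a split mother or daughter, a split precedes or
#'   follows it within `lookaround` frames on its own branch, its immediate
#'   successor is a cluster object (a split inside a cluster is
#'   undetectable), or its immediate successor is labelled `cell_death`.
#'   Otherwise it is corrected to `interphase`.
#' * **R3** (no spurious deaths): an object labelled `cell_death` keeps the
#'   label only if its immediate successor is `cell_death` and at least
#'   `death_fraction` of the rest of its branch is labelled `cell_death`;
#'   otherwise it is corrected to `interphase`.
#'
#' `artifact` labels are never altered. Objects removed upstream (e.g. by
#' the reliability filter) are simply absent, so "immediate successor"
#' means the next retained object on the branch.
#'
#' @param labeled Tibble of labelled trajectories: `branch_id`,
#'   `parent_branch`, `frame`, `object_id`, `label`, optionally
#'   `is_cluster`.
#' @param lookaround K, the rule-2 window in frames around a split.
#' @param death_fraction Minimum fraction of the remaining branch labelled
#'   `cell_death` for rule 3 (a tie at exactly the fraction counts as
#'   death).
#' @return `labeled` with `corrected_label` and `rule` (`none`, `R1`,
#'   `R2`, `R3`) columns appended.
#' @export
apply_correction <- function(labeled, lookaround = 2, death_fraction = 0.5) {
  lab <- dplyr::arrange(labeled, .data$branch_id, .data$frame)
  n <- nrow(lab)
  cur <- as.character(lab$label)
  rule <- rep("none", n)
  is_art <- cur == "artifact"
  cluster <- if ("is_cluster" %in% names(lab)) lab$is_cluster else
    rep(FALSE, n)

  br <- lab$branch_id
  idx_by_branch <- split(seq_len(n), br)
  first_of <- vapply(idx_by_branch, `[`, numeric(1), 1)
  last_of <- vapply(idx_by_branch, function(i) i[length(i)], numeric(1))
  kids <- lab$parent_branch[first_of]          # parent of each branch
  branch_names <- as.numeric(names(idx_by_branch))
  kids_of <- split(branch_names, factor(kids, levels = branch_names))

  # split events: branch with children -> mother = its last object,
  # daughters = first object of each child branch
  mother_rows <- integer(0); daughter_rows <- integer(0)
  split_frame_of_branch <- stats::setNames(rep(NA_real_, length(branch_names)),
                                           branch_names)
  origin_frame_of_branch <- split_frame_of_branch
  for (b in seq_along(branch_names)) {
    ch <- kids_of[[as.character(branch_names[b])]]
    if (length(ch) > 0) {
      m <- last_of[b]
      mother_rows <- c(mother_rows, m)
      split_frame_of_branch[b] <- lab$frame[m]
      for (cb in ch) {
        d <- first_of[match(cb, branch_names)]
        daughter_rows <- c(daughter_rows, d)
        origin_frame_of_branch[match(cb, branch_names)] <- lab$frame[d]
      }
    }
  }

  # successor within branch (NA at branch end)
  succ <- rep(NA_integer_, n)
  for (i in idx_by_branch) {
    if (length(i) > 1) succ[i[-length(i)]] <- i[-1]
  }

  # R1
  r1 <- setdiff(c(mother_rows, daughter_rows), which(is_art))
  changed <- r1[cur[r1] != "mitosis"]
  cur[r1] <- "mitosis"
  rule[changed] <- "R1"

  # R2
  split_involved <- rep(FALSE, n)
  split_involved[c(mother_rows, daughter_rows)] <- TRUE
  bmatch <- match(br, branch_names)
  near_split <- (!is.na(split_frame_of_branch[bmatch]) &
                   abs(lab$frame - split_frame_of_branch[bmatch]) <= lookaround) |
    (!is.na(origin_frame_of_branch[bmatch]) &
       abs(lab$frame - origin_frame_of_branch[bmatch]) <= lookaround)
  succ_cluster <- !is.na(succ) & cluster[pmax(succ, 1)]
  succ_death <- !is.na(succ) & cur[pmax(succ, 1)] == "cell_death"
  m_rows <- which(cur == "mitosis" & !is_art)
  bad <- m_rows[!(split_involved[m_rows] | near_split[m_rows] |
                    succ_cluster[m_rows] | succ_death[m_rows])]
  cur[bad] <- "interphase"
  rule[bad] <- "R2"

  # R3 (on post-R2 labels); an object at the end of its branch has no
  # successor because observation stopped, not because the cell recovered,
  # so the successor condition is vacuously satisfied there
  snapshot <- cur
  d_rows <- which(snapshot == "cell_death" & !is_art)
  for (i in d_rows) {
    s <- succ[i]
    if (is.na(s)) next
    keep <- snapshot[s] == "cell_death"
    if (keep) {
      rest <- idx_by_branch[[as.character(br[i])]]
      rest <- rest[rest > i]
      keep <- mean(snapshot[rest] == "cell_death") >= death_fraction
    }
    if (!keep) {
      cur[i] <- "interphase"
      rule[i] <- "R3"
    }
  }

  lab$corrected_label <- cur
  lab$rule <- rule
  lab
}

#' Compare classification accuracy before and after correction
#'
#' @param truth,before,after Aligned label vectors (or tibbles with a
#'   `label`/`corrected_label` column).
#' @return List with `before` and `after`, each containing `accuracy`,
#'   `per_class` recall and the predicted x true `confusion` matrix, plus
#'   `delta` (after - before overall accuracy).
#' @export
evaluate_correction <- function(truth, before, after) {
  pick <- function(x, cols) {
    if (is.data.frame(x)) {
      col <- intersect(cols, names(x))[1]
      as.character(x[[col]])
    } else as.character(x)
  }
  tr <- pick(truth, c("label", "true_label"))
  be <- pick(before, c("label", "pred_label"))
  af <- pick(after, c("corrected_label", "label"))
  if (length(tr) != length(be) || length(tr) != length(af)) {
    stop("length mismatch: truth, before and after must align")
  }
  classes <- sort(unique(c(tr, be, af)))
  report <- function(pred) {
    cm <- table(factor(pred, classes), factor(tr, classes))
    list(accuracy = mean(pred == tr),
         per_class = tibble::tibble(
           class = classes,
           recall = diag(cm) / pmax(colSums(cm), 1)),
         confusion = as.matrix(cm))
  }
  b <- report(be); a <- report(af)
  list(before = b, after = a, delta = a$accuracy - b$accuracy)
}
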