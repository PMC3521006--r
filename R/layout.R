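#' Assemble a gene panel from several source lists
#'
#' Screening panels are typically drawn from several selection routes (e.g.
#' promoter-motif clusters, expression-predictor clusters, literature
#' curation). `assemble_panel()` takes a named list of character vectors and
#' returns their union with a provenance tag per gene. Genes appearing in
#' more than one source raise a warning (not an error) and keep the first
#' source they were seen in.
#'
#' @param source_lists Named list of non-empty character vectors of gene
#'   symbols.
#' @return A tibble with columns `gene` and `source`, one row per unique
#'   gene. For disjoint sources the number of rows equals the sum of the
#'   source sizes.
#' @examples
#' assemble_panel(list(motif = c("UBE2C", "PLK1"), literature = "SMO"))
#' @export
assemble_panel <- function(source_lists) {
  if (!is.list(source_lists) || length(source_lists) == 0) {
    stop("`source_lists` must be a non-empty named list of character vectors")
  }
  if (is.null(names(source_lists)) || any(names(source_lists) == "")) {
    stop("every source list must be named")
  }
  if (any(lengths(source_lists) == 0)) {
    stop("every source list must be non-empty")
  }
  tbl <- purrr::imap(source_lists, function(genes, src) {
    tibble::tibble(gene = as.character(genes), source = src)
  })
  tbl <- dplyr::bind_rows(tbl)
  dups <- unique(tbl$gene[duplicated(tbl$gene)])
  if (length(dups) > 0) {
    warning("duplicated genes across sources: ", paste(dups, collapse = ", "))
  }
  dplyr::distinct(tbl, .data$gene, .keep_all = TRUE)
}

#' Choose a near-square grid for a given number of spots
#'
#' Picks `rows` as the largest divisor of `n_spots` not exceeding
#' `sqrt(n_spots)`, so 275 spots become an 11 x 25 grid.
#'
#' @param n_spots Number of spots per array.
#' @return Integer vector `c(rows, cols)`.
#' @export
spot_grid_dims <- function(n_spots) {
  stopifnot(n_spots >= 1)
  r <- floor(sqrt(n_spots))
  while (r > 1 && n_spots %% r != 0) r <- r - 1
  c(as.integer(r), as.integer(n_spots / r))
}

#' Build a randomized plate layout for a reverse-transfection screen
#'
#' Distributes `sirnas_per_gene * replicates` sample spots per gene over the
#' arrays, at random positions, and fills per-array control spots (negative,
#' positive, mock) with the remainder left empty. Replicates of one siRNA
#' land on distinct random positions. The layout is deterministic under
#' `seed`.
#'
#' @param n_arrays Number of arrays (chambered slides).
#' @param spots_per_array Spots per array (e.g. 275).
#' @param genes Character vector of gene symbols.
#' @param sirnas_per_gene siRNA constructs per gene (default 2).
#' @param replicates Replicate spots per siRNA (default 4).
#' @param controls Named integer vector of per-array control spot counts;
#'   names among `negative_control`, `positive_control`, `mock`. Use
#'   `c()`/`NULL` for no controls.
#' @param grid_dims `c(rows, cols)` of the spot grid, or `NULL` to pick a
#'   near-square factorization of `spots_per_array`.
#' @param seed Integer seed controlling the random placement.
#' @return A tibble with one row per spot: `array_id`, `row`, `col`,
#'   `gene`, `sirna`, `replicate`, `role`.
#' @examples
#' layout <- build_layout(1, 20, genes = c("UBE2C", "PLK1"), seed = 1)
#' table(layout$role)
#' @export
build_layout <- function(n_arrays, spots_per_array, genes,
                         sirnas_per_gene = 2, replicates = 4,
                         controls = c(negative_control = 8,
                                      positive_control = 8,
                                      mock = 10),
                         grid_dims = NULL, seed = 1) {
  n_arrays <- as.integer(n_arrays)
  spots_per_array <- as.integer(spots_per_array)
  genes <- as.character(genes)
  n_sample <- length(genes) * sirnas_per_gene * replicates
  n_ctrl_per_array <- if (length(controls)) sum(controls) else 0L
  capacity <- n_arrays * spots_per_array
  if (n_sample + n_arrays * n_ctrl_per_array > capacity) {
    stop("capacity exceeded: ", n_sample, " sample spots + ",
         n_arrays * n_ctrl_per_array, " control spots > ",
         capacity, " available spots")
  }
  if (is.null(grid_dims)) grid_dims <- spot_grid_dims(spots_per_array)
  if (prod(grid_dims) < spots_per_array) {
    stop("grid_dims too small for spots_per_array")
  }

  grid <- tidyr::expand_grid(
    array_id = seq_len(n_arrays),
    row = seq_len(grid_dims[1]),
    col = seq_len(grid_dims[2])
  )
  grid <- dplyr::group_by(grid, .data$array_id)
  grid <- dplyr::slice_head(grid, n = spots_per_array)
  grid <- dplyr::ungroup(grid)

  old <- .Random.seed_exists()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)

  grid$role <- "empty"
  grid$gene <- NA_character_
  grid$sirna <- NA_character_
  grid$replicate <- NA_integer_

  # per-array control placement
  if (n_ctrl_per_array > 0) {
    for (a in seq_len(n_arrays)) {
      idx <- which(grid$array_id == a)
      pick <- sample(idx, n_ctrl_per_array)
      grid$role[pick] <- rep(names(controls), times = controls)
    }
  }
  # sample spots on the remaining positions, shuffled globally
  free <- which(grid$role == "empty")
  pick <- sample(free, n_sample)
  assign_tbl <- tidyr::expand_grid(
    gene = genes,
    sirna_i = seq_len(sirnas_per_gene),
    replicate = seq_len(replicates)
  )
  grid$role[pick] <- "sample"
  grid$gene[pick] <- assign_tbl$gene
  grid$sirna[pick] <- paste0(assign_tbl$gene, "_si", assign_tbl$sirna_i)
  grid$replicate[pick] <- assign_tbl$replicate
  dplyr::arrange(grid, .data$array_id, .data$row, .data$col)
}

# Save/restore the global RNG state so seeded helpers do not clobber the
# caller's stream.
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Derive a per-spot RNG seed from plate coordinates and a master seed
#'
#' Gives every spot its own reproducible random stream. The result is a
#' positive integer below 2^31.
#'
#' @param array_id,row,col Spot coordinates (vectors recycle).
#' @param seed Master integer seed.
#' @return Integer vector of derived seeds.
#' @export
spot_seed <- function(array_id, row, col, seed) {
  h <- (as.numeric(array_id) * 2654435761 +
          as.numeric(row) * 40503 +
          as.numeric(col) * 9973 +
          as.numeric(seed) * 97) %% 2147483629
  as.integer(h + 1)
}
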