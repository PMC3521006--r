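#' Simulate phenotype counts for a whole screen
#'
#' Runs one population simulation per spot of a plate layout, with every
#' spot on its own reproducible random stream derived from its plate
#' coordinates. Sample spots of genes named in `effects` receive that
#' knockdown effect; positive-control spots receive `positive_effect`
#' (a fully penetrant death-in-mitotic-arrest phenotype, the behaviour of
#' classic spindle-gene controls); negative controls, mocks and all other
#' sample spots proliferate unperturbed. Empty spots carry no cells.
#' Optionally injects additive spatial edge effects per array.
#'
#' @param layout Plate layout from [build_layout()].
#' @param config A [sim_config()] describing each spot's population.
#' @param effects Named list of [knockdown_effect()]s keyed by gene symbol.
#' @param positive_effect Effect applied to positive-control spots.
#' @param bias `NULL` for none, or a list with `row_effects`/`col_effects`
#'   (e.g. from [edge_bias()]) applied to every array's counts.
#' @param seed Master integer seed.
#' @return Tibble with the layout columns plus `frame`, `time_h`,
#'   `interphase`, `mitosis`, `cell_death`.
#' @export
simulate_screen <- function(layout, config = sim_config(),
                            effects = list(),
                            positive_effect = knockdown_effect(
                              "death_in_mitosis", penetrance = 1),
                            bias = NULL, seed = 1) {
  no_effect <- knockdown_effect("none")
  spot_effect <- function(role, gene) {
    if (role == "positive_control") return(positive_effect)
    if (role == "sample" && !is.na(gene) && gene %in% names(effects)) {
      return(effects[[gene]])
    }
    no_effect
  }
  seeds <- spot_seed(layout$array_id, layout$row, layout$col, seed)
  pieces <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    if (layout$role[i] == "empty") next
    cnt <- simulate_population(config,
                               spot_effect(layout$role[i], layout$gene[i]),
                               seed = seeds[i], keep = "counts")
    pieces[[i]] <- dplyr::bind_cols(layout[rep(i, nrow(cnt)), ], cnt)
  }
  out <- dplyr::bind_rows(pieces)
  if (!is.null(bias)) {
    out <- inject_spatial_bias(out, bias$row_effects, bias$col_effects)
  }
  attr(out, "config") <- config
  out
}
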