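# mitokin

Phenotype kinetics from time-lapse, image-based RNAi screens of
H2B-GFP-labelled nuclei.

In a reverse-transfection screen, cells carrying a GFP-tagged histone
are seeded onto arrays of siRNA spots and imaged for five days at
roughly 40-minute intervals, one nucleus-channel snapshot per spot per
timepoint. Knocking down a gene that the cell needs for mitosis
produces a characteristic *temporal* signature: cells accumulate in
mitosis and then die, either during mitotic arrest or directly after
slipping out of it. mitokin implements the full analysis that turns
such movies into a ranked list of these candidate genes, together with
a ground-truthed synthetic-screen generator that stands in for the
microscope, so every stage is testable against known truth.

The pipeline, stage by stage:

* **Synthetic screens** — plate layouts (e.g. 8 arrays × 275 spots,
  2 siRNAs × 4 replicates per gene plus controls), branching-process
  population simulations with transfection synchronization and
  knockdown-effect archetypes, rendered nucleus images with per-pixel
  ground truth, and injected spatial (edge) plate effects.
* **Image processing** — grey-value histogram normalization onto the
  screen-wide mean signature; region-adaptive segmentation (local mean
  + k·sd); watershed splitting of touching nuclei with cluster
  flagging; per-nucleus features (intensity, shape, Haralick texture,
  Zernike moments, granulometry, wavelet energies).
* **Tracking** — frame-to-frame linking by combined spatial/feature
  cost, single-frame gap closing, and mitosis (cell-splitting)
  detection by a Gaussian-product likelihood over mother/daughter areas
  and intensities.
* **Classification** — class-weighted (w_c = n_l/n_c) one-against-one
  SVM-RBF over interphase / mitosis / cell death / artifact, grid
  search C = 2¹…2¹⁰, γ = 2⁻¹⁶…2⁻⁶ in nested cross-validation, and a
  reliability filter that discards predictions with posterior gap
  r = |l₁−l₂| ≤ 0.2.
* **Trajectory correction** — three rules that repair
  mitosis/interphase and death/interphase confusions using tracking
  context (split events, cluster successors, death runs).
* **Kinetics** — B-score plate normalization (row/column effect
  removal, residual-MAD scaling); 24 h signal windows shifted by 8 h
  (13 time-frames over 120 h) integrated by the trapezoid rule;
  one-sided Wilcoxon rank-sum tests of replicate spots against the
  screen population; candidate calling by the death-in-or-after-mitosis
  rule (mitosis significant at t₀, death at t₀ or t₀+1, p ≤ 0.05);
  control QC; hypergeometric overlap enrichment between screens; and
  cell-cycle period estimation by a sinusoid-plus-trend fit to
  synchronized interphase dynamics.

## Worked example

A small synthetic screen: six genes on one 77-spot array, one of them
(`G01`) planted with a fully characteristic death-in-mitotic-arrest
phenotype at 90% penetrance.

```r
library(mitokin)
library(dplyr)

cfg <- pipeline_config(
  genes    = sprintf("G%02d", 1:6),
  n_arrays = 1, spots_per_array = 77,
  controls = c(negative_control = 4, positive_control = 4, mock = 4),
  effects  = list(G01 = knockdown_effect("death_in_mitosis",
                                         penetrance = 0.9)),
  sim      = sim_config(n_cells_initial = 25),
  image_spots = 0, seed = 7)

res <- run_pipeline(cfg, quiet = TRUE)

filter(res$candidates, candidate)
#> # A tibble: 1 × 4
#>   gene  candidate sirnas_flagged    t0
#>   <chr> <lgl>              <int> <int>
#> 1 G01   TRUE                   1     3

glance(res$period)
#> # A tibble: 1 × 6
#>   period_h amplitude   rss sigma n_frames identifiable
#>      <dbl>     <dbl> <dbl> <dbl>    <int> <lgl>
#> 1     35.7     0.229 0.496 0.119       40 TRUE
```

The planted gene — and only the planted gene — is called as a
candidate: its mitosis signal is significantly elevated at time-frame
t₀ = 3 (the 16–40 h window, right after the 24 h knockdown onset) with
cell death following in the same or next frame. The periodicity fit on
the screen-averaged interphase counts recovers a 35.7 h cell cycle from
the synchronized division waves (the simulation preset divides every
35 h). Per-frame p-values live in `res$profiles`:

```r
head(filter(res$profiles, gene == "G01", phenotype == "cell_death"), 4)
#> # A tibble: 4 × 6
#>   gene  sirna   phenotype  time_frame n_replicates        p
#>   <chr> <chr>   <chr>           <int>        <int>    <dbl>
#> 1 G01   G01_si1 cell_death          1            4 0.897
#> 2 G01   G01_si1 cell_death          2            4 0.829
#> 3 G01   G01_si1 cell_death          3            4 0.238
#> 4 G01   G01_si1 cell_death          4            4 0.000262
```

— background-level death before the knockdown acts, then a sharp
elevation once arrested cells start dying. `res$qc` reports the
control check (positive controls proliferate significantly less than
negative controls in 10 of 13 time-frames here; the earliest frames
predate the knockdown onset). `autoplot(res$period)`,
`plot_plate(res$bscore)` and `plot_phenotype_profile(res$profiles)`
draw the standard figures, and `run_pipeline(cfg, out_dir = ...)`
writes every stage as CSV with an embedded configuration hash.

The imaging stages (rendering, segmentation, tracking, classification,
correction) run on `image_spots > 0` spots; the methods vignette
(`vignettes/mitokin-methods.Rmd`) documents the models, defaults and
numerical choices of every stage.

A thin command-line front end is installed with the package
(`system.file("cli", "mitokin", package = "mitokin")`) with subcommands
`simulate`, `score`, `candidates`, `qc`, `periodicity` and `run`.

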