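---
title: "Phenotype kinetics from time-lapse RNAi screens: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotype kinetics from time-lapse RNAi screens: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitokin)
```

mitokin analyses image-based, time-lapse siRNA knockdown screens of
H2B-GFP-labelled nuclei: populations of cells imaged in hundreds of
reverse-transfection spots for five days, one greyscale nucleus-channel
snapshot per spot roughly every 40 minutes. The scientific question it
serves is temporal: not just *whether* a knockdown kills cells, but
*when* relative to mitosis — death during mitotic arrest and directly
after mitosis are the signatures of the most attractive anti-mitotic
drug targets. This vignette explains the models behind each stage, the
defaults and their units, what the synthetic-data generator does and
does not emulate, and the numerical choices that are easy to get subtly
wrong.

## The synthetic screen generator

No raw screen of this kind is publicly downloadable, so the package
ships a ground-truthed generator used by every test and by the
reproduction script. It is first-class, tested code, not a fixture.

**Population model.** Each spot holds an exponentially proliferating
population simulated at the acquisition interval. A cell's generation
time is drawn from a normal distribution truncated below at half its
mean; the default spread (sd = 10% of the mean) lets transfection-induced
synchrony decay over successive division waves, which is what makes the
population's interphase counts oscillate at the cell-cycle period for the
first two to three cycles. Presets fix the mean generation time at 35 h
(`"SH-EP"`) and 31 h (`"SK-N-BE(2)-C"`). The visible mitosis duration
defaults to one acquisition interval (~40 min): at this sampling rate a
division is typically caught in a single snapshot, and the first frame
of each daughter is still labelled `mitosis` because its chromatin has
not yet decondensed. Every live cell also carries a basal death hazard
(default 0.0015 per hour): real screens show background apoptosis in
every spot, and without it the cell-death channel of unperturbed spots
would be identically zero and its plate normalization degenerate.

**Knockdown archetypes.** `knockdown_effect()` implements the classic
fates of a mitotic-gene knockdown: `death_in_mitosis` (affected cells
arrest in mitosis, default 6 h, then die), `slippage_then_death` (arrest,
exit without division, die after an exponential lag, default mean 12 h),
`interphase_death`, `arrest` and `none`. Penetrance is a per-cell
Bernoulli draw made when the knockdown becomes active (default onset
24 h post seeding, the typical time scale for siRNA protein depletion)
and at birth for cells born later.

**Rendering.** `render_frame()` draws each cell by archetype: interphase
nuclei as smooth textured ellipses (~150 px² at the default geometry),
mitotic figures as brighter condensed plates or bilobed anaphase shapes
(~90–100 px²), freshly divided daughters as compact telophase nuclei of
roughly half the mother's footprint (~45 px², which is what makes the
area terms of split detection informative), dying cells as fans of
small bright fragments, and artifacts as unresolvable multi-ellipse
aggregates. Cells whose rendered masks overlap by more than 20% of the
smaller area are merged and flagged `artifact` in the truth table.
Rendering is bit-identical under a fixed seed, and every spot derives
its own stream from its plate coordinates (`spot_seed()`), so any spot
can be re-rendered in isolation.

**What the generator does not emulate.** No point-spread function,
vignetting or illumination gradients beyond the additive plate effects;
no focus drift; no cytoplasm channel; motion is a reflected random walk
(default 5 px/h), not directed migration; fragment dispersal of dead
cells is not modelled (fragment clusters persist). Passing tests
therefore demonstrate correctness of the analysis logic under the
model's statistical structure — proliferation, synchrony, spatial bias,
class imbalance, merging — not robustness to every optical artifact of
a real microscope.

## Segmentation and features

Nuclei are segmented by a region-adaptive threshold: a pixel is
foreground when it exceeds its local mean by `offset_k` local standard
deviations (window 51 px, `offset_k` 0.5, minimum component area 40 px).
The local rule finds dim and bright nuclei together, where any global
threshold set for the bright cells misses the dim ones. Touching cells
are split by a watershed on the Euclidean distance transform; objects
that remain larger than 3× the median object area are dense aggregates,
flagged `is_cluster` and excluded from single-cell interpretation.

Grey-value normalization maps every image's foreground histogram onto
the screen-wide mean signature — peak location plus left and right
widths at half maximum — by a piecewise-linear transform anchored at the
peak. Widths are measured on a lightly smoothed histogram with
interpolated half-maximum crossings; without smoothing the signature of
a sparse foreground is so noisy that the mapping fails to be idempotent.
Normalization runs before feature extraction; segmentation operates on
the same normalized frames.

The default feature vector (~70 features) covers intensity statistics,
morphology (area, perimeter, circularity 4πA/P², radius statistics,
eccentricity), Haralick co-occurrence texture, Zernike moment magnitudes
to radial order 9 (rotation invariant), a granulometry spectrum from
greyscale openings at disc diameters 3–11 px, and two-level Haar wavelet
sub-band energies. The set is configuration, not contract: classifier
quality is the testable property, and the tests assert rotation and
translation invariance of the vector rather than its length.

## Tracking and mitosis detection

Frame-to-frame correspondences minimize a combined cost — spatial
distance plus Euclidean distance on z-scored morphology (area, mean
intensity, circularity) — with each term normalized by its median over
candidate pairs inside a 25 px gate, matched greedily in ascending cost.
Single-frame gaps are bridged before a trajectory is closed.

Mitosis detection scores candidate mother/daughter-pair configurations
with a product of Gaussian terms: combined daughter area over mother
area (mode 1), daughter area asymmetry (mode 0), and the daughters'
intensity ratio to the mother (mode 1.2; ratios above the mode are not
penalized, since mitotic chromatin is brighter). The intensity
denominator is the mother's intensity *one frame earlier*, where it is
still an uncondensed interphase nucleus; this is the single most
effective guard against the classic false positive — two touching
interphase cells drifting apart, which reproduces the geometry of a
division exactly but not the brightness jump. Candidate daughters
dimmer than half the frame's mean object intensity are disregarded.
Accepted splits merge the mother branch with two daughter branches in
the trajectory forest.

## Classification, reliability and correction

The phenotype classifier is a one-against-one SVM with an RBF kernel.
Class imbalance is handled by weighting each sample of class c with
w_c = n_l/n_c (n_l the largest class size), so the largest class has
weight 1. Cost C and kernel width gamma are chosen on the grid
C = 2¹…2¹⁰, gamma = 2⁻¹⁶…2⁻⁶ (110 pairs) by seeded 10-fold
cross-validated class-weighted misclassification; ties prefer smaller C,
then smaller gamma — the smoother model. Performance estimates come from
a nested 5-fold outer loop that re-runs the entire grid search inside
each training split, so no test sample influences its own model.

Predicted labels are the machine's voting decision. The pairwise-coupled
posterior probabilities serve the reliability score r = |l₁−l₂|, the gap
between the two largest class likelihoods; objects with r ≤ 0.2 are
discarded from phenotype counting (they keep their identity so tracking
passes through them). The posteriors are not used as the label because
their Platt calibration is fitted on an internal random partition that
is not reproducible call-to-call, and for ambiguous objects its argmax
can disagree with the decision — exactly the objects the filter removes.

Three trajectory rules then repair the classifier's characteristic
confusions, in one R1→R2→R3 pass: R1 relabels every split mother and
both immediate daughters `mitosis` (no missed mitoses); R2 keeps a
mitosis label only with split, cluster-successor or death-successor
support within 2 frames, else corrects it to interphase (no spurious
mitoses); R3 keeps a cell-death label only if the immediate successor is
cell death and at least half the remaining branch is cell death (ties
count as death), else corrects to interphase. Artifact labels are never
touched. An object at the end of its branch has no successor because
observation stopped, so R3 treats the successor condition as vacuously
satisfied there; without this reading every terminal death frame would
be "corrected" and repeated passes would erode death runs from the back.
A known limitation remains: under heavy death burden with noisy labels,
re-applying the single pass still changes a small percentage of labels
(one frame per noise hole), so the pipeline applies the correction
exactly once, as specified.

## Plate normalization and phenotype kinetics

Counts of each phenotype class are normalized per plate and timepoint by
a B-score: the residual x − μ_row − μ_col + μ_plate (the unique additive
form with exactly zero row and column means) divided by the median
absolute deviation of those residuals, computed as median(|x − median|)
with no consistency constant. Residual MAD, rather than raw-value MAD,
keeps the scale coherent with what is being standardized. A plate whose
residuals are identically zero (perfectly additive) yields zeros with a
warning rather than NaNs.

Normalized traces are cut into 24 h time-frames shifted by 8 h — 13
frames across a 120 h screen — and integrated by the trapezoidal rule
against the actual acquisition timestamps (exact for the piecewise-linear
traces, and indifferent to the 35–40 min jitter of real schedules). The
AUC is the phenotype signal of the frame. Significance per gene, siRNA,
phenotype and frame comes from a one-sided Wilcoxon rank-sum test of the
four replicate spots against the reference population (all sample and
mock spots of the screen, excluding positive controls and the siRNA's
own replicates); the exact null is used automatically for small untied
groups. No multiple-testing correction is applied in candidate calling;
a gene-siRNA is flagged when some frame t₀ has p ≤ 0.05 for mitosis and
p ≤ 0.05 for cell death at t₀ or t₀+1 — death in, or directly after,
mitosis — and a gene is a candidate when any of its siRNAs is flagged
(an OR across siRNAs; both thresholds are inclusive).

Two supporting analyses share the machinery: control QC tests, per
frame, whether positive-control spots proliferate less than negative
controls (one-sided rank-sum on interphase signals), and
`overlap_enrichment()` gives the upper-tail hypergeometric probability
of the observed overlap between two screens' hit lists.

## Cell-cycle periodicity

Synchronized populations double in waves, so interphase counts carry the
cell-cycle period. The series (typically averaged over spots) is reduced
to 3 h integration frames — 40 frames for five days — and fitted with
f(t) = α·sin(2πt/P + δ) + m·t + c by Levenberg–Marquardt least squares.
The model is parameterized directly by the period P in hours. The fit is
started from the three strongest discrete-Fourier peaks of the linearly
detrended series (the single dominant bin is sometimes a residual trend
component), each at four phase offsets and with halved and doubled
periods; the restart with the lowest residual sum of squares wins. A fit
whose amplitude falls below the residual noise floor is flagged
unidentifiable rather than reported. For raw count series the package
fits log2 counts: exponential growth is linear in log2, so the division
staircase becomes an additive oscillation around the trend the model
already contains. The reproduction script measures the median fitted
period over 20 simulated SH-EP populations; it recovers the 35 h preset
to within about 1.5 h (slightly long, because discrete sampling delays
each division by up to one frame).

## Problem sizes and determinism

The shipped tests run entire small screens (a full 8 × 275-spot layout
at count level for candidate calling; rendered movies of 10–40 founder
cells over 45–90 h for segmentation, tracking and correction; 160
rendered patches for the nested CV), sizes chosen so the whole suite
exercises every stage end to end in a few minutes on one core. Every
stochastic component takes an explicit seed, per-spot streams derive
from plate coordinates, and the pipeline embeds an MD5 hash of its
configuration in every output table so downstream stages can refuse
inputs produced under a different configuration.
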