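---
title: "Phenotyping selfish polysaccharide uptake: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping selfish polysaccharide uptake: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Marine bacteria process polysaccharides in two distinct ways. *External
hydrolyzers* cleave the polymer outside the cell with secreted or
surface-attached enzymes, releasing low-molecular-weight products into the
water, where anyone can take them up. *Selfish* bacteria bind the polymer at
the outer membrane, clip off large fragments, and pull them into the
periplasm before further hydrolysis, losing little to the surroundings.
Incubating a water sample with a fluorescently labeled polysaccharide
(FLAPS) makes both strategies measurable: selfish cells accumulate label in
the periplasm and light up under the microscope, while external hydrolysis
shifts the substrate's molecular-weight distribution in the filtrate.

`flapsphenotyper` implements the downstream quantitative workflow for such
incubations:

1. **Image analysis** — count DAPI-stained cells, decide per cell whether it
   co-localizes with FLAPS (and with a FISH probe and/or pigment
   autofluorescence), and convert counts to volumetric abundances.
2. **Hydrolysis rates** — bin gel-permeation chromatograms of the filtrate
   into molecular-weight classes and convert the class shift over time into
   a monomer-equivalent rate, with a killed-control correction.
3. **Flow cytometry** — place a fluorescence gate from an unamended control
   community and score the FLAPS-positive event fraction.
4. **Simulation** — generate ground-truthed synthetic fields of view,
   chromatogram series, and event tables so that every step above can be
   validated against known truth.

## Cell classification model

A *cell* is a connected component in the DAPI channel that passes an area
filter. Classification of each cell uses co-localization evidence from the
other channels:

- **FLAPS-positive**: the best-overlapping FLAPS object covers at least 30%
  of the cell's DAPI mask **and** has a signal-to-background ratio (SBR,
  mean object intensity over the median intensity of non-object pixels) of
  at least 1. Both thresholds are inclusive minima and configurable
  (`phenotype_thresholds()`).
- **FISH-positive / AUTO-positive**: same 30% overlap rule on the FISH and
  autofluorescence channels.
- **Phenotype**, in order of precedence: `cyanobacterium` when AUTO- and
  FLAPS-positive (pigmented cells mimic substrate staining and are excluded
  from selfish-uptake calculations); `flaps_fish_cell` when FLAPS- and
  FISH-positive (all three signals overlap); `flaps_cell` when only
  FLAPS-positive; otherwise `unstained_cell`.
- **Background rejection**: FLAPS objects that overlap no DAPI object at the
  30% level are non-cell substrate particles. They never enter cell counts.

The overlap denominator is the DAPI mask (cell-centric). The alternative —
the FLAPS object's own area — would make a large diffuse deposit grazing a
cell count as weakly overlapping and a tiny speck inside a cell count as
fully overlapping; for classifying *cells*, the cell is the natural
reference. This is a package convention; the threshold value itself is the
field's customary 30%.

The substrate channel is acquired at three exposures (10, 35, 140 ms by
default) because staining intensity spans orders of magnitude: dim cells
need the long exposure, bright cells saturate it. Each exposure is segmented
separately and the series is consolidated by `merge_exposures()`: detections
whose centroids lie within 0.5 µm, or whose masks intersect, are one
physical object, represented by the longest *unsaturated* exposure
(saturation flag: ≥1% of object pixels at ≥98% of `bit_max`), falling back
to the shortest exposure when all saturate. Both the saturation rule and the
merge radius are package decisions — the upstream acquisition protocol only
motivates using several exposures — and both are configurable.

Red-excited FISH staining can bleed into the FLAPS channel and create false
positives; `correct_crosstalk()` subtracts a configurable fraction of the
FISH raster from each FLAPS raster (clipped at zero) before segmentation.
The default coefficient is 0, i.e. trust the optical separation unless told
otherwise.

### Quantification

For a pooled sample over *n* fields of view:

- `total_cells` counts every DAPI object, including cyanobacteria.
- `frac_flaps_pos = n_flaps_pos / (total_cells − n_cyanobacteria)`:
  autofluorescent cells leave both numerator and denominator, implementing
  their exclusion from selfish-uptake calculations. Whether the field's
  denominators include cyanobacteria is rarely stated in publications; this
  package's convention is explicit and configurable only by filtering the
  record table.
- `cells_per_L = (mean cells per FOV) × (filter area / FOV area) / volume
  filtered` — the standard epifluorescence filter-count conversion.
- The 95% interval on the stained fraction is the Wilson score interval
  (computed through `stats::prop.test` without continuity correction), which
  behaves well for small counts and fractions near 0, unlike the Wald
  interval.

`timecourse_summary()` flags intervals where the stained fraction falls
while cell numbers rise: substrate split between daughter cells dilutes
per-cell fluorescence after division, so such a drop need not mean a loss
of selfish activity. The flag is advisory; the package does not correct for
it.

## Hydrolysis rate model

Gel-permeation chromatography maps elution volume to molecular weight
through a log-linear calibration, `log10(MW) = a + b·V` with `b < 0`
(`calibrate_mw()`, least squares through the standards). A chromatogram is
integrated per molecular-weight class with the trapezoid rule on its native
elution grid — no resampling, so the result is deterministic — and
normalized to class fractions (`bin_chromatogram()`). Class boundaries are
user inputs: they depend on the substrate and column and are not universal
constants. The defaults (`Inf, 3000, 800, 250, 0` Da) suit a ~6 kDa parent
polysaccharide hydrolyzed toward oligo- and monosaccharides.

Over an interval $(t_a, t_b)$ the rate is the monomer-equivalent mass that
arrived in classes below the parent class:

$$\mathrm{rate} = \frac{\sum_{i>\mathrm{parent}} \max(0,\; f_i(t_b) - f_i(t_a))
\cdot C_\mathrm{monomer}}{t_b - t_a}$$

with $C_\mathrm{monomer}$ the amendment concentration in nmol monomer
equivalent L⁻¹ (3500 for the standard 3.5 µM incubation). Because fractions
are normalized, the rate is invariant to uniform rescaling of the raw
fluorescence signal. When a killed-control series is supplied, the
control's class-wise drift over the interval is subtracted from the live
endpoint fractions (clipped at zero, renormalized) first, so abiotic shifts
cancel; a control identical to the live series yields a rate of exactly 0
(gains below 1e-9 are treated as floating-point residue). Rates are
reported both against the first timepoint and between consecutive
timepoints, since published rates often leave the baseline implicit; both
views are in the output table.

The classical refinement of weighting product classes by the number of
enzymatic cuts needed to produce them is deliberately **not** applied: it
lives in the older methodological literature and is not part of this
package's model. The unweighted product-gain definition is stated here so
users holding that reference can apply their own per-class weights to the
`per_class_deltas` attribute.

## Cytometry gating model

Events below the instrument's electric threshold (17,000 FSC-H by default)
are discarded. The fluorescence gate is the nearest-rank 0.999 quantile of
FL1-H among surviving events of a negative control — either the unamended
community or a fixed-and-inactivated sample with FLAPS added (to capture
unspecific binding); the computation is agnostic to which. Sample events
are positive when FL1-H *strictly* exceeds the gate, so a control gated
against its own quantile scores ≈ 0.1% positive — a built-in consistency
check. The 0.999 default is a package decision: published gates are drawn
as lines on plots without a stated rule, and a quantile rule makes the gate
reproducible and control-calibrated. At least 100 surviving control events
are required; fewer is a control-insufficiency error, not a silent gate.

No doublet gating (FSC-A/FSC-H) is performed; pulse-area columns are not
part of the supported input.

## What the simulator emulates — and what it does not

`simulate_field()` renders, on a 12-bit camera model (`bit_max = 4095`,
0.1 µm pixels):

- rod-shaped cells as filled ellipses (default 1.5 × 0.7 µm) placed
  uniformly without contact (a guard margin keeps masks disconnected under
  8-connectivity; bounded retries, then a placement error — never silent
  overlap);
- **halo** staining as the cell ellipse dilated by one pixel: in 2-D
  projection a periplasmic shell covers the whole cell body, which is what
  makes the 30% DAPI-overlap rule attainable (a bare ring strictly outside
  the cell would overlap the DAPI mask by exactly 0 and no halo cell could
  ever be called positive);
- **polar** staining as caps of cell half-width radius at one or both poles,
  inside the footprint, so a single cap still covers ≈ 47% of the cell;
- per-cell FLAPS brightness from a log-normal law in counts · ms⁻¹, scaled
  linearly by exposure and clipped at `bit_max` — the brightest cells
  saturate the 140 ms exposure, exercising the merge rule;
- non-cell substrate particles (FLAPS, no DAPI), autofluorescent
  cyanobacteria-like cells (AUTO + FLAPS + DAPI), FISH-positive cells, an
  optional FISH→FLAPS crosstalk coefficient, and additive Gaussian camera
  noise (default sd 5 counts on a background of 60, a typical CCD read-noise
  scale).

Counts planted from fractions use round-half-away-from-zero applied once,
so truth counts are deterministic; selfish and autofluorescent pools are
drawn disjointly so the expected confusion matrix is diagonal. Identical
seeds give bit-identical rasters.

Not emulated: optical point-spread blur, 3-D structure, touching or
dividing cells, irregular particle morphology, uneven illumination, and
real staining-intensity distributions (no quantitative intensity data exist
for the staining patterns; the simulator's levels are free parameters).
Passing the recovery tests therefore shows the *scoring logic* is correct
under the stated signal model — it does not certify segmentation
performance on crowded or blurry real images, where touching cells are a
stated limitation (no watershed splitting is attempted).

`simulate_chromatogram_series()` builds each chromatogram as a sum of
Gaussian peaks: a parent peak plus one peak per product class at the
class's geometric-mean MW, with a fraction of the parent's area transferred
per timepoint. Total integrated signal is conserved by construction, so
mass balance can be asserted to 0.1%. Peak width (0.35 mL) and the default
class bounds keep peaks ≥ ~2.5 sd from the parent-class boundary; leakage
between *product* classes cancels in the rate sum, so recovery is accurate
to ≪1% (integration error only). `simulate_event_table()` draws FL1-H from
a two-component log-normal mixture with scatter independent of staining.

## Numerical choices

- Segmentation threshold: image median + 5 × MAD (`robust_background`), a
  robust rule for sparse-cell fields where the background dominates the
  histogram; Otsu is available for denser images. Foreground is strictly
  above the threshold, so a constant raster yields no objects.
- Connected components: compiled two-pass union-find, 8-connectivity by
  default, 4 available; verified against a brute-force BFS oracle in tests.
- Background estimate requires ≥ 100 non-object pixels; the median over a
  handful of pixels would be unstable. Objects over a zero background
  (possible in blank synthetic channels) get SBR = ∞ rather than an error.
- Area filters are expressed in µm² (defaults 0.1–20) so they are
  independent of pixel size.
- Ties/boundaries: all classification thresholds are inclusive (≥);
  quantiles are nearest-rank; counts from fractions round half away from
  zero.
- Seeded generators save and restore the caller's RNG state.

## Problem sizes used in the shipped validation

The test suite validates classification on all 16 evidence combinations at
the exact 0.30/1.0 boundaries; exact truth recovery on 20 noise-free
100-cell fields (256×256 px); fraction recovery of a planted 16% stained
fraction over 100 seeds × 45 fields × 50 cells (192×192 px) under default
camera noise, requiring the Wilson interval to cover the planted value in
≥95 seeds; hydrolysis-rate recovery within 1% of the analytic value for a
50% transfer over 24 h; cytometry recovery of a planted 30% positive
fraction over 100 seeds at 10,000 events; threshold-sweep monotonicity; and
byte-identical reproducibility of all generators and the full pipeline.
Field sizes for the large sweeps were chosen so that the planted per-field
counts are integers (0.16 × 50 = 8) and placement stays comfortably below
~25% occupancy.

## Known limitations

- Touching cells are not split; the simulator never places them, and real
  crowded filters will undercount.
- One FISH probe per field of view; multiplexing is out of scope.
- FISH signal-loss correction is not modeled (reported losses lack a
  correction model); probe-positive fractions are lower bounds.
- The hydrolysis model assumes the calibration holds across the full
  elution range and that class boundaries are chosen sensibly for the
  substrate; no peak deconvolution or column-spreading correction is done.
- Binary FCS files are not parsed; export events as delimited text.
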