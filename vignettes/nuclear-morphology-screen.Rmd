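---
title: "Scoring imaging-based siRNA screens of nuclear size and shape"
author: "nucscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring imaging-based siRNA screens of nuclear size and shape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucscreen)
```

# The analysis problem

High-content siRNA screens for nuclear morphology knock down one gene per
well in 384-well plates (three independent oligos per gene, in separate
wells), stain nuclei with DAPI and antibodies against lamin A/C and lamin B1,
image dozens of fields per well, and ask which knockdowns change nuclear
shape, nuclear size, or lamin levels. The statistical core is a chain of
well-known steps whose details matter:

1. **Morphometry.** Nuclei are segmented from the DAPI channel; partial
   nuclei touching the field border are discarded. Per nucleus we record the
   cross-sectional area (a standard proxy for nuclear size in a single focal
   plane), the major/minor axis lengths, the perimeter, the circularity
   $c = 4\pi A / P^2$ (1 for a circle, smaller for blebbed or elongated
   shapes), and mean lamin A/C and lamin B1 intensities. Typically well over
   250 nuclei per well are analyzed.
2. **Per-well averaging.** Single-cell values are averaged per well.
3. **B-score per plate.** Each plate-by-feature matrix is decomposed by a
   two-way additive fit over the *library* wells only (control wells are
   scored against the fit but never inform it); the residuals are scaled by
   $1.4826 \times \mathrm{MAD}$ of the library residuals. This removes
   additive row/column plate artifacts (dispenser gradients, edge effects).
4. **Robust Z per replicate.** B-scores of all library wells of one
   biological replicate are pooled; every well's Z is
   $(b - \mathrm{median}) / (1.4826 \times \mathrm{MAD})$ of that reference.
5. **Replicate averaging.** Z-scores of the two replicates are averaged per
   oligo.
6. **Gene calls.** The gene's score per feature is the median Z over its
   three oligos; for three oligos, "median beyond a threshold" is exactly
   the "at least two of three oligos beyond it on the same side" rule. Hits
   are directional and thresholds inclusive: shape hits at median
   $Z \le -1.5$ (reduced circularity), size hits at $|Z| \ge 1.5$ on area
   (up and down reported separately), lamin level hits at $Z \le -1.5$.
7. **Viability exclusion.** Genes whose cell-count median Z is $\le -2$
   (scored through the identical chain) are removed from all hit lists --
   cell death and cell-cycle arrest confound morphology -- but keep their
   flags for audit.

The package implements this chain end to end, plus a fully ground-truthed
synthetic screen generator so every stage is testable without any external
data, and the two-sample statistics (Kolmogorov-Smirnov, Spearman) used for
single-cell distribution comparisons between engineered cell lines.

# What the generator emulates

`buildLibraryLayout()` reproduces the screen structure: 384-well plates
(`A01`..`P24`), three oligos per gene in separate wells (867 genes x 3 =
2601 library wells in the full design), per-plate negative, lethal
(transfection control), and LMNA positive-control wells, and a seeded
gene/oligo-to-well permutation. Library wells are spread evenly over the
minimum number of plates: a nearly empty trailing plate would make the
two-way median fit ill-posed (single-cell rows and columns absorb real
effects), which is a property of the estimator, not of the biology.

`sampleGroundTruth()` draws the designed truth: per-gene additive shifts of
the per-cell feature distributions in units of the baseline SD,
cytotoxicity multipliers in (0, 1] on the expected cell count, and per-plate
additive artifacts -- row-linear and column-linear gradients plus an edge
offset. Gradients are row/column-separable *by design*: they are exactly the
structure the B-score is supposed to remove, so simulations with gradients
up to one population SD test that removal directly. The edge offset is not
exactly row+column separable (corners), which leaves a small realistic
imperfection.

`simulateCells()` draws per-nucleus features as baseline + gene effect +
plate effect + Gaussian cell noise. Choices worth knowing:

* **Cell counts** are negative binomial (default mean 300, dispersion 20,
  giving a realistic ~23% CV), times the cytotoxic multiplier; lethal
  control wells get at most 5 cells. The default mean of 300 makes most
  wells exceed 250 analyzed nuclei, the scale at which per-well means are
  stable.
* **Circularity** is clipped to (0, 1]; the per-nucleus perimeter is derived
  from area and circularity so the defining identity holds exactly in
  tabular data.
* **Baseline values** (`defaultBaseline()`): circularity 0.88 +/- 0.05, area
  2500 +/- 450 px^2 (a ~28 px radius nucleus at a typical 20x/2x-binned
  pixel scale), length 72 +/- 9, width 46 +/- 6 px, lamin intensities
  ~1100-1200 arbitrary units. These are ordinary fibroblast-like values at a
  convenient pixel scale; all are configurable.
* **Seeding**: a master seed spawns an independent child stream per
  (replicate, plate, well) through a deterministic hash, so any subset of
  the screen regenerates bit-identically in isolation.

The renderer (`renderField()`, `sampleFieldShapes()`, `shapesFromRecords()`)
draws nuclei as radially Fourier-perturbed ellipses: with zero perturbation
the boundary is an exact ellipse; "lobulation" terms with harmonic $k \ge 2$
and amplitude below 0.5 produce blebbed and multilobed outlines whose area
and perimeter are computed from the analytic boundary polygon (720 vertices;
area and perimeter change by well under 0.1% when the vertex count doubles).
`shapesFromRecords()` inverts the morphometry -- aspect from length/width,
lobulation amplitude root-found to match circularity, then scaled to match
area -- so rendered fields reproduce a tabular simulation's ground truth and
the image path of the pipeline can be compared with the tabular path on the
same genes.

What the generator does *not* emulate: point-spread functions, chromatic
aberration, uneven illumination, focus drift, touching/overlapping nuclei,
cell-cycle structure, or segmentation errors on real stains. Passing tests
therefore demonstrate the correctness of the *statistics and the estimator
chain*, and the internal consistency of the image path, not robustness to
every real-microscopy artifact.

# Morphometry choices

* **Threshold**: Otsu's method on the DAPI channel by default (the original
  analysis used a proprietary commercial pipeline whose segmentation is
  unstated); fixed thresholds are available. Touching nuclei are not split
  by default -- the generator enforces non-overlap, and watershed splitting
  of real data is out of scope.
* **Perimeter**: a 4-direction Crofton estimator computed from the histogram
  of 2x2 pixel configurations. Naive boundary-pixel counting inflates the
  perimeter of a digital disk by several percent and biases circularity low;
  the Crofton estimator measures a radius-50 disk within ~0.4% (and ~1.2% at
  radius 25), which keeps the digital circle's circularity inside the +/-2%
  contract the tests enforce.
* **Length/width** are the major/minor axis lengths of the best-fit ellipse
  from the region's second central moments (with the 1/12 pixel-footprint
  correction); the source analysis does not define them, and this is the
  standard regionprops convention.
* A nucleus "touches the border" iff any of its pixels lies in the first or
  last row or column; such nuclei are removed entirely.

# Numerical choices in the scoring chain

**Median polish initialization.** Tukey's alternating median polish has a
continuum of fixed points: two converged fits can differ by an additive
row-plus-column matrix whose row and column medians vanish. Consequently the
classical zero-initialized polish is *not* exactly invariant under additive
row/column shifts of the data -- on random 16x24 plates the attained
B-scores can differ by several tenths of a unit depending on the artifact
realization, defeating the purpose of the B-score. `medianPolish()`
therefore initializes the effects at the least-squares two-way fit
(alternating masked mean sweeps run to convergence) before the median sweeps
start. The LS projection maps additively shifted data to *identical*
starting residuals, and each subsequent median sweep is a deterministic
function of those residuals, so the final residuals -- and hence B-scores --
are invariant to additive plate gradients at machine precision. The median
sweeps re-absorb the LS step's sensitivity to outliers: a single spiked cell
ends up entirely in its own residual, as in the classical polish.
`init = "zero"` restores the classical algorithm (it agrees with
`stats::medpolish` and is kept as the cross-checked reference).

Other conventions: polish runs up to 100 sweeps to a 1e-9 effect-update
tolerance (the residual decomposition, not the iteration count, is the
contract); the MAD carries the Gaussian-consistency constant 1.4826 both in
the B-score and the robust Z (the convention of the standard screen-analysis
tooling; configurable); fully masked rows/columns get zero effects and are
flagged; a plate whose library-residual MAD is zero is an error naming the
plate, with an explicit opt-in fallback to raw residuals; the robust-Z
reference set is all library wells of one replicate, pooled across plates,
and control wells are scored against it but never enter it.

**Replicate-averaged null spread.** Per replicate, library Z-scores have
median 0 and scaled MAD 1 *by construction*. The mean of two independent
standardized replicates has spread $1/\sqrt{2} \approx 0.707$, so per-oligo
`z_mean` is tighter than N(0, 1); null-rate computations in the tests use
the simulation's own empirical tail probability rather than a nominal
Gaussian.

**Gene-level edge cases.** Genes with exactly two scored oligos use the mean
of the pair as the median and require *both* oligos beyond the threshold
(the two-of-three spirit), flagged `reduced_evidence`; genes with fewer than
two scored oligos are unscorable. The viability cutoff is implemented
inclusively ($\le -2$), the stricter of the two natural readings, and is
config-exposed, as is two-sided shape calling (decreased circularity only by
default). The cell-number exclusion is applied uniformly to all hit classes.

**KS test.** D is the supremum of the ECDF difference over the pooled unique
points (ties allowed). The p-value uses the asymptotic Kolmogorov series
with effective size $n_x n_y / (n_x + n_y)$ -- adequate at the hundreds of
cells per condition this assay produces -- switching to the exact null
distribution (conditional on ties) when $n_x n_y \le 10^4$. Empirical type-I
error at $\alpha = 0.05$ over 2000 null pairs of n = 200 sits near 0.046.

# Problem sizes used by the tests

The canonical recovery simulation is 500 genes x 3 oligos x 2 replicates at
~300 cells per well with row/column gradients up to 1 SD, 20 designed shape
hits at -3 SD and 10 cytotoxic genes at 0.2x cell count -- about 0.9 million
simulated nuclei, scored in seconds. Unit tests use dense small plates
(96-well format, 20-30 genes, 25-60 cells per well): B-scoring needs several
library wells per row and column to be well posed, so toy screens use small
dense plates rather than sparse 384-well ones. The image-path consistency
check renders ~1500 nuclei across ~190 fields and verifies that gene-level
calls from segmentation + measurement match the tabular path exactly at
large (>= 3 SD) designed effects.

# Known limitations

* The B-score removes additive, row/column-separable artifacts; bowl-shaped
  or radial artifacts (and the non-separable part of edge offsets) are
  reduced but not eliminated. No loess/spatial smoothing alternative is
  provided.
* Per-well means discard single-cell shape heterogeneity; the KS machinery
  in `compareConditions()` exists precisely for questions where the
  population distribution matters.
* The renderer's non-overlap placement sidesteps nucleus clumping, so the
  segmentation defaults (no watershed) should be revisited on real,
  confluent material.
* Cytotoxicity enters only as a count multiplier; dying cells' altered
  morphology is not modeled, so the viability exclusion is exercised on
  counts alone.
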