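---
title: "Hexagonal-grid heterogeneity and immunogradient indicators: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hexagonal-grid heterogeneity and immunogradient indicators: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hexiz)
```

## Scope and data model

`hexiz` computes spatial biomarkers from two per-slide inputs that any
digital image analysis platform can produce: a *cell table* (one row per
detected cell: pixel coordinates, marker class, positivity flag) and a
*tissue label map* (a raster over tumor / stroma / background at a known
resolution, 0.5 μm/pixel by default, as in 20× whole-slide scans). Tissue
classification and cell segmentation themselves are upstream of this
package and out of scope.

All spatial computation happens on pointy-top hexagonal grids with axial
(q, r) indexing. Two grids are used: a coarse one for Ki67 intratumoral
heterogeneity and a fine one for the CD8 interface-zone analysis.

### Hexagon sizes and the "diameter" convention

The defaults encode hexagons quoted both in pixels and micrometres: a
1050-pixel circumcircle diameter for the Ki67 grid and a 260-pixel diameter
for the CD8 grid. At 0.5 μm/pixel these readings give side lengths of
exactly 262.5 μm and 65 μm respectively — the only interpretation under
which the pixel and micrometre figures are mutually consistent (if
1050 pixels were the side length, it would be 525 μm, not 262.5 μm). We
therefore read "diameter" as the circumcircle diameter, i.e. twice the
side, and document this in `hex_config()`. A hexagon of side *s* has area
(3√3/2)·s²; for s = 65 μm that is ≈ 0.010977 mm², the denominator scale of
all density indicators.

The grid origin is offset uniformly at random within one hexagon pitch
(drawn from an explicit seed), so no tissue structure is privileged by the
grid alignment. Indicator stability under re-randomized offsets is a tested
property (coefficient of variation of the main CD8 indicators ≤ 15% over 20
offsets; observed values are in the low single digits to ≈ 8%).

Point-in-hexagon assignment uses fractional axial coordinates with cube
rounding, which partitions the plane: each cell lands in exactly one
hexagon, and totals are conserved (tested by round-trip assignment).
Tissue-area fractions are computed by pixel-centre membership rather than
polygon clipping, matching the raster precision of the input; tests accept
a 0.02 pixelation tolerance against the analytic fraction for hexagons
straddling a straight boundary.

## Ki67 intratumoral heterogeneity

Per hexagon of the coarse grid, the Ki67 positivity percentage is computed
over tumor cells; hexagons with fewer than 50 cells are treated as
insufficiently sampled and dropped. Percentages are ranked into ten
intervals — [0, 10], (10, 20], …, (90, 100] — and a co-occurrence matrix is
accumulated over unordered pairs of retained hexagons within one hexagonal
step of each other (the neighbourhood radius is exposed as a knob; default
1). Each pair increments both (i, j) and (j, i), so the matrix is symmetric
by construction, and it is normalized to sum to one. From it we compute
Haralick's indicators:

- entropy −Σ p ln p (with 0·ln 0 := 0), bounded by ln 100 ≈ 4.605;
- contrast Σ (i−j)² p, dissimilarity Σ |i−j| p;
- homogeneity as the inverse difference moment Σ p/(1+(i−j)²), Haralick's
  original form (the quantity is named but not defined in the motivating
  literature);
- energy Σ p².

The logarithm base is natural by default and configurable: reported
cohort-scale entropy values in the literature (means around 2.2–4.1) do not
disambiguate the base, so we fix and expose it rather than guess. Entropy
is the indicator passed to the survival layer; the other four are computed
and exported alongside.

## CD8 immunogradient across the tumor–stroma interface

On the fine grid, each hexagon carries tumor/stroma/background area
fractions. Edge detection looks for abrupt composition changes: along each
of the three grid axes, the difference in tumor fraction between a
hexagon's two opposite neighbours is compared against a threshold τ
(default 0.5; the motivating description is qualitative, so τ is exposed in
`edge_config()`). To keep the edge one hexagon thick we apply per-axis
non-maximum suppression — a hexagon is flagged only where its difference
magnitude is a local maximum along the triggering axis. Flagged hexagons
are then classified by the tissue on the low-tumor side: only tumor–stroma
transitions are retained (tumor–background transitions, e.g. the section
border, are discarded). On a simulated tumor disk this yields an edge count
within ±30% of the perimeter-over-pitch estimate 2πR/(√3·s).

Signed ranks follow from a breadth-first search over the 6-neighbour
adjacency restricted to non-background hexagons: |rank| is the hexagonal
distance to the nearest edge hexagon (verified exactly against an
independent BFS oracle), with the sign given by the hexagon's dominant
tissue class — tumor positive, stroma negative. Background-dominant
hexagons (background fraction > 0.5) are excluded. With several disjoint
tumor nests, ranks are computed against the union of all edge hexagons.
The interface zone retains ranks −4…+4: nine classes, a one-rank-wide
central edge.

Per-hexagon CD8⁺ density divides the count by the *analyzed tissue area*
(tumor + stroma, in mm²) rather than the full hexagon area, so
background-heavy hexagons at the section border are not artificially
diluted — an interpretation we flag, since the motivating description does
not state the denominator. Eight indicators summarize the zone:

- mean and SD of density in the stroma aspect (ranks −4…−1), edge (0) and
  tumor aspect (+1…+4);
- immunodrop ID = mean density at rank −1 / mean density at rank +1. If
  the denominator is zero with a positive numerator, a configured cap
  (default 100) is reported with a flag; 0/0 reports 1 with a flag;
- center of mass CM = Σ r·D̄ᵣ / Σ D̄ᵣ over per-rank *mean* densities
  (empty rank classes drop out of both sums). The one-sentence definition
  in the motivating literature leaves open whether per-rank totals or
  hexagon counts should weight the sum; we fix the mean-density form,
  isolate it in `center_of_mass()`, and note that stroma-skewed profiles
  give CM < 0, matching the negative cohort means reported for both breast
  cancer subtypes.

## Synthetic data: what it emulates and what it does not

`generate_tissue_map()` builds analytic geometries (half-plane, disk, blob
union, degenerate single-class canvases) standing in for pixelwise
tumor/stroma segmentation. `generate_cells()` draws Poisson point
processes on the label map:

- tumor cells homogeneous on the tumor region (default 2000 cells/mm², a
  realistic epithelial detection density at 20×);
- Ki67 positivity from a patch mosaic: seed points at about one per patch
  disk (default diameter 400 μm, on the scale of reported proliferation
  hotspots), each patch perturbing the base rate by Uniform(±spread)
  clamped to [0, 1], cells inheriting the probability of the nearest seed.
  Spread 0 recovers spatially uniform positivity. This one-knob mosaic
  produces the hotspot structure the entropy indicator targets, but it is
  a stand-in: no quantitative description of real Ki67 hotspot
  autocorrelation was available to fit;
- CD8⁺ cells with stromal intensity λ_S (default 800 cells/mm², within the
  reported cohort range of interface-zone stromal densities) and
  intratumoral intensity λ_S/κ · exp(−depth/decay), depth being the
  Euclidean distance transform from the tumor boundary. κ ≥ 1 is the
  stroma-to-tumor drop factor at the boundary; the default decay of
  4000 μm is deliberately shallow so that κ is identified by the
  immunodrop rather than confounded with the decay.

Passing recovery tests on these generators shows the pipeline measures
what the generators encode — gradient direction and magnitude, patch
contrast — not that it captures every feature of real tissue (no nuclear
morphology, staining artifacts, necrosis structure, or nest-size
distributions).

`generate_cohort()` simulates breast-cancer-specific survival from an
exponential proportional-hazards model over clinicopathological covariates
and indicator values with stated log-hazard coefficients (acting on
z-scored continuous covariates), administratively censored at 120 months
(follow-up restricted to ten years). The baseline rate is calibrated by
`uniroot` so the expected event fraction matches a target rate, default
13% — the scale of 33 deaths among 252 ER+HER2− patients that motivated
the design. Defaults for effect sizes (|log HR| 0.5–0.7 per SD) are chosen
so that effects are clinically plausible yet detectable at n = 250 with
~33 events.

## Survival layer

The optimal cutoff for each indicator scans all midpoints between
consecutive distinct values whose split leaves at least 10% of patients in
each group, minimizing the log-rank p (computed via `survival::survdiff`);
the scan agrees exactly with an exhaustive oracle by construction. The
reported p-values are *not* corrected for the multiplicity of the scan —
matching common optimal-cutpoint practice — so their type-I error is
inflated; this is deliberate and documented, and the null-calibration test
quantifies the effect at the screen level. Variables with p < 0.05 enter a
multivariable Cox model (partial likelihood, Efron ties, via
`survival::coxph`); separation and non-convergence raise explicit
diagnostics. Harrell's C is implemented in-package (ties in the predictor
count ½; a pair is comparable when the shorter observed time is an event)
and verified against an O(n²) enumeration and, on tie-free data, against
`survival::concordance`.

The combined prognostic score sums binary poor-prognosis indicators —
ER+HER2− model: nodal involvement, entropy above cutoff, tumor-aspect CD8
density below cutoff, immunodrop above cutoff (total 0–4 mapped to
low/intermediate/high as 0 / 1 / 2–4); TNBC model: tumor stage, entropy,
stroma-aspect CD8 density (total 0–3 mapped as {0,1} / 2 / 3). For the
TNBC mapping two inconsistent descriptions circulate in the motivating
literature; we adopt the three-indicator {0,1}/2/3 form and note the
discrepancy rather than resolving it. Componentwise boosting and
train/test model selection are non-goals; the univariate-screen →
multivariable-Cox path reproduces the reported modeling surface.

## Numerical choices and problem sizes

- Degenerate inputs fail loudly: no hexagon passing the 50-cell filter, no
  adjacent hexagon pair, no tumor–stroma interface, all-identical cutoff
  values, and too few events per covariate (events < covariates + 5) are
  errors, not silent NAs.
- Boundary cells on hexagon edges are resolved deterministically by cube
  rounding; ties in the cutoff scan resolve to the first minimum.
- Slide QC excludes slides with < 6 mm² of tumor by label-map pixel count;
  the demonstration and test slides are deliberately smaller (1–5 mm²
  canvases, 20-seed averages), chosen to exercise every code path at
  desk scale while keeping the full suite within minutes; QC is then
  bypassed explicitly with `run_qc = FALSE`.
- Recovery studies use 20 seeds per condition, cohort simulations 100
  replicates of n = 250; these sizes give Monte-Carlo error comfortably
  inside the stated tolerances (e.g. ±25% for κ recovery).

## Known limitations

- The patch mosaic and analytic geometries are caricatures of tissue; the
  generators exist to validate the measurement pipeline, not to simulate
  histology.
- Edge detection assumes the tissue map is reliable at hexagon scale;
  segmentation errors propagate directly into rank assignment.
- The optimal-cutoff p-values are anti-conservative by design (see above).
- Only CD8 is modelled as an immune marker; multi-marker gradients and
  per-nest stratified reporting are out of scope.
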